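# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / direct enumeration so they share no code path with the
# package implementations they check.

# small genotype matrix from an explicit integer matrix
toy_matrix <- function(geno, species = NULL, tag = NULL, pos = NULL,
                       qd = NULL, reads = NULL, n_alleles = NULL,
                       lat = NULL, lon = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("A%02d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("L%02d", seq_len(ncol(geno)))
  loci <- data.frame(locus = colnames(geno))
  if (!is.null(tag)) loci$tag <- tag
  if (!is.null(pos)) loci$pos <- pos
  if (!is.null(qd)) loci$qd <- qd
  if (!is.null(n_alleles)) loci$n_alleles <- n_alleles
  acc <- data.frame(accession = rownames(geno))
  if (!is.null(species)) acc$species <- species
  if (!is.null(reads)) acc$reads <- reads
  if (!is.null(lat)) acc$lat <- lat
  if (!is.null(lon)) acc$lon <- lon
  genotype_matrix(geno, loci = loci, accessions = acc)
}

random_toy <- function(seed, n_groups = 3, n_per = 4, n_loci = 20,
                       missing_rate = 0) {
  set.seed(seed)
  n <- n_groups * n_per
  g <- matrix(sample(0:2, n * n_loci, replace = TRUE), n, n_loci)
  if (missing_rate > 0)
    g[matrix(runif(n * n_loci) < missing_rate, n, n_loci)] <- NA
  toy_matrix(g, species = rep(paste0("g", seq_len(n_groups)), each = n_per))
}

# --- naive diversity oracle: direct per-locus enumeration ------------------
naive_group_indices <- function(geno, labels) {
  groups <- unique(labels)
  res <- list()
  for (g in groups) {
    sub <- geno[labels == g, , drop = FALSE]
    ne <- i_sh <- ho <- he <- numeric(ncol(sub))
    fis <- rep(NA_real_, ncol(sub))
    poly <- typed <- logical(ncol(sub))
    for (l in seq_len(ncol(sub))) {
      calls <- sub[, l][!is.na(sub[, l])]
      if (!length(calls)) next
      typed[l] <- TRUE
      p <- sum(calls) / (2 * length(calls))
      q <- 1 - p
      ne[l] <- 1 / (p^2 + q^2)
      i_sh[l] <- -(ifelse(p > 0, p * log(p), 0) + ifelse(q > 0, q * log(q), 0))
      ho[l] <- mean(calls == 1)
      he[l] <- 1 - p^2 - q^2
      if (he[l] > 0) fis[l] <- (he[l] - ho[l]) / he[l]
      poly[l] <- p > 0 && p < 1
    }
    res[[g]] <- list(Ne = mean(ne), I = mean(i_sh), Ho = mean(ho),
                     He = mean(he), Fis = mean(fis, na.rm = TRUE),
                     P_pct = 100 * sum(poly) / sum(typed))
  }
  res
}

# --- naive allele classification over (locus, allele, group) triples -------
naive_classify <- function(geno, labels) {
  groups <- unique(labels)
  out <- list()
  for (l in seq_len(ncol(geno))) {
    for (allele in c("ref", "alt")) {
      freqs <- sapply(groups, function(g) {
        calls <- geno[labels == g, l]
        calls <- calls[!is.na(calls)]
        if (!length(calls)) return(NA_real_)
        alt_f <- sum(calls) / (2 * length(calls))
        if (allele == "alt") alt_f else 1 - alt_f
      })
      carriers <- groups[!is.na(freqs) & freqs > 0]
      status <- if (length(carriers) == 0) "absent"
                else if (length(carriers) > 1) "shared"
                else if (freqs[carriers] >= 1) "private" else "diagnostic"
      out[[length(out) + 1]] <- data.frame(
        locus = colnames(geno)[l], allele = allele, status = status,
        carrier = if (length(carriers) == 1) carriers else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# --- Evanno spreadsheet-style recomputation --------------------------------
naive_evanno <- function(k, lk) {
  kv <- sort(unique(k))
  mlk <- sapply(kv, function(K) mean(lk[k == K]))
  slk <- sapply(kv, function(K) sd(lk[k == K]))
  dk <- rep(NA_real_, length(kv))
  for (i in seq(2, length(kv) - 1)) {
    l1 <- mlk[i] - mlk[i - 1]
    l1n <- mlk[i + 1] - mlk[i]
    dk[i] <- abs(l1n - l1) / slk[i]
  }
  dk
}

# additive distance matrix from a random tree (for NJ exactness checks)
additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
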