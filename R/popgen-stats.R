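# Per-population diversity indices and between-population differentiation,
# under GenAlEx-style conventions: per-locus indices averaged over loci
# (untyped loci contribute Ne = I = Ho = He = 0 and are excluded from Fis),
# Nei (1972) standard distance, Fst = (Ht - Hs)/Ht averaged over loci, and
# island-model gene flow Nm = 0.25(1 - Fst)/Fst averaged per locus.

#' Per-group per-locus alternate-allele frequencies
#'
#' Frequency = (2 x homAlt + het) / (2 x non-missing calls). Loci with zero
#' non-missing calls in a group are flagged untyped (`NA` frequency).
#'
#' @param gm a [genotype_matrix()]
#' @param partition named accession -> group vector (see
#'   [species_partition()]).
#' @return list with `freq` (loci x groups alternate-allele frequency, NA =
#'   untyped), `n_typed` (loci x groups non-missing genotype counts),
#'   `n_het` (loci x groups heterozygote counts).
#' @export
allele_frequencies <- function(gm, partition) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- check_partition(gm, partition)
  if (any(table(p) == 0)) stop("empty group in partition")
  groups <- levels(p)
  L <- ncol(gm$geno)
  freq <- n_typed <- n_het <- matrix(NA_real_, L, length(groups),
                                     dimnames = list(colnames(gm$geno), groups))
  for (g in groups) {
    sub <- gm$geno[p == g, , drop = FALSE]
    nt <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    freq[, g] <- ifelse(nt > 0, alt / (2 * nt), NA_real_)
    n_typed[, g] <- nt
    n_het[, g] <- colSums(sub == 1L, na.rm = TRUE)
  }
  list(freq = freq, n_typed = n_typed, n_het = n_het)
}

# per-locus index matrices for one group given alt freq p, Ho; NA freq =
# untyped -> Ne = I = Ho = He = 0, Fis = NA
locus_indices <- function(p, ho) {
  typed <- !is.na(p)
  q <- 1 - p
  sumsq <- p^2 + q^2
  ne <- ifelse(typed, 1 / sumsq, 0)
  i_sh <- ifelse(typed,
                 -(ifelse(p > 0, p * log(p), 0) + ifelse(q > 0, q * log(q), 0)),
                 0)
  he <- ifelse(typed, 1 - sumsq, 0)
  ho <- ifelse(typed, ho, 0)
  fis <- ifelse(typed & he > 0, (he - ho) / he, NA_real_)
  list(ne = ne, i = i_sh, ho = ho, he = he, fis = fis, typed = typed,
       poly = typed & p > 0 & p < 1)
}

se_over_loci <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-group diversity indices and per-accession heterozygosity
#'
#' Per locus and group: Ne = 1/sum(p^2), I = -sum(p ln p), Ho =
#' hets/non-missing, He = 1 - sum(p^2), Fis = (He - Ho)/He (loci with He >
#' 0 only). Group values are means over all loci — untyped loci enter as
#' Ne = I = Ho = He = 0, which is why a group's mean Ne can fall below 1 —
#' with SE = sd/sqrt(n loci). P% is the percentage of polymorphic loci
#' among loci typed in the group. Per-accession heterozygosity is the
#' percentage of heterozygous calls among an accession's non-missing calls.
#'
#' @inheritParams allele_frequencies
#' @return list with `groups` (data frame: group, N, n_untyped, Ne, I, Ho,
#'   He, Fis with SEs, P_pct), `accessions` (data frame: accession, group,
#'   pct_het, n_typed) and `per_locus` (list of per-group per-locus index
#'   lists).
#' @export
diversity_indices <- function(gm, partition) {
  p <- check_partition(gm, partition)
  af <- allele_frequencies(gm, partition)
  groups <- colnames(af$freq)
  per_locus <- list()
  rows <- lapply(groups, function(g) {
    ho_loc <- ifelse(af$n_typed[, g] > 0, af$n_het[, g] / af$n_typed[, g], NA)
    li <- locus_indices(af$freq[, g], ho_loc)
    per_locus[[g]] <<- li
    fis <- li$fis[!is.na(li$fis)]
    data.frame(
      group = g, N = sum(p == g), n_untyped = sum(!li$typed),
      Ne = mean(li$ne), Ne_se = se_over_loci(li$ne),
      I = mean(li$i), I_se = se_over_loci(li$i),
      Ho = mean(li$ho), Ho_se = se_over_loci(li$ho),
      He = mean(li$he), He_se = se_over_loci(li$he),
      Fis = if (length(fis)) mean(fis) else NA_real_,
      Fis_se = if (length(fis) > 1) se_over_loci(fis) else NA_real_,
      P_pct = 100 * sum(li$poly) / max(sum(li$typed), 1))
  })
  acc_het <- 100 * rowSums(gm$geno == 1L, na.rm = TRUE) /
    pmax(rowSums(!is.na(gm$geno)), 1)
  accessions <- data.frame(accession = rownames(gm$geno),
                           group = as.character(p),
                           pct_het = unname(acc_het),
                           n_typed = unname(rowSums(!is.na(gm$geno))))
  list(groups = do.call(rbind, rows), accessions = accessions,
       per_locus = per_locus)
}

new_distance_matrix <- function(m, metric) {
  stopifnot(isSymmetric(unname(m)))
  structure(list(matrix = m, metric = metric), class = "gbs_dist")
}

#' @export
print.gbs_dist <- function(x, ...) {
  cat(sprintf("<distance matrix: %s> %d entities\n", x$metric,
              nrow(x$matrix)))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Pairwise Nei (1972) standard genetic distance between groups
#'
#' D = -ln(Jxy / sqrt(Jx Jy)) with the J identity terms averaged over loci
#' typed in both groups. Group pairs sharing no alleles at any co-typed
#' locus (Jxy = 0) get an infinite distance, reported as `Inf` with a
#' warning rather than clipped.
#'
#' @inheritParams allele_frequencies
#' @param unbiased apply Nei's (1978) small-sample correction to the
#'   within-group identities (default FALSE: the classical 1972 form).
#' @return a `gbs_dist` distance-matrix object.
#' @export
nei_distance <- function(gm, partition, unbiased = FALSE) {
  af <- allele_frequencies(gm, partition)
  groups <- colnames(af$freq)
  if (length(groups) < 2) stop("need >= 2 groups")
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b in seq_len(a - 1)) {
    pa <- af$freq[, a]; pb <- af$freq[, b]
    ok <- !is.na(pa) & !is.na(pb)
    if (!any(ok)) stop("groups ", groups[a], " and ", groups[b],
                       " share no co-typed loci")
    jx_loc <- pa[ok]^2 + (1 - pa[ok])^2
    jy_loc <- pb[ok]^2 + (1 - pb[ok])^2
    if (unbiased) {
      nx <- 2 * af$n_typed[ok, a]; ny <- 2 * af$n_typed[ok, b]
      jx_loc <- (nx * jx_loc - 1) / (nx - 1)
      jy_loc <- (ny * jy_loc - 1) / (ny - 1)
    }
    jxy <- mean(pa[ok] * pb[ok] + (1 - pa[ok]) * (1 - pb[ok]))
    jx <- mean(jx_loc); jy <- mean(jy_loc)
    d <- if (jxy <= 0) Inf else -log(jxy / sqrt(jx * jy))
    if (!is.finite(d))
      warning("no shared alleles between ", groups[a], " and ", groups[b],
              ": Nei distance is infinite")
    D[a, b] <- D[b, a] <- max(d, 0)
  }
  new_distance_matrix(D, if (unbiased) "nei_1978" else "nei_1972")
}

# per-locus Fst = (Ht - Hs)/Ht from a loci x groups frequency matrix
# (unweighted mean of group frequencies for Ht); NA where Ht = 0 or any
# group untyped
fst_per_locus <- function(freq_sub) {
  ok <- rowSums(is.na(freq_sub)) == 0
  hs <- rowMeans(2 * freq_sub * (1 - freq_sub))
  pbar <- rowMeans(freq_sub)
  ht <- 2 * pbar * (1 - pbar)
  ifelse(ok & ht > 0, (ht - hs) / ht, NA_real_)
}

#' Pairwise and overall Fst between groups
#'
#' Default method: per-locus Fst = (Ht - Hs)/Ht, where Hs is the mean
#' within-group expected heterozygosity and Ht the expected heterozygosity
#' at the pooled (unweighted mean) frequency; group-pair and overall values
#' are means over loci with Ht > 0. `method = "wc"` instead computes the
#' Weir-Cockerham (1984) theta (ratio of summed variance components),
#' which corrects for sample size and number of demes and recovers the
#' generating drift coefficient of a Balding-Nichols simulation.
#'
#' @inheritParams allele_frequencies
#' @param method `"gst"` (the (Ht-Hs)/Ht form) or `"wc"` (Weir-Cockerham
#'   theta).
#' @return list with `pairwise` (a `gbs_dist`), `overall` (all groups
#'   jointly), and `per_locus` (overall per-locus values).
#' @export
pairwise_fst <- function(gm, partition, method = c("gst", "wc")) {
  method <- match.arg(method)
  p <- check_partition(gm, partition)
  af <- allele_frequencies(gm, partition)
  groups <- colnames(af$freq)
  if (length(groups) < 2) stop("need >= 2 groups")
  pairfun <- function(sel) {
    if (method == "gst") {
      v <- fst_per_locus(af$freq[, sel, drop = FALSE])
      if (all(is.na(v))) stop("no polymorphic co-typed loci")
      mean(v, na.rm = TRUE)
    } else {
      wc_theta(gm, p, sel)$theta
    }
  }
  Fm <- matrix(0, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b in seq_len(a - 1))
    Fm[a, b] <- Fm[b, a] <- pairfun(groups[c(a, b)])
  per_locus <- if (method == "gst") fst_per_locus(af$freq) else NULL
  overall <- if (method == "gst") {
    if (all(is.na(per_locus))) stop("no polymorphic loci")
    mean(per_locus, na.rm = TRUE)
  } else wc_theta(gm, p, groups)$theta
  list(pairwise = new_distance_matrix(Fm, paste0("fst_", method)),
       overall = overall, per_locus = per_locus)
}

# Weir & Cockerham (1984) theta over a subset of groups, summing a and
# (a + b + c) components over loci (random-union-of-gametes form)
wc_theta <- function(gm, p, sel) {
  keep <- p %in% sel
  sub <- gm$geno[keep, , drop = FALSE]
  pops <- factor(as.character(p[keep]), levels = sel)
  r <- length(sel)
  by_group <- function(fn) {
    m <- vapply(sel, fn, numeric(ncol(sub)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    t(m)
  }
  n_i <- by_group(function(g)
    colSums(!is.na(sub[pops == g, , drop = FALSE])))
  p_i <- by_group(function(g) {
    m <- sub[pops == g, , drop = FALSE]
    colSums(m, na.rm = TRUE) / pmax(2 * colSums(!is.na(m)), 1)
  })
  h_i <- by_group(function(g)
    colMeans(sub[pops == g, , drop = FALSE] == 1L, na.rm = TRUE))
  ok <- colSums(n_i > 0) == r
  n_i <- n_i[, ok, drop = FALSE]; p_i <- p_i[, ok, drop = FALSE]
  h_i <- h_i[, ok, drop = FALSE]
  nbar <- colMeans(n_i)
  nc <- (r * nbar - colSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  use <- is.finite(a) & is.finite(b) & is.finite(cc)
  list(theta = sum(a[use]) / sum((a + b + cc)[use]),
       a = a, b = b, c = cc)
}

#' Island-model gene-flow estimate Nm from per-locus Fst
#'
#' Per locus, Nm = 0.25 (1 - Fst)/Fst. The headline estimate averages the
#' per-locus Nm values over loci with Fst > 0; applying the formula to the
#' mean Fst instead gives a (much smaller) alternative, and both are
#' returned because the two conventions diverge strongly when per-locus
#' Fst is variable.
#'
#' @param fst_per_locus numeric vector of per-locus Fst values (NAs
#'   ignored).
#' @return list with `nm_mean_of_loci`, `nm_from_mean_fst`, `n_loci_used`.
#' @export
gene_flow_nm <- function(fst_per_locus) {
  v <- fst_per_locus[!is.na(fst_per_locus)]
  v <- v[v > 0]
  if (!length(v)) stop("Nm undefined: no loci with Fst > 0")
  nm_loc <- 0.25 * (1 - v) / v
  list(nm_mean_of_loci = mean(nm_loc),
       nm_from_mean_fst = 0.25 * (1 - mean(v)) / mean(v),
       n_loci_used = length(v))
}
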