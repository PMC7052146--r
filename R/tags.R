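# GBS tag redundancy: pairwise sequence identity, single-linkage collapse
# of near-identical tags, and cross-population shared-tag accounting, plus
# the matching generator of synthetic tag sets.

#' Simulate GBS tag sets for several populations
#'
#' A `shared_fraction` of tags is present in every population (each
#' population carries its own copy, mutated per base at `mutation_rate`);
#' the remaining tags are unique random sequences per population.
#'
#' @param n_tags tags per population.
#' @param length tag length in bp (>= 30).
#' @param n_populations number of populations.
#' @param shared_fraction fraction of each population's tags drawn from the
#'   shared pool, in `[0, 1]`.
#' @param mutation_rate per-base substitution probability applied
#'   independently to each population's copy of a shared tag.
#' @param seed integer seed.
#' @return list with `tagsets` (per population, named character vector of
#'   sequences) and `truth` (`shared_ids`: the shared-pool index carried by
#'   each tag ID, NA for unique tags).
#' @export
simulate_tags <- function(n_tags, length = 64, n_populations = 3,
                          shared_fraction = 0.2, mutation_rate = 0.005,
                          seed = 4L) {
  if (length < 30) stop("tag length must be >= 30")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(bases, length, replace = TRUE), collapse = ""), "")
  n_shared <- round(shared_fraction * n_tags)
  shared_pool <- rand_seq(n_shared)
  mutate <- function(s) {
    if (mutation_rate == 0) return(s)
    v <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(v)) < mutation_rate
    if (any(hit))
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1), "")
    paste(v, collapse = "")
  }
  tagsets <- list(); truth <- list()
  for (p in seq_len(n_populations)) {
    pop <- sprintf("pop%d", p)
    ids <- c(if (n_shared) sprintf("%s_S%04d", pop, seq_len(n_shared)),
             if (n_tags - n_shared)
               sprintf("%s_U%04d", pop, seq_len(n_tags - n_shared)))
    seqs <- c(vapply(shared_pool, mutate, "", USE.NAMES = FALSE),
              rand_seq(n_tags - n_shared))
    tagsets[[pop]] <- stats::setNames(seqs, ids)
    truth[[pop]] <- stats::setNames(
      c(if (n_shared) seq_len(n_shared),
        rep(NA_integer_, n_tags - n_shared)), ids)
  }
  list(tagsets = tagsets, truth = list(shared_ids = truth))
}

check_dna <- function(s) {
  if (any(!nzchar(s))) stop("empty sequence")
  if (any(grepl("[^ACGTN]", toupper(s))))
    stop("sequences must contain only A, C, G, T or N")
  toupper(s)
}

#' Pairwise sequence identity between two tags
#'
#' Equal-length sequences are compared position by position; unequal
#' lengths fall back to a global end-gap-free (overlap) alignment, with
#' identity = matches / alignment length.
#'
#' @param seq_a,seq_b nucleotide strings (ACGTN).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  seq_a <- check_dna(seq_a); seq_b <- check_dna(seq_b)
  if (nchar(seq_a) == nchar(seq_b)) {
    a <- strsplit(seq_a, "")[[1]]; b <- strsplit(seq_b, "")[[1]]
    return(mean(a == b))
  }
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "overlap")
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

# identity matrix for a character vector of sequences (equal lengths fast
# path; an optional shared-16-mer prefilter bounds the quadratic scan)
identity_matrix <- function(seqs, prefilter = length(seqs) > 2000) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n < 2) return(m)
  if (length(unique(nchar(seqs))) == 1) {
    chars <- do.call(rbind, strsplit(seqs, ""))
    cand <- NULL
    if (prefilter) {
      k <- 16L
      kmers <- lapply(seqs, function(s)
        unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s))))
      cand <- matrix(FALSE, n, n)
      idx <- new.env()
      for (i in seq_len(n)) for (km in kmers[[i]]) {
        prev <- idx[[km]]
        if (!is.null(prev)) cand[cbind(prev, i)] <- TRUE
        idx[[km]] <- c(prev, i)
      }
    }
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      if (!is.null(cand)) js <- js[cand[i, js] | cand[js, i]]
      if (!length(js)) next
      eq <- chars[js, , drop = FALSE] ==
        matrix(chars[i, ], length(js), ncol(chars), byrow = TRUE)
      m[i, js] <- m[js, i] <- rowMeans(eq)
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[i], seqs[j])
  }
  m
}

# union-find single linkage over an identity matrix at >= threshold
single_linkage_clusters <- function(idm, threshold) {
  n <- nrow(idm)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  hits <- which(idm >= threshold & upper.tri(idm), arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    a <- find(hits[r, 1]); b <- find(hits[r, 2])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, 0L)
}

#' Collapse near-identical tags into a non-redundant set
#'
#' Single-linkage clustering at `>= threshold` identity; one representative
#' is kept per cluster (the lexicographically smallest tag ID, for
#' determinism).
#'
#' @param tagset named character vector (tag ID -> sequence).
#' @param threshold identity threshold in (0, 1], e.g. 0.98 for
#'   reference-building, 0.95 for cross-population pooling.
#' @return list with `tagset` (representatives), `cluster_map` (named
#'   vector: every input tag ID -> its representative ID).
#' @export
dedup_tags <- function(tagset, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  seqs <- check_dna(tagset)
  if (anyDuplicated(names(seqs))) stop("tag IDs must be unique")
  ids <- names(seqs)
  cl <- single_linkage_clusters(identity_matrix(seqs), threshold)
  rep_of <- vapply(split(ids, cl), function(g) sort(g)[1], "")
  cluster_map <- stats::setNames(rep_of[as.character(cl)], ids)
  reps <- unique(unname(cluster_map))
  list(tagset = seqs[reps], cluster_map = cluster_map)
}

#' Cross-population shared-tag analysis
#'
#' Pools all populations' tags, builds a non-redundant set at `threshold`
#' identity (single linkage), and reports which populations carry each
#' non-redundant tag, plus per-combination sharing percentages.
#'
#' @param tagsets named list of tag sets (each a named character vector),
#'   one per population.
#' @param threshold pooling identity threshold (default 0.95).
#' @return list with `membership` (data frame: representative tag,
#'   population presence flags, n_populations), `summary` (data frame of
#'   population combinations with counts and percent of the non-redundant
#'   set), and `per_population` (for each population: % of its tags unique
#'   vs shared).
#' @export
shared_tag_analysis <- function(tagsets, threshold = 0.95) {
  if (length(tagsets) < 2) stop("need >= 2 populations")
  if (any(!vapply(tagsets, length, 0L))) stop("empty population tag set")
  pops <- names(tagsets)
  if (is.null(pops)) pops <- names(tagsets) <- sprintf("pop%d", seq_along(tagsets))
  all_ids <- unlist(lapply(pops, function(p)
    paste0(p, "::", names(tagsets[[p]]))), use.names = FALSE)
  all_seqs <- stats::setNames(unlist(tagsets, use.names = FALSE), all_ids)
  dd <- dedup_tags(all_seqs, threshold)
  src_pop <- sub("::.*$", "", names(dd$cluster_map))
  carriers <- split(src_pop, dd$cluster_map)
  reps <- names(carriers)
  pres <- vapply(pops, function(p)
    vapply(carriers, function(cs) p %in% cs, TRUE), logical(length(carriers)))
  pres <- matrix(pres, nrow = length(carriers),
                 dimnames = list(reps, pops))
  membership <- data.frame(tag = reps, pres,
                           n_populations = rowSums(pres), row.names = NULL)
  combo <- apply(pres, 1, function(r) paste(pops[r], collapse = "+"))
  tab <- table(combo)
  summary <- data.frame(populations = names(tab),
                        n_tags = as.integer(tab),
                        pct = 100 * as.integer(tab) / length(reps),
                        row.names = NULL)
  per_population <- do.call(rbind, lapply(pops, function(p) {
    mine <- pres[, p]
    data.frame(population = p,
               n_tags = length(tagsets[[p]]),
               n_nonredundant = sum(mine),
               pct_unique = 100 * mean(rowSums(pres[mine, , drop = FALSE]) == 1),
               pct_shared = 100 * mean(rowSums(pres[mine, , drop = FALSE]) > 1))
  }))
  list(membership = membership, summary = summary,
       per_population = per_population)
}

#' Read / write tag sets as FASTA
#'
#' @param path FASTA file path
#' @return `read_tags_fasta`: named character vector of sequences.
#' @export
read_tags_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param tagset named character vector (tag ID -> sequence)
#' @rdname read_tags_fasta
#' @export
write_tags_fasta <- function(tagset, path) {
  x <- Biostrings::DNAStringSet(tagset)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
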