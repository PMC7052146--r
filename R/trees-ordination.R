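# Accession-level dissimilarity, NJ/UPGMA trees with locus bootstrap,
# principal coordinates, haversine geographic distances, Mantel tests and
# multilocus-genotype accumulation curves. Tree agglomeration is delegated
# to ape (NJ) and stats::hclust (UPGMA); the dissimilarity coefficient,
# bootstrap resampling, Mantel permutation scheme and PCoA eigenvalue
# conventions are pinned here.

#' Allele-sharing dissimilarity between accessions
#'
#' Per locus, for codominant diploid genotypes: d = 0 for identical
#' genotypes, 0.5 when one allele is shared (homozygote vs heterozygote),
#' 1 when no allele is shared; averaged over loci typed in both accessions
#' (pairwise deletion). With alt-dosage coding this is |g1 - g2| / 2.
#' `method = "simple"` uses simple matching (d = fraction of differing
#' genotypes) instead.
#'
#' @param gm a [genotype_matrix()]
#' @param method `"allele_sharing"` (default) or `"simple"` matching.
#' @param min_cotyped minimum number of co-typed loci per pair before the
#'   pair is declared uncomputable (default 50).
#' @return a `gbs_dist` over accessions.
#' @export
genetic_dissimilarity <- function(gm, method = c("allele_sharing", "simple"),
                                  min_cotyped = 50) {
  stopifnot(inherits(gm, "genotype_matrix"))
  method <- match.arg(method)
  g <- gm$geno
  n <- nrow(g)
  if (n < 2) stop("need >= 2 accessions")
  ok <- !is.na(g)
  g0 <- g; g0[!ok] <- 0L
  co <- tcrossprod(ok * 1)                       # co-typed locus counts
  if (any(co[upper.tri(co)] < min_cotyped)) {
    idx <- which(co < min_cotyped & upper.tri(co), arr.ind = TRUE)[1, ]
    stop(sprintf("accessions %s and %s share only %d co-typed loci (< %d)",
                 rownames(g)[idx[1]], rownames(g)[idx[2]],
                 co[idx[1], idx[2]], min_cotyped))
  }
  if (method == "allele_sharing") {
    # sum |gi - gl| over co-typed loci, computed via dosage decomposition:
    # |a-b| = a + b - 2*min(a,b); with 0/1/2 dosages min(a,b) needs care ->
    # do it per pair on indicator matrices instead
    d01 <- (g0 == 1L) * ok; d2 <- (g0 == 2L) * ok
    # |a-b| = (a-b)^2 adjusted: for values in {0,1,2}, |a-b| = (a-b)^2 - 2*[|a-b|=2]...
    # simplest exact route: (a-b)^2 = a^2 - 2ab + b^2 and |a-b| = (a-b)^2 - 2*1[{a,b}={0,2}]
    sq <- tcrossprod(g0 * ok, g0 * ok)
    a2 <- (g0^2) * ok
    ssq <- a2 %*% t(ok * 1) + (ok * 1) %*% t(a2) - 2 * sq   # sum (a-b)^2
    opp <- (g0 == 0L & ok) %*% t(d2) + d2 %*% t((g0 == 0L & ok) * 1)
    absdiff <- ssq - 2 * opp
    D <- absdiff / (2 * co)
  } else {
    eq <- matrix(0, n, n)
    for (v in 0:2) {
      iv <- (g0 == v & ok) * 1
      eq <- eq + tcrossprod(iv)
    }
    D <- 1 - eq / co
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(g), rownames(g))
  new_distance_matrix(D, paste0("genotype_", method))
}

as_dist_obj <- function(d) {
  if (inherits(d, "gbs_dist")) return(stats::as.dist(d$matrix))
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  stats::as.dist(m)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration (via ape); negative branch lengths are clamped
#' to zero with a warning.
#'
#' @param d a `gbs_dist`, `dist` or symmetric matrix over >= 3 entities.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  dd <- as_dist_obj(d)
  if (attr(dd, "Size") < 3) stop("NJ needs >= 3 entities")
  tr <- ape::nj(dd)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' UPGMA tree
#'
#' Average-linkage agglomeration; the result is ultrametric. hclust breaks
#' ties by the lowest pair indices, giving a deterministic topology.
#'
#' @inheritParams nj_tree
#' @return a rooted ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(d) {
  dd <- as_dist_obj(d)
  if (attr(dd, "Size") < 2) stop("UPGMA needs >= 2 entities")
  hc <- stats::hclust(dd, method = "average")
  ape::as.phylo(hc)
}

#' Locus-bootstrap support for a tree
#'
#' Resamples loci (columns) with replacement, rebuilds the dissimilarity
#' and the tree for each replicate, and reports for each internal
#' bipartition of the full-data tree the percentage of replicates
#' containing it.
#'
#' @param gm a [genotype_matrix()]
#' @param method `"nj"` or `"upgma"`.
#' @param n_reps bootstrap replicates (default 500).
#' @param seed integer seed.
#' @param dissimilarity,min_cotyped passed to [genetic_dissimilarity()].
#' @return list with `tree` (full-data tree with `node.label` set to
#'   support percentages) and `support` (numeric per internal node).
#' @export
bootstrap_support <- function(gm, method = c("nj", "upgma"), n_reps = 500,
                              seed = 1L, dissimilarity = "allele_sharing",
                              min_cotyped = 1) {
  method <- match.arg(method)
  if (n_reps < 1) stop("n_reps must be >= 1")
  build <- function(m) {
    d <- genetic_dissimilarity(m, method = dissimilarity,
                               min_cotyped = min_cotyped)
    if (method == "nj") nj_tree(d) else upgma_tree(d)
  }
  full <- build(gm)
  set.seed(seed)
  # loci are drawn by sorted ID so supports do not depend on the column
  # order of the input
  locus_order <- sort(colnames(gm$geno))
  reps <- lapply(seq_len(n_reps), function(r) {
    idx <- locus_order[sample(length(locus_order), replace = TRUE)]
    g <- gm$geno[, idx, drop = FALSE]
    colnames(g) <- make.unique(colnames(g))    # resampling duplicates loci
    loci <- gm$loci[idx, , drop = FALSE]
    loci$locus <- colnames(g)
    build(genotype_matrix(g, loci = loci, accessions = gm$accessions))
  })
  counts <- ape::prop.clades(full, reps, rooted = method == "upgma")
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  full$node.label <- round(support, 1)
  list(tree = full, support = support)
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a distance matrix.
#' Negative eigenvalues are excluded from the percent-variance denominator
#' and reported separately.
#'
#' @inheritParams nj_tree
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return list with `coordinates` (entities x axes), `eigenvalues`
#'   (all, decreasing), `pct_variance` (per returned axis, over the
#'   positive eigenvalues only), `negative_eigenvalues`.
#' @export
pcoa <- function(d, k = NULL) {
  m <- if (inherits(d, "gbs_dist")) d$matrix else as.matrix(d)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  n <- nrow(m)
  # Gower centering: B = J A J with A = -d^2/2
  B <- -0.5 * m^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eig$values > 1e-9 * max(abs(eig$values), 1))
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eig$values[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig$values,
       pct_variance = 100 * eig$values[pos[seq_len(k)]] /
         sum(eig$values[pos]),
       negative_eigenvalues = eig$values[eig$values < 0])
}

#' Great-circle geographic distances between accessions
#'
#' Haversine distance in kilometres (Earth radius 6371 km) from decimal
#' latitude/longitude accession metadata.
#'
#' @param gm a [genotype_matrix()] with `lat`/`lon` metadata, or a data
#'   frame with `accession`, `lat`, `lon` columns.
#' @return a `gbs_dist` in km.
#' @export
geographic_distance <- function(gm) {
  meta <- if (inherits(gm, "genotype_matrix")) gm$accessions else gm
  if (!all(c("lat", "lon") %in% names(meta)))
    stop("lat/lon metadata required")
  if (any(is.na(meta$lat) | is.na(meta$lon)))
    stop("missing coordinates")
  if (any(abs(meta$lat) > 90) || any(abs(meta$lon) > 180))
    stop("coordinates out of range")
  n <- nrow(meta)
  D <- matrix(0, n, n, dimnames = list(meta$accession, meta$accession))
  pts <- cbind(meta$lon, meta$lat)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dk <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                   pts[j, , drop = FALSE], r = 6371)
    D[i, j] <- D[j, i] <- dk
  }
  new_distance_matrix(D, "haversine_km")
}

#' Mantel test between two distance matrices
#'
#' Rxy is the Pearson correlation of the upper off-diagonal triangles;
#' significance comes from jointly permuting rows and columns of the
#' second matrix, with the one-tailed (positive association)
#' P = (number of permuted statistics >= observed, + 1) / (n_perm + 1).
#'
#' @param dist_a,dist_b `gbs_dist`, `dist` or symmetric matrices with
#'   matching entity labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (one-tailed positive, default) or
#'   `"two.sided"` (on |Rxy|).
#' @return list with `rxy`, `p_value`, `n_perm`, `permuted` (the permuted
#'   statistics).
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  A <- if (inherits(dist_a, "gbs_dist")) dist_a$matrix else as.matrix(dist_a)
  B <- if (inherits(dist_b, "gbs_dist")) dist_b$matrix else as.matrix(dist_b)
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("entity labels of the two matrices do not match")
    B <- B[rownames(A), rownames(A)]
  } else if (!all(dim(A) == dim(B))) stop("matrix dimensions do not match")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ut <- upper.tri(A)
  obs <- stats::cor(A[ut], B[ut])
  set.seed(seed)
  n <- nrow(A)
  perm_stat <- vapply(seq_len(n_perm), function(r) {
    o <- sample(n)
    stats::cor(A[ut], B[o, o][ut])
  }, 0)
  p <- if (alternative == "greater")
    (sum(perm_stat >= obs) + 1) / (n_perm + 1)
  else (sum(abs(perm_stat) >= abs(obs)) + 1) / (n_perm + 1)
  list(rxy = obs, p_value = p, n_perm = n_perm, permuted = perm_stat)
}

# exhaustive-permutation Mantel P for small n (testing oracle exposed for
# reuse): enumerates all n! joint permutations
mantel_exhaustive <- function(A, B, alternative = "greater") {
  A <- if (inherits(A, "gbs_dist")) A$matrix else as.matrix(A)
  B <- if (inherits(B, "gbs_dist")) B$matrix else as.matrix(B)
  n <- nrow(A)
  perms <- all_permutations(n)
  ut <- upper.tri(A)
  obs <- stats::cor(A[ut], B[ut])
  stats <- apply(perms, 1, function(o) stats::cor(A[ut], B[o, o][ut]))
  p <- if (alternative == "greater") mean(stats >= obs)
       else mean(abs(stats) >= abs(obs))
  list(rxy = obs, p_value = p, n_perm = nrow(perms))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Genotype accumulation curves
#'
#' For each subset size, repeatedly samples that many loci without
#' replacement and counts the distinct multilocus genotypes (MLGs) they
#' resolve. Counting is missing-aware: two accessions are considered
#' identical when they agree at every co-typed sampled locus, and the MLG
#' count is the number of connected components of that identity relation.
#'
#' @param gm a [genotype_matrix()]
#' @param subset_sizes locus subset sizes (e.g. `c(100, 200, 500, 1000)`).
#' @param n_reps random subsets per size (default 50).
#' @param seed integer seed.
#' @return data frame: size, mean_mlg, min_mlg, max_mlg.
#' @export
genotype_accumulation <- function(gm, subset_sizes, n_reps = 50, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  L <- ncol(gm$geno)
  if (any(subset_sizes > L)) stop("subset size exceeds locus count")
  if (any(subset_sizes < 1)) stop("subset sizes must be >= 1")
  set.seed(seed)
  count_mlg <- function(sub) {
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      co <- !is.na(sub[i, ]) & !is.na(sub[j, ])
      if (!any(co) || all(sub[i, co] == sub[j, co])) {
        a <- find(i); b <- find(j)
        if (a != b) parent[b] <- a
      }
    }
    length(unique(vapply(seq_len(n), find, 0L)))
  }
  rows <- lapply(subset_sizes, function(sz) {
    counts <- vapply(seq_len(n_reps), function(r)
      count_mlg(gm$geno[, sample(L, sz), drop = FALSE]), 0L)
    data.frame(size = sz, mean_mlg = mean(counts),
               min_mlg = min(counts), max_mlg = max(counts))
  })
  do.call(rbind, rows)
}
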