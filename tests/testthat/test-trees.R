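test_that("allele-sharing dissimilarity follows the 0 / 0.5 / 1 rule", {
  g <- rbind(c(0L, 0L), c(1L, 0L))     # hom vs het at L1, identical at L2
  gm <- toy_matrix(g)
  d <- genetic_dissimilarity(gm, min_cotyped = 1)
  expect_equal(d$matrix[1, 2], 0.25)

  same <- toy_matrix(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(genetic_dissimilarity(same, min_cotyped = 1)$matrix[1, 2], 0)

  opp <- toy_matrix(rbind(c(0L, 0L), c(2L, 2L)))
  expect_equal(genetic_dissimilarity(opp, min_cotyped = 1)$matrix[1, 2], 1)

  # pairwise deletion and the co-typed floor
  gmiss <- toy_matrix(rbind(c(0L, NA), c(NA, 0L)))
  expect_error(genetic_dissimilarity(gmiss, min_cotyped = 1), "co-typed")

  # simple matching alternative
  gsm <- toy_matrix(rbind(c(0L, 0L), c(1L, 0L)))
  expect_equal(genetic_dissimilarity(gsm, method = "simple",
                                     min_cotyped = 1)$matrix[1, 2], 0.5)
})

test_that("dissimilarity equals a per-pair loop oracle with missing data", {
  gm <- random_toy(3, n_groups = 2, n_per = 5, n_loci = 12,
                   missing_rate = 0.2)
  d <- genetic_dissimilarity(gm, min_cotyped = 1)$matrix
  g <- gm$geno
  for (i in 1:9) for (j in (i + 1):10) {
    co <- !is.na(g[i, ]) & !is.na(g[j, ])
    expect_equal(d[i, j], mean(abs(g[i, co] - g[j, co]) / 2),
                 tolerance = 1e-12)
  }
})

test_that("NJ is exact on additive matrices from random trees", {
  for (n in c(4, 6, 8, 10)) {
    am <- additive_matrix(n, seed = n)
    tr <- nj_tree(am$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(am$tree), tr)), 0)
    cd <- ape::cophenetic.phylo(tr)[rownames(am$d), colnames(am$d)]
    expect_equal(cd, am$d, tolerance = 1e-9)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3")
})

test_that("UPGMA is ultrametric and exact on ultrametric input", {
  am <- local({
    set.seed(5)
    tr <- ape::rcoal(7)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
  tr <- upgma_tree(am$d)
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(tr, am$tree))), 0)
  depths <- ape::node.depth.edgelength(tr)[seq_len(7)]
  expect_lt(diff(range(depths)), 1e-9)

  gm <- random_toy(9, n_groups = 2, n_per = 6, n_loci = 30)
  tr2 <- upgma_tree(genetic_dissimilarity(gm, min_cotyped = 1))
  depths2 <- ape::node.depth.edgelength(tr2)[seq_len(12)]
  expect_lt(diff(range(depths2)), 1e-9)
})

test_that("bootstrap supports are deterministic and permutation-invariant", {
  gm <- random_toy(13, n_groups = 2, n_per = 4, n_loci = 30)
  b1 <- bootstrap_support(gm, "nj", n_reps = 25, seed = 4, min_cotyped = 1)
  b2 <- bootstrap_support(gm, "nj", n_reps = 25, seed = 4, min_cotyped = 1)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))

  single <- bootstrap_support(gm, "nj", n_reps = 1, seed = 1,
                              min_cotyped = 1)
  expect_true(all(single$support %in% c(0, 100)))

  perm <- sample(ncol(gm$geno))
  gmp <- subset_genotypes(gm, loci = perm)
  b3 <- bootstrap_support(gmp, "nj", n_reps = 25, seed = 4, min_cotyped = 1)
  expect_identical(sort(unname(b1$support)), sort(unname(b3$support)))
})

test_that("strongly diverged species form highly supported clades", {
  cfg <- sim_config(n_species = 3, n_per_species = 6, n_loci = 300,
                    F_divergence = 0.8, inbreeding = 0.4,
                    private_fixed_fraction = 0.03, missing_rate = 0.02,
                    seed = 14)
  sim <- simulate_species_genotypes(cfg)
  bs <- bootstrap_support(sim$matrix, "nj", n_reps = 100, seed = 2,
                          min_cotyped = 10)
  tr <- bs$tree
  # support of each species bipartition (unrooted-aware)
  part <- species_partition(sim$matrix)
  parts <- ape::prop.part(tr)
  for (s in unique(part)) {
    tips <- names(part)[part == s]
    expect_true(ape::is.monophyletic(tr, tips))
    tip_idx <- match(tips, tr$tip.label)
    comp_idx <- setdiff(seq_along(tr$tip.label), tip_idx)
    hit <- which(vapply(parts, function(p)
      setequal(p, tip_idx) || setequal(p, comp_idx), TRUE))
    expect_gte(max(bs$support[hit]), 98)
  }
})

test_that("PCoA reproduces known geometry", {
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  expect_equal(p$pct_variance[1], 100)

  eq <- matrix(1, 3, 3) - diag(3)
  p2 <- pcoa(eq)
  expect_equal(p2$pct_variance[1:2], c(50, 50), tolerance = 1e-9)

  set.seed(7)
  pts <- matrix(rnorm(15), 5, 3)
  d3 <- as.matrix(dist(pts))
  p3 <- pcoa(d3)
  expect_equal(as.matrix(dist(p3$coordinates)), unname(d3),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("haversine distances match closed-form references", {
  meta <- data.frame(accession = c("a", "b", "c"),
                     lat = c(0, 0, 0), lon = c(0, 180, 1))
  d <- geographic_distance(meta)$matrix
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  expect_equal(d["a", "c"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  expect_equal(d["a", "a"], 0)
  bad <- data.frame(accession = "x", lat = 95, lon = 0)
  expect_error(geographic_distance(rbind(meta, bad)), "range")
})

test_that("Mantel permutation P agrees with exhaustive enumeration", {
  set.seed(21)
  for (n in c(4, 5)) {
    A <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    B <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(A) <- dimnames(B) <- list(letters[1:n], letters[1:n])
    exact <- mantel_exhaustive(A, B)
    approx <- mantel_test(A, B, n_perm = 20000, seed = 1)
    expect_equal(approx$rxy, exact$rxy, tolerance = 1e-12)
    expect_lt(abs(approx$p_value - exact$p_value), 0.02)
  }
  # identity
  A <- as.matrix(dist(1:5)); dimnames(A) <- list(letters[1:5], letters[1:5])
  expect_equal(mantel_test(A, A, n_perm = 9, seed = 1)$rxy, 1)
  B <- A[c(2:5, 1), c(2:5, 1)]
  expect_silent(mantel_test(A, B, n_perm = 9, seed = 1))  # label-aligned
  dimnames(B) <- list(LETTERS[1:5], LETTERS[1:5])
  expect_error(mantel_test(A, B, n_perm = 9), "labels")
})

test_that("Mantel results agree with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  A <- as.matrix(dist(matrix(rnorm(20), 10)))
  B <- as.matrix(dist(matrix(rnorm(20), 10)))
  mine <- mantel_test(A, B, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(mine$rxy, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$signif), 0.05)
})

test_that("genotype accumulation matches its hypergeometric expectation", {
  # all identical -> 1 MLG at every size
  same <- toy_matrix(matrix(1L, 5, 20))
  ga <- genotype_accumulation(same, c(5, 10), n_reps = 10, seed = 1)
  expect_true(all(ga$mean_mlg == 1))

  # pairwise distinct at every locus -> n MLGs
  dis <- toy_matrix(matrix(c(0L, 1L, 2L), 3, 10))
  ga2 <- genotype_accumulation(dis, c(1, 5), n_reps = 10, seed = 1)
  expect_true(all(ga2$mean_mlg == 3))

  # two accessions differing at 1 of 100 loci, subsets of 10:
  # P(resolve) = 1 - C(99,10)/C(100,10) = 0.10
  g <- rbind(rep(0L, 100), c(1L, rep(0L, 99)))
  gm <- toy_matrix(g)
  ga3 <- genotype_accumulation(gm, 10, n_reps = 400, seed = 2)
  expected <- 1 + (1 - choose(99, 10) / choose(100, 10))
  expect_lt(abs(ga3$mean_mlg - expected), 0.05)

  expect_error(genotype_accumulation(gm, 200, 5), "exceeds")
})
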