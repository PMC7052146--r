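morpho_toy <- function() {
  data.frame(
    accession = sprintf("a%02d", 1:8),
    flower = c("red", "red", "red", "red", "blue", "blue", "blue", "blue"),
    leaf = c("flat", "flat", "wavy", "flat", "flat", "flat", "flat", "flat"),
    height = c(10, 11, 12, 10, 30, 31, 29, 30))
}
morpho_part <- function() setNames(rep(c("s1", "s2"), each = 4),
                                   sprintf("a%02d", 1:8))

test_that("Shannon index matches closed forms", {
  tab <- data.frame(accession = paste0("a", 1:7),
                    t1 = rep("x", 7),
                    t2 = letters[1:7],
                    t3 = c("a", "a", "a", "a", "b", "c", NA))
  h <- shannon_trait_index(tab)
  expect_equal(unname(h["t1"]), 0)
  expect_equal(unname(h["t2"]), log(7), tolerance = 1e-12)
  # freq (4/6, 1/6, 1/6) over non-missing
  p <- c(4, 1, 1) / 6
  expect_equal(unname(h["t3"]), -sum(p * log(p)), tolerance = 1e-12)
  # the (0.5, 0.25, 0.25) reference value
  tab2 <- data.frame(accession = paste0("b", 1:4),
                     t = c("x", "x", "y", "z"))
  expect_equal(unname(shannon_trait_index(tab2)["t"]), 1.0397,
               tolerance = 1e-4)
  # all-missing trait flagged as NA
  tab3 <- data.frame(accession = "c1", t = NA_character_)
  expect_true(is.na(shannon_trait_index(tab3)["t"]))
})

test_that("H' is bounded by ln(states) with equality at equifrequency", {
  set.seed(2)
  for (r in 1:5) {
    states <- sample(letters[1:4], 40, replace = TRUE)
    tab <- data.frame(accession = paste0("x", 1:40), t = states)
    h <- unname(shannon_trait_index(tab)["t"])
    expect_gte(h, 0)
    expect_lte(h, log(length(unique(states))) + 1e-12)
  }
})

test_that("species-level diversity averages per-trait H' with SE over traits", {
  tab <- morpho_toy()
  res <- species_morph_diversity(tab, morpho_part())
  s1 <- res[res$group == "s1", ]
  # direct evaluation: trait H' within s1 (height binned by quartiles)
  h_flower <- 0
  h_leaf <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  h_height <- shannon_trait_index(tab[1:4, c("accession", "height")])["height"]
  hs <- c(h_flower, h_leaf, unname(h_height))
  expect_equal(s1$H, mean(hs), tolerance = 1e-12)
  expect_equal(s1$H_se, sd(hs) / sqrt(3), tolerance = 1e-12)

  # monomorphic species scores zero
  mono <- data.frame(accession = c("m1", "m2"), t1 = "a", t2 = "b")
  res2 <- species_morph_diversity(mono, setNames(c("s", "s"), c("m1", "m2")))
  expect_equal(res2$H[res2$group == "s"], 0)
})

test_that("more trait noise strictly raises mean diversity", {
  species <- paste0("sp0", 1:4)
  spec <- default_trait_spec(species)
  truth <- list(species = setNames(rep(species, each = 10),
                                   sprintf("n%02d", 1:40)))
  lo <- simulate_morphology(truth, spec, noise_rates = 0.03, seed = 5)
  hi <- simulate_morphology(truth, spec, noise_rates = 0.30, seed = 5)
  p <- truth$species
  dlo <- species_morph_diversity(lo$table, p)
  dhi <- species_morph_diversity(hi$table, p)
  expect_gt(dhi$H[dhi$group == "Total"], dlo$H[dlo$group == "Total"])
})

test_that("morphotype enumeration equals brute-force distinct rows", {
  tab <- morpho_toy()
  em <- enumerate_morphotypes(tab, morpho_part())
  brute <- nrow(unique(tab[, -1]))
  expect_identical(nrow(em$morphotypes), brute)
  expect_identical(unname(em$assignment["a01"]), unname(em$assignment["a04"]))
  # a01/a04 share a full vector (heights differ for a02); private to s1
  mt <- em$morphotypes[em$morphotypes$morphotype == em$assignment[["a01"]], ]
  expect_identical(mt$n_members, 2L)
  expect_true(mt$private)

  # sharing a vector across species breaks privacy
  tab2 <- tab
  tab2[5, -1] <- tab2[1, -1]
  em2 <- enumerate_morphotypes(tab2, morpho_part())
  mt2 <- em2$morphotypes[em2$morphotypes$morphotype ==
                           em2$assignment[["a01"]], ]
  expect_false(mt2$private)

  # missing states excluded under the complete-case policy
  tab3 <- tab
  tab3$leaf[1] <- NA
  em3 <- enumerate_morphotypes(tab3, morpho_part())
  expect_identical(em3$n_excluded, 1L)
  expect_false("a01" %in% names(em3$assignment))
})

test_that("private and diagnostic characters follow the frequency rules", {
  tab <- morpho_toy()
  pd <- private_diagnostic_characters(tab, morpho_part())
  red <- pd[pd$state == "red", ]
  expect_identical(red$status, "private")
  expect_identical(red$species, "s1")
  wavy <- pd[pd$state == "wavy", ]
  expect_identical(wavy$status, "diagnostic")
  expect_equal(wavy$freq_in_carrier, 0.25)

  # a state present in two species is neither
  tab2 <- tab; tab2$flower[5] <- "red"
  pd2 <- private_diagnostic_characters(tab2, morpho_part())
  expect_false("red" %in% pd2$state)
})

test_that("variance partition behaves at its extremes and calibrates", {
  # internally identical, mutually distinct species -> 100% among
  d <- matrix(1, 6, 6) - diag(6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  rownames(d) <- colnames(d) <- paste0("v", 1:6)
  part <- setNames(rep(c("p", "q"), each = 3), paste0("v", 1:6))
  vp <- variance_partition(d, part, n_perm = 999, seed = 1)
  expect_equal(vp$pct_among, 100, tolerance = 1e-9)
  # only the 2/20 label assignments reproducing the split reach the
  # observed F, so the permutation P sits near 0.1
  expect_lte(vp$p_value, 0.15)

  # no group difference -> ~0% among, large P
  set.seed(4)
  pts <- matrix(rnorm(24), 12)
  d2 <- as.matrix(dist(pts))
  rownames(d2) <- colnames(d2) <- paste0("w", 1:12)
  part2 <- setNames(rep(c("p", "q"), 6), paste0("w", 1:12))
  vp2 <- variance_partition(d2, part2, n_perm = 199, seed = 2)
  expect_lt(vp2$pct_among, 25)
  expect_gt(vp2$p_value, 0.1)
  expect_equal(vp2$pct_among + vp2$pct_within, 100, tolerance = 1e-9)
})

test_that("trait contributions identify the separating trait", {
  tab <- data.frame(accession = paste0("z", 1:8),
                    sep = rep(c("a", "b"), each = 4),
                    const1 = "k", const2 = "k")
  mo <- morpho_ordination(tab, k = 1)
  expect_gt(mo$contributions["sep", 1], 99)

  # duplicated trait columns share the contribution equally
  tab2 <- data.frame(accession = paste0("z", 1:8),
                     t1 = rep(c("a", "b"), each = 4),
                     t2 = rep(c("a", "b"), each = 4))
  mo2 <- morpho_ordination(tab2, k = 1)
  expect_equal(unname(mo2$contributions[1, 1]),
               unname(mo2$contributions[2, 1]), tolerance = 1e-9)
})

test_that("morphology-genetics congruence extremes behave", {
  set.seed(6)
  d <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(d) <- list(paste0("m", 1:10), paste0("m", 1:10))
  self <- morpho_genetic_congruence(d, d, n_perm = 99, seed = 1)
  expect_equal(self$rxy, 1)
  expect_lte(self$p_value, 0.05)
})

test_that("morphology tables round-trip with their schema sidecar", {
  tab <- morpho_toy()
  path <- withr::local_tempfile(); sch <- withr::local_tempfile()
  write_morphology(tab, path, schema = sch)
  back <- read_morphology(path, schema = sch)
  expect_equal(back, tab)
  expect_true(is.numeric(back$height))
})
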