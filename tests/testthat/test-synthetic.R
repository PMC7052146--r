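test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_species = 0), "n_species")
  expect_error(sim_config(missing_rate = 1.5), "rates")
  expect_error(sim_config(F_divergence = 1), "rates")
  expect_error(sim_config(n_species = 5, n_loci = 10,
                          private_fixed_fraction = 0.5), "too large")
})

test_that("the generator is bit-for-bit reproducible from its seed", {
  cfg <- sim_config(n_species = 3, n_per_species = 5, n_loci = 50,
                    missing_rate = 0.1, seed = 99)
  a <- simulate_species_genotypes(cfg)
  b <- simulate_species_genotypes(cfg)
  expect_identical(a$matrix$geno, b$matrix$geno)
  expect_identical(a$truth$species_freq, b$truth$species_freq)
  ga <- assign_geography(a$truth)
  gb <- assign_geography(b$truth)
  expect_identical(ga$coords, gb$coords)
})

test_that("no divergence and no inbreeding reproduce panmixia", {
  cfg <- sim_config(n_species = 2, n_per_species = 50, n_loci = 500,
                    F_divergence = 0, inbreeding = 0,
                    private_fixed_fraction = 0, missing_rate = 0, seed = 8)
  sim <- simulate_species_genotypes(cfg)
  expect_identical(sim$truth$species_freq[, 1], sim$truth$species_freq[, 2])
  fst <- pairwise_fst(sim$matrix, species_partition(sim$matrix),
                      method = "wc")$overall
  expect_lt(abs(fst), 0.02)
})

test_that("genotype counts are Hardy-Weinberg when inbreeding is zero", {
  cfg <- sim_config(n_species = 1, n_per_species = 120, n_loci = 400,
                    F_divergence = 0, inbreeding = 0,
                    private_fixed_fraction = 0, missing_rate = 0, seed = 17)
  sim <- simulate_species_genotypes(cfg)
  pvals <- apply(sim$matrix$geno, 2, function(g) {
    p <- sum(g) / (2 * length(g))
    expd <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1L, 3)
    suppressWarnings(stats::chisq.test(obs, p = expd / sum(expd))$p.value)
  })
  # pass rate approximately nominal at alpha = 0.05
  expect_gt(mean(pvals > 0.05), 0.90)
})

test_that("downstream Fis recovers the inbreeding parameter", {
  cfg <- sim_config(n_species = 1, n_per_species = 40, n_loci = 2000,
                    F_divergence = 0, inbreeding = 0.3,
                    private_fixed_fraction = 0, missing_rate = 0, seed = 23)
  sim <- simulate_species_genotypes(cfg)
  fis <- diversity_indices(sim$matrix, species_partition(sim$matrix))$groups$Fis
  expect_lt(abs(fis - 0.3), 0.05)
})

test_that("injected private-fixed loci are always recovered without missingness", {
  cfg <- sim_config(n_species = 4, n_per_species = 6, n_loci = 200,
                    F_divergence = 0.4, inbreeding = 0.2,
                    private_fixed_fraction = 0.05, missing_rate = 0,
                    seed = 41)
  sim <- simulate_species_genotypes(cfg)
  cls <- classify_alleles(sim$matrix, species_partition(sim$matrix))
  for (s in names(sim$truth$private_loci)) {
    found <- cls$locus[cls$status == "private" & !is.na(cls$carrier) &
                         cls$carrier == s & cls$allele == "alt"]
    expect_true(all(sim$truth$private_loci[[s]] %in% found))
  }
})

test_that("hybrid simulation raises heterozygosity as designed", {
  # parents fixed for opposite alleles -> 100% heterozygous at proportion 0.5
  cfg <- sim_config(n_species = 2, n_per_species = 5, n_loci = 60,
                    F_divergence = 0.3, inbreeding = 0, missing_rate = 0,
                    private_fixed_fraction = 0, seed = 3)
  sim <- simulate_species_genotypes(cfg)
  truth <- sim$truth
  truth$species_freq[, 1] <- 0; truth$species_freq[, 2] <- 1
  hyb <- simulate_hybrid(truth, "sp01", "sp02", 0.5, seed = 5)
  expect_true(all(hyb$geno == 1L))
  expect_equal(sum(hyb$admixture), 1)

  # diverged, inbred parents: hybrid het far above the within-species mean
  cfg2 <- sim_config(n_species = 2, n_per_species = 30, n_loci = 1000,
                     F_divergence = 0.6, inbreeding = 0.45, missing_rate = 0,
                     private_fixed_fraction = 0, seed = 13)
  sim2 <- simulate_species_genotypes(cfg2)
  hyb2 <- simulate_hybrid(sim2$truth, "sp01", "sp02", 0.5, seed = 7)
  het_hyb <- mean(hyb2$geno == 1L)
  het_within <- mean(sim2$matrix$geno == 1L)
  expect_gt(het_hyb, 3 * het_within)

  expect_error(simulate_hybrid(sim$truth, "sp01", "sp02", 1.0), "proportion")
  expect_error(simulate_hybrid(sim$truth, "sp01", "nope", 0.5), "parents")
})

test_that("geographic cline strength controls isolation by distance", {
  cfg <- sim_config(n_species = 7, n_per_species = 13, n_loci = 300,
                    F_divergence = 0.6, inbreeding = 0.3,
                    private_fixed_fraction = 0.02, missing_rate = 0.02,
                    seed = 19)
  sim <- simulate_species_genotypes(cfg)
  gen_d <- genetic_dissimilarity(sim$matrix, min_cotyped = 10)

  expect_error(assign_geography(sim$truth, cline_strength = 1.4), "cline")

  # cline 1, no jitter: species blocks perfectly ordered by longitude
  t1 <- assign_geography(sim$truth, cline_strength = 1, jitter_sd = 0,
                         seed = 2)
  lon_by_sp <- tapply(t1$coords$lon, sim$truth$species[t1$coords$accession],
                      function(x) diff(range(x)))
  expect_true(all(lon_by_sp == 0))

  # cline 0: Mantel correlation is null
  t0 <- assign_geography(sim$truth, cline_strength = 0, seed = 3)
  gm0 <- apply_geography(sim$matrix, t0)
  m0 <- mantel_test(gen_d, geographic_distance(gm0), n_perm = 199, seed = 1)
  expect_lt(abs(m0$rxy), 0.1)

  # strong cline: significant positive correlation at 999 permutations
  t6 <- assign_geography(sim$truth, cline_strength = 0.6, seed = 4)
  gm6 <- apply_geography(sim$matrix, t6)
  m6 <- mantel_test(gen_d, geographic_distance(gm6), n_perm = 999, seed = 1)
  expect_gt(m6$rxy, 0)
  expect_lte(m6$p_value, 0.05)
  expect_gt(m6$rxy, m0$rxy)
})

test_that("morphology generator respects species modality and designed privates", {
  species <- paste0("sp0", 1:5)
  spec <- default_trait_spec(species)
  truth <- list(species = setNames(rep(species, each = 6),
                                   sprintf("A%02d", 1:30)))
  part <- truth$species

  zero <- simulate_morphology(truth, spec, noise_rates = 0, seed = 1)
  em <- enumerate_morphotypes(zero$table, part)
  expect_identical(nrow(em$morphotypes), 5L)
  expect_true(all(em$morphotypes$private))
  pd <- private_diagnostic_characters(zero$table, part)
  for (i in seq_len(nrow(zero$truth$private_characters))) {
    row <- zero$truth$private_characters[i, ]
    hit <- pd[pd$trait == row$trait & pd$state == row$state, ]
    expect_identical(hit$species, row$species)
    expect_identical(hit$status, "private")
  }

  noisy <- simulate_morphology(truth, spec, noise_rates = 0.2, seed = 2)
  emn <- enumerate_morphotypes(noisy$table, part)
  expect_gt(nrow(emn$morphotypes), 5L)
  # designed private characters never leak into other species
  pdn <- private_diagnostic_characters(noisy$table, part)
  for (i in seq_len(nrow(noisy$truth$private_characters))) {
    row <- noisy$truth$private_characters[i, ]
    states <- noisy$table[[row$trait]]
    carriers <- unique(part[noisy$table$accession][states == row$state])
    expect_true(all(carriers == row$species))
  }
  expect_error(simulate_morphology(truth, spec, noise_rates = 2), "noise")
})

test_that("tag generator honours sharing fraction and mutation arithmetic", {
  full <- simulate_tags(40, 64, 3, shared_fraction = 1, mutation_rate = 0,
                        seed = 1)
  sh <- shared_tag_analysis(full$tagsets, 0.95)
  expect_true(all(sh$membership$n_populations == 3))

  none <- simulate_tags(40, 64, 3, shared_fraction = 0, seed = 2)
  sh0 <- shared_tag_analysis(none$tagsets, 0.95)
  expect_true(all(sh0$membership$n_populations == 1))

  expect_error(simulate_tags(10, 20), "length")
  expect_error(simulate_tags(10, 64, shared_fraction = 2), "shared_fraction")
})
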