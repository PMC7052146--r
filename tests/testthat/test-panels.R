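test_that("allele classification follows the private/diagnostic definitions", {
  # monomorphic shared locus: no private alleles
  g <- matrix(0L, 6, 1)
  gm <- toy_matrix(g, species = rep(c("a", "b"), each = 3))
  cls <- classify_alleles(gm, species_partition(gm))
  expect_false(any(cls$status == "private"))

  # group a all homAlt, others all homRef -> alt private to a, ref shared
  g2 <- rbind(matrix(2L, 3, 1), matrix(0L, 9, 1))
  gm2 <- toy_matrix(g2, species = rep(c("a", "b", "c", "d"), each = 3))
  cls2 <- classify_alleles(gm2, species_partition(gm2))
  alt <- cls2[cls2$allele == "alt", ]
  expect_identical(alt$status, "private")
  expect_identical(alt$carrier, "a")
  expect_equal(alt$carrier_freq, 1)
  expect_identical(cls2[cls2$allele == "ref", ]$status, "shared")

  # alt at freq < 1 in one group only -> diagnostic
  g3 <- rbind(c(2L), c(1L), c(0L), c(0L), c(0L), c(0L))
  gm3 <- toy_matrix(g3, species = rep(c("a", "b", "c"), each = 2))
  cls3 <- classify_alleles(gm3, species_partition(gm3))
  alt3 <- cls3[cls3$allele == "alt", ]
  expect_identical(alt3$status, "diagnostic")
  expect_equal(alt3$carrier_freq, 0.75)

  expect_error(classify_alleles(gm, setNames(rep("one", 6),
                                             rownames(gm$geno))), ">= 2")
})

test_that("classification equals brute-force enumeration on random toys", {
  for (seed in 1:25) {
    gm <- random_toy(seed, n_groups = 3, n_per = 4, n_loci = 20,
                     missing_rate = if (seed %% 2) 0 else 0.2)
    mine <- classify_alleles(gm, species_partition(gm))
    oracle <- naive_classify(gm$geno, gm$accessions$species)
    expect_identical(mine$status, oracle$status)
    expect_identical(mine$carrier, oracle$carrier)
  }
})

test_that("statuses partition carried alleles; removal never creates sharing", {
  gm <- random_toy(33, n_groups = 3, n_per = 5, n_loci = 30,
                   missing_rate = 0.1)
  part <- species_partition(gm)
  cls <- classify_alleles(gm, part)
  expect_true(all(cls$status %in% c("private", "diagnostic", "shared",
                                    "absent")))
  expect_identical(nrow(cls), 2L * ncol(gm$geno))
  # drop group g3: its private/diagnostic alleles may only become absent
  keep <- gm$accessions$species != "g3"
  gm2 <- subset_genotypes(gm, accessions = keep)
  cls2 <- classify_alleles(gm2, species_partition(gm2))
  key <- paste(cls$locus, cls$allele)
  key2 <- paste(cls2$locus, cls2$allele)
  i2 <- match(key, key2)
  # alleles carried only by g3 become absent; nothing new becomes shared
  only_g3 <- !is.na(cls$carrier) & cls$carrier == "g3"
  expect_true(all(cls2$status[i2[only_g3]] == "absent"))
  not_shared_before <- cls$status != "shared"
  expect_false(any(cls2$status[i2[not_shared_before]] == "shared"))
  # g1/g2 private alleles stay private
  kept_priv <- cls$status == "private" & cls$carrier %in% c("g1", "g2")
  expect_true(all(cls2$status[i2[kept_priv]] == "private"))
})

test_that("private/diagnostic counts recover synthetic truth exactly", {
  cfg <- sim_config(n_species = 7, n_per_species = 6, n_loci = 600,
                    F_divergence = 0.5, inbreeding = 0.2,
                    private_fixed_fraction = 0.05, missing_rate = 0,
                    seed = 77)
  sim <- simulate_species_genotypes(cfg)
  part <- species_partition(sim$matrix)
  cls <- classify_alleles(sim$matrix, part)
  counts <- count_private_diagnostic(cls, groups = sort(unique(part)))
  k <- round(0.05 * 600)
  for (s in names(sim$truth$private_loci)) {
    privs <- cls$locus[cls$status == "private" & !is.na(cls$carrier) &
                         cls$carrier == s]
    expect_true(all(sim$truth$private_loci[[s]] %in% privs))
    expect_gte(counts$n_private[counts$group == s], k)
  }
  # duplicated identical groups have no private alleles
  g <- matrix(rep(c(0L, 1L, 2L), 4), 4, 3, byrow = TRUE)
  gmd <- toy_matrix(g, species = c("a", "a", "b", "b"))
  cd <- count_private_diagnostic(classify_alleles(gmd, species_partition(gmd)))
  expect_identical(sum(cd$n_private) + sum(cd$n_diagnostic), 0L)
})

test_that("complex-level classification can only gain private alleles", {
  gm <- random_toy(55, n_groups = 4, n_per = 5, n_loci = 40,
                   missing_rate = 0.05)
  part <- species_partition(gm)
  cls <- classify_alleles(gm, part)
  merged <- merge_groups(part, c("g1", "g2"), "cx")
  clsm <- classify_alleles(gm, merged)
  n_member <- sum(cls$status == "private" & cls$carrier %in% c("g1", "g2"))
  n_complex <- sum(clsm$status == "private" & clsm$carrier == "cx")
  expect_gte(n_complex, n_member)
})

test_that("panel selection resolves each species and honours separators", {
  cfg <- sim_config(n_species = 7, n_per_species = 5, n_loci = 350,
                    F_divergence = 0.5, inbreeding = 0.2,
                    private_fixed_fraction = 0.04, missing_rate = 0,
                    seed = 12)
  sim <- simulate_species_genotypes(cfg)
  part <- species_partition(sim$matrix)
  res <- select_panel(sim$matrix, part)
  expect_identical(nrow(res$panel), 7L)
  expect_setequal(res$panel$target, unique(part))
  expect_true(all(res$panel$backing == "private"))
  expect_length(res$uncoverable, 0)

  # subspecies pair: diagnostic allele carried (hom or het) by all of s1,
  # partners homozygous reference -> separator; L02 is fixed in the complex
  # and absent in the outgroup (complex-level private)
  gm <- toy_matrix(rbind(cbind(c(2L, 1L, 1L, 0L, 0L, 0L), rep(2L, 6)),
                         cbind(rep(0L, 4), rep(0L, 4))),
                   species = c(rep("s1", 3), rep("s2", 3), rep("out", 4)))
  res2 <- suppressWarnings(select_panel(gm, species_partition(gm),
                                        complexes = list(cx = c("s1", "s2"))))
  pan <- res2$panel
  expect_true(any(pan$backing == "separator" & pan$target == "s1" &
                    pan$locus == "L01"))
  expect_true(any(pan$target == "cx" & pan$backing == "private"))

  # single group is uncoverable
  gm1 <- toy_matrix(matrix(0:2, 3, 2), species = rep("only", 3))
  expect_error(select_panel(gm1, species_partition(gm1)), ">= 2")
})

test_that("species assignment calls pure carriers, hybrids and unresolved", {
  cfg <- sim_config(n_species = 3, n_per_species = 8, n_loci = 300,
                    F_divergence = 0.4, inbreeding = 0.2,
                    private_fixed_fraction = 0.05, missing_rate = 0,
                    seed = 21)
  sim <- simulate_species_genotypes(cfg)
  part <- species_partition(sim$matrix)
  pan <- select_panel(sim$matrix, part)$panel
  hyb <- simulate_hybrid(sim$truth, "sp01", "sp02", 0.5, seed = 9)
  gm <- bind_accession(sim$matrix, hyb$id, hyb$geno)
  calls <- assign_species(pan, gm)
  own <- calls$call[match(names(part), calls$accession)]
  expect_identical(unname(own), unname(part))
  expect_identical(calls$call[calls$accession == hyb$id], "conflict")

  # all panel loci missing -> unresolved with zero evidence
  blank <- rep(NA_integer_, ncol(gm$geno))
  gm2 <- bind_accession(gm, "BLANK", blank)
  calls2 <- assign_species(pan, gm2)
  expect_identical(calls2$call[calls2$accession == "BLANK"], "unresolved")
  expect_true(calls2$zero_evidence[calls2$accession == "BLANK"])
})

test_that("heterozygosity flagging isolates injected hybrids", {
  cfg <- sim_config(n_species = 2, n_per_species = 15, n_loci = 400,
                    F_divergence = 0.7, inbreeding = 0.5,
                    private_fixed_fraction = 0, missing_rate = 0, seed = 31)
  sim <- simulate_species_genotypes(cfg)
  hyb <- simulate_hybrid(sim$truth, "sp01", "sp02", 0.5, seed = 2)
  gm <- bind_accession(sim$matrix, hyb$id, hyb$geno, species = "sp01")
  part <- species_partition(gm)
  fl <- flag_hybrids(gm, part, het_multiplier = 3)
  expect_true(fl$flagged[fl$accession == hyb$id])
  expect_lte(sum(fl$flagged), 2)

  # uniform heterozygosity flags nothing
  gu <- matrix(1L, 6, 10)
  gu[, 1] <- 0L
  gmu <- toy_matrix(gu, species = rep("s", 6))
  expect_false(any(flag_hybrids(gmu, species_partition(gmu))$flagged))
  expect_warning(flag_hybrids(gmu, species_partition(gmu), 0.9),
                 "multiplier")
})
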