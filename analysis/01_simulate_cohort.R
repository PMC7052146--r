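#!/usr/bin/env Rscript
# Generates the synthetic study cohort: seven species diverged under a
# drift model (uneven sampling, species-private fixed alleles, strong
# inbreeding), an East-West geographic cline, one 50/50 interspecific
# hybrid, species-determined morphology, and per-subpopulation GBS tag
# sets. Writes the delimited genotype/metadata/morphology tables and tag
# FASTA files that the later drivers consume.
source("analysis/00_config.R")

cfg <- sim_config(seed = SEED)
sim <- simulate_species_genotypes(cfg)
truth <- assign_geography(sim$truth, seed = SEED + 1L)
hyb <- simulate_hybrid(truth, "sp07", "sp05", 0.5, seed = SEED + 2L,
                       id = HYBRID_ID)
gm <- bind_accession(apply_geography(sim$matrix, truth), hyb$id, hyb$geno,
                     species = "sp07", reads = 2e6)
gm$accessions$lat[nrow(gm$accessions)] <- mean(truth$coords$lat)
gm$accessions$lon[nrow(gm$accessions)] <- mean(truth$coords$lon)

write_genotypes(gm, file.path(DATA_DIR, "genotypes.tsv"),
                locus_meta = file.path(DATA_DIR, "loci.tsv"),
                accession_meta = file.path(DATA_DIR, "accessions.tsv"))
write_vcf(gm, file.path(DATA_DIR, "genotypes.vcf"))

trait_spec <- default_trait_spec(colnames(truth$species_freq))
mor <- simulate_morphology(truth, trait_spec, seed = SEED + 3L)
write_morphology(mor$table, file.path(DATA_DIR, "morphology.tsv"),
                 schema = file.path(DATA_DIR, "morphology_schema.tsv"))
write.table(mor$truth$private_characters,
            file.path(DATA_DIR, "truth_private_characters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tg <- simulate_tags(400, 64, 3, shared_fraction = 0.21,
                    mutation_rate = 0.003, seed = SEED + 4L)
for (p in names(tg$tagsets))
  write_tags_fasta(tg$tagsets[[p]], file.path(DATA_DIR, paste0("tags_", p, ".fa")))

# ground truth for downstream validation
priv <- data.frame(species = rep(names(truth$private_loci),
                                 lengths(truth$private_loci)),
                   locus = unlist(truth$private_loci))
write.table(priv, file.path(DATA_DIR, "truth_private_loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d accessions (incl. hybrid %s) x %d loci; %d tag sets\n",
            nrow(gm$geno), HYBRID_ID, ncol(gm$geno), length(tg$tagsets)))
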