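#!/usr/bin/env Rscript
# Per-species diversity indices (Ne, I, Ho, He, Fis, P%), per-accession
# heterozygosity, pairwise Nei (1972) distances, Fst and island-model
# gene flow. The hybrid is excluded from the per-species table, mirroring
# standard practice of holding suspect accessions out of diversity
# summaries.
source("analysis/00_config.R")

gm <- read_genotypes(file.path(DATA_DIR, "genotypes_filtered.tsv"),
                     locus_meta = file.path(DATA_DIR, "loci_filtered.tsv"),
                     accession_meta = file.path(DATA_DIR, "accessions_filtered.tsv"))
gm_core <- subset_genotypes(gm, accessions = setdiff(rownames(gm$geno),
                                                     HYBRID_ID))
part <- species_partition(gm_core)

di <- diversity_indices(gm_core, part)
write.table(di$groups, file.path(OUT_DIR, "diversity_by_species.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(di$accessions, file.path(OUT_DIR, "accession_heterozygosity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(di$groups[, c("group", "N", "Ne", "I", "Ho", "He", "Fis", "P_pct")],
      digits = 3)

nei <- nei_distance(gm_core, part)
write.table(round(nei$matrix, 4), file.path(OUT_DIR, "nei_distance.tsv"),
            sep = "\t", quote = FALSE)
fst <- pairwise_fst(gm_core, part)
write.table(round(fst$pairwise$matrix, 4),
            file.path(OUT_DIR, "pairwise_fst.tsv"), sep = "\t", quote = FALSE)
nm <- gene_flow_nm(fst$per_locus)

# hybrid heterozygosity vs the rest of the cohort
het_all <- diversity_indices(gm, species_partition(gm))$accessions
hyb_het <- het_all$pct_het[het_all$accession == HYBRID_ID]

cat(sprintf("overall Fst = %.3f; Nm (mean over loci) = %.3f; Nm (from mean Fst) = %.3f\n",
            fst$overall, nm$nm_mean_of_loci, nm$nm_from_mean_fst))
cat(sprintf("mean pairwise Nei distance = %.3f\n",
            mean(nei$matrix[upper.tri(nei$matrix)])))
cat(sprintf("hybrid %s heterozygosity = %.1f%% vs cohort mean %.1f%%\n",
            HYBRID_ID, hyb_het,
            mean(het_all$pct_het[het_all$accession != HYBRID_ID])))
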