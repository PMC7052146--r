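#!/usr/bin/env Rscript
# Accession-level allele-sharing dissimilarity, NJ and UPGMA trees with
# 500-replicate locus bootstraps (Newick with support labels), PCoA of the
# genetic distances, the Mantel test of isolation by distance on
# haversine geographic distances, and genotype accumulation curves.
source("analysis/00_config.R")

gm <- read_genotypes(file.path(DATA_DIR, "genotypes_filtered.tsv"),
                     locus_meta = file.path(DATA_DIR, "loci_filtered.tsv"),
                     accession_meta = file.path(DATA_DIR, "accessions_filtered.tsv"))
gm_core <- subset_genotypes(gm, accessions = setdiff(rownames(gm$geno),
                                                     HYBRID_ID))

gen_d <- genetic_dissimilarity(gm, min_cotyped = 50)

part <- species_partition(gm_core)
for (method in c("nj", "upgma")) {
  bs <- bootstrap_support(gm_core, method, n_reps = 500, seed = SEED + 12L,
                          min_cotyped = 50)
  ape::write.tree(bs$tree, file.path(OUT_DIR, paste0(method, "_tree.nwk")))
  parts <- ape::prop.part(bs$tree)
  sp_support <- vapply(unique(part), function(s) {
    tips <- match(names(part)[part == s], bs$tree$tip.label)
    comp <- setdiff(seq_along(bs$tree$tip.label), tips)
    hit <- which(vapply(parts, function(p)
      setequal(p, tips) || setequal(p, comp), TRUE))
    if (length(hit)) max(bs$support[hit]) else 0
  }, 0)
  cat(sprintf("%s: species-clade support %.0f-%.0f%%; median internal-edge support %.0f%%\n",
              toupper(method), min(sp_support), max(sp_support),
              median(bs$support)))
}

ord <- pcoa(genetic_dissimilarity(gm_core, min_cotyped = 50))
coords <- data.frame(accession = rownames(ord$coordinates),
                     ord$coordinates[, 1:3])
write.table(coords, file.path(OUT_DIR, "pcoa_genetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("genetic PCoA: axis1 %.1f%%, axis2 %.1f%%, axis3 %.1f%%\n",
            ord$pct_variance[1], ord$pct_variance[2], ord$pct_variance[3]))

geo_d <- geographic_distance(gm)
mt <- mantel_test(gen_d, geo_d, n_perm = 999, seed = SEED + 13L)
cat(sprintf("isolation by distance: Rxy = %.3f, P = %.3f (999 permutations)\n",
            mt$rxy, mt$p_value))

ga <- genotype_accumulation(gm, c(100, 200, 500, 1000), n_reps = 50,
                            seed = SEED + 14L)
write.table(ga, file.path(OUT_DIR, "genotype_accumulation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ga)
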