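#!/usr/bin/env Rscript
# Sample QC (read count, missing data) followed by the species-tier SNP
# filter (biallelic, adjacency, QD >= 10, staged missing-data thresholds,
# MAF > 5%). Writes the filtered genotype table and an itemised filter
# report. The subpopulation-tier filter is demonstrated on the largest
# species.
source("analysis/00_config.R")

gm <- read_genotypes(file.path(DATA_DIR, "genotypes.tsv"),
                     locus_meta = file.path(DATA_DIR, "loci.tsv"),
                     accession_meta = file.path(DATA_DIR, "accessions.tsv"))

qc <- filter_samples(gm)
print(qc$report)
filt <- filter_snps_species(qc$matrix)
print(filt$report)
gm_f <- filt$matrix
write_genotypes(gm_f, file.path(DATA_DIR, "genotypes_filtered.tsv"),
                locus_meta = file.path(DATA_DIR, "loci_filtered.tsv"),
                accession_meta = file.path(DATA_DIR, "accessions_filtered.tsv"))
report <- rbind(cbind(tier = "sample_qc", qc$report$stages),
                cbind(tier = "species", filt$report$stages))
write.table(report, file.path(OUT_DIR, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# subpopulation tier on the largest species
part <- species_partition(gm_f)
big <- names(which.max(table(part)))
gm_big <- subset_genotypes(gm_f, accessions = names(part)[part == big])
sub <- filter_snps_subpop(gm_big)
cat(sprintf("subpopulation tier (%s): %d -> %d loci\n", big,
            ncol(gm_big$geno), ncol(sub$matrix$geno)))

cat(sprintf("species tier: %d -> %d accessions, %d -> %d loci\n",
            nrow(gm$geno), nrow(gm_f$geno), ncol(gm$geno), ncol(gm_f$geno)))
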