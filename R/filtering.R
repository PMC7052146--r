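# Two-tier SNP filtering: a cross-species tier (QD, staged missing-data
# thresholds, MAF) and a within-subpopulation tier (QD, allele-frequency
# band, tighter missing-data cap). Rule order is fixed and itemised in the
# FilterReport because the MAF denominator depends on what was removed first.

new_filter_report <- function(stages, input_dim, output_dim,
                              removed_accessions = character(),
                              removed_loci = character()) {
  structure(list(stages = stages, input_dim = input_dim,
                 output_dim = output_dim,
                 removed_accessions = removed_accessions,
                 removed_loci = removed_loci),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %dx%d -> %dx%d (accessions x loci)\n",
              x$input_dim[1], x$input_dim[2],
              x$output_dim[1], x$output_dim[2]))
  if (nrow(x$stages))
    for (i in seq_len(nrow(x$stages)))
      cat(sprintf("  %-28s removed %d %s\n", x$stages$rule[i],
                  x$stages$removed[i], x$stages$unit[i]))
  invisible(x)
}

stage_row <- function(rule, unit, removed)
  data.frame(rule = rule, unit = unit, removed = removed)

locus_missing_fraction <- function(gm) colMeans(is.na(gm$geno))
accession_missing_fraction <- function(gm) rowMeans(is.na(gm$geno))

# minor-allele frequency per locus over non-missing allele calls, pooled
# across all accessions (het contributes one copy of each allele)
locus_maf <- function(gm) {
  alt <- colSums(gm$geno, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(gm$geno))
  p <- ifelse(n2 > 0, alt / n2, NA_real_)
  pmin(p, 1 - p)
}

#' Remove accessions failing read-count or missing-data QC
#'
#' Sample-level QC applied before the locus filters: accessions with fewer
#' than `min_reads` reads are dropped first, then accessions whose remaining
#' missing-call fraction exceeds `max_missing_fraction`.
#'
#' @param gm a [genotype_matrix()]
#' @param min_reads minimum read count (default 600,000); `NULL` skips the
#'   rule.
#' @param max_missing_fraction maximum tolerated fraction of missing calls
#'   (default 0.75, i.e. accessions with > 75% missing are removed); `NULL`
#'   skips the rule.
#' @return list with elements `matrix` (filtered [genotype_matrix()]) and
#'   `report` (a `filter_report`).
#' @export
filter_samples <- function(gm, min_reads = 6e5, max_missing_fraction = 0.75) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stages <- stage_row(character(), character(), integer())[0, ]
  removed <- character()
  cur <- gm
  if (!is.null(min_reads)) {
    if (!"reads" %in% names(cur$accessions))
      stop("read-count metadata ('reads') required when min_reads is set")
    fail <- cur$accessions$reads < min_reads
    stages <- rbind(stages, stage_row(
      sprintf("reads < %g", min_reads), "accessions", sum(fail)))
    removed <- c(removed, rownames(cur$geno)[fail])
    cur <- subset_genotypes(cur, accessions = !fail)
  }
  if (!is.null(max_missing_fraction)) {
    fail <- accession_missing_fraction(cur) > max_missing_fraction
    stages <- rbind(stages, stage_row(
      sprintf("missing > %g%%", 100 * max_missing_fraction),
      "accessions", sum(fail)))
    removed <- c(removed, rownames(cur$geno)[fail])
    cur <- subset_genotypes(cur, accessions = !fail)
  }
  list(matrix = cur,
       report = new_filter_report(stages, dim(gm), dim(cur),
                                  removed_accessions = removed))
}

#' Remove adjacent SNPs on the same tag
#'
#' Multiple side-by-side SNPs on a GBS tag are often alignment artefacts;
#' any locus with another locus within `max_gap` bases on the same tag is
#' removed — both members of each adjacent pair.
#'
#' @param gm a [genotype_matrix()] whose locus metadata carries `tag` and
#'   `pos`.
#' @param max_gap maximum base-pair gap treated as adjacent (default 1).
#' @return list(`matrix`, `report`)
#' @export
remove_adjacent_snps <- function(gm, max_gap = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(c("tag", "pos") %in% names(gm$loci)))
    stop("locus metadata needs 'tag' and 'pos' for adjacency filtering")
  drop <- rep(FALSE, ncol(gm$geno))
  for (idx in split(seq_len(ncol(gm$geno)), gm$loci$tag)) {
    if (length(idx) < 2) next
    pos <- gm$loci$pos[idx]
    o <- order(pos)
    gaps <- diff(pos[o])
    adj <- gaps <= max_gap
    hit <- unique(c(o[which(adj)], o[which(adj) + 1L]))
    drop[idx[hit]] <- TRUE
  }
  out <- subset_genotypes(gm, loci = !drop)
  list(matrix = out,
       report = new_filter_report(
         stage_row(sprintf("adjacent (gap <= %g bp)", max_gap), "loci",
                   sum(drop)),
         dim(gm), dim(out), removed_loci = colnames(gm$geno)[drop]))
}

apply_locus_rule <- function(cur, keep, rule, stages, removed) {
  stages <- rbind(stages, stage_row(rule, "loci", sum(!keep)))
  removed <- c(removed, colnames(cur$geno)[!keep])
  list(cur = subset_genotypes(cur, loci = keep), stages = stages,
       removed = removed)
}

#' Species-level (cross-species) SNP filter
#'
#' Fixed rule order: biallelic -> remove adjacent SNPs -> quality-depth >=
#' `qd_min` -> missing fraction < `missing_stage1` -> missing fraction <=
#' `missing_stage2` -> minor allele frequency > `maf_min`. The two staged
#' missing-data rules reflect a first pass at 50% followed by a tightening
#' to 30% after sample QC; both are exposed so the stages can be run around
#' [filter_samples()]. MAF is computed on allele counts over non-missing
#' calls across all retained accessions.
#'
#' @param gm a [genotype_matrix()]
#' @param qd_min minimum quality-depth (default 10); `NULL` skips (also
#'   skipped with a note when no `qd` metadata is present).
#' @param missing_stage1 first-stage missing-data threshold, strict `<`
#'   (default 0.50).
#' @param missing_stage2 second-stage threshold, `<=` (default 0.30); `NULL`
#'   skips.
#' @param maf_min loci with MAF `<= maf_min` are removed (default 0.05).
#' @param max_gap adjacency gap passed to [remove_adjacent_snps()]; `NULL`
#'   skips the adjacency rule (e.g. when no tag metadata exists).
#' @return list(`matrix`, `report`)
#' @export
filter_snps_species <- function(gm, qd_min = 10, missing_stage1 = 0.50,
                                missing_stage2 = 0.30, maf_min = 0.05,
                                max_gap = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stages <- stage_row(character(), character(), integer())[0, ]
  removed <- character()
  cur <- gm

  st <- apply_locus_rule(cur, cur$loci$n_alleles == 2L, "not biallelic",
                         stages, removed)
  cur <- st$cur; stages <- st$stages; removed <- st$removed

  if (!is.null(max_gap) && all(c("tag", "pos") %in% names(cur$loci))) {
    adj <- remove_adjacent_snps(cur, max_gap = max_gap)
    stages <- rbind(stages, adj$report$stages)
    removed <- c(removed, adj$report$removed_loci)
    cur <- adj$matrix
  }
  if (!is.null(qd_min) && "qd" %in% names(cur$loci)) {
    st <- apply_locus_rule(cur, cur$loci$qd >= qd_min,
                           sprintf("QD < %g", qd_min), stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  if (!is.null(missing_stage1)) {
    st <- apply_locus_rule(cur, locus_missing_fraction(cur) < missing_stage1,
                           sprintf("missing >= %g%%", 100 * missing_stage1),
                           stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  if (!is.null(missing_stage2)) {
    st <- apply_locus_rule(cur, locus_missing_fraction(cur) <= missing_stage2,
                           sprintf("missing > %g%%", 100 * missing_stage2),
                           stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  if (!is.null(maf_min)) {
    st <- apply_locus_rule(cur, locus_maf(cur) > maf_min,
                           sprintf("MAF <= %g%%", 100 * maf_min),
                           stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  list(matrix = cur,
       report = new_filter_report(stages, dim(gm), dim(cur),
                                  removed_loci = removed))
}

#' Subpopulation-level SNP filter
#'
#' Same machinery as [filter_snps_species()] with within-subpopulation
#' thresholds: biallelic, adjacency, QD >= `qd_min`, both allele frequencies
#' within `[freq_min, 1 - freq_min]`, and missing fraction <= `missing_max`.
#' Apply to a matrix already restricted to one subpopulation's accessions.
#'
#' @inheritParams filter_snps_species
#' @param freq_min allele-frequency band edge (default 0.10): loci are kept
#'   when the alternate-allele frequency lies in `[freq_min, 1 - freq_min]`.
#' @param missing_max maximum missing fraction, `<=` (default 0.15).
#' @return list(`matrix`, `report`)
#' @export
filter_snps_subpop <- function(gm, qd_min = 10, freq_min = 0.10,
                               missing_max = 0.15, max_gap = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stages <- stage_row(character(), character(), integer())[0, ]
  removed <- character()
  cur <- gm

  st <- apply_locus_rule(cur, cur$loci$n_alleles == 2L, "not biallelic",
                         stages, removed)
  cur <- st$cur; stages <- st$stages; removed <- st$removed
  if (!is.null(max_gap) && all(c("tag", "pos") %in% names(cur$loci))) {
    adj <- remove_adjacent_snps(cur, max_gap = max_gap)
    stages <- rbind(stages, adj$report$stages)
    removed <- c(removed, adj$report$removed_loci)
    cur <- adj$matrix
  }
  if (!is.null(qd_min) && "qd" %in% names(cur$loci)) {
    st <- apply_locus_rule(cur, cur$loci$qd >= qd_min,
                           sprintf("QD < %g", qd_min), stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  if (!is.null(freq_min)) {
    maf <- locus_maf(cur)
    st <- apply_locus_rule(cur, !is.na(maf) & maf >= freq_min,
                           sprintf("allele freq < %g%%", 100 * freq_min),
                           stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  if (!is.null(missing_max)) {
    st <- apply_locus_rule(cur, locus_missing_fraction(cur) <= missing_max,
                           sprintf("missing > %g%%", 100 * missing_max),
                           stages, removed)
    cur <- st$cur; stages <- st$stages; removed <- st$removed
  }
  list(matrix = cur,
       report = new_filter_report(stages, dim(gm), dim(cur),
                                  removed_loci = removed))
}
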