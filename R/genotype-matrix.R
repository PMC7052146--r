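`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genotype matrix object
#'
#' The central container of the pipeline: diploid genotype calls for a set of
#' accessions at a set of biallelic SNP loci, together with per-locus metadata
#' (GBS tag, position on tag, quality-depth) and per-accession metadata
#' (species label, subgenus, coordinates, read count).
#'
#' Genotypes are stored as an integer matrix of alternate-allele dosages:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing call.
#'
#' @param geno integer matrix, accessions in rows, loci in columns, values in
#'   `{0, 1, 2, NA}`. Dimnames are taken as accession / locus IDs when the
#'   `loci` / `accessions` tables do not override them.
#' @param loci data frame of locus metadata with at least a `locus` column;
#'   recognised columns: `tag` (tag ID), `pos` (1-based position on tag),
#'   `qd` (quality-depth score), `ref`, `alt` (allele letters), `n_alleles`
#'   (allele count at the raw call, default 2).
#' @param accessions data frame of accession metadata with at least an
#'   `accession` column; recognised columns: `species`, `subgenus`, `lat`,
#'   `lon` (decimal degrees), `reads` (read count).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci = NULL, accessions = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ACC%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("M%04d", seq_len(ncol(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicate accession IDs")
  if (anyDuplicated(colnames(geno))) stop("duplicate locus IDs")
  row_ids <- rownames(geno) %||% character()
  col_ids <- colnames(geno) %||% character()

  if (is.null(loci)) loci <- data.frame(locus = col_ids)
  if (is.null(accessions)) accessions <- data.frame(accession = row_ids)
  loci <- as.data.frame(loci)
  accessions <- as.data.frame(accessions)
  if (!"locus" %in% names(loci)) stop("`loci` needs a 'locus' column")
  if (!"accession" %in% names(accessions))
    stop("`accessions` needs an 'accession' column")
  if (!identical(as.character(loci$locus), col_ids))
    stop("locus metadata does not match genotype columns")
  if (!identical(as.character(accessions$accession), row_ids))
    stop("accession metadata does not match genotype rows")
  if (!"n_alleles" %in% names(loci)) loci$n_alleles <- 2L
  if ("pos" %in% names(loci) && any(stats::na.omit(loci$pos) < 1))
    stop("locus positions must be >= 1")
  if ("qd" %in% names(loci) && any(stats::na.omit(loci$qd) < 0))
    stop("quality-depth must be >= 0")
  rownames(loci) <- NULL
  rownames(accessions) <- NULL
  structure(list(geno = geno, loci = loci, accessions = accessions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("<genotype_matrix> %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss))
  if ("species" %in% names(x$accessions)) {
    tab <- table(x$accessions$species)
    cat("  species:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by accessions and/or loci
#'
#' Metadata tables are subset in step with the genotype matrix.
#'
#' @param gm a [genotype_matrix()]
#' @param accessions,loci character IDs, logical or integer indices; `NULL`
#'   keeps everything.
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(gm, accessions = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ai <- resolve_index(accessions, rownames(gm$geno), "accession")
  li <- resolve_index(loci, colnames(gm$geno), "locus")
  genotype_matrix(gm$geno[ai, li, drop = FALSE],
                  loci = gm$loci[li, , drop = FALSE],
                  accessions = gm$accessions[ai, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    i <- match(idx, ids)
    if (anyNA(i)) stop("unknown ", what, " ID(s): ",
                       paste(idx[is.na(i)], collapse = ", "))
    return(i)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}

#' Extract the species partition from accession metadata
#'
#' @param gm a [genotype_matrix()]
#' @param column metadata column holding the group label.
#' @return named character vector mapping accession ID to group label.
#' @export
species_partition <- function(gm, column = "species") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!column %in% names(gm$accessions))
    stop("no '", column, "' column in accession metadata")
  stats::setNames(as.character(gm$accessions[[column]]),
                  gm$accessions$accession)
}

# validate that `partition` covers exactly the accessions of gm; returns a
# factor in the order of gm's rows, preserving first-appearance group order
check_partition <- function(gm, partition) {
  if (is.factor(partition))
    partition <- stats::setNames(as.character(partition), names(partition))
  ids <- rownames(gm$geno)
  if (is.null(names(partition))) {
    if (length(partition) != length(ids))
      stop("unnamed partition must have one label per accession")
    names(partition) <- ids
  }
  if (!all(ids %in% names(partition)))
    stop("partition is missing accessions: ",
         paste(utils::head(setdiff(ids, names(partition))), collapse = ", "))
  p <- partition[ids]
  if (anyNA(p)) stop("partition contains NA group labels")
  factor(p, levels = unique(p))
}

#' Merge groups of a partition into a declared species complex
#'
#' Used to classify alleles and count private/diagnostic SNPs at the level of
#' a species complex (for example two inter-fertile subspecies treated as one
#' taxon).
#'
#' @param partition named vector accession -> group
#' @param members character vector of group labels to merge
#' @param name label for the merged complex (default: members joined by "/")
#' @return named character vector with the members relabelled.
#' @export
merge_groups <- function(partition, members, name = paste(members, collapse = "/")) {
  p <- stats::setNames(as.character(partition), names(partition))
  if (!all(members %in% p))
    stop("group(s) not present in partition: ",
         paste(setdiff(members, p), collapse = ", "))
  p[p %in% members] <- name
  p
}
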