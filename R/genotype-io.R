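#' Convert raw GBS mapping scores to genotype codes
#'
#' GBS pipelines emit per-call mapping scores A (homozygous reference),
#' B (homozygous alternate), H (heterozygous), and the ambiguous scores
#' D (A or H) and C (B or H). Under the strict conversion used here, the
#' ambiguous C and D scores become missing data, mirroring the 11/22/12/00
#' recoding used by GenAlEx-style analyses.
#'
#' @param raw character matrix (or vector) with values in `{A,B,H,C,D}`.
#' @return integer codes: A -> 0, B -> 2, H -> 1, C/D -> NA, same shape as
#'   `raw`.
#' @export
convert_scores <- function(raw) {
  map <- c(A = 0L, B = 2L, H = 1L, C = NA_integer_, D = NA_integer_)
  v <- toupper(as.character(raw))
  unknown <- !(v %in% c(names(map), NA))
  if (any(unknown))
    stop("unknown score token(s): ",
         paste(unique(v[unknown]), collapse = ", "))
  out <- map[v]
  if (!is.null(dim(raw))) {
    dim(out) <- dim(raw)
    dimnames(out) <- dimnames(raw)
  } else names(out) <- names(raw)
  out
}

.vocab_numeric <- c("11" = 0L, "22" = 2L, "12" = 1L, "21" = 1L, "00" = NA_integer_)

#' Read a genotype table from delimited text
#'
#' Expects a header row of locus IDs and one row per accession (first column =
#' accession ID). Two cell vocabularies are accepted: the numeric GenAlEx-style
#' codes `{11, 22, 12, 00}` and the GBS mapping scores `{A, B, H, C, D}`
#' (C and D convert to missing, see [convert_scores()]).
#'
#' @param path delimited text file; delimiter auto-detected (tab or comma)
#'   unless given.
#' @param vocab `"auto"`, `"numeric"` (11/22/12/00) or `"letters"` (A/B/H/C/D).
#' @param sep field delimiter; `NULL` = auto-detect from the header line.
#' @param locus_meta,accession_meta optional paths to sidecar metadata tables
#'   (same delimiter) with `locus` / `accession` key columns.
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, vocab = c("auto", "numeric", "letters"),
                           sep = NULL, locus_meta = NULL, accession_meta = NULL) {
  vocab <- match.arg(vocab)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("genotype table needs a header and >= 1 row")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  ncol_expected <- length(cells[[1]])
  ragged <- which(vapply(cells, length, 0L) != ncol_expected)
  if (length(ragged))
    stop("ragged row(s) at line(s): ", paste(ragged, collapse = ", "))
  header <- trimws(cells[[1]])
  loci_ids <- header[-1]
  body <- do.call(rbind, lapply(cells[-1], trimws))
  acc_ids <- body[, 1]
  if (anyDuplicated(acc_ids)) stop("duplicate accession IDs in table")
  if (anyDuplicated(loci_ids)) stop("duplicate locus IDs in header")
  raw <- body[, -1, drop = FALSE]
  dimnames(raw) <- list(acc_ids, loci_ids)

  tokens <- unique(as.vector(raw))
  if (vocab == "auto") {
    vocab <- if (all(tokens %in% names(.vocab_numeric))) "numeric"
             else "letters"
  }
  if (vocab == "numeric") {
    unknown <- !(raw %in% names(.vocab_numeric))
    dim(unknown) <- dim(raw)
    if (any(unknown)) {
      ij <- which(unknown, arr.ind = TRUE)[1, ]
      stop(sprintf("unknown token '%s' at accession %s, locus %s",
                   raw[unknown][1], acc_ids[ij[1]], loci_ids[ij[2]]))
    }
    geno <- .vocab_numeric[raw]
    dim(geno) <- dim(raw); dimnames(geno) <- dimnames(raw)
  } else {
    geno <- convert_scores(raw)
  }

  lmeta <- if (!is.null(locus_meta))
    utils::read.delim(locus_meta, sep = sep, stringsAsFactors = FALSE)
  ameta <- if (!is.null(accession_meta))
    utils::read.delim(accession_meta, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(lmeta)) {
    i <- match(loci_ids, lmeta$locus)
    if (anyNA(i)) stop("locus metadata missing loci: ",
                       paste(utils::head(loci_ids[is.na(i)]), collapse = ", "))
    lmeta <- lmeta[i, , drop = FALSE]
  }
  if (!is.null(ameta)) {
    i <- match(acc_ids, ameta$accession)
    if (anyNA(i)) stop("accession metadata missing accessions: ",
                       paste(utils::head(acc_ids[is.na(i)]), collapse = ", "))
    ameta <- ameta[i, , drop = FALSE]
  }
  genotype_matrix(geno, loci = lmeta, accessions = ameta)
}

#' Write a genotype matrix (and metadata sidecars) to delimited text
#'
#' @param gm a [genotype_matrix()]
#' @param path output file for the genotype table.
#' @param vocab `"numeric"` writes 11/22/12/00, `"letters"` writes A/B/H with
#'   missing as C.
#' @param sep field delimiter.
#' @param locus_meta,accession_meta optional output paths for the metadata
#'   sidecar tables.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, vocab = c("numeric", "letters"),
                            sep = "\t", locus_meta = NULL, accession_meta = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vocab <- match.arg(vocab)
  codes <- if (vocab == "numeric") c("11", "12", "22") else c("A", "H", "B")
  na_code <- if (vocab == "numeric") "00" else "C"
  chr <- matrix(na_code, nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  chr[ok] <- codes[gm$geno[ok] + 1L]
  out <- cbind(accession = rownames(gm$geno), chr)
  colnames(out) <- c("accession", colnames(gm$geno))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(locus_meta))
    utils::write.table(gm$loci, locus_meta, sep = sep, quote = FALSE,
                       row.names = FALSE)
  if (!is.null(accession_meta))
    utils::write.table(gm$accessions, accession_meta, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Export biallelic genotypes as minimal VCF-style records
#'
#' Tag IDs become contigs and position-on-tag the POS field; only the GT
#' field is written. Intended for interoperability, not round-tripping.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  l <- gm$loci
  ref <- if ("ref" %in% names(l)) as.character(l$ref) else rep("A", nrow(l))
  alt <- if ("alt" %in% names(l)) as.character(l$alt) else rep("T", nrow(l))
  tag <- if ("tag" %in% names(l)) as.character(l$tag) else as.character(l$locus)
  pos <- if ("pos" %in% names(l)) l$pos else rep(1L, nrow(l))
  gt_map <- c("0/0", "0/1", "1/1")
  gts <- apply(gm$geno, 2, function(col) {
    out <- rep("./.", length(col))
    out[!is.na(col)] <- gt_map[col[!is.na(col)] + 1L]
    out
  })
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gbspopgen",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$geno)), collapse = "\t")),
             con)
  qual <- if ("qd" %in% names(l)) format(l$qd, trim = TRUE) else "."
  for (j in seq_len(ncol(gm$geno))) {
    writeLines(paste(c(tag[j], pos[j], l$locus[j], ref[j], alt[j],
                       if (length(qual) > 1) qual[j] else qual,
                       "PASS", ".", "GT", gts[, j]), collapse = "\t"), con)
  }
  invisible(path)
}
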