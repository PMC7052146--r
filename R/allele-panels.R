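# Private/diagnostic allele machinery. Allele-level definitions: an allele
# carried (frequency > 0 among non-missing calls) by exactly one group is
# private when fixed (frequency 1.0) in that group and diagnostic
# otherwise; alleles carried by two or more groups are shared. A
# heterozygote carries both alleles for the uniqueness test and contributes
# one copy of each to frequencies. Classification can be run at the level
# of a declared species complex by merging groups first (merge_groups()).

#' Classify every allele as private, diagnostic, shared or absent
#'
#' @param gm a [genotype_matrix()] (biallelic loci).
#' @param partition named accession -> group vector; must define >= 2
#'   groups. Merge groups with [merge_groups()] to classify at
#'   species-complex level.
#' @return data frame with one row per (locus, allele): `locus`, `allele`
#'   (`"ref"`/`"alt"`), `status`, `carrier` (group, for private/diagnostic),
#'   `carrier_freq` (allele frequency within the carrier).
#' @export
classify_alleles <- function(gm, partition) {
  af <- allele_frequencies(gm, partition)
  groups <- colnames(af$freq)
  if (length(groups) < 2)
    stop("allele classification needs >= 2 groups")
  classify_one <- function(freq_row) {
    # freq_row: per-group frequency of one allele, NA = group untyped
    carried <- which(!is.na(freq_row) & freq_row > 0)
    if (length(carried) == 0)
      return(list(status = "absent", carrier = NA_character_,
                  carrier_freq = NA_real_))
    if (length(carried) > 1)
      return(list(status = "shared", carrier = NA_character_,
                  carrier_freq = NA_real_))
    g <- carried
    list(status = if (freq_row[g] >= 1) "private" else "diagnostic",
         carrier = groups[g], carrier_freq = unname(freq_row[g]))
  }
  L <- nrow(af$freq)
  out <- vector("list", 2 * L)
  for (i in seq_len(L)) {
    alt <- classify_one(af$freq[i, ])
    ref <- classify_one(1 - af$freq[i, ])
    out[[2 * i - 1]] <- c(list(locus = rownames(af$freq)[i], allele = "ref"), ref)
    out[[2 * i]] <- c(list(locus = rownames(af$freq)[i], allele = "alt"), alt)
  }
  do.call(rbind, lapply(out, as.data.frame))
}

#' Count private and diagnostic alleles per group
#'
#' @param classification output of [classify_alleles()].
#' @param groups optional group ordering for the output (default: groups
#'   observed as carriers).
#' @return data frame: group, n_private, n_diagnostic, plus a `Total` row.
#' @export
count_private_diagnostic <- function(classification, groups = NULL) {
  cls <- classification
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(cls$carrier)))
  count <- function(g, status) sum(cls$status == status &
                                     !is.na(cls$carrier) & cls$carrier == g)
  out <- data.frame(group = groups,
                    n_private = vapply(groups, count, 0L, status = "private"),
                    n_diagnostic = vapply(groups, count, 0L,
                                          status = "diagnostic"),
                    row.names = NULL)
  rbind(out, data.frame(group = "Total",
                        n_private = sum(out$n_private),
                        n_diagnostic = sum(out$n_diagnostic)))
}

#' Select a minimal species-diagnostic SNP panel
#'
#' One private-allele SNP per group where available (tie-break: least
#' missing data at the locus, then lowest locus ID). For a group without
#' private alleles that belongs to a declared complex, a diagnostic SNP is
#' accepted as a separator when every one of the group's accessions carries
#' the allele (homozygous or heterozygous) and every other accession of the
#' same complex is homozygous for the opposite allele. Groups coverable by
#' neither are reported uncoverable and a partial panel is returned with a
#' warning.
#'
#' @param gm a [genotype_matrix()]
#' @param partition named accession -> group vector (finest level, e.g.
#'   species).
#' @param complexes optional named list: complex name -> member groups.
#'   Private alleles are first sought at complex level for member groups.
#' @return list with `panel` (data frame: locus, allele, target, backing =
#'   `"private"`/`"separator"`), `uncoverable` (character vector of groups).
#' @export
select_panel <- function(gm, partition, complexes = NULL) {
  p0 <- stats::setNames(as.character(partition), names(partition))
  groups <- unique(p0[rownames(gm$geno)])
  if (length(groups) < 2)
    stop("panel selection needs >= 2 groups")
  # classification partition: members of a declared complex merged
  p_cls <- p0
  complex_of <- stats::setNames(rep(NA_character_, length(groups)), groups)
  for (cx in names(complexes)) {
    p_cls <- merge_groups(p_cls, complexes[[cx]], cx)
    complex_of[complexes[[cx]]] <- cx
  }
  cls <- classify_alleles(gm, p_cls)
  miss <- colMeans(is.na(gm$geno))

  pick_private <- function(target) {
    cand <- cls[cls$status == "private" & !is.na(cls$carrier) &
                  cls$carrier == target, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(miss[cand$locus], cand$locus), , drop = FALSE]
    cand[1, c("locus", "allele")]
  }
  freq_tbl <- allele_frequencies(gm, p0)$freq

  separator_for <- function(g) {
    cx <- complex_of[g]
    if (is.na(cx)) return(NULL)
    partners <- setdiff(complexes[[cx]], g)
    mine <- gm$geno[p0[rownames(gm$geno)] == g, , drop = FALSE]
    theirs <- gm$geno[p0[rownames(gm$geno)] %in% partners, , drop = FALSE]
    for (allele in c("alt", "ref")) {
      m <- if (allele == "alt") mine else 2L - mine
      t2 <- if (allele == "alt") theirs else 2L - theirs
      # all target accessions typed and carrying (>= 1 copy); all partners
      # typed and homozygous for the opposite allele
      ok <- colSums(is.na(m)) == 0 & colSums(m >= 1L) == nrow(m) &
        colSums(is.na(t2)) == 0 & colSums(t2 == 0L) == nrow(t2)
      if (any(ok)) {
        loc <- colnames(gm$geno)[ok]
        loc <- loc[order(miss[loc], loc)][1]
        return(data.frame(locus = loc, allele = allele))
      }
    }
    NULL
  }

  rows <- list(); uncoverable <- character()
  covered_cx <- character()
  for (g in groups) {
    cx <- complex_of[g]
    hit <- pick_private(if (is.na(cx)) g else cx)
    if (!is.null(hit) && is.na(cx)) {
      rows[[g]] <- data.frame(hit, target = g, backing = "private",
                              complex = NA_character_)
      next
    }
    sep <- separator_for(g)
    if (!is.na(cx) && !is.null(hit) && !(cx %in% covered_cx)) {
      # one complex-level private identifies the complex itself
      rows[[paste0(cx, "::complex")]] <-
        data.frame(hit, target = cx, backing = "private",
                   complex = cx)
      covered_cx <- c(covered_cx, cx)
    }
    if (!is.null(sep)) {
      rows[[g]] <- data.frame(sep, target = g, backing = "separator",
                              complex = cx)
    } else {
      uncoverable <- c(uncoverable, g)
    }
  }
  if (length(uncoverable))
    warning("no private or fully-separating allele for: ",
            paste(uncoverable, collapse = ", "), " (partial panel)")
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  list(panel = panel, uncoverable = uncoverable)
}

#' Assign accessions to species from a diagnostic panel
#'
#' An accession is assigned to the target whose panel allele it carries
#' (one or two copies). Carrying panel alleles of two or more targets
#' yields status `"conflict"` (putative hybrid); carrying none,
#' `"unresolved"`. Missing panel genotypes are counted and reported as
#' reduced evidence.
#'
#' @param panel panel data frame from [select_panel()].
#' @param gm a [genotype_matrix()] with the panel loci present.
#' @return data frame: accession, call (target label, `"conflict"` or
#'   `"unresolved"`), targets_carried, n_panel_missing, zero_evidence.
#' @export
assign_species <- function(panel, gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(panel$locus %in% colnames(gm$geno)))
    stop("panel loci absent from matrix: ",
         paste(setdiff(panel$locus, colnames(gm$geno)), collapse = ", "))
  res <- lapply(rownames(gm$geno), function(acc) {
    g <- gm$geno[acc, panel$locus]
    dos <- ifelse(panel$allele == "alt", g, 2L - g)
    hit <- !is.na(dos) & dos >= 1L
    carried <- unique(panel$target[hit])
    # a complex-level call is refined, not contradicted, by a carried
    # member-level separator
    if ("complex" %in% names(panel)) {
      refined <- stats::na.omit(unique(panel$complex[hit & panel$backing ==
                                                       "separator"]))
      carried <- setdiff(carried, refined)
    }
    n_missing <- sum(is.na(g))
    call <- if (n_missing == nrow(panel)) "unresolved"
            else if (length(carried) == 0) "unresolved"
            else if (length(carried) > 1) "conflict"
            else carried
    data.frame(accession = acc, call = call,
               targets_carried = paste(carried, collapse = "+"),
               n_panel_missing = n_missing,
               zero_evidence = n_missing == nrow(panel))
  })
  do.call(rbind, res)
}

#' Flag putative hybrids by excess heterozygosity
#'
#' Accessions whose heterozygous-SNP fraction exceeds `het_multiplier`
#' times their group's median are flagged.
#'
#' @inheritParams allele_frequencies
#' @param het_multiplier flag threshold as a multiple of the group median
#'   (default 3); values `<= 1` flag everything above the median and draw a
#'   warning.
#' @return data frame: accession, group, pct_het, group_median, flagged.
#' @export
flag_hybrids <- function(gm, partition, het_multiplier = 3) {
  if (het_multiplier <= 1)
    warning("het_multiplier <= 1 flags every accession above its group median")
  p <- check_partition(gm, partition)
  pct_het <- 100 * rowSums(gm$geno == 1L, na.rm = TRUE) /
    pmax(rowSums(!is.na(gm$geno)), 1)
  med <- stats::ave(pct_het, p, FUN = stats::median)
  data.frame(accession = rownames(gm$geno), group = as.character(p),
             pct_het = unname(pct_het), group_median = unname(med),
             flagged = unname(pct_het > het_multiplier * med))
}
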