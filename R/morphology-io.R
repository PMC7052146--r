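#' Read / write morphology tables with a trait-schema sidecar
#'
#' The table is delimited text with an `accession` column plus one column
#' per trait; the optional schema sidecar declares each trait's type
#' (`categorical` / `quantitative`) so quantitative columns are parsed as
#' numeric on read.
#'
#' @param path morphology table path (tab-delimited).
#' @param schema optional path of the schema sidecar (columns: trait,
#'   type).
#' @return `read_morphology`: the morphology data frame.
#' @export
read_morphology <- function(path, schema = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  tab <- as_morpho(tab)
  if (!is.null(schema)) {
    sch <- utils::read.delim(schema, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sch))) {
      tr <- sch$trait[i]
      if (!tr %in% names(tab)) stop("schema names unknown trait: ", tr)
      tab[[tr]] <- if (sch$type[i] == "quantitative")
        as.numeric(tab[[tr]]) else as.character(tab[[tr]])
    }
  }
  tab
}

#' @param table morphology data frame.
#' @rdname read_morphology
#' @export
write_morphology <- function(table, path, schema = NULL) {
  tab <- as_morpho(table)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(schema)) {
    traits <- trait_columns(tab)
    sch <- data.frame(trait = traits,
                      type = ifelse(vapply(tab[traits], is.numeric, TRUE),
                                    "quantitative", "categorical"))
    utils::write.table(sch, schema, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
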