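#' Read a per-taxon meiofauna abundance table
#'
#' The expected layout is one row per taxon plus one `Total` row, with
#' `<treatment>_avg` and `<treatment>_se` columns (abundances in
#' individuals per 10 cm2). The package bundles such a table for the four
#' incubation treatments in `inst/extdata/meiofauna_taxa.tsv`.
#'
#' @param path tab-separated file; defaults to the bundled table.
#' @return a data.frame.
#' @export
read_taxa_table <- function(path = system.file("extdata",
                                               "meiofauna_taxa.tsv",
                                               package = "poreflux")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Check that per-taxon abundances sum to the printed totals
#'
#' A consistency check for treatment-average meiofauna tables: for each
#' treatment, the per-taxon averages are summed and compared with the
#' table's own `Total` row. Printed averages are rounded, so sums may
#' differ from printed totals by a unit or two; `tolerance` sets how much
#' discrepancy still counts as consistent (default 0 = exact).
#'
#' @param taxa data.frame from [read_taxa_table].
#' @param tolerance maximum absolute difference accepted as consistent.
#' @return data.frame with one row per treatment: `treatment`, `taxa_sum`,
#'   `printed_total`, `difference`, `consistent`.
#' @examples
#' check_taxa_totals(read_taxa_table())
#' @export
check_taxa_totals <- function(taxa = read_taxa_table(), tolerance = 0) {
  stopifnot(is.data.frame(taxa), "organism" %in% names(taxa))
  total_row <- grepl("^total", taxa$organism, ignore.case = TRUE)
  if (sum(total_row) != 1)
    stop("table must contain exactly one Total row", call. = FALSE)
  avg_cols <- grep("_avg$", names(taxa), value = TRUE)
  if (!length(avg_cols)) stop("no *_avg columns found", call. = FALSE)
  out <- lapply(avg_cols, function(cl) {
    s <- sum(taxa[[cl]][!total_row])
    tot <- taxa[[cl]][total_row]
    data.frame(treatment = sub("_avg$", "", cl), taxa_sum = s,
               printed_total = tot, difference = s - tot,
               consistent = abs(s - tot) <= tolerance)
  })
  do.call(rbind, out)
}
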