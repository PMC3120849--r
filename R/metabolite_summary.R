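TAXANES <- c("DAB", "B", "DAXT", "DAT", "C", "P")

#' Load a taxane concentration table
#'
#' Reads a tidy table of per-collection-site taxane concentrations
#' (ug/g dry material) for the six routinely quantified analytes:
#' 10-deacetylbaccatin III (DAB), baccatin III (B),
#' 7-xylosyl-10-deacetylpaclitaxel (DAXT), 10-deacetylpaclitaxel (DAT),
#' cephalomannine (C) and paclitaxel (P). With no argument, loads the
#' packaged fixture transcribing published UFLC-MS quantitation of
#' *Taxus mairei* needles and roots from four Chinese collection areas.
#'
#' @param path Path to a TSV with columns `tissue`, `site`, `n_samples`,
#'   the six analytes, and optionally `total_printed` (the total as
#'   printed in the source, kept for consistency checking). Default:
#'   the packaged table.
#' @return Data frame with one row per (tissue, site).
#' @export
taxane_table <- function(path = system.file("extdata",
                                            "taxane_concentrations.tsv",
                                            package = "dgetag")) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("tissue", "site", "n_samples", TAXANES)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(as.matrix(x[TAXANES]) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  x
}

#' Row totals of a taxane table
#'
#' Sum of the six analyte concentrations per row.
#'
#' @param table Data frame from [taxane_table()] (or any subset of its
#'   rows).
#' @return Numeric vector of totals (ug/g).
#' @export
row_total <- function(table) {
  miss <- setdiff(TAXANES, names(table))
  if (length(miss)) stop("missing analyte(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  unname(rowSums(as.matrix(table[TAXANES])))
}

#' Across-site mean concentration for one tissue
#'
#' Unweighted arithmetic mean over collection sites, which is the
#' convention behind published "Average" rows; site sample sizes are
#' deliberately not used as weights.
#'
#' @param table Data frame from [taxane_table()].
#' @param tissue Tissue label (`"needle"` or `"root"` in the fixture).
#' @param taxane One of `"DAB"`, `"B"`, `"DAXT"`, `"DAT"`, `"C"`, `"P"`,
#'   or `"total"` for the mean of row totals.
#' @return Mean concentration (ug/g).
#' @export
site_mean <- function(table, tissue, taxane) {
  rows <- table[table$tissue == tissue, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows for tissue '", tissue, "'",
                            call. = FALSE)
  if (identical(taxane, "total")) return(mean(row_total(rows)))
  stopifnot(taxane %in% TAXANES)
  mean(rows[[taxane]])
}

#' Root-to-needle concentration ratio of a taxane
#'
#' Ratio of across-site mean concentrations, root over needle — the
#' summary statistic behind statements like "root paclitaxel is two to
#' eight times the needle concentration".
#'
#' @param table Data frame from [taxane_table()].
#' @param taxane Analyte code or `"total"`.
#' @param tissues Character pair, numerator tissue first.
#' @return Dimensionless ratio.
#' @export
tissue_ratio <- function(table, taxane, tissues = c("root", "needle")) {
  stopifnot(length(tissues) == 2)
  num <- site_mean(table, tissues[1], taxane)
  den <- site_mean(table, tissues[2], taxane)
  if (den == 0) stop("denominator tissue mean is zero", call. = FALSE)
  num / den
}

#' Check printed totals against component sums
#'
#' Published tables occasionally carry totals differing from the sum of
#' their components by one rounding unit. This reports, per row, the
#' recomputed total, the printed total and their difference; rows off
#' by more than `tol` are flagged — flagged, not corrected, since the
#' printed value is the citable one.
#'
#' @param table Data frame from [taxane_table()] including a
#'   `total_printed` column.
#' @param tol Tolerance in ug/g (default 0.05, one rounding unit at one
#'   decimal place).
#' @return Data frame `tissue`, `site`, `total_computed`,
#'   `total_printed`, `difference`, `consistent`.
#' @export
check_totals <- function(table, tol = 0.05) {
  if (!"total_printed" %in% names(table)) {
    stop("table has no total_printed column", call. = FALSE)
  }
  tc <- row_total(table)
  data.frame(tissue = table$tissue, site = table$site,
             total_computed = tc,
             total_printed = table$total_printed,
             difference = tc - table$total_printed,
             consistent = abs(tc - table$total_printed) <= tol,
             stringsAsFactors = FALSE)
}
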