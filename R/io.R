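read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read a case-control sample from a delimited file
#'
#' Reads a comma- or tab-separated file (delimiter chosen by extension:
#' `.tsv`/`.tab`/`.txt` are tab, anything else comma) with a header row and
#' maps the named columns onto a [cc_sample()]. Rows with missing values in
#' any mapped column are dropped with a warning giving the count. Distinct
#' error conditions are signalled for a missing column
#' (`retroreg_missing_column`), non-binary case coding (`retroreg_bad_y`),
#' and an empty file (`retroreg_empty`).
#'
#' @param path File path.
#' @param x_col,w_col,y_col Column names holding x, w and case status.
#' @param y_codes Length-2 vector `c(control, case)` giving the codes used
#'   in `y_col` (default `c(0, 1)`).
#' @return A [cc_sample()].
#' @export
read_sample <- function(path, x_col = "x", w_col = "w", y_col = "y",
                        y_codes = c(0, 1)) {
  d <- read_delim_auto(path)
  if (nrow(d) == 0L)
    stop(structure(class = c("retroreg_empty", "error", "condition"),
                   list(message = sprintf("no data rows in '%s'", path),
                        call = NULL)))
  for (col in c(x_col, w_col, y_col)) {
    if (!col %in% names(d))
      stop(structure(class = c("retroreg_missing_column", "error", "condition"),
                     list(message = sprintf("column '%s' not found in '%s'",
                                            col, path), call = NULL)))
  }
  x <- d[[x_col]]; w <- d[[w_col]]; yraw <- d[[y_col]]
  keep <- !(is.na(x) | is.na(w) | is.na(yraw))
  if (any(!keep)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)),
            call. = FALSE)
    x <- x[keep]; w <- w[keep]; yraw <- yraw[keep]
  }
  if (!all(yraw %in% y_codes))
    stop(structure(class = c("retroreg_bad_y", "error", "condition"),
                   list(message = sprintf(
                     "column '%s' contains values outside the declared codes (%s)",
                     y_col, paste(y_codes, collapse = ", ")), call = NULL)))
  y <- ifelse(yraw == y_codes[2L], 1L, 0L)
  cc_sample(x, w, y)
}

#' Write estimator results to a delimited file
#'
#' Serializes one or more `"cc_estimate"` rows (method, estimate, stderr,
#' n_used) at full precision, comma- or tab-separated by extension.
#'
#' @param estimates Data frame of estimate rows (e.g. rbind of estimator
#'   outputs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  d <- as.data.frame(estimates)
  d$estimate <- formatC(d$estimate, digits = 15, format = "g")
  d$stderr <- formatC(d$stderr, digits = 15, format = "g")
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stratified 2x2 tables from a delimited file
#'
#' Expects a header row naming the cells `w1x1, w1x0, w0x1, w0x0` plus a
#' `stratum` column with values `controls` and `cases`; entries may be
#' probabilities or counts (counts are normalized per stratum).
#'
#' @param path File path.
#' @param pi Population case probability, in (0, 1).
#' @param haldane Passed to [tables_from_counts()] when entries are counts.
#' @return A [stratified_tables()] object.
#' @export
read_tables <- function(path, pi, haldane = FALSE) {
  d <- read_delim_auto(path)
  need <- c("stratum", "w1x1", "w1x0", "w0x1", "w0x0")
  if (!all(need %in% names(d)))
    stop(structure(class = c("retroreg_missing_column", "error", "condition"),
                   list(message = sprintf(
                     "table file must have columns %s", paste(need, collapse = ", ")),
                     call = NULL)))
  row_of <- function(lab) {
    r <- d[d$stratum == lab, c("w1x1", "w1x0", "w0x1", "w0x0")]
    if (nrow(r) != 1L)
      stop(sprintf("expected exactly one '%s' row", lab), call. = FALSE)
    as.numeric(r[1L, ])
  }
  ctrl <- row_of("controls"); cas <- row_of("cases")
  is_counts <- any(c(ctrl, cas) > 1) || all(c(ctrl, cas) == round(c(ctrl, cas)))
  if (is_counts && all(c(ctrl, cas) == round(c(ctrl, cas))))
    tables_from_counts(ctrl, cas, pi, haldane = haldane)
  else
    stratified_tables(ctrl, cas, pi)
}
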