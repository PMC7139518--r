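# CSV conventions: percent units in files, fractions in memory; values
# written with 6 significant digits; UTF-8, decimal point.

.cohort_cols <- c("patient_id", "group", "cell_type",
                  "pb_naive_pct", "pb_diff_pct",
                  "csf_naive_pct", "csf_diff_pct")

#' Read a cohort of patient records from CSV
#'
#' Expects header columns `patient_id, group, cell_type, pb_naive_pct,
#' pb_diff_pct, csf_naive_pct, csf_diff_pct` plus optional
#' `pb_total_count, csf_total_count`.  Each compartment's naive/diff pair
#' must sum to 100 within 0.5 percentage points (accommodating rounded
#' tables); pairs are renormalised to exactly 100, anything further off is
#' rejected with the offending row number.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `c("lymph_cohort", "data.frame")`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(.cohort_cols, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 1L) stop("cohort file has no rows", call. = FALSE)
  num_cols <- c("pb_naive_pct", "pb_diff_pct", "csf_naive_pct",
                "csf_diff_pct",
                intersect(c("pb_total_count", "csf_total_count"), names(df)))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric value in column %s (row %s)", cl,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  for (pair in list(c("pb_naive_pct", "pb_diff_pct"),
                    c("csf_naive_pct", "csf_diff_pct"))) {
    s <- df[[pair[1]]] + df[[pair[2]]]
    bad <- which(!is.finite(s) | abs(s - 100) > 0.5)
    if (length(bad))
      stop(sprintf("%s + %s differs from 100 by more than 0.5 in row(s): %s",
                   pair[1], pair[2], paste(bad, collapse = ", ")),
           call. = FALSE)
    df[[pair[1]]] <- 100 * df[[pair[1]]] / s
    df[[pair[2]]] <- 100 - df[[pair[1]]]
  }
  class(df) <- c("lymph_cohort", "data.frame")
  df
}

#' Write a cohort of patient records to CSV
#'
#' Numeric columns are written with 6 significant digits; a write/read
#' round trip reproduces the cohort at that precision.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  miss <- setdiff(.cohort_cols, names(df))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- signif(df[[cl]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition-rates table from CSV
#'
#' The canonical layout mirrors published rate tables: one row per
#' `cell_type` x rate, one column per clinical group, values in percent by
#' default.  The unit is recorded in a leading header comment line
#' (`# units: percent` or `# units: fraction`); a file without the header
#' is read as percent.  Values are stored in the returned table in the
#' file's units; [rates_for()] converts to fractions.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `"rates_table"` with columns `cell_type`,
#'   `rate` and one column per group; attribute `"units"`.
#' @examples
#' tab <- read_rates_csv(system.file("extdata", "reference_rates.csv",
#'                                   package = "lymphtraffic"))
#' rates_for(tab, "CD4", "controls")
#' @export
read_rates_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("rates file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  units <- "percent"
  if (length(lines) && grepl("^#", lines[1])) {
    u <- sub("^#\\s*units:\\s*", "", lines[1])
    if (!u %in% c("percent", "fraction"))
      stop(sprintf("unknown units %s in rates file header", deparse(u)),
           call. = FALSE)
    units <- u
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("cell_type", "rate") %in% names(df)))
    stop("rates file needs `cell_type` and `rate` columns", call. = FALSE)
  bad <- setdiff(unique(df$rate), .rate_names)
  if (length(bad))
    stop("unknown rate label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("cell_type", "rate")]))
    stop("duplicate (cell_type, rate) rows in rates file", call. = FALSE)
  groups <- setdiff(names(df), c("cell_type", "rate"))
  if (length(groups) == 0L) stop("rates file has no group columns",
                                 call. = FALSE)
  hi <- if (units == "percent") 100 else 1
  for (g in groups) {
    v <- df[[g]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > hi))
      stop(sprintf("column %s has values outside [0, %g] (%s units)",
                   g, hi, units), call. = FALSE)
  }
  structure(df, units = units, class = c("rates_table", "data.frame"))
}

#' Write a transition-rates table to CSV
#'
#' Inverse of [read_rates_csv()]; writing a table read from a canonical
#' file reproduces it byte for byte.
#'
#' @param table A `"rates_table"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(table, path) {
  units <- attr(table, "units")
  if (is.null(units)) units <- "percent"
  df <- as.data.frame(table)
  groups <- setdiff(names(df), c("cell_type", "rate"))
  for (g in groups)
    df[[g]] <- vapply(df[[g]], function(v)
      format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one lineage/group's rates from a rates table
#'
#' @param table A `"rates_table"` from [read_rates_csv()].
#' @param cell_type,group Row/column selectors.
#' @return A [transition_rates()] object (fractions).
#' @export
rates_for <- function(table, cell_type, group) {
  if (!inherits(table, "rates_table"))
    stop("`table` must be a rates_table (see read_rates_csv)", call. = FALSE)
  groups <- setdiff(names(table), c("cell_type", "rate"))
  if (!group %in% groups)
    stop(sprintf("unknown group %s; file has: %s", deparse(group),
                 paste(groups, collapse = ", ")), call. = FALSE)
  sub <- table[table$cell_type == cell_type, ]
  if (nrow(sub) == 0L)
    stop(sprintf("unknown cell_type %s; file has: %s", deparse(cell_type),
                 paste(unique(table$cell_type), collapse = ", ")),
         call. = FALSE)
  v <- sub[[group]]
  names(v) <- sub$rate
  if (!all(.rate_names %in% names(v)))
    stop(sprintf("rates for %s are incomplete", cell_type), call. = FALSE)
  scale <- if (identical(attr(table, "units"), "fraction")) 1 else 100
  transition_rates(v[["alpha1"]] / scale, v[["alpha2"]] / scale,
                   v[["beta1"]] / scale, v[["beta2"]] / scale,
                   cell_type = cell_type, group = group)
}
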