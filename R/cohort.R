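#' Histology vocabulary of the gastric-polyp cohort tables
#'
#' Fixed column vocabulary shared by the three bundled tables: hyperplastic,
#' inflammatory, fundic-gland, metaplastic, hamartoma, adenomatous polyps and
#' gastric cancer (adenocarcinoma).
#'
#' @return Character vector of the seven histology labels.
#' @export
histology_levels <- function() {
  c("hyperplastic", "inflammatory", "fundic_gland", "metaplastic",
    "hamartoma", "adenomatous", "gastric_cancer")
}

#' Load a cohort contingency table from CSV
#'
#' The CSV must have a header row whose first column is `stratum` followed by
#' the seven histology labels of [histology_levels()], and non-negative
#' integer cells.  Validation failures report the offending cell.
#'
#' @param path CSV path.
#' @param expect_total If given, the grand total must equal this number of
#'   patients.
#' @return A `cohort_table`: list with `counts` (integer matrix, strata x
#'   histologies), `strata`, `histologies`, `n_patients`.
#' @export
load_table <- function(path, expect_total = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("table ", path, " is empty or has no histology columns",
         call. = FALSE)
  }
  hist_cols <- names(df)[-1L]
  unknown <- setdiff(hist_cols, histology_levels())
  if (length(unknown) > 0L) {
    stop("unknown histology label(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  strata <- as.character(df[[1L]])
  counts <- matrix(0L, nrow(df), length(hist_cols),
                   dimnames = list(strata, hist_cols))
  for (j in seq_along(hist_cols)) {
    col <- df[[j + 1L]]
    for (i in seq_len(nrow(df))) {
      v <- suppressWarnings(as.numeric(col[i]))
      if (is.na(v) || v != round(v) || v < 0) {
        stop("non-integer or negative cell at row '", strata[i],
             "', column '", hist_cols[j], "' in ", path, call. = FALSE)
      }
      counts[i, j] <- as.integer(v)
    }
  }
  total <- sum(counts)
  if (!is.null(expect_total) && total != expect_total) {
    stop("grand total ", total, " does not match expected ", expect_total,
         " in ", path, call. = FALSE)
  }
  structure(
    list(counts = counts, strata = strata, histologies = hist_cols,
         n_patients = total),
    class = "cohort_table"
  )
}

#' Load one of the bundled gastric-polyp cohort tables
#'
#' The package ships transcriptions of the 111-patient cohort tabulations:
#' age band x histology, maximum-diameter band x histology, and anatomical
#' location x histology.
#'
#' @param which `"age"`, `"size"` or `"location"`.
#' @return A `cohort_table` (see [load_table()]).
#' @export
cohort_table <- function(which = c("age", "size", "location")) {
  which <- match.arg(which)
  fname <- switch(which,
    age = "table1_age.csv",
    size = "table2_size.csv",
    location = "table3_location.csv"
  )
  path <- system.file("extdata", fname, package = "endostitch")
  if (path == "") stop("bundled table ", fname, " not found", call. = FALSE)
  load_table(path, expect_total = 111L)
}

#' Round half-up to a fixed number of decimals
#'
#' Unlike base [round()], ties go away from zero for positive input
#' (e.g. 50.45 -> 50.5 at 1 decimal), matching how clinical percentages are
#' conventionally printed.
#'
#' @param x Numeric vector (non-negative use case).
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Marginal counts and percentage distribution of a cohort table
#'
#' Sums over the requested axis and reports each margin as a count plus a
#' percentage of the grand total (patients), rounded half-up to 1 decimal.
#'
#' @param table A `cohort_table`.
#' @param axis `"rows"` (strata) or `"columns"` (histologies).
#' @return Data frame with `label`, `count`, `percent`.
#' @export
marginal <- function(table, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  stopifnot(inherits(table, "cohort_table"))
  tot <- if (axis == "rows") rowSums(table$counts) else colSums(table$counts)
  data.frame(
    label = names(tot),
    count = as.integer(tot),
    percent = round_half_up(100 * tot / table$n_patients, 1L),
    row.names = NULL
  )
}

#' Percentage summary of single versus multiple polyps
#'
#' @param single,multiple Patient counts (must sum to the cohort size when
#'   `n_total` is given).
#' @param n_total Optional expected total (e.g. 111).
#' @return Data frame with `label`, `count`, `percent` (half-up, 1 decimal).
#' @export
singleness_summary <- function(single, multiple, n_total = NULL) {
  stopifnot(single >= 0, multiple >= 0)
  tot <- single + multiple
  if (!is.null(n_total) && tot != n_total) {
    stop("single + multiple = ", tot, " does not equal the cohort size ",
         n_total, call. = FALSE)
  }
  data.frame(
    label = c("single", "multiple"),
    count = as.integer(c(single, multiple)),
    percent = round_half_up(100 * c(single, multiple) / tot, 1L)
  )
}

#' Full descriptive summary of the bundled cohort
#'
#' Reproduces the cohort's printed descriptive statistics: histology,
#' age-band, size-band and location distributions, the single/multiple polyp
#' split (80/31), and the non-tumour (91) versus neoplastic (20) totals.
#'
#' @return Nested list of data frames / counts, JSON-serializable.
#' @export
cohort_summary <- function() {
  age <- cohort_table("age")
  size <- cohort_table("size")
  loc <- cohort_table("location")
  hist <- marginal(age, "columns")
  non_tumor <- c("hyperplastic", "inflammatory", "fundic_gland",
                 "metaplastic", "hamartoma")
  list(
    n_patients = age$n_patients,
    histology = hist,
    age = marginal(age, "rows"),
    size = marginal(size, "rows"),
    location = marginal(loc, "rows"),
    singleness = singleness_summary(80L, 31L, n_total = age$n_patients),
    non_tumor_total = sum(hist$count[hist$label %in% non_tumor]),
    neoplastic_total = sum(hist$count[hist$label %in%
                                        c("adenomatous", "gastric_cancer")])
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", x$n_patients, "patients,",
      length(x$strata), "strata x", length(x$histologies), "histologies\n")
  print(x$counts)
  invisible(x)
}
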