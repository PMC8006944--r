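#' Read a subject record
#'
#' Reads one oral-test time series from CSV with mandatory unit-bearing
#' columns `time_min`, `glucose_mmol_L`, `cpeptide_pmol_L`. Demographics and
#' test metadata (`id`, `age_years`, `bmi_kg_m2`, `test_type`) come from a
#' JSON sidecar (`<path>.json`) or the `meta` argument. Validation is
#' row-level: times must be strictly increasing and include 0,
#' concentrations must be positive.
#'
#' @param path CSV file path.
#' @param meta Optional named list overriding/replacing the sidecar.
#' @return A one-row cohort tibble (`id`, `age_years`, `bmi_kg_m2`,
#'   `test_type`, `data`), the same shape as [generate_cohort()] rows.
#' @export
read_subject <- function(path, meta = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_min", "glucose_mmol_L", "cpeptide_pmol_L")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(raw[need])
  if (any(bad <- !is.finite(d$time_min))) {
    stop("non-numeric time in row(s) ", paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(diff(d$time_min) <= 0)) {
    stop("sample times must be strictly increasing (rows ",
         paste(which(diff(d$time_min) <= 0) + 1L, collapse = ", "), ")", call. = FALSE)
  }
  if (d$time_min[1] != 0) stop("record must contain a t = 0 row", call. = FALSE)
  for (col in c("glucose_mmol_L", "cpeptide_pmol_L")) {
    bad <- !is.finite(d[[col]]) | d[[col]] <= 0
    if (any(bad)) {
      stop("non-positive ", col, " in row(s) ", paste(which(bad), collapse = ", "),
           call. = FALSE)
    }
  }

  sidecar <- paste0(path, ".json")
  if (is.null(meta) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  meta <- meta %||% list()
  tibble::tibble(
    id = meta$id %||% sub("\\.csv$", "", basename(path)),
    age_years = meta$age_years %||% NA_real_,
    bmi_kg_m2 = meta$bmi_kg_m2 %||% NA_real_,
    test_type = meta$test_type %||% NA_character_,
    data = list(d)
  )
}

#' Write a subject record
#'
#' Inverse of [read_subject()]: writes the sample CSV and a JSON metadata
#' sidecar. `write_subject()` then `read_subject()` round-trips exactly.
#'
#' @param subject A one-row cohort tibble (columns `id`, `age_years`,
#'   `bmi_kg_m2`, `test_type`, `data`).
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  stopifnot(is.data.frame(subject), nrow(subject) == 1L,
            all(c("id", "data") %in% names(subject)))
  utils::write.csv(subject$data[[1]], path, row.names = FALSE)
  meta <- list(id = subject$id, age_years = subject$age_years,
               bmi_kg_m2 = subject$bmi_kg_m2, test_type = subject$test_type)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Distribution and location tests used in the cohort analyses
#'
#' Thin wrappers over the standard tests used to summarise parameter
#' estimates: Lilliefors' normality test (via the nortest package), the
#' paired Wilcoxon signed-rank test for within-cohort approach comparisons,
#' and the Mann-Whitney U test for between-cohort comparisons.
#'
#' @param x,y Numeric vectors (paired and equal-length for
#'   `wilcoxon_signed_rank`).
#' @return The underlying `htest` object.
#' @name cohort_tests
NULL

#' @rdname cohort_tests
#' @export
lilliefors_test <- function(x) {
  if (!requireNamespace("nortest", quietly = TRUE)) {
    stop("the nortest package is required for the Lilliefors test", call. = FALSE)
  }
  nortest::lillie.test(x)
}

#' @rdname cohort_tests
#' @export
wilcoxon_signed_rank <- function(x, y) stats::wilcox.test(x, y, paired = TRUE)

#' @rdname cohort_tests
#' @export
mann_whitney_u <- function(x, y) stats::wilcox.test(x, y, paired = FALSE)
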