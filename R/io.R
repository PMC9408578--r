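# Delimited cohort files: one record per row, header mandatory, flags 0/1,
# decimal point, UTF-8, missing optionals empty.

cohort_schema_cols <- function() {
  c("id", "group", "sex", "age", "qrs_ms",
    "lafb", "rbbb", "lbbb", "hdavb",
    st_cols(), "collateral", "died_in_hospital")
}

#' Read a cohort from a delimited file
#'
#' Expects the schema written by [write_cohort()]: columns `id`, `group`,
#' `sex`, `age`, `qrs_ms`, the four conduction flags (0/1), `st_I` ..
#' `st_V6` in mm, `collateral`, `died_in_hospital`. Optional fields may be
#' empty. All type invariants are enforced; errors name the offending column
#' or row.
#'
#' @param path File path (comma-separated).
#' @return A cohort tibble, row order preserved.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), age = readr::col_double(),
    qrs_ms = readr::col_double(),
    lafb = readr::col_integer(), rbbb = readr::col_integer(),
    lbbb = readr::col_integer(), hdavb = readr::col_integer(),
    collateral = readr::col_character(),
    died_in_hospital = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(cohort_schema_cols(), names(raw))
  if (length(missing)) {
    abort(paste0("Cohort file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (fl in c("lafb", "rbbb", "lbbb", "hdavb")) {
    bad <- which(!raw[[fl]] %in% c(0L, 1L))
    if (length(bad)) {
      abort(paste0("Row ", bad[1], ": flag `", fl, "` must be 0 or 1."))
    }
    raw[[fl]] <- raw[[fl]] == 1L
  }
  raw$died_in_hospital <- dplyr::if_else(is.na(raw$died_in_hospital),
                                         NA, raw$died_in_hospital == 1L)
  cohort <- dplyr::select(raw, dplyr::all_of(cohort_schema_cols()))
  check_cohort(cohort)
  cohort
}

#' Write a cohort to a delimited file
#'
#' Deterministic byte output for fixed input: fixed column order, flags as
#' 0/1, ST values with at most two decimals, empty fields for missing
#' optionals.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  out <- dplyr::select(tibble::as_tibble(cohort),
                       dplyr::all_of(cohort_schema_cols()))
  for (fl in c("lafb", "rbbb", "lbbb", "hdavb", "died_in_hospital")) {
    out[[fl]] <- as.integer(out[[fl]])
  }
  for (cl in st_cols()) out[[cl]] <- round(out[[cl]], 2)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
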