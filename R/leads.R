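# Lead geometry, ST-elevation thresholds and per-lead predicates.
#
# ST deviations are stored in millimetres throughout (1 mm = 0.1 mV at
# standard calibration); positive values are elevation, negative depression.

#' The canonical 12 ECG leads
#'
#' Returns the twelve standard leads in canonical order: the six limb leads
#' followed by the six precordial leads. Lead names are case-sensitive and
#' used verbatim as suffixes of the `st_*` columns of a cohort table.
#'
#' @return A character vector of length 12.
#' @export
#' @examples
#' ecg_leads()
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", "V1", "V2", "V3", "V4", "V5", "V6")
}

# st_* column names in canonical lead order
st_cols <- function() paste0("st_", ecg_leads())

#' Sex-specific ST-elevation threshold for a lead
#'
#' ST elevation is called at >= 1 mm in every lead except V2 and V3, where the
#' threshold is 2 mm for men and 1.5 mm for women. The boundary is inclusive.
#'
#' @param lead Character vector of lead names (see [ecg_leads()]).
#' @param sex Character vector, `"male"` or `"female"`, recycled against
#'   `lead`.
#' @return Numeric vector of thresholds in mm.
#' @export
#' @examples
#' ste_threshold("V2", "male")   # 2.0
#' ste_threshold("V3", "female") # 1.5
#' ste_threshold("aVR", "male")  # 1.0
ste_threshold <- function(lead, sex) {
  if (!all(lead %in% ecg_leads())) {
    abort(paste0(
      "Unknown lead name(s): ",
      paste(unique(setdiff(lead, ecg_leads())), collapse = ", "),
      ". Valid leads: ", paste(ecg_leads(), collapse = ", ")
    ))
  }
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  n <- max(length(lead), length(sex))
  lead <- rep_len(lead, n)
  sex <- rep_len(sex, n)
  ifelse(lead %in% c("V2", "V3"), ifelse(sex == "male", 2.0, 1.5), 1.0)
}

# Logical n x 12 matrix of lead-wise ST elevation for a cohort tibble.
# Columns named by lead, canonical order.
ste_flag_matrix <- function(cohort) {
  check_cohort(cohort)
  leads <- ecg_leads()
  out <- vapply(leads, function(ld) {
    cohort[[paste0("st_", ld)]] >= ste_threshold(ld, cohort$sex)
  }, logical(nrow(cohort)))
  if (nrow(cohort) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, leads))
  out
}

#' Per-lead ST-elevation calls for a cohort
#'
#' Applies the sex-specific thresholds to every lead of every record and
#' returns the calls in long form, one row per record-lead pair.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] for the schema).
#' @return A tibble with columns `id`, `lead` (factor in canonical order),
#'   `st_mm` and `ste` (logical).
#' @export
ecg_ste <- function(cohort) {
  check_cohort(cohort)
  m <- ste_flag_matrix(cohort)
  tidyr::pivot_longer(
    dplyr::mutate(
      tibble::as_tibble(m),
      id = cohort$id,
      .before = 1
    ),
    cols = -"id", names_to = "lead", values_to = "ste"
  ) |>
    dplyr::mutate(
      lead = factor(.data$lead, levels = ecg_leads()),
      st_mm = as.vector(t(as.matrix(cohort[st_cols()])))
    ) |>
    dplyr::select("id", "lead", "st_mm", "ste")
}

#' Set of leads with qualifying ST elevation, per record
#'
#' @param cohort A cohort tibble.
#' @return A list of character vectors, one per record, each the subset of
#'   [ecg_leads()] at or above its threshold, in canonical order.
#' @export
ste_lead_set <- function(cohort) {
  m <- ste_flag_matrix(cohort)
  leads <- ecg_leads()
  lapply(seq_len(nrow(m)), function(i) leads[m[i, ]])
}

#' Count leads with ST depression
#'
#' A lead is depressed when its deviation is at or below `-threshold_mm`
#' (inclusive). The study's aVR pattern is accompanied by widespread
#' depression in at least 7 leads; no mm threshold is stated in that context,
#' so the conventional clinical floor of 0.5 mm is the default.
#'
#' @param cohort A cohort tibble.
#' @param threshold_mm Positive depression threshold in mm (default 0.5).
#' @return Integer vector, one count per record.
#' @export
depressed_lead_count <- function(cohort, threshold_mm = 0.5) {
  if (!is.numeric(threshold_mm) || length(threshold_mm) != 1L ||
      !is.finite(threshold_mm) || threshold_mm <= 0) {
    abort("`threshold_mm` must be a single positive number.")
  }
  check_cohort(cohort)
  m <- as.matrix(cohort[st_cols()])
  as.integer(rowSums(m <= -threshold_mm))
}

#' Construct a single ECG feature record
#'
#' Convenience constructor for a one-row cohort tibble. ST deviations default
#' to 0 mm; only the named leads need to be given.
#'
#' @param st Named numeric vector of ST deviations in mm, names from
#'   [ecg_leads()]; unnamed leads are 0.
#' @param sex `"male"` or `"female"`.
#' @param qrs_ms QRS duration in ms (default 90).
#' @param lafb,rbbb,lbbb,hdavb Conduction-abnormality flags.
#' @param group Optional culprit-artery group label.
#' @param collateral Optional collateral status (`"none"`, `"lad"`, `"lcx"`,
#'   `"both"`); only meaningful for left-main occlusion records.
#' @param age,died_in_hospital Optional demographics / outcome.
#' @param id Record identifier.
#' @return A one-row cohort tibble.
#' @export
#' @examples
#' r <- ecg_record(st = c(aVR = 1.5, aVL = 1.2), sex = "male")
#' ste_lead_set(r)
ecg_record <- function(st = numeric(), sex = "male", qrs_ms = 90,
                       lafb = FALSE, rbbb = FALSE, lbbb = FALSE, hdavb = FALSE,
                       group = NA_character_, collateral = NA_character_,
                       age = NA_real_, died_in_hospital = NA,
                       id = "r1") {
  if (length(st) && (is.null(names(st)) || !all(names(st) %in% ecg_leads()))) {
    abort("`st` must be named with valid lead names.")
  }
  dev <- setNames(rep(0, 12), ecg_leads())
  dev[names(st)] <- st
  rec <- tibble::tibble(
    id = id, group = group, sex = sex, age = age, qrs_ms = qrs_ms,
    lafb = lafb, rbbb = rbbb, lbbb = lbbb, hdavb = hdavb
  )
  for (ld in ecg_leads()) rec[[paste0("st_", ld)]] <- unname(dev[ld])
  rec$collateral <- collateral
  rec$died_in_hospital <- died_in_hospital
  check_cohort(rec)
  rec
}

# Validate cohort invariants; abort with the offending row on violation.
check_cohort <- function(cohort, arg = "cohort") {
  if (!is.data.frame(cohort)) abort(paste0("`", arg, "` must be a data frame."))
  needed <- c("id", "sex", "qrs_ms", "lafb", "rbbb", "lbbb", "hdavb", st_cols())
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0L) return(invisible(cohort))
  if (!all(cohort$sex %in% c("male", "female"))) {
    bad <- which(!cohort$sex %in% c("male", "female"))[1]
    abort(paste0("Row ", bad, ": `sex` must be \"male\" or \"female\"."))
  }
  stm <- as.matrix(cohort[st_cols()])
  if (!all(is.finite(stm))) {
    bad <- which(!apply(is.finite(stm), 1, all))[1]
    abort(paste0("Row ", bad, ": all 12 ST deviations must be present and finite."))
  }
  if (any(abs(stm) > 20)) {
    bad <- which(apply(abs(stm) > 20, 1, any))[1]
    abort(paste0("Row ", bad, ": |ST deviation| exceeds the 20 mm sanity bound."))
  }
  if (!all(is.finite(cohort$qrs_ms) & cohort$qrs_ms >= 40 & cohort$qrs_ms <= 300)) {
    bad <- which(!(is.finite(cohort$qrs_ms) & cohort$qrs_ms >= 40 & cohort$qrs_ms <= 300))[1]
    abort(paste0("Row ", bad, ": `qrs_ms` must lie in [40, 300]."))
  }
  excl <- cohort$lbbb & (cohort$rbbb | cohort$lafb)
  if (any(excl)) {
    abort(paste0("Row ", which(excl)[1],
                 ": LBBB is mutually exclusive with RBBB and LAFB."))
  }
  if ("collateral" %in% names(cohort) && "group" %in% names(cohort)) {
    bad <- !is.na(cohort$collateral) &
      (is.na(cohort$group) | cohort$group != "lm_occlusion")
    if (any(bad)) {
      abort(paste0("Row ", which(bad)[1],
                   ": only lm_occlusion records may carry a collateral status."))
    }
  }
  invisible(cohort)
}

#' Culprit-artery group labels
#'
#' The six angiographic groups: total left main occlusion (TIMI 0, 100%
#' stenosis), left main subtotal occlusion (TIMI 1-3, >90%), proximal and mid
#' left anterior descending, left circumflex, and right coronary occlusion.
#'
#' @return Character vector of the six group labels in study order.
#' @export
culprit_groups <- function() {
  c("lm_occlusion", "lm_subocclusion", "plad", "mlad", "lcx", "rca")
}
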