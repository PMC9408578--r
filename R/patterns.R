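# Pattern taxonomy and the rule engine for combined diagnostic criteria.

#' @rdname classify_cohort
#' @export
main_patterns <- function() c("stemi", "avr", "avr_avl", "other_nstemi")

#' @rdname classify_cohort
#' @export
fine_patterns <- function() {
  c("i_avl_v2_v5", "i_avl_v1_v5", "v1_v5", "v2_v5",
    "avr_avl", "i_avl_avr", "avr_avl_partial",
    "avr", "avr_v1", "inferior", "other_stemi", "other_nstemi")
}

# fine -> main projection, total by construction of classify_fine
fine_to_main <- function(fine) {
  map <- c(
    i_avl_v2_v5 = "stemi", i_avl_v1_v5 = "stemi", v1_v5 = "stemi",
    v2_v5 = "stemi", inferior = "stemi", other_stemi = "stemi",
    avr = "avr", avr_v1 = "avr",
    avr_avl = "avr_avl", i_avl_avr = "avr_avl", avr_avl_partial = "avr_avl",
    other_nstemi = "other_nstemi"
  )
  factor(unname(map[as.character(fine)]), levels = main_patterns())
}

# The STEMI lead-criteria rule: >= 2 adjacent leads in the V1..V6 chain, or
# >= 2 of {II, III, aVF}, or a lateral combination (V5 or V6) with (I or aVL).
stemi_rule <- function(S) {
  adj <- (S[, "V1"] & S[, "V2"]) | (S[, "V2"] & S[, "V3"]) |
    (S[, "V3"] & S[, "V4"]) | (S[, "V4"] & S[, "V5"]) | (S[, "V5"] & S[, "V6"])
  inferior <- (S[, "II"] + S[, "III"] + S[, "aVF"]) >= 2
  lateral <- (S[, "V5"] | S[, "V6"]) & (S[, "I"] | S[, "aVL"])
  adj | inferior | lateral
}

#' Classify ECG records into the ST-elevation pattern taxonomy
#'
#' `classify_cohort()` appends two columns to a cohort tibble: `main_pattern`
#' (one of `r paste(main_patterns(), collapse = ", ")`) and `fine_pattern`
#' (twelve mutually exclusive fine-grained patterns). `classify_main()` and
#' `classify_fine()` return just the factor vectors.
#'
#' The main taxonomy, in priority order:
#' \enumerate{
#'   \item `avr`: elevation in aVR, with no qualifying elevation in any lead
#'     outside aVR and V1 (the global-subendocardial-ischemia pattern,
#'     accompanied by diffuse ST depression);
#'   \item `avr_avl`: elevation in both aVR and aVL, none in V4-V6, and the
#'     STEMI lead rule not met;
#'   \item `stemi`: at least two adjacent precordial leads (V1..V6 chain), or
#'     at least two of II/III/aVF, or (V5 or V6) together with (I or aVL);
#'   \item `other_nstemi` otherwise.
#' }
#' Ties are impossible by construction, and the fine taxonomy projects onto
#' the main one consistently for every representable record.
#'
#' @param cohort A cohort tibble.
#' @return `classify_cohort()`: the cohort with `main_pattern` and
#'   `fine_pattern` factor columns appended. `classify_main()` /
#'   `classify_fine()`: a factor vector.
#' @export
#' @examples
#' r <- ecg_record(st = c(aVR = 1.5, aVL = 1.2), sex = "male")
#' classify_main(r)
classify_cohort <- function(cohort) {
  dplyr::mutate(
    tibble::as_tibble(cohort),
    main_pattern = classify_main(cohort),
    fine_pattern = classify_fine(cohort)
  )
}

#' @rdname classify_cohort
#' @export
classify_main <- function(cohort) {
  S <- ste_flag_matrix(cohort)
  if (nrow(S) == 0L) return(factor(character(), levels = main_patterns()))
  outside_avr_v1 <- rowSums(S[, setdiff(ecg_leads(), c("aVR", "V1")), drop = FALSE]) > 0
  is_stemi <- stemi_rule(S)
  avr <- S[, "aVR"] & !outside_avr_v1
  avr_avl <- !avr & S[, "aVR"] & S[, "aVL"] &
    !S[, "V4"] & !S[, "V5"] & !S[, "V6"] & !is_stemi
  out <- rep("other_nstemi", nrow(S))
  out[is_stemi] <- "stemi"
  out[avr_avl] <- "avr_avl"
  out[avr] <- "avr"
  factor(out, levels = main_patterns())
}

#' @rdname classify_cohort
#' @export
classify_fine <- function(cohort) {
  S <- ste_flag_matrix(cohort)
  if (nrow(S) == 0L) return(factor(character(), levels = fine_patterns()))
  main <- classify_main(cohort)
  has <- function(...) {
    leads <- c(...)
    rowSums(S[, leads, drop = FALSE]) == length(leads)
  }
  none_of <- function(...) rowSums(S[, c(...), drop = FALSE]) == 0
  n_ste <- rowSums(S)
  # partial precordial involvement: V2/V3 elevated, or deviated >= 1 mm (the
  # generic threshold) while below the sex-specific V2-V3 threshold
  v23_partial <- S[, "V2"] | S[, "V3"] |
    cohort$st_V2 >= 1 | cohort$st_V3 >= 1

  out <- dplyr::case_when(
    has("I", "aVL", "V1", "V2", "V3", "V4", "V5") & !S[, "aVR"] ~ "i_avl_v1_v5",
    has("I", "aVL", "V2", "V3", "V4", "V5") & !S[, "V1"] & !S[, "aVR"] ~ "i_avl_v2_v5",
    has("V1", "V2", "V3", "V4", "V5") & none_of("I", "aVL", "aVR") ~ "v1_v5",
    has("V2", "V3", "V4", "V5") & none_of("V1", "I", "aVL", "aVR") ~ "v2_v5",
    S[, "aVR"] & S[, "V1"] & n_ste == 2 ~ "avr_v1",
    S[, "aVR"] & n_ste == 1 ~ "avr",
    main == "avr_avl" & v23_partial ~ "avr_avl_partial",
    has("I", "aVL", "aVR") & none_of("V4", "V5", "V6") & main != "stemi" ~ "i_avl_avr",
    has("aVR", "aVL") & !S[, "I"] & none_of("V4", "V5", "V6") & main != "stemi" ~ "avr_avl",
    (S[, "II"] + S[, "III"] + S[, "aVF"]) >= 2 ~ "inferior",
    main == "stemi" ~ "other_stemi",
    .default = "other_nstemi"
  )
  factor(out, levels = fine_patterns())
}

# ---- criteria registry -----------------------------------------------------

# each criterion is a pure function cohort -> logical vector
criterion_fns <- function() {
  S <- function(cohort) ste_flag_matrix(cohort)
  fine <- function(cohort) classify_fine(cohort)
  list(
    # exclusive fine-pattern criteria (the aVR rows of the feature table)
    avr_isolated = function(cohort) fine(cohort) == "avr",
    avr_v1 = function(cohort) fine(cohort) == "avr_v1",
    # permissive lead-pair criterion: any record with both aVR and aVL elevated
    ste_avr_avl = function(cohort) {
      s <- S(cohort); s[, "aVR"] & s[, "aVL"]
    },
    # anterolateral elevation without V1 and without aVR; the aVR exclusion
    # makes this disjoint from ste_avr_avl so Model 1 counts add exactly
    i_avl_v2_v5 = function(cohort) {
      s <- S(cohort)
      s[, "I"] & s[, "aVL"] & s[, "V2"] & s[, "V3"] & s[, "V4"] & s[, "V5"] &
        !s[, "V1"] & !s[, "aVR"]
    },
    i_avl_v1_v5 = function(cohort) fine(cohort) == "i_avl_v1_v5",
    v1_v5 = function(cohort) fine(cohort) == "v1_v5",
    v2_v5 = function(cohort) fine(cohort) == "v2_v5",
    inferior = function(cohort) {
      s <- S(cohort); s[, "II"] & s[, "III"] & s[, "aVF"]
    },
    stemi = function(cohort) classify_main(cohort) == "stemi",
    nstemi = function(cohort) classify_main(cohort) != "stemi",
    lafb = function(cohort) cohort$lafb & !cohort$rbbb,
    rbbb = function(cohort) cohort$rbbb & !cohort$lafb,
    bifascicular = function(cohort) cohort$lafb & cohort$rbbb,
    lafb_any = function(cohort) cohort$lafb,
    # the four Model 2 components
    avr_avl_lafb = function(cohort) {
      s <- S(cohort); s[, "aVR"] & s[, "aVL"] & cohort$lafb & !cohort$rbbb
    },
    avr_avl_bifascicular = function(cohort) {
      s <- S(cohort); s[, "aVR"] & s[, "aVL"] & cohort$lafb & cohort$rbbb
    },
    i_avl_v2_v5_lafb = function(cohort) {
      builtin_criteria()$i_avl_v2_v5(cohort) & cohort$lafb & !cohort$rbbb
    },
    i_avl_v2_v5_bifascicular = function(cohort) {
      builtin_criteria()$i_avl_v2_v5(cohort) & cohort$lafb & cohort$rbbb
    },
    model1 = function(cohort) model1(cohort),
    model2 = function(cohort) model2(cohort)
  )
}

#' Built-in diagnostic criteria
#'
#' Returns the registry of named Boolean criteria over cohort records. The
#' registry distinguishes exclusive-pattern criteria (`avr_isolated`,
#' `avr_v1`: the record's whole elevation set is that pattern) from permissive
#' lead-pair criteria (`ste_avr_avl`: both leads elevated, any company),
#' mirroring how the study's feature table counts them.
#'
#' @param extra Optional named list of additional criterion functions
#'   (`function(cohort) logical`). Re-using a built-in name is an error.
#' @return Named list of criterion functions.
#' @export
#' @examples
#' names(builtin_criteria())
builtin_criteria <- function(extra = NULL) {
  reg <- criterion_fns()
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      abort("All extra criteria must be named.")
    }
    dup <- intersect(names(extra), names(reg))
    if (length(dup)) {
      abort(paste0("Duplicate criterion registration: ",
                   paste(dup, collapse = ", ")))
    }
    ok <- vapply(extra, is.function, logical(1))
    if (!all(ok)) abort("Extra criteria must be functions of a cohort.")
    reg <- c(reg, extra)
  }
  reg
}

#' Combined rule-based criteria for left main occlusion
#'
#' `model1()` is the union of two ST-elevation criteria: elevation in both aVR
#' and aVL, or elevation in I, aVL and V2-V5 without V1 (and without aVR,
#' which makes the two components disjoint). `model2()` conjoins `model1()`
#' with left anterior fascicular block (with or without RBBB), which is
#' exactly the union of the four published component criteria.
#'
#' @param cohort A cohort tibble.
#' @return Logical vector, one call per record.
#' @export
#' @examples
#' model1(ecg_record(st = c(aVR = 1.5, aVL = 1.2)))
model1 <- function(cohort) {
  reg <- criterion_fns()
  reg$ste_avr_avl(cohort) | reg$i_avl_v2_v5(cohort)
}

#' @rdname model1
#' @export
model2 <- function(cohort) {
  check_cohort(cohort)
  model1(cohort) & cohort$lafb
}

#' Evaluate named criteria over a cohort
#'
#' @param cohort A cohort tibble.
#' @param criteria Character vector of criterion names (see
#'   [builtin_criteria()]), or a named list mixing names and criterion
#'   functions.
#' @param registry Criterion registry, default [builtin_criteria()].
#' @return A tibble with one row per record per criterion: `id`, `criterion`,
#'   `positive`.
#' @export
evaluate_criterion <- function(cohort, criteria, registry = builtin_criteria()) {
  check_cohort(cohort)
  if (is.character(criteria)) criteria <- as.list(setNames(criteria, criteria))
  purrr::imap(criteria, function(cr, nm) {
    fn <- if (is.function(cr)) cr else {
      if (!cr %in% names(registry)) {
        abort(paste0("Unknown criterion: \"", cr, "\"."))
      }
      registry[[cr]]
    }
    tibble::tibble(id = cohort$id, criterion = nm, positive = fn(cohort))
  }) |>
    purrr::list_rbind()
}
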