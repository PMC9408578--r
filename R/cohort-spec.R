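# Study cohort specification: all printed marginal counts and distribution
# parameters, resolved into one feasible joint allocation of
# pattern x conduction x collateral x territory per group.
#
# The joint allocation is under-determined beyond the published margins; the
# one fixed here is feasible and reproduces every feature-table row, the
# collateral cross-tabulation, and the fascicular-block split between STEMI
# and NSTEMI. Any feasible allocation yields the same marginal counts, which
# is all the downstream statistics depend on.

# per-archetype elevated / sub-threshold / depressed lead sets
archetype_defs <- function() {
  list(
    i_avl_v2_v5 = list(elev = c("I", "aVL", "V2", "V3", "V4", "V5"),
                       sub = character(), depress = FALSE, fine = "i_avl_v2_v5"),
    i_avl_v1_v5 = list(elev = c("I", "aVL", "V1", "V2", "V3", "V4", "V5"),
                       sub = character(), depress = FALSE, fine = "i_avl_v1_v5"),
    v1_v5 = list(elev = c("V1", "V2", "V3", "V4", "V5"),
                 sub = character(), depress = FALSE, fine = "v1_v5"),
    v2_v5 = list(elev = c("V2", "V3", "V4", "V5"),
                 sub = character(), depress = FALSE, fine = "v2_v5"),
    avr_avl = list(elev = c("aVR", "aVL"),
                   sub = character(), depress = FALSE, fine = "avr_avl"),
    i_avl_avr = list(elev = c("I", "aVL", "aVR"),
                     sub = character(), depress = FALSE, fine = "i_avl_avr"),
    # the two records with aVR+aVL elevation and partial precordial
    # involvement: V2-V3 deviated >= 1 mm but below the sex-specific
    # threshold, so they stay in the aVR+aVL (NSTEMI) family
    avr_avl_partial = list(elev = c("I", "aVL", "aVR"),
                           sub = c("V2", "V3"), depress = FALSE,
                           fine = "avr_avl_partial"),
    avr = list(elev = "aVR", sub = character(), depress = TRUE, fine = "avr"),
    avr_v1 = list(elev = c("aVR", "V1"), sub = character(), depress = TRUE,
                  fine = "avr_v1"),
    inferior = list(elev = c("II", "III", "aVF"),
                    sub = character(), depress = FALSE, fine = "inferior"),
    # filler STEMI morphologies matching no feature-table criterion row
    filler_anterior = list(elev = c("V2", "V3", "V4"),
                           sub = character(), depress = FALSE,
                           fine = "other_stemi"),
    filler_lateral = list(elev = c("I", "aVL", "V5", "V6"),
                          sub = character(), depress = FALSE,
                          fine = "other_stemi")
  )
}

# leads depressed in the aVR / aVR+V1 patterns (widespread depression,
# inferior leads and V3-V6 plus I: 8 leads)
avr_depressed_leads <- function() c("I", "II", "III", "aVF", "V3", "V4", "V5", "V6")

cohort_blocks <- function() {
  b <- function(group, pattern, lafb, rbbb, lbbb, hdavb, collateral, n) {
    tibble::tibble(group = group, pattern = pattern, lafb = lafb, rbbb = rbbb,
                   lbbb = lbbb, hdavb = hdavb, collateral = collateral, n = n)
  }
  F <- FALSE; T <- TRUE
  dplyr::bind_rows(
    # ---- total LM occlusion (n = 84): 45 STEMI (no collateral), 39 NSTEMI
    b("lm_occlusion", "i_avl_v2_v5", T, F, F, F, "none", 16),
    b("lm_occlusion", "i_avl_v2_v5", T, T, F, F, "none", 6),
    b("lm_occlusion", "i_avl_v2_v5", F, F, F, F, "none", 7),
    b("lm_occlusion", "i_avl_v1_v5", T, F, F, F, "none", 5),
    b("lm_occlusion", "i_avl_v1_v5", T, T, F, F, "none", 2),
    b("lm_occlusion", "i_avl_v1_v5", F, T, F, F, "none", 2),
    b("lm_occlusion", "i_avl_v1_v5", F, F, T, F, "none", 1),
    b("lm_occlusion", "i_avl_v1_v5", F, F, F, F, "none", 4),
    b("lm_occlusion", "v1_v5", F, F, F, F, "none", 1),
    b("lm_occlusion", "v2_v5", F, F, F, F, "none", 1),
    b("lm_occlusion", "avr_avl", T, T, F, F, "none", 1),
    b("lm_occlusion", "avr_avl", T, F, F, F, "none", 2),
    b("lm_occlusion", "avr_avl", T, F, F, F, "lad", 2),
    b("lm_occlusion", "avr_avl", T, F, F, F, "both", 1),
    b("lm_occlusion", "avr_avl", T, T, F, F, "lad", 2),
    b("lm_occlusion", "avr_avl", T, T, F, F, "both", 1),
    b("lm_occlusion", "avr_avl", F, F, F, F, "lad", 3),
    b("lm_occlusion", "avr_avl", F, F, F, F, "both", 1),
    b("lm_occlusion", "i_avl_avr", T, T, F, F, "lad", 1),
    b("lm_occlusion", "i_avl_avr", T, T, F, F, "both", 1),
    b("lm_occlusion", "i_avl_avr", F, F, F, F, "lad", 5),
    b("lm_occlusion", "i_avl_avr", F, F, F, F, "both", 1),
    b("lm_occlusion", "avr_avl_partial", F, F, F, F, "lad", 2),
    b("lm_occlusion", "avr", T, F, F, F, "none", 1),
    b("lm_occlusion", "avr", T, F, F, F, "both", 2),
    b("lm_occlusion", "avr", T, F, F, F, "lad", 1),
    b("lm_occlusion", "avr", F, T, F, F, "both", 2),
    b("lm_occlusion", "avr", F, F, F, F, "both", 4),
    b("lm_occlusion", "avr", F, F, F, F, "lad", 1),
    b("lm_occlusion", "avr_v1", F, T, F, F, "none", 1),
    b("lm_occlusion", "avr_v1", T, F, F, F, "both", 1),
    b("lm_occlusion", "avr_v1", F, F, F, F, "both", 3),
    # ---- LM subtotal occlusion (n = 89)
    b("lm_subocclusion", "avr", T, F, F, F, NA, 10),
    b("lm_subocclusion", "avr", F, T, F, F, NA, 1),
    b("lm_subocclusion", "avr", F, F, F, F, NA, 42),
    b("lm_subocclusion", "avr_v1", F, F, F, F, NA, 26),
    b("lm_subocclusion", "avr_avl", T, F, F, F, NA, 1),
    b("lm_subocclusion", "avr_avl", F, F, F, F, NA, 3),
    b("lm_subocclusion", "i_avl_v1_v5", F, F, F, F, NA, 3),
    b("lm_subocclusion", "i_avl_v2_v5", F, F, F, F, NA, 2),
    b("lm_subocclusion", "v1_v5", F, F, F, F, NA, 1),
    # ---- proximal LAD occlusion (n = 85)
    b("plad", "v1_v5", T, F, F, F, NA, 5),
    b("plad", "v1_v5", T, T, F, F, NA, 1),
    b("plad", "v1_v5", F, T, F, F, NA, 6),
    b("plad", "v1_v5", F, F, T, F, NA, 1),
    b("plad", "v1_v5", F, F, F, F, NA, 22),
    b("plad", "i_avl_v1_v5", F, T, F, F, NA, 1),
    b("plad", "i_avl_v1_v5", F, F, F, F, NA, 31),
    b("plad", "i_avl_v2_v5", T, F, F, F, NA, 1),
    b("plad", "i_avl_v2_v5", F, F, F, F, NA, 5),
    b("plad", "avr", F, F, F, F, NA, 5),
    b("plad", "avr_v1", F, F, F, F, NA, 4),
    b("plad", "avr_avl", T, F, F, F, NA, 1),
    b("plad", "avr_avl", F, F, F, F, NA, 2),
    # ---- mid LAD occlusion (n = 98)
    b("mlad", "v1_v5", T, F, F, F, NA, 13),
    b("mlad", "v1_v5", F, T, F, F, NA, 9),
    b("mlad", "v1_v5", F, F, F, F, NA, 20),
    b("mlad", "i_avl_v1_v5", F, T, F, F, NA, 1),
    b("mlad", "i_avl_v1_v5", F, F, F, F, NA, 20),
    b("mlad", "i_avl_v2_v5", F, F, F, F, NA, 5),
    b("mlad", "v2_v5", F, F, F, F, NA, 2),
    b("mlad", "inferior", F, F, F, T, NA, 1),
    b("mlad", "inferior", F, F, F, F, NA, 1),
    b("mlad", "filler_anterior", F, F, T, F, NA, 1),
    b("mlad", "filler_anterior", F, F, F, F, NA, 19),
    b("mlad", "avr", F, F, F, F, NA, 4),
    b("mlad", "avr_v1", F, F, F, F, NA, 2),
    # ---- LCX occlusion (n = 91)
    b("lcx", "inferior", T, F, F, F, NA, 3),
    b("lcx", "inferior", F, T, F, F, NA, 1),
    b("lcx", "inferior", F, F, T, F, NA, 1),
    b("lcx", "inferior", F, F, F, T, NA, 1),
    b("lcx", "inferior", F, F, F, F, NA, 59),
    b("lcx", "filler_lateral", F, F, F, F, NA, 12),
    b("lcx", "avr", F, F, F, F, NA, 8),
    b("lcx", "avr_v1", F, F, F, F, NA, 3),
    b("lcx", "avr_avl", F, F, F, F, NA, 3),
    # ---- RCA occlusion (n = 105)
    b("rca", "inferior", F, T, F, F, NA, 3),
    b("rca", "inferior", F, F, F, T, NA, 13),
    b("rca", "inferior", F, F, F, F, NA, 82),
    b("rca", "avr", F, F, F, F, NA, 7)
  )
}

#' The resolved study cohort specification
#'
#' All sample sizes, archetype allocations, conduction and collateral
#' assignments, and distribution parameters (QRS, age, sex, in-hospital
#' mortality) that drive the synthetic-cohort generator, fully resolved from
#' the published group tables. Use [validate_spec()] to verify every encoded
#' marginal identity.
#'
#' @return An object of class `cohort_spec`: a list with elements
#'   \describe{
#'     \item{groups}{tibble of per-group sample sizes, male/mortality counts,
#'       age and QRS normal parameters;}
#'     \item{blocks}{the joint allocation: one row per homogeneous cell of
#'       pattern x conduction flags x collateral, with its count;}
#'     \item{lm_collateral_qrs}{QRS normal parameters for the left-main
#'       occlusion group split by collateral presence;}
#'     \item{qrs_bounds, age_bounds}{truncation bounds for sampling.}
#'   }
#' @export
#' @examples
#' spec <- cohort_spec()
#' spec$groups
cohort_spec <- function() {
  groups <- tibble::tibble(
    group = culprit_groups(),
    n = c(84L, 89L, 85L, 98L, 91L, 105L),
    male = c(73L, 61L, 63L, 74L, 69L, 84L),
    died = c(37L, 10L, 8L, 4L, 1L, 1L),
    age_mean = c(61, 65, 63, 63, 62, 64),
    age_sd = c(12, 10, 13, 11, 14, 11),
    qrs_mean = c(117, 93, 96, 98, 99, 99),
    qrs_sd = c(23, 13, 18, 18, 17, 15)
  )
  structure(
    list(
      groups = groups,
      blocks = cohort_blocks(),
      lm_collateral_qrs = tibble::tibble(
        collateral_present = c(TRUE, FALSE),
        qrs_mean = c(112, 120), qrs_sd = c(25, 22)
      ),
      qrs_bounds = c(40, 300),
      age_bounds = c(18, 100)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification:", sum(x$groups$n), "patients in",
      nrow(x$groups), "culprit-artery groups\n")
  print(x$groups)
  invisible(x)
}

#' Check every encoded marginal identity of a cohort spec
#'
#' Recomputes, from the joint allocation, each marginal count that the
#' published tables fix — group sizes, pattern rows, conduction rows, the
#' fascicular-block split between STEMI and NSTEMI, the collateral
#' cross-tabulation and territory counts — and compares them with the
#' expected values.
#'
#' @param spec A [cohort_spec()] object.
#' @return A tibble with columns `check`, `expected`, `actual`, `pass`.
#' @export
#' @examples
#' all(validate_spec(cohort_spec())$pass)
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  blk <- spec$blocks
  grp <- spec$groups
  defs <- archetype_defs()
  stemi_fine <- c("i_avl_v2_v5", "i_avl_v1_v5", "v1_v5", "v2_v5",
                  "inferior", "other_stemi")
  blk$fine <- vapply(blk$pattern, function(p) defs[[p]]$fine, "")
  blk$is_stemi <- blk$fine %in% stemi_fine
  blk$family_avr_avl <- blk$pattern %in% c("avr_avl", "i_avl_avr", "avr_avl_partial")

  cnt <- function(cond, groups = culprit_groups()) {
    vapply(groups, function(g) sum(blk$n[cond & blk$group == g]), 0)
  }
  checks <- list()
  add <- function(check, expected, actual) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check,
      expected = paste(expected, collapse = ","),
      actual = paste(actual, collapse = ","),
      pass = isTRUE(all(expected == actual))
    )
  }

  add("group sizes", grp$n, cnt(rep(TRUE, nrow(blk))))
  add("NSTEMI per group", c(39, 83, 12, 6, 14, 7), cnt(!blk$is_stemi))
  add("STEMI per group", c(45, 6, 73, 92, 77, 98), cnt(blk$is_stemi))
  add("STE in aVR (exclusive) per group", c(11, 53, 5, 4, 8, 7),
      cnt(blk$pattern == "avr"))
  add("STE in aVR+V1 per group", c(5, 26, 4, 2, 3, 0),
      cnt(blk$pattern == "avr_v1"))
  add("STE in aVR+aVL (any) per group", c(23, 4, 3, 0, 3, 0),
      cnt(blk$family_avr_avl))
  add("STE in V1-V5 per group", c(1, 1, 35, 42, 0, 0), cnt(blk$pattern == "v1_v5"))
  add("STE in V2-V5 per group", c(1, 0, 0, 2, 0, 0), cnt(blk$pattern == "v2_v5"))
  add("STE in I,aVL,V1-V5 per group", c(14, 3, 32, 21, 0, 0),
      cnt(blk$pattern == "i_avl_v1_v5"))
  add("STE in I,aVL,V2-V5 per group", c(29, 2, 6, 5, 0, 0),
      cnt(blk$pattern == "i_avl_v2_v5"))
  add("STE in II,III,aVF per group", c(0, 0, 0, 2, 65, 98),
      cnt(blk$pattern == "inferior"))
  add("isolated LAFB per group", c(31, 11, 7, 13, 3, 0), cnt(blk$lafb & !blk$rbbb))
  add("isolated RBBB per group", c(5, 1, 7, 10, 1, 3), cnt(blk$rbbb & !blk$lafb))
  add("LAFB+RBBB per group", c(14, 0, 1, 0, 0, 0), cnt(blk$lafb & blk$rbbb))
  add("LBBB per group", c(1, 0, 1, 1, 1, 0), cnt(blk$lbbb))
  add("HDAVB per group", c(0, 0, 0, 1, 1, 13), cnt(blk$hdavb))
  add("aVR,aVL + LAFB per group", c(5, 1, 1, 0, 0, 0),
      cnt(blk$family_avr_avl & blk$lafb & !blk$rbbb))
  add("aVR,aVL + LAFB+RBBB per group", c(6, 0, 0, 0, 0, 0),
      cnt(blk$family_avr_avl & blk$lafb & blk$rbbb))
  add("I,aVL,V2-V5 + LAFB per group", c(16, 0, 1, 0, 0, 0),
      cnt(blk$pattern == "i_avl_v2_v5" & blk$lafb & !blk$rbbb))
  add("I,aVL,V2-V5 + LAFB+RBBB per group", c(6, 0, 0, 0, 0, 0),
      cnt(blk$pattern == "i_avl_v2_v5" & blk$lafb & blk$rbbb))

  lm <- blk$group == "lm_occlusion"
  add("LM Model 1 positives", 52,
      sum(blk$n[lm & (blk$family_avr_avl | blk$pattern == "i_avl_v2_v5")]))
  add("LM Model 2 positives", 33,
      sum(blk$n[lm & (blk$family_avr_avl | blk$pattern == "i_avl_v2_v5") & blk$lafb]))
  add("LM fine-pattern counts (Fig 1B order)", c(29, 14, 13, 11, 8, 5),
      vapply(c("i_avl_v2_v5", "i_avl_v1_v5", "avr_avl", "avr", "i_avl_avr",
               "avr_v1"),
             function(p) sum(blk$n[lm & blk$pattern == p]), 0))
  add("LM isolated-LAFB split STEMI/NSTEMI", c(21, 10),
      c(sum(blk$n[lm & blk$is_stemi & blk$lafb & !blk$rbbb]),
        sum(blk$n[lm & !blk$is_stemi & blk$lafb & !blk$rbbb])))
  add("LM STEMI archetypes sum to 45", 45, sum(blk$n[lm & blk$is_stemi]))

  coll <- lm & !is.na(blk$collateral) & blk$collateral != "none"
  noncoll <- lm & !is.na(blk$collateral) & blk$collateral == "none"
  add("LM collateral split", c(34, 50), c(sum(blk$n[coll]), sum(blk$n[noncoll])))
  t2 <- function(cond) c(sum(blk$n[coll & cond]), sum(blk$n[noncoll & cond]))
  add("collateral x STE in aVR", c(10, 1), t2(blk$pattern == "avr"))
  add("collateral x STE in aVR+V1", c(4, 1), t2(blk$pattern == "avr_v1"))
  add("collateral x STE in aVR+aVL", c(20, 3), t2(blk$family_avr_avl))
  add("collateral x STEMI", c(0, 45), t2(blk$is_stemi))
  add("collateral x isolated LAFB", c(7, 24), t2(blk$lafb & !blk$rbbb))
  add("collateral x isolated RBBB", c(2, 3), t2(blk$rbbb & !blk$lafb))
  add("collateral x LAFB+RBBB", c(5, 9), t2(blk$lafb & blk$rbbb))
  add("LAD-territory filling in aVR+aVL records", 15,
      sum(blk$n[lm & blk$family_avr_avl & !is.na(blk$collateral) &
                  blk$collateral == "lad"]))
  add("both-territory filling in aVR-pattern records", 8,
      sum(blk$n[lm & blk$pattern == "avr" & !is.na(blk$collateral) &
                  blk$collateral == "both"]))
  add("non-LM records carry no collateral", 0,
      sum(blk$n[blk$group != "lm_occlusion" & !is.na(blk$collateral)]))
  add("male counts within group sizes", rep(TRUE, 6), grp$male <= grp$n)
  add("mortality counts within group sizes", rep(TRUE, 6), grp$died <= grp$n)

  purrr::list_rbind(checks)
}
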