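# expected published margins, used by both the spec checks and the
# generated-cohort round trips (order: LM occlusion, LM subocclusion,
# pLAD, mLAD, LCX, RCA)
table1_rows <- list(
  nstemi = c(39, 83, 12, 6, 14, 7),
  avr_isolated = c(11, 53, 5, 4, 8, 7),
  avr_v1 = c(5, 26, 4, 2, 3, 0),
  ste_avr_avl = c(23, 4, 3, 0, 3, 0),
  stemi = c(45, 6, 73, 92, 77, 98),
  v1_v5 = c(1, 1, 35, 42, 0, 0),
  v2_v5 = c(1, 0, 0, 2, 0, 0),
  i_avl_v1_v5 = c(14, 3, 32, 21, 0, 0),
  i_avl_v2_v5 = c(29, 2, 6, 5, 0, 0),
  inferior = c(0, 0, 0, 2, 65, 98),
  lafb = c(31, 11, 7, 13, 3, 0),
  rbbb = c(5, 1, 7, 10, 1, 3),
  bifascicular = c(14, 0, 1, 0, 0, 0),
  avr_avl_lafb = c(5, 1, 1, 0, 0, 0),
  i_avl_v2_v5_lafb = c(16, 0, 1, 0, 0, 0),
  avr_avl_bifascicular = c(6, 0, 0, 0, 0, 0),
  i_avl_v2_v5_bifascicular = c(6, 0, 0, 0, 0, 0)
)

test_that("the default spec encodes the study's sizes and passes every margin check", {
  spec <- cohort_spec()
  expect_equal(spec$groups$n, c(84, 89, 85, 98, 91, 105))
  expect_equal(sum(spec$groups$n), 552)
  lm <- dplyr::filter(spec$blocks, group == "lm_occlusion")
  expect_equal(sum(lm$n), 84)
  sub <- dplyr::filter(spec$blocks, group == "lm_subocclusion")
  expect_equal(sum(sub$n[sub$pattern %in%
                           c("avr", "avr_v1", "avr_avl")]), 83) # NSTEMI
  checks <- validate_spec(spec)
  expect_true(all(checks$pass))
})

test_that("injected spec defects are caught by the right margin check", {
  spec <- cohort_spec()
  # remove one STEMI record from the left-main group
  i <- with(spec$blocks, which(group == "lm_occlusion" & pattern == "i_avl_v2_v5" &
                                 !lafb & !rbbb))[1]
  spec$blocks$n[i] <- spec$blocks$n[i] - 1L
  checks <- validate_spec(spec)
  expect_false(all(checks$pass))
  expect_true("LM STEMI archetypes sum to 45" %in% checks$check[!checks$pass])
  expect_error(simulate_cohort(spec), "Infeasible")

  # reassign a collateral-positive cell to no-collateral: the 34/50 split
  # and the territory identities must both trip
  spec2 <- cohort_spec()
  j <- with(spec2$blocks, which(group == "lm_occlusion" & pattern == "i_avl_avr" &
                                  collateral == "lad" & !lafb))[1]
  spec2$blocks$collateral[j] <- "none"
  checks2 <- validate_spec(spec2)
  expect_true("LM collateral split" %in% checks2$check[!checks2$pass])
})

test_that("exact mode reproduces every criterion-row count and collateral cell", {
  cohort <- simulate_cohort(seed = 2024)
  expect_equal(nrow(cohort), 552)
  expect_equal(as.vector(table(factor(cohort$group, culprit_groups()))),
               c(84, 89, 85, 98, 91, 105))

  # every Table-1-style criterion row, recomputed by the classifier
  calls <- evaluate_criterion(cohort, names(table1_rows))
  for (crit in names(table1_rows)) {
    got <- vapply(culprit_groups(), function(g) {
      sum(calls$positive[calls$criterion == crit][cohort$group == g])
    }, 0)
    expect_equal(unname(got), table1_rows[[crit]], label = paste("row", crit))
  }

  # collateral cross-tabulation within the left-main group
  classified <- classify_cohort(cohort)
  lm <- dplyr::filter(classified, group == "lm_occlusion")
  coll <- lm$collateral != "none"
  expect_equal(sum(coll), 34)
  expect_equal(sum(!coll), 50)
  cell <- function(crit) {
    pos <- evaluate_criterion(lm, crit)$positive
    c(sum(pos & coll), sum(pos & !coll))
  }
  expect_equal(cell("avr_isolated"), c(10, 1))
  expect_equal(cell("avr_v1"), c(4, 1))
  expect_equal(cell("ste_avr_avl"), c(20, 3))
  expect_equal(cell("stemi"), c(0, 45))
  expect_equal(cell("lafb"), c(7, 24))
  expect_equal(cell("rbbb"), c(2, 3))
  expect_equal(cell("bifascicular"), c(5, 9))

  # territory statements: LAD filling in 15/23 aVR+aVL records, both-territory
  # filling in 8/10 collateral-positive isolated-aVR records
  aa <- evaluate_criterion(lm, "ste_avr_avl")$positive
  expect_equal(sum(aa & lm$collateral == "lad"), 15)
  av <- lm$fine_pattern == "avr"
  expect_equal(sum(av & lm$collateral == "both"), 8)

  # fascicular-block split between STEMI and NSTEMI in the left-main group
  lafb_iso <- lm$lafb & !lm$rbbb
  expect_equal(sum(lafb_iso & lm$main_pattern == "stemi"), 21)
  expect_equal(sum(lafb_iso & lm$main_pattern != "stemi"), 10)

  # demographics at the published margins
  expect_equal(unname(vapply(culprit_groups(), function(g)
    sum(cohort$sex[cohort$group == g] == "male"), 0)),
    c(73, 61, 63, 74, 69, 84))
  expect_equal(unname(vapply(culprit_groups(), function(g)
    sum(cohort$died_in_hospital[cohort$group == g]), 0)),
    c(37, 10, 8, 4, 1, 1))

  # aVR-pattern records carry widespread depression
  avr_recs <- dplyr::filter(classified, main_pattern == "avr")
  expect_true(all(depressed_lead_count(avr_recs) >= 7))
})

test_that("exact mode is deterministic under a seed and varies across seeds", {
  a <- simulate_cohort(seed = 5)
  b <- simulate_cohort(seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(seed = 6)
  expect_false(identical(a, c))
  # cell counts are seed-invariant
  expect_equal(table(classify_fine(a)), table(classify_fine(c)))
})

test_that("sampled mode is reproducible and converges to the spec proportions", {
  s1 <- simulate_cohort(mode = "sampled", n_per_group = 30, seed = 9)
  s2 <- simulate_cohort(mode = "sampled", n_per_group = 30, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 180)
  tiny <- simulate_cohort(mode = "sampled", n_per_group = 1, seed = 1)
  expect_equal(nrow(tiny), 6)
  expect_error(simulate_cohort(mode = "sampled"), "n_per_group")

  big <- simulate_cohort(mode = "sampled",
                         n_per_group = c(20000, 10, 10, 10, 10, 10), seed = 4)
  lm <- dplyr::filter(big, group == "lm_occlusion")
  expect_equal(mean(model1(lm)), 52 / 84, tolerance = 0.01 / (52 / 84))
  # QRS moments converge to the collateral-subgroup parameters
  qc <- lm$qrs_ms[lm$collateral != "none"]
  expect_equal(mean(qc), 112, tolerance = 0.01)
  expect_equal(stats::sd(qc), 25, tolerance = 0.05)
})

test_that("every generated record passes the feature-model invariants", {
  cohort <- simulate_cohort(seed = 77)
  expect_silent(lmocc:::check_cohort(cohort))
  stm <- as.matrix(cohort[paste0("st_", ecg_leads())])
  expect_true(all(abs(stm) <= 20))
  expect_true(all(cohort$qrs_ms >= 40 & cohort$qrs_ms <= 300))
  expect_true(all(is.na(cohort$collateral) | cohort$group == "lm_occlusion"))
  # no control-group filler archetype triggers any published criterion row
  controls <- dplyr::filter(cohort, group %in% c("mlad", "lcx"))
  fillers <- dplyr::filter(classify_cohort(controls), fine_pattern == "other_stemi")
  expect_gt(nrow(fillers), 0)
  crit_rows <- setdiff(names(table1_rows), c("stemi", "nstemi", "lafb", "rbbb",
                                             "bifascicular"))
  calls <- evaluate_criterion(fillers, crit_rows)
  expect_false(any(calls$positive))
})
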