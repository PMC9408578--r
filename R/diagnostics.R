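# Contingency-table diagnostic accuracy, group-comparison tests and ROC.

#' Build a 2x2 contingency table from calls and labels
#'
#' @param predictions,labels Logical vectors of equal length (>= 1).
#' @return An object of class `two_by_two`: a list with integer counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
#' @examples
#' two_by_two(c(TRUE, FALSE), c(TRUE, FALSE))
two_by_two <- function(predictions, labels) {
  if (!is.logical(predictions) || !is.logical(labels)) {
    abort("`predictions` and `labels` must be logical vectors.")
  }
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have the same length.")
  }
  if (length(predictions) < 1L) abort("Need at least one observation.")
  if (anyNA(predictions) || anyNA(labels)) abort("Missing values are not allowed.")
  structure(
    list(
      tp = sum(predictions & labels),
      fp = sum(predictions & !labels),
      fn = sum(!predictions & labels),
      tn = sum(!predictions & !labels)
    ),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 table: tp =", x$tp, " fp =", x$fp, " fn =", x$fn, " tn =", x$tn, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.two_by_two <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 n = c(x$tp, x$fp, x$fn, x$tn))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf_level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(lo, hi)`, both in `[0, 1]` and bracketing
#'   `successes / n`.
#' @export
#' @examples
#' wilson_ci(52, 84)
wilson_ci <- function(successes, n, conf_level = 0.95) {
  if (length(successes) != 1L || length(n) != 1L || !is.finite(successes) ||
      !is.finite(n) || n < 1 || successes < 0 || successes > n) {
    abort("Need 0 <= successes <= n with n >= 1.")
  }
  if (!is.finite(conf_level) || conf_level <= 0 || conf_level >= 1) {
    abort("`conf_level` must lie strictly between 0 and 1.")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity, specificity, predictive values and accuracy with Wilson score
#' confidence intervals. A metric whose denominator is zero is reported as
#' `NA` with `NA` interval bounds, never silently as 0/0.
#'
#' @param t A [two_by_two()] object, or a cohort tibble when `predictions`
#'   and `labels` columns/vectors are supplied via [evaluate_criteria()].
#' @param conf_level Confidence level for the Wilson intervals.
#' @return A tibble with columns `metric`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
#' @examples
#' dx_metrics(two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)))
dx_metrics <- function(t, conf_level = 0.95) {
  if (!inherits(t, "two_by_two")) abort("`t` must be a `two_by_two` object.")
  total <- t$tp + t$fp + t$fn + t$tn
  if (total <= 0) abort("Cannot compute metrics on an empty table.")
  one <- function(num, den) {
    if (den == 0) {
      tibble::tibble(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_)
    } else {
      ci <- wilson_ci(num, den, conf_level)
      tibble::tibble(estimate = num / den, conf.low = ci[["lo"]], conf.high = ci[["hi"]])
    }
  }
  dplyr::bind_cols(
    tibble::tibble(metric = c("sensitivity", "specificity", "ppv", "npv", "accuracy")),
    dplyr::bind_rows(
      one(t$tp, t$tp + t$fn),
      one(t$tn, t$tn + t$fp),
      one(t$tp, t$tp + t$fp),
      one(t$tn, t$tn + t$fn),
      one(t$tp + t$tn, total)
    )
  )
}

#' Evaluate criteria as predictors of a culprit group
#'
#' The workhorse evaluation: restricts the cohort to the positive group plus
#' a control set, evaluates each criterion, and tabulates diagnostic
#' accuracy. The control set must be named explicitly because the study's
#' single-criterion figures use different comparison groups (all five
#' controls vs the subtotal-occlusion group alone).
#'
#' @param cohort A labeled cohort tibble (non-missing `group`).
#' @param criteria Character vector of registry names, or named list of
#'   criterion functions.
#' @param positive Positive-class group label (default `"lm_occlusion"`).
#' @param controls `"all"` (every non-positive group present) or a character
#'   vector of group labels; must not contain `positive`.
#' @param conf_level Confidence level for Wilson intervals.
#' @param registry Criterion registry, default [builtin_criteria()].
#' @return A tibble, one row per criterion: counts `tp`, `fp`, `fn`, `tn`,
#'   then `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` with
#'   `*_low`/`*_high` Wilson bounds for sensitivity and specificity.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' evaluate_criteria(cohort, c("model1", "model2"))
evaluate_criteria <- function(cohort, criteria,
                              positive = "lm_occlusion", controls = "all",
                              conf_level = 0.95, registry = builtin_criteria()) {
  check_cohort(cohort)
  if (!"group" %in% names(cohort) || anyNA(cohort$group)) {
    abort("Evaluation requires a fully labeled `group` column.")
  }
  if (length(criteria) == 0L) abort("`criteria` must name at least one criterion.")
  if (identical(controls, "all")) {
    controls <- setdiff(unique(cohort$group), positive)
  }
  if (positive %in% controls) abort("`positive` must not be in `controls`.")
  sub <- dplyr::filter(cohort, .data$group %in% c(positive, controls))
  if (!any(sub$group == positive) || !any(sub$group %in% controls)) {
    abort("Both the positive group and the control set must be non-empty.")
  }
  labels <- sub$group == positive
  calls <- evaluate_criterion(sub, criteria, registry = registry)
  calls |>
    dplyr::group_by(.data$criterion) |>
    dplyr::group_modify(function(d, key) {
      t <- two_by_two(d$positive, labels)
      m <- dx_metrics(t, conf_level)
      est <- setNames(m$estimate, m$metric)
      tibble::tibble(
        tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
        sensitivity = est[["sensitivity"]],
        sensitivity_low = m$conf.low[m$metric == "sensitivity"],
        sensitivity_high = m$conf.high[m$metric == "sensitivity"],
        specificity = est[["specificity"]],
        specificity_low = m$conf.low[m$metric == "specificity"],
        specificity_high = m$conf.high[m$metric == "specificity"],
        ppv = est[["ppv"]], npv = est[["npv"]], accuracy = est[["accuracy"]]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(criterion = factor(.data$criterion, levels = unique(calls$criterion))) |>
    dplyr::arrange(.data$criterion) |>
    dplyr::mutate(criterion = as.character(.data$criterion))
}

#' Round a proportion to integer percent, halves up
#'
#' Matches the printing convention of clinical reports (61.9% -> 62;
#' 95.5% -> 96).
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Integer percent(s).
#' @export
percent_half_up <- function(p) {
  as.integer(floor(100 * p + 0.5))
}

# ---- group-comparison tests ------------------------------------------------

#' Chi-square test of independence (with Fisher fallback)
#'
#' Pearson chi-square without continuity correction, with `(r-1)(c-1)`
#' degrees of freedom. For 2x2 tables with any expected count below 5 the
#' test falls back to Fisher's exact test (standard sparse-table practice).
#'
#' @param contingency A matrix of non-negative counts, at least 2x2.
#' @return A tibble with `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' chi_square_test(matrix(c(37, 10, 47, 79), 2))
chi_square_test <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || nrow(m) < 2 || ncol(m) < 2) {
    abort("`contingency` must be a matrix of non-negative counts, at least 2x2.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate table: a row or column margin is zero.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(dim(m) == 2L) && any(expected < 5)) {
    f <- stats::fisher.test(m)
    return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                          p.value = f$p.value, method = "fisher_exact"))
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p.value = ct$p.value, method = "pearson_chi_square")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) comparing
#' group means of a continuous variable such as QRS duration.
#'
#' @param values Numeric vector.
#' @param group Grouping vector of the same length, at least two groups with
#'   at least two values each.
#' @return A tibble with `statistic` (F), `df` (between), `df_resid`,
#'   `p.value`, `method`.
#' @export
one_way_anova <- function(values, group) {
  if (length(values) != length(group)) abort("`values` and `group` lengths differ.")
  group <- factor(group)
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("Need at least two groups with at least two values each.")
  }
  ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ft$statistic),
    df = unname(ft$parameter[1]), df_resid = unname(ft$parameter[2]),
    p.value = ft$p.value, method = "one_way_anova"
  )
}

# ---- ROC -------------------------------------------------------------------

#' Empirical ROC curve, AUC and Youden cutoff
#'
#' Thresholds are the distinct observed scores (plus an `Inf` sentinel where
#' nothing is called positive); a record is called positive when its score is
#' at or above the threshold, so a higher score must favour the positive
#' class — the direction is explicit, never inferred. The AUC is the
#' trapezoidal integral of the curve, which equals the tie-corrected
#' Mann-Whitney statistic (ties counted 1/2). The Youden cutoff maximises
#' `tpr - fpr`; ties break toward the lower threshold (higher sensitivity).
#'
#' @param scores Finite numeric vector (e.g. QRS duration in ms).
#' @param labels Logical vector; both classes must be present.
#' @return An object of class `ecg_roc`: list with `curve` (tibble
#'   `threshold`, `tpr`, `fpr`), `auc`, `youden_cutoff`, `sens_at_cutoff`,
#'   `spec_at_cutoff`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' r$auc
roc_curve <- function(scores, labels) {
  if (!is.numeric(scores) || !all(is.finite(scores))) {
    abort("`scores` must be finite numeric values.")
  }
  if (!is.logical(labels) || anyNA(labels) || length(labels) != length(scores)) {
    abort("`labels` must be a logical vector matching `scores`.")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("Both classes must be present.")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  run_end <- cumsum(rle(s)$lengths) # last index of each tied block
  thresholds <- s[run_end]
  tpr <- cumsum(l)[run_end] / n_pos
  fpr <- cumsum(!l)[run_end] / n_neg
  curve <- tibble::tibble(
    threshold = c(Inf, thresholds),
    tpr = c(0, tpr), fpr = c(0, fpr)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)

  j <- tpr - fpr
  # ties toward the LOWER threshold: thresholds are in decreasing order, so
  # take the last maximising index
  best <- max(which(j == max(j)))
  structure(
    list(
      curve = curve, auc = auc,
      youden_cutoff = thresholds[best],
      sens_at_cutoff = tpr[best], spec_at_cutoff = 1 - fpr[best],
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "ecg_roc"
  )
}

#' ROC of a cohort variable against a culprit group
#'
#' Data-frame-first wrapper around [roc_curve()].
#'
#' @param cohort A labeled cohort tibble.
#' @param var Column to use as the score (default `qrs_ms`).
#' @param positive Positive-class group label.
#' @param controls `"all"` or a character vector of control group labels.
#' @return An `ecg_roc` object.
#' @export
cohort_roc <- function(cohort, var = "qrs_ms", positive = "lm_occlusion",
                       controls = "all") {
  check_cohort(cohort)
  if (identical(controls, "all")) controls <- setdiff(unique(cohort$group), positive)
  sub <- dplyr::filter(cohort, .data$group %in% c(positive, controls))
  roc_curve(sub[[var]], sub$group == positive)
}

#' @export
print.ecg_roc <- function(x, ...) {
  cat("Empirical ROC:", x$n_pos, "positives vs", x$n_neg, "negatives\n")
  cat(sprintf("  AUC %.3f; Youden cutoff %g (sens %.2f, spec %.2f)\n",
              x$auc, x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ecg_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.ecg_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, youden_cutoff = x$youden_cutoff,
    sens_at_cutoff = x$sens_at_cutoff, spec_at_cutoff = x$spec_at_cutoff,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Closed-form AUC under the binormal model
#'
#' For scores distributed Normal(`mu_pos`, `sd_pos`) in positives and
#' Normal(`mu_neg`, `sd_neg`) in negatives, the AUC is
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Used as the
#' analytic oracle for the empirical ROC.
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg Normal parameters; sds must be > 0.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' binormal_auc(117, 23, 97.1, 16.5)
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (!is.finite(sd_pos) || !is.finite(sd_neg) || sd_pos <= 0 || sd_neg <= 0) {
    abort("Standard deviations must be positive.")
  }
  pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}
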