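# shared fixtures: random records and independent oracles

# one-row cohort with fully random (possibly non-archetypal) ST deviations
random_record <- function(id = "r") {
  ecg_record(
    st = setNames(round(runif(12, -3, 4), 2), ecg_leads()),
    sex = sample(c("male", "female"), 1),
    qrs_ms = runif(1, 60, 180),
    lafb = runif(1) < 0.3, rbbb = runif(1) < 0.2,
    id = id
  )
}

random_cohort <- function(n) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) random_record(paste0("r", i))))
}

# brute-force pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# textbook Pearson chi-square statistic
pearson_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
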