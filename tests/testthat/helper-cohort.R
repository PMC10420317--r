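# Fixtures built in code: small valid cohorts with random but plausible
# values, and an independent brute-force CERT1 oracle.

make_test_cohort <- function(n, seed = NULL, group = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group)) {
    group <- rep(c("NW", "OB_METS_NEG", "OB_METS_POS"), length.out = n)
  }
  cohort_frame(data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = group,
    sex = rep(c("F", "M"), length.out = n),
    smoking = rep(c(FALSE, TRUE), length.out = n),
    treated_htn = FALSE, diabetes = FALSE,
    age = runif(n, 25, 50),
    bmi = runif(n, 20, 45),
    wc = runif(n, 70, 130),
    sbp = 5 * round(runif(n, 100, 150) / 5),
    dbp = 5 * round(runif(n, 60, 95) / 5),
    glucose = runif(n, 75, 110),
    insulin = rlnorm(n, log(10), 0.5),
    tc = runif(n, 130, 220),
    hdl = runif(n, 30, 75),
    ldl = runif(n, 70, 140),
    tg = rlnorm(n, log(90), 0.4),
    crp = rlnorm(n, log(0.3), 1),
    cer16 = rlnorm(n, log(0.45), 0.2),
    cer18 = rlnorm(n, log(0.09), 0.35),
    cer241 = rlnorm(n, log(0.9), 0.3),
    cer240 = rlnorm(n, log(2.8), 0.3)
  ), provenance = "test fixture")
}

# Independent oracle: classify each scoring variable's quartile membership
# from stats::quantile directly and sum, bypassing the package's reference
# plumbing and scorer.
oracle_cert1 <- function(cohort) {
  df <- as.data.frame(cohort)
  vals <- data.frame(
    cer16 = df$cer16, cer18 = df$cer18, cer241 = df$cer241,
    r16_240 = df$cer16 / df$cer240,
    r18_240 = df$cer18 / df$cer240,
    r241_240 = df$cer241 / df$cer240)
  score <- rep(0L, nrow(df))
  for (v in names(vals)) {
    x <- vals[[v]]
    q50 <- stats::quantile(x, 0.5, type = 7, names = FALSE)
    q75 <- stats::quantile(x, 0.75, type = 7, names = FALSE)
    score <- score + (x >= q50) + (x >= q75)
  }
  as.integer(score)
}

# an external reference with round cutoffs, convenient for boundary tests
flat_reference <- function(q25 = 1, q50 = 2, q75 = 3) {
  quartile_reference(
    data.frame(variable = cert1_variables(), q25 = q25, q50 = q50, q75 = q75),
    source = "external_table")
}

# one subject whose six scoring variables can be dialed exactly
subject_with <- function(cer16, cer18, cer241, cer240 = 1) {
  cohort_frame(data.frame(
    id = "X1", group = "UNASSIGNED", sex = "F", smoking = FALSE,
    treated_htn = FALSE, diabetes = FALSE,
    age = 40, bmi = 25, wc = 75, sbp = 120, dbp = 80, glucose = 90,
    insulin = 8, tc = 180, hdl = 55, ldl = 100, tg = 90, crp = 0.2,
    cer16 = cer16, cer18 = cer18, cer241 = cer241, cer240 = cer240))
}
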