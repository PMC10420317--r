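test_that("HOMA-IR follows the insulin x glucose / 22.5 formula", {
  # glucose 18.016 mg/dL is exactly 1 mmol/L
  expect_equal(homa_ir(22.5, 18.016), 1.0, tolerance = 1e-12)
  expect_equal(homa_ir(10, 90.08), 2.222, tolerance = 1e-3)
  # normal-weight medians; deliberately NOT the published median index
  # (1.54) because a median of products is not a product of medians
  expect_equal(homa_ir(6.65, 87), 1.427, tolerance = 1e-2)
  # bilinear in both arguments
  expect_equal(homa_ir(2 * 7, 90), 2 * homa_ir(7, 90), tolerance = 1e-12)
  expect_equal(homa_ir(7, 3 * 90), 3 * homa_ir(7, 90), tolerance = 1e-12)
  expect_error(homa_ir(0, 90), "positive")
  expect_error(homa_ir(7, -1), "positive")
})

test_that("metabolic syndrome classification counts five criteria", {
  normal <- subject_with(0.4, 0.07, 0.8, 3.5)
  r <- classify_mets(normal)
  expect_identical(r$count, 0L)
  expect_false(r$positive)

  # four criteria met (female): WC 120, TG 160, HDL 35, SBP 135
  df <- as.data.frame(normal)
  df$wc <- 120; df$tg <- 160; df$hdl <- 35; df$sbp <- 135; df$glucose <- 90
  r4 <- classify_mets(cohort_frame(df))
  expect_identical(r4$count, 4L)
  expect_true(r4$positive)

  # exactly two flags -> negative (boundary of the >=3 rule)
  df2 <- as.data.frame(normal)
  df2$wc <- 120; df2$tg <- 160
  r2 <- classify_mets(cohort_frame(df2))
  expect_identical(r2$count, 2L)
  expect_false(r2$positive)

  # treatment flags satisfy their criteria
  df3 <- as.data.frame(normal)
  df3$treated_htn <- TRUE; df3$diabetes <- TRUE; df3$wc <- 120
  expect_true(classify_mets(cohort_frame(df3))$positive)

  # sex-specific waist cutoff: 90 cm flags F but not M
  dfF <- as.data.frame(normal); dfF$wc <- 90
  dfM <- dfF; dfM$sex <- "M"
  expect_true(classify_mets(cohort_frame(dfF))$abdominal)
  expect_false(classify_mets(cohort_frame(dfM))$abdominal)

  # canonical rule requires central obesity
  df5 <- as.data.frame(normal)
  df5$tg <- 160; df5$hdl <- 35; df5$sbp <- 135  # 3 flags, WC normal
  expect_true(classify_mets(cohort_frame(df5))$positive)
  expect_false(classify_mets(cohort_frame(df5), rule = "idf")$positive)

  dfna <- as.data.frame(normal); dfna$tg <- NA
  expect_error(classify_mets(cohort_frame(dfna)), "tg")
})

test_that("Framingham risk matches the published worked example", {
  # 61-year-old woman, TC 180, HDL 47, SBP 124 untreated, smoker,
  # non-diabetic: 10.48% in the source publication (hand-recomputed from
  # the embedded coefficient table)
  r <- frs_2008(61, 180, 47, 124, FALSE, TRUE, FALSE, "F")
  expect_equal(as.numeric(r), 10.4842, tolerance = 1e-3)
  # determinism: identical records give identical risk
  expect_identical(as.numeric(frs_2008(61, 180, 47, 124, FALSE, TRUE, FALSE, "F")),
                   as.numeric(r))
})

test_that("Framingham risk is monotone in each risk factor", {
  base <- list(age = 50, tc = 180, hdl = 50, sbp = 120,
               treated_htn = FALSE, smoking = FALSE, diabetes = FALSE)
  risk_of <- function(args, sex) {
    as.numeric(do.call(frs_2008, c(args, list(sex = sex), quiet = TRUE)))
  }
  for (sex in c("F", "M")) {
    r0 <- risk_of(base, sex)
    up <- function(field, value) {
      b <- base; b[[field]] <- value; risk_of(b, sex)
    }
    expect_gt(up("age", 60), r0)
    expect_gt(up("sbp", 150), r0)
    expect_gt(up("tc", 240), r0)
    expect_gt(up("smoking", TRUE), r0)
    expect_gt(up("diabetes", TRUE), r0)
    expect_lt(up("hdl", 70), r0)
    expect_gt(up("treated_htn", TRUE), r0)  # treated SBP carries more risk
  }
})

test_that("ages outside 30-74 are flagged or rejected per config", {
  expect_warning(r <- frs_2008(25, 180, 50, 120, FALSE, FALSE, FALSE, "M"),
                 "extrapolated")
  expect_true(attr(r, "extrapolated"))
  expect_error(frs_2008(25, 180, 50, 120, FALSE, FALSE, FALSE, "M",
                        extrapolate = FALSE), "validity")
})

test_that("the shipped coefficient table matches the hand-verified values", {
  co <- frs_coefficients()
  expected <- c(
    F_log_age = 2.32888, F_log_tc = 1.20904, F_log_hdl = -0.70833,
    F_log_sbp_untreated = 2.76157, F_log_sbp_treated = 2.82263,
    F_smoking = 0.52873, F_diabetes = 0.69154,
    F_mean_lp = 26.1931, F_s0_10y = 0.95012,
    M_log_age = 3.06117, M_log_tc = 1.12370, M_log_hdl = -0.93263,
    M_log_sbp_untreated = 1.93303, M_log_sbp_treated = 1.99881,
    M_smoking = 0.65451, M_diabetes = 0.57367,
    M_mean_lp = 23.9802, M_s0_10y = 0.88936)
  got <- setNames(co$value, paste(co$sex, co$term, sep = "_"))
  expect_identical(got[names(expected)], expected)
})

test_that("vascular age inverts the risk curve", {
  prof <- normal_risk_profile()
  for (sex in c("F", "M")) {
    for (age in c(30, 40, 55, 70)) {
      r <- frs_2008(age, prof$tc, prof$hdl, prof$sbp, prof$treated_htn,
                    prof$smoking, prof$diabetes, sex, quiet = TRUE)
      expect_equal(as.numeric(vascular_age(r, sex)), age, tolerance = 0.1)
    }
    # monotone: higher risk, higher vascular age
    va <- vascular_age(c(1, 2, 5, 10), sex)
    expect_true(all(diff(va) > 0))
  }
})

test_that("vascular age agrees with a 0.01-year grid-search oracle", {
  prof <- normal_risk_profile()
  grid <- seq(1, 120, by = 0.01)
  for (sex in c("F", "M")) {
    risks <- frs_2008(grid, prof$tc, prof$hdl, prof$sbp, FALSE, FALSE,
                      FALSE, sex, quiet = TRUE)
    # 2.45% is the obese-with-MetS group's median published risk
    for (target in c(1.0, 2.45, 8)) {
      oracle <- grid[which.min(abs(risks - target))]
      expect_equal(as.numeric(vascular_age(target, sex)), oracle,
                   tolerance = 0.1)
    }
  }
})

test_that("unachievable risks are clamped and flagged", {
  va <- vascular_age(c(1e-9, 99.9), "F")
  expect_identical(attr(va, "clamped"), c(TRUE, TRUE))
  expect_identical(as.numeric(va), c(1, 120))
})
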