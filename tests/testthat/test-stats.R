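test_that("kruskal_dunn reports all pairs with adjusted p >= raw p", {
  co <- make_test_cohort(45, seed = 51)
  res <- kruskal_dunn(as.data.frame(co), "cer18")
  expect_identical(nrow(res$pairwise), 3L)  # all unordered group pairs
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_identical(res$df, 2L)
  expect_identical(nrow(res$summary), 3L)
  # holm and none are available
  res_none <- kruskal_dunn(as.data.frame(co), "cer18", adjust = "none")
  expect_equal(res_none$pairwise$p_adj, res_none$pairwise$p_raw)
})

test_that("kruskal_dunn flags degenerate all-equal input", {
  df <- as.data.frame(make_test_cohort(12, seed = 52))
  df$glucose <- 90
  res <- kruskal_dunn(df, "glucose")
  expect_true(res$degenerate)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_value, 1)
  expect_true(all(res$pairwise$p_adj == 1))
})

test_that("kruskal_dunn holds its size under the null", {
  set.seed(53)
  rejections <- 0L
  for (i in 1:100) {
    df <- data.frame(group = rep(c("NW", "OB_METS_NEG", "OB_METS_POS"),
                                 each = 15),
                     y = rnorm(45))
    if (kruskal_dunn(df, "y")$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_lt(rejections, 11L)  # p > 0.05 in >= 90% of null replicates
})

test_that("kruskal_dunn detects a 3-SD shift in every pairwise contrast", {
  set.seed(54)
  df <- data.frame(group = rep(c("NW", "OB_METS_NEG"), each = 30),
                   y = c(rnorm(30), rnorm(30, mean = 3)))
  res <- kruskal_dunn(df, "y")
  expect_lt(res$p_value, 0.05)
  expect_true(all(res$pairwise$p_adj < 0.05))
})

test_that("kruskal_dunn refuses unusable groupings", {
  df <- data.frame(group = c("NW", "NW", "OB_METS_NEG"), y = 1:3)
  expect_error(kruskal_dunn(df, "y"), "OB_METS_NEG")
  expect_error(kruskal_dunn(data.frame(group = rep("NW", 5), y = rnorm(5)),
                            "y"), "2 groups")
})

test_that("OLS recovers a noiseless linear outcome exactly", {
  df <- as.data.frame(make_test_cohort(40, seed = 55))
  df$homa_ir <- homa_ir(df$insulin, df$glucose)
  df$y <- 2.5 * df$wc + 7
  res <- suppressWarnings(   # summary.lm warns on an exact fit
    ols_multiple_regression(df, "y", c("wc", "homa_ir", "crp")))
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  expect_equal(est[["wc"]], 2.5, tolerance = 1e-10)
  expect_equal(est[["homa_ir"]], 0, tolerance = 1e-10)
  expect_equal(est[["crp"]], 0, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
})

test_that("OLS rejects underdetermined and collinear designs", {
  df <- as.data.frame(make_test_cohort(8, seed = 56))
  preds <- c("wc", "sbp", "dbp", "homa_ir", "hdl", "tg", "crp")
  df$homa_ir <- homa_ir(df$insulin, df$glucose)
  df$y <- rnorm(8)
  expect_error(ols_multiple_regression(df, "y", preds), "complete cases")
  df2 <- as.data.frame(make_test_cohort(30, seed = 57))
  df2$y <- rnorm(30)
  df2$wc2 <- 2 * df2$wc  # exact collinearity
  expect_error(ols_multiple_regression(df2, "y", c("wc", "wc2")), "wc2")
})

test_that("OLS flags the generating predictors in the majority of replicates", {
  preds <- c("wc", "sbp", "dbp", "homa_ir", "hdl", "tg", "crp")
  hits <- 0L
  set.seed(58)
  for (i in 1:100) {
    df <- as.data.frame(make_test_cohort(84))
    df$homa_ir <- homa_ir(df$insulin, df$glucose)
    z <- function(v) (v - mean(v)) / sd(v)
    df$y <- 0.5 * z(df$wc) + 0.5 * z(df$homa_ir) + 0.5 * z(df$crp) + rnorm(84)
    p <- with(ols_multiple_regression(df, "y", preds),
              setNames(coefficients$p, coefficients$term))
    if (all(p[c("wc", "homa_ir", "crp")] < 0.05) &&
        all(p[c("sbp", "dbp", "tg", "hdl")] > 0.05)) hits <- hits + 1L
  }
  expect_gt(hits, 50L)
})

test_that("rank ANCOVA with no covariates reduces to the unadjusted model", {
  df <- as.data.frame(make_test_cohort(45, seed = 59))
  a0 <- rank_ancova(df, "cer18", character(0))
  fit <- stats::lm(rank(cer18) ~ stats::relevel(factor(group), "NW"),
                   data = df)
  co <- summary(fit)$coefficients
  expect_equal(a0$contrasts$p, unname(co[-1, 4]), tolerance = 1e-12)
  expect_equal(a0$contrasts$estimate, unname(co[-1, 1]), tolerance = 1e-12)
})

test_that("a null covariate leaves group contrasts essentially unchanged", {
  set.seed(60)
  concordant <- 0L
  for (i in 1:100) {
    df <- as.data.frame(make_test_cohort(45))
    df$noise_cov <- rnorm(45)  # independent of outcome and group
    adj <- rank_ancova(df, "cer18", "noise_cov")$contrasts
    kw <- kruskal_dunn(df, "cer18", adjust = "none")$pairwise
    kw_nw <- kw[kw$group1 == "NW", ]
    same <- all((adj$p < 0.05) ==
                  (kw_nw$p_raw[match(adj$group, kw_nw$group2)] < 0.05))
    if (same) concordant <- concordant + 1L
  }
  expect_gte(concordant, 90L)
})

test_that("full mediation through the covariate removes the group effect", {
  set.seed(61)
  nonsig <- 0L
  for (i in 1:100) {
    grp <- rep(c("NW", "OB_METS_NEG", "OB_METS_POS"), each = 20)
    cov <- rnorm(60, mean = c(0, 1.5, 3)[match(grp, unique(grp))])
    df <- data.frame(group = grp, cov = cov,
                     y = cov^3 + rnorm(60, sd = 0.5))  # monotone in cov
    adj <- rank_ancova(df, "y", "cov")$contrasts
    if (all(adj$p > 0.05)) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 90L)
})

test_that("rank ANCOVA validates its inputs", {
  df <- as.data.frame(make_test_cohort(30, seed = 62))
  df$k <- 1
  expect_error(rank_ancova(df, "cer18", "k"), "constant")
  expect_error(rank_ancova(df, "cer18", character(0), reference = "OB"),
               "reference")
  # quade variant runs and returns the same shape
  q <- rank_ancova(df, "cer18", "wc", method = "quade")
  expect_identical(names(q$contrasts),
                   c("group", "estimate", "se", "t", "p"))
})

test_that("spearman_with_linfit handles exact and noisy relations", {
  df <- data.frame(x = 1:20, y = (1:20)^2)
  r <- spearman_with_linfit(df, "x", "y")
  expect_identical(r$rho, 1)
  df$y <- -df$x
  expect_identical(spearman_with_linfit(df, "x", "y")$rho, -1)
  set.seed(63)
  df2 <- data.frame(x = runif(84, 0, 10))
  df2$y <- 2 * df2$x + 1 + rnorm(84, sd = 0.5)
  r2 <- spearman_with_linfit(df2, "x", "y")
  expect_equal(r2$slope, 2, tolerance = 0.1)
  expect_equal(r2$intercept, 1, tolerance = 0.5)
  expect_lt(r2$p_value, 0.001)
  # constant input flagged, not crashed
  df3 <- data.frame(x = rep(1, 10), y = rnorm(10))
  r3 <- spearman_with_linfit(df3, "x", "y")
  expect_true(r3$degenerate)
  expect_true(is.na(r3$rho))
  expect_error(spearman_with_linfit(data.frame(x = 1:3, y = 1:3), "x", "y"),
               ">= 4")
})

test_that("contingency analysis has df 6 and detects group-shifted scores", {
  co <- make_test_cohort(60, seed = 64)
  res <- risk_category_contingency(co, cert1_score(co))
  expect_identical(res$df, 6L)  # (3-1) x (4-1)
  expect_true(sum(res$table) == nrow(co))

  # identical row distributions -> statistic 0, p 1
  df <- as.data.frame(make_test_cohort(24, seed = 65))
  scores <- cert1_score(cohort_frame(df))
  scores$category <- factor(rep(cert1_categories(), 6),
                            levels = cert1_categories())
  res0 <- risk_category_contingency(cohort_frame(df), scores)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)

  # agrees with the textbook Pearson statistic on a complete table
  set.seed(68)
  scores2 <- cert1_score(co)
  scores2$category <- factor(sample(cert1_categories(), nrow(co),
                                    replace = TRUE),
                             levels = cert1_categories())
  res2 <- risk_category_contingency(co, scores2)
  ref <- suppressWarnings(stats::chisq.test(res2$table, correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)

  # statistic invariant under relabeling (row/column permutation)
  perm <- as.data.frame(co)
  perm$group <- c(NW = "OB_METS_POS", OB_METS_NEG = "NW",
                  OB_METS_POS = "OB_METS_NEG")[perm$group]
  res_p <- risk_category_contingency(cohort_frame(perm), cert1_score(co))
  expect_equal(res_p$statistic, res$statistic, tolerance = 1e-9)

  expect_error(risk_category_contingency(
    make_test_cohort(10, seed = 66, group = "UNASSIGNED"),
    cert1_score(make_test_cohort(10, seed = 66, group = "UNASSIGNED"))),
    "UNASSIGNED")
})

test_that("a Fisher exact p accompanies sparse tables", {
  co <- make_test_cohort(24, seed = 67)  # small cohort -> expected < 5
  res <- risk_category_contingency(co, cert1_score(co))
  expect_lt(res$min_expected, 5)
  expect_false(is.na(res$fisher_p))
  expect_true(res$fisher_p >= 0 && res$fisher_p <= 1)
})
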