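## Non-parametric cohort statistics ----------------------------------------

.check_groups <- function(data, group_col = "group") {
  g <- data[[group_col]]
  if (any(g == "UNASSIGNED")) {
    stop("cohort contains UNASSIGNED subjects", call. = FALSE)
  }
  factor(g, levels = intersect(cohort_groups(), unique(g)))
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' Compares a variable across groups by the tie-corrected Kruskal-Wallis
#' rank test, followed by Dunn's z-tests on all unordered group pairs with
#' multiplicity adjustment (Bonferroni by default). Per-group medians and
#' quartiles are reported alongside. A variable that is constant over the
#' whole sample is flagged degenerate (statistic 0, all p = 1).
#'
#' @param data Data frame with a `group` column.
#' @param variable Name of the numeric column to test.
#' @param adjust Pairwise p adjustment: `"bonferroni"` (default), `"holm"`
#'   or `"none"`.
#' @param group_col Name of the grouping column.
#' @return List with `variable`, per-group `summary`, `statistic`, `df`,
#'   `p_value`, `degenerate`, and `pairwise` (z, raw and adjusted p per
#'   pair).
#' @export
kruskal_dunn <- function(data, variable,
                         adjust = c("bonferroni", "holm", "none"),
                         group_col = "group") {
  adjust <- match.arg(adjust)
  g <- .check_groups(data, group_col)
  x <- data[[variable]]
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (nlevels(g) < 2L || any(counts < 2L)) {
    empty <- if (nlevels(g) < 2L) "need >= 2 groups" else
      paste("group(s) too small:",
            paste(names(counts)[counts < 2L], collapse = ", "))
    stop("kruskal_dunn('", variable, "'): ", empty, call. = FALSE)
  }
  summ <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- x[g == lev]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = lev, n = length(v),
               median = q[2], q25 = q[1], q75 = q[3])
  }))
  degenerate <- length(unique(x)) == 1L
  if (degenerate) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  # Dunn pairwise z on pooled mid-ranks with tie correction
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  pairs <- utils::combn(levels(g), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (degenerate) {
      z <- 0; praw <- 1
    } else {
      se <- sqrt((N * (N + 1) / 12 - tie_term) *
                   (1 / counts[[a]] + 1 / counts[[b]]))
      z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
      praw <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group1 = a, group2 = b, z = z, p_raw = praw)
  }))
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = adjust)
  rownames(pw) <- NULL; rownames(summ) <- NULL
  list(variable = variable, summary = summ, statistic = H,
       df = nlevels(g) - 1L, p_value = p, degenerate = degenerate,
       adjust = adjust, pairwise = pw)
}

#' Multiple linear regression of a cohort endpoint on clinical predictors
#'
#' Ordinary least squares with intercept; per-coefficient two-sided t
#' tests. Complete cases only; rank-deficient designs are rejected with
#' the offending predictors named.
#'
#' @param data Data frame.
#' @param outcome Name of the dependent variable.
#' @param predictors Character vector of predictor names.
#' @return List with `outcome`, `coefficients` (term, estimate, se, t, p),
#'   `r_squared`, `adj_r_squared` and `n`.
#' @export
ols_multiple_regression <- function(data, outcome, predictors) {
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) stop("unknown variable(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  df <- data[stats::complete.cases(data[, cols, drop = FALSE]),
             cols, drop = FALSE]
  if (nrow(df) < length(predictors) + 2L) {
    stop("too few complete cases (", nrow(df), ") for ",
         length(predictors), " predictors", call. = FALSE)
  }
  X <- stats::model.matrix(
    stats::reformulate(predictors, response = NULL), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(predictors, response = outcome),
                   data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  list(outcome = outcome,
       coefficients = data.frame(term = rownames(co),
                                 estimate = co[, 1], se = co[, 2],
                                 t = co[, 3], p = co[, 4],
                                 row.names = NULL),
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       n = nrow(df))
}

#' Rank-transform analysis of covariance
#'
#' Non-parametric covariate adjustment in the Conover-Iman style: the
#' outcome and every covariate are replaced by mid-ranks over the pooled
#' sample and a linear model `rank(outcome) ~ group + rank(covariates)` is
#' fitted; the reported contrasts are each group against the reference
#' (treatment coding). With an empty covariate set this reduces to the
#' unadjusted one-way rank model. Quade's method (ANCOVA on the residuals
#' of rank(outcome) regressed on rank(covariates), then a group one-way
#' test) is available as an alternative.
#'
#' @param data Data frame with a `group` column.
#' @param outcome Outcome column name.
#' @param covariates Character vector of covariate names (possibly empty).
#' @param reference Reference group label (default `"NW"`).
#' @param method `"rank_lm"` (default) or `"quade"`.
#' @return List with `outcome`, `covariates`, `method` and `contrasts`
#'   (group, estimate on the rank scale, se, t, p vs reference).
#' @export
rank_ancova <- function(data, outcome, covariates, reference = "NW",
                        method = c("rank_lm", "quade")) {
  method <- match.arg(method)
  g <- .check_groups(data)
  cols <- c(outcome, covariates)
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  df <- data[keep, , drop = FALSE]
  g <- droplevels(g[keep])
  if (!reference %in% levels(g)) {
    stop("reference group '", reference, "' absent", call. = FALSE)
  }
  if (min(table(g)) < 3L) {
    stop("rank_ancova: need >= 3 subjects per group", call. = FALSE)
  }
  rdf <- data.frame(.group = stats::relevel(g, ref = reference))
  rdf$.y <- rank(df[[outcome]])
  for (cv in covariates) {
    v <- df[[cv]]
    if (length(unique(v)) == 1L) {
      stop("covariate '", cv, "' is constant", call. = FALSE)
    }
    rdf[[paste0(".r_", cv)]] <- rank(v)
  }
  if (method == "quade" && length(covariates) > 0L) {
    rhs <- paste0(".r_", covariates)
    res <- stats::residuals(stats::lm(
      stats::reformulate(rhs, response = ".y"), data = rdf))
    fit <- stats::lm(res ~ .group, data = rdf)
  } else {
    rhs <- c(".group", if (length(covariates)) paste0(".r_", covariates))
    fit <- stats::lm(stats::reformulate(rhs, response = ".y"), data = rdf)
  }
  co <- summary(fit)$coefficients
  grp_rows <- grep("^\\.group", rownames(co))
  contrasts <- data.frame(
    group = sub("^\\.group", "", rownames(co)[grp_rows]),
    estimate = co[grp_rows, 1], se = co[grp_rows, 2],
    t = co[grp_rows, 3], p = co[grp_rows, 4], row.names = NULL)
  list(outcome = outcome, covariates = covariates, method = method,
       reference = reference, contrasts = contrasts)
}

#' Spearman correlation with a companion linear fit
#'
#' Reports the tie-corrected Spearman rank correlation and its asymptotic
#' two-sided p, together with the ordinary least-squares slope and
#' intercept of `y` on `x` (both are conventional companions in clinical
#' reports).
#'
#' @param data Data frame.
#' @param x,y Column names.
#' @return List with `x`, `y`, `rho`, `p_value`, `slope`, `intercept`,
#'   `n`, and `degenerate` (TRUE when either variable is constant, in
#'   which case `rho` is `NA`).
#' @export
spearman_with_linfit <- function(data, x, y) {
  keep <- stats::complete.cases(data[, c(x, y)])
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  if (length(xv) < 4L) stop("need >= 4 paired observations", call. = FALSE)
  degenerate <- length(unique(xv)) == 1L || length(unique(yv)) == 1L
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(xv, yv, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  fit <- stats::lm(yv ~ xv)
  list(x = x, y = y, rho = rho, p_value = p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(xv), degenerate = degenerate)
}

#' Group-by-risk-category contingency analysis
#'
#' Cross-tabulates study group against the four CERT1 risk categories and
#' tests independence by Pearson's chi-square (no continuity correction).
#' When any expected cell count falls below 5 a Fisher exact p-value is
#' reported alongside.
#'
#' @param cohort A `cohort` data frame (groups assigned).
#' @param scores Per-subject score table from [cert1_score()], aligned on
#'   `id`.
#' @return List with the count `table`, `statistic`, `df`, `p_value`,
#'   `fisher_p` (`NA` unless triggered) and `min_expected`.
#' @export
risk_category_contingency <- function(cohort, scores) {
  g <- .check_groups(cohort)
  cat <- scores$category[match(cohort$id, scores$id)]
  if (any(is.na(cat))) stop("scores missing for some subjects", call. = FALSE)
  if (nlevels(droplevels(g)) < 2L) {
    stop("contingency analysis needs >= 2 groups", call. = FALSE)
  }
  tab <- table(group = g,
               category = factor(cat, levels = cert1_categories()))
  # Pearson chi-square computed explicitly so that an unused risk category
  # (expected count 0) contributes nothing instead of producing NaN; df
  # stays (r-1)(c-1) on the full 3x4 table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- expected > 0
  stat <- sum((tab[nz] - expected[nz])^2 / expected[nz])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  min_exp <- min(expected)
  fisher_p <- NA_real_
  if (min_exp < 5) {
    fisher_p <- tryCatch(
      stats::fisher.test(tab, workspace = 2e7)$p.value,
      error = function(e) NA_real_)
  }
  list(table = tab, statistic = stat, df = df, p_value = p,
       min_expected = min_exp, fisher_p = fisher_p)
}
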