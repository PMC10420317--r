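## End-to-end analysis battery ---------------------------------------------

# Table-1-style variables tested across groups
.group_test_variables <- c("age", "bmi", "wc", "sbp", "dbp", "glucose",
                           "insulin", "homa_ir", "tc", "hdl", "ldl", "tg",
                           "crp", "cer16", "cer18", "cer241", "cer240",
                           "r16_240", "r18_240", "r241_240", "frs", "va")
.regression_outcomes <- c("cer16", "cer18", "cer241", "cer240",
                          "r16_240", "r18_240", "r241_240", "cert1")
.regression_predictors <- c("wc", "sbp", "dbp", "homa_ir", "hdl", "tg", "crp")

#' Analysis configuration
#'
#' Battery toggles and method options for [run_full_analysis()].
#'
#' @param group_tests,regressions,ancova,associations,contingency Logical
#'   toggles for the corresponding report sections.
#' @param adjust Pairwise adjustment for Dunn tests.
#' @param ancova_covariate_sets List of covariate name vectors for the
#'   CERT1 rank-ANCOVA battery.
#' @param ancova_method `"rank_lm"` or `"quade"`.
#' @param alpha Nominal significance level recorded in the report.
#' @param glucose_factor Glucose unit conversion variant (see
#'   [convert_glucose()]).
#' @return Named list of settings.
#' @export
analysis_config <- function(group_tests = TRUE, regressions = TRUE,
                            ancova = TRUE, associations = TRUE,
                            contingency = TRUE,
                            adjust = "bonferroni",
                            ancova_covariate_sets = list(
                              "wc",
                              c("homa_ir", "crp"),
                              c("wc", "homa_ir"),
                              c("wc", "crp")),
                            ancova_method = "rank_lm",
                            alpha = 0.05,
                            glucose_factor = "exact") {
  list(group_tests = group_tests, regressions = regressions,
       ancova = ancova, associations = associations,
       contingency = contingency, adjust = adjust,
       ancova_covariate_sets = ancova_covariate_sets,
       ancova_method = ancova_method, alpha = alpha,
       glucose_factor = glucose_factor)
}

#' Derive the per-subject analysis frame
#'
#' Augments a cohort with the computed quantities every downstream stage
#' consumes: ceramide ratios, HOMA-IR, CERT1 subscores/total/category, the
#' 10-year Framingham risk (`frs`, percent) and vascular age (`va`, years).
#'
#' @param cohort A `cohort` data frame.
#' @param reference Optional external `quartile_reference` for CERT1
#'   scoring; default scores against the cohort's own quartiles.
#' @param config Settings from [analysis_config()].
#' @param risk_scores Also derive `frs` and `va` (the costly root-finding
#'   step); set `FALSE` for batteries that do not use them.
#' @return Data frame: cohort columns plus the derived ones.
#' @export
build_analysis_frame <- function(cohort, reference = NULL,
                                 config = analysis_config(),
                                 risk_scores = TRUE) {
  df <- as.data.frame(cohort)
  df <- cbind(df, compute_ratios(df))
  df$homa_ir <- homa_ir(df$insulin, df$glucose, config$glucose_factor)
  scores <- cert1_score(cohort, reference)
  df <- cbind(df, scores[match(df$id, scores$id),
                         setdiff(names(scores), "id")])
  if (risk_scores) {
    df$frs <- suppressWarnings(
      frs_2008(df$age, df$tc, df$hdl, df$sbp, df$treated_htn,
               df$smoking, df$diabetes, df$sex, quiet = TRUE))
    df$va <- vascular_age(df$frs, df$sex)
    attr(df$frs, "extrapolated") <- NULL
    attr(df$va, "clamped") <- NULL
  }
  rownames(df) <- NULL
  df
}

#' Run the full cohort analysis battery
#'
#' Executes, in order: per-variable group comparisons (Kruskal-Wallis +
#' Dunn) over the demographic/clinical/ceramide panel, the CERT1 group
#' comparison, the multiple-regression battery (each ceramide, ratio and
#' CERT1 on the seven clinical surrogates), the CERT1 rank-ANCOVA battery
#' over the configured covariate sets, the CERT1-vs-FRS and CERT1-vs-VA
#' associations, and the group-by-risk-category contingency test. Stages
#' are run independently: a stage that fails (e.g. group tests on a
#' single-group cohort) records its error under `$errors` and the
#' remaining stages still run. Deterministic given cohort and config.
#'
#' @param cohort A `cohort` data frame with groups assigned.
#' @param config Settings from [analysis_config()].
#' @param reference Optional external quartile reference for scoring.
#' @return An `analysis_report` list with sections `scores`,
#'   `group_tests`, `cert1_test`, `regressions`, `ancova`, `associations`,
#'   `contingency`, plus `errors` and provenance metadata.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              reference = NULL) {
  report <- list(provenance = attr(cohort, "provenance"),
                 n = nrow(cohort), config = config, errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  risk_scores <- isTRUE(config$group_tests) || isTRUE(config$associations)
  frame <- build_analysis_frame(cohort, reference, config,
                                risk_scores = risk_scores)
  score_cols <- c("id", "group", paste0("s_", cert1_variables()),
                  "cert1", "category", "homa_ir",
                  if (risk_scores) c("frs", "va"))
  report$scores <- frame[, score_cols]
  report$scores$category <- as.character(report$scores$category)
  if (isTRUE(config$group_tests)) {
    report$group_tests <- stage("group_tests", {
      out <- lapply(.group_test_variables, function(v)
        kruskal_dunn(frame, v, adjust = config$adjust))
      names(out) <- .group_test_variables
      out
    })
    report$cert1_test <- stage("cert1_test",
      kruskal_dunn(frame, "cert1", adjust = config$adjust))
  }
  if (isTRUE(config$regressions)) {
    report$regressions <- stage("regressions", {
      out <- lapply(.regression_outcomes, function(o)
        ols_multiple_regression(frame, o, .regression_predictors))
      names(out) <- .regression_outcomes
      out
    })
  }
  if (isTRUE(config$ancova)) {
    report$ancova <- stage("ancova",
      lapply(config$ancova_covariate_sets, function(cv)
        rank_ancova(frame, "cert1", cv, method = config$ancova_method)))
  }
  if (isTRUE(config$associations)) {
    report$associations <- stage("associations", list(
      frs = spearman_with_linfit(frame, "cert1", "frs"),
      va = spearman_with_linfit(frame, "cert1", "va")))
  }
  if (isTRUE(config$contingency)) {
    report$contingency <- stage("contingency", {
      res <- risk_category_contingency(
        cohort, frame[, c("id", "category")])
      res$table <- as.data.frame.matrix(res$table)
      res
    })
  }
  class(report) <- "analysis_report"
  report
}

#' Write / read an analysis report
#'
#' Reports are serialized as JSON at full numeric precision so that
#' re-reading reproduces every numeric field bit-exactly.
#'
#' @param report An `analysis_report` (or any list).
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   deserialized report list.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                           auto_unbox = TRUE, digits = I(17), na = "null",
                           null = "null", force = TRUE)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write report to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Export the tabular sections of a report as CSV files
#'
#' Writes per-subject scores, the regression coefficient tables, ANCOVA
#' contrasts and the contingency table as separate CSV files under a
#' directory.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
export_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  if (!is.null(report$scores)) put(report$scores, "scores")
  if (!is.null(report$regressions)) {
    coefs <- do.call(rbind, lapply(report$regressions, function(r)
      cbind(outcome = r$outcome, r$coefficients)))
    put(coefs, "regressions")
  }
  if (!is.null(report$ancova)) {
    contr <- do.call(rbind, lapply(report$ancova, function(a)
      cbind(covariates = paste(a$covariates, collapse = "+"), a$contrasts)))
    put(contr, "ancova")
  }
  if (!is.null(report$contingency)) {
    put(cbind(group = rownames(report$contingency$table),
              report$contingency$table), "contingency")
  }
  if (!is.null(report$group_tests)) {
    gt <- do.call(rbind, lapply(report$group_tests, function(t)
      data.frame(variable = t$variable, statistic = t$statistic,
                 df = t$df, p_value = t$p_value)))
    put(gt, "group_tests")
  }
  invisible(written)
}
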