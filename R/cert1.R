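## CERT1: quartile-based ceramide risk scoring -----------------------------

# The six scored variables: three plasma concentrations and the three
# ratios to Cer 24:0. Cer 24:0 itself enters only as the denominator.
.cert1_variables <- c("cer16", "cer18", "cer241",
                      "r16_240", "r18_240", "r241_240")

#' Names of the six CERT1 scoring variables
#' @return Character vector: `cer16`, `cer18`, `cer241`, `r16_240`,
#'   `r18_240`, `r241_240`.
#' @export
cert1_variables <- function() .cert1_variables

#' Ceramide ratios to Cer 24:0
#'
#' Computes Cer 16:0/24:0, Cer 18:0/24:0 and Cer 24:1/24:0 as exact
#' quotients of the plasma concentrations, without rounding.
#'
#' @param cohort A `cohort` data frame (or any data frame with `cer16`,
#'   `cer18`, `cer241`, `cer240` columns).
#' @return Data frame with columns `r16_240`, `r18_240`, `r241_240`.
#' @export
compute_ratios <- function(cohort) {
  needed <- c("cer16", "cer18", "cer241", "cer240")
  miss <- setdiff(needed, names(cohort))
  if (length(miss) > 0L) {
    stop("ceramide panel incomplete: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  c240 <- cohort$cer240
  if (any(is.na(c240)) || any(c240 <= 0)) {
    stop("Cer 24:0 must be present and strictly positive to form ratios",
         call. = FALSE)
  }
  if (any(is.na(cohort$cer16)) || any(is.na(cohort$cer18)) ||
      any(is.na(cohort$cer241))) {
    stop("ceramide panel incomplete: NA concentration", call. = FALSE)
  }
  data.frame(r16_240 = cohort$cer16 / c240,
             r18_240 = cohort$cer18 / c240,
             r241_240 = cohort$cer241 / c240)
}

#' Fit quartile cutoffs for CERT1 scoring
#'
#' Computes Q25/Q50/Q75 for each of the six scoring variables on the pooled
#' cohort (the default reference population is the analyzed cohort itself).
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] `type = 7`, the common scientific-software default);
#' the estimator is configurable.
#'
#' @param cohort A `cohort` data frame with complete ceramide panels.
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return A `quartile_reference`: data frame with columns `variable`,
#'   `q25`, `q50`, `q75`, plus a `source` attribute (`"self_cohort"`).
#' @export
fit_quartile_reference <- function(cohort, type = 7) {
  panel <- c("cer16", "cer18", "cer241", "cer240")
  complete <- stats::complete.cases(as.data.frame(cohort)[, panel])
  if (sum(complete) < 8L) {
    stop("insufficient data: need >= 8 subjects with complete ceramide panels",
         call. = FALSE)
  }
  sub <- as.data.frame(cohort)[complete, , drop = FALSE]
  values <- cbind(sub[, c("cer16", "cer18", "cer241")], compute_ratios(sub))
  qs <- t(vapply(.cert1_variables, function(v) {
    stats::quantile(values[[v]], probs = c(0.25, 0.5, 0.75),
                    type = type, names = FALSE)
  }, numeric(3)))
  ref <- data.frame(variable = .cert1_variables,
                    q25 = qs[, 1], q50 = qs[, 2], q75 = qs[, 3],
                    row.names = NULL)
  quartile_reference(ref, source = "self_cohort")
}

#' Construct a quartile reference table
#'
#' @param ref Data frame with columns `variable`, `q25`, `q50`, `q75`
#'   covering all six scoring variables.
#' @param source `"self_cohort"` or `"external_table"`.
#' @return A validated `quartile_reference`.
#' @export
quartile_reference <- function(ref, source = c("self_cohort", "external_table")) {
  source <- match.arg(source)
  need <- c("variable", "q25", "q50", "q75")
  if (!all(need %in% names(ref))) {
    stop("quartile reference must have columns variable, q25, q50, q75",
         call. = FALSE)
  }
  miss <- setdiff(.cert1_variables, ref$variable)
  if (length(miss) > 0L) {
    stop("quartile reference missing variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(ref$q25 > ref$q50 | ref$q50 > ref$q75)) {
    stop("quartile cutoffs must satisfy q25 <= q50 <= q75", call. = FALSE)
  }
  out <- as.data.frame(ref)[, need]
  attr(out, "source") <- source
  class(out) <- c("quartile_reference", "data.frame")
  out
}

#' Read/write a quartile reference as plain text
#'
#' Serialized as a small CSV (`variable,q25,q50,q75,source`) so that scores
#' are reproducible across runs and new individuals can be scored against a
#' frozen population reference.
#'
#' @param ref A `quartile_reference`.
#' @param path File path.
#' @return `write_quartile_reference()` returns `path` invisibly;
#'   `read_quartile_reference()` returns a `quartile_reference`.
#' @export
write_quartile_reference <- function(ref, path) {
  df <- as.data.frame(ref)
  df$source <- attr(ref, "source")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quartile_reference
#' @export
read_quartile_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  src <- unique(df$source)
  quartile_reference(df[, c("variable", "q25", "q50", "q75")], source = src)
}

#' Quartile-membership subscore of a single value
#'
#' Scores a value against reference cutoffs: 0 below the median, +1 in the
#' third quartile, +2 in the fourth. Intervals are half-open:
#' `[q50, q75) -> 1`, `[q75, Inf) -> 2`, so a value exactly at Q75 belongs
#' to the fourth quartile.
#'
#' @param value Numeric value(s).
#' @param q50,q75 Reference median and 75th percentile, `q50 <= q75`.
#' @return Integer subscore(s) in `{0, 1, 2}`.
#' @export
subscore <- function(value, q50, q75) {
  if (any(q50 > q75)) stop("cutoffs must satisfy q50 <= q75", call. = FALSE)
  as.integer(value >= q50) + as.integer(value >= q75)
}

#' Map a CERT1 total to its risk category
#'
#' Categories: low = 0-2, moderate = 3-6, increased = 7-9, high = 10-12.
#'
#' @param total Integer total score(s) in `[0, 12]`.
#' @return Factor with ordered levels `low`, `moderate`, `increased`, `high`.
#' @export
categorize <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 12) ||
      any(total != round(total))) {
    stop("CERT1 total must be an integer in [0, 12]", call. = FALSE)
  }
  cut(total, breaks = c(-0.5, 2.5, 6.5, 9.5, 12.5),
      labels = c("low", "moderate", "increased", "high"),
      ordered_result = TRUE)
}

#' Levels of the CERT1 risk category
#' @return `c("low", "moderate", "increased", "high")`.
#' @export
cert1_categories <- function() c("low", "moderate", "increased", "high")

#' Score a cohort with CERT1
#'
#' For each subject the six scoring variables (Cer 16:0, Cer 18:0, Cer 24:1
#' concentrations and their ratios to Cer 24:0) receive a quartile
#' subscore against the reference; CERT1 is their sum (0-12) and maps to a
#' four-level risk category.
#'
#' @param cohort A `cohort` data frame with complete ceramide panels.
#' @param reference A `quartile_reference`; default fits quartiles on
#'   `cohort` itself (the pooled-sample convention).
#' @return Data frame with `id`, the six per-variable subscores
#'   (`s_<variable>`), `cert1` total and `category`.
#' @export
cert1_score <- function(cohort, reference = NULL) {
  if (is.null(reference)) reference <- fit_quartile_reference(cohort)
  if (!inherits(reference, "quartile_reference")) {
    reference <- quartile_reference(reference, source = "external_table")
  }
  df <- as.data.frame(cohort)
  values <- cbind(df[, c("cer16", "cer18", "cer241")], compute_ratios(df))
  sub <- sapply(.cert1_variables, function(v) {
    row <- reference[reference$variable == v, ]
    subscore(values[[v]], row$q50, row$q75)
  })
  sub <- matrix(as.integer(sub), nrow = nrow(df),
                dimnames = list(NULL, paste0("s_", .cert1_variables)))
  total <- as.integer(rowSums(sub))
  out <- data.frame(id = df$id, sub, cert1 = total,
                    category = categorize(total))
  rownames(out) <- NULL
  out
}
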