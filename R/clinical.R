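## HOMA-IR, metabolic-syndrome classification, Framingham risk, vascular age

#' Homeostatic model assessment of insulin resistance
#'
#' HOMA-IR = insulin (uIU/mL) x glucose (mmol/L) / 22.5. Glucose is supplied
#' in mg/dL and converted internally (exact molar factor by default; see
#' [convert_glucose()]).
#'
#' @param insulin Fasting insulin in uIU/mL (= mU/L), strictly positive.
#' @param glucose Fasting glucose in mg/dL, strictly positive.
#' @param glucose_factor Conversion variant passed to [convert_glucose()].
#' @return Dimensionless HOMA-IR index.
#' @export
homa_ir <- function(insulin, glucose, glucose_factor = "exact") {
  if (any(is.na(insulin)) || any(is.na(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0)) {
    stop("homa_ir requires strictly positive insulin and glucose",
         call. = FALSE)
  }
  insulin * convert_glucose(glucose, glucose_factor) / 22.5
}

#' Default metabolic-syndrome thresholds
#'
#' IDF-consensus adult cutoffs (Europid waist circumference): abdominal
#' obesity WC >= 94 cm (M) / >= 80 cm (F); triglycerides >= 150 mg/dL;
#' HDL-C < 40 (M) / < 50 (F) mg/dL; blood pressure SBP >= 130 or
#' DBP >= 85 mmHg; fasting glucose >= 100 mg/dL. Any corresponding
#' treatment flag satisfies its criterion.
#'
#' @return Named list of cutoffs, editable and passable to
#'   [classify_mets()].
#' @export
mets_thresholds <- function() {
  list(wc_m = 94, wc_f = 80,
       tg = 150,
       hdl_m = 40, hdl_f = 50,
       sbp = 130, dbp = 85,
       glucose = 100)
}

#' Classify metabolic syndrome from five clinical criteria
#'
#' Five flags are evaluated per subject: abdominal obesity (sex-specific
#' WC), hypertriglyceridemia (or lipid treatment), reduced HDL-C (or lipid
#' treatment), hypertension (or antihypertensive treatment), and
#' hyperglycemia (or diagnosed type 2 diabetes). Under the default
#' `rule = "any3"` a subject is positive with three or more flags; under
#' `rule = "idf"` the canonical consensus rule applies (central obesity
#' mandatory plus at least two of the remaining four).
#'
#' @param cohort A `cohort` data frame.
#' @param thresholds Cutoff list as from [mets_thresholds()].
#' @param rule `"any3"` (default) or `"idf"`.
#' @return Data frame with `id`, the five logical flags, `count`
#'   and `positive`.
#' @export
classify_mets <- function(cohort, thresholds = mets_thresholds(),
                          rule = c("any3", "idf")) {
  rule <- match.arg(rule)
  df <- as.data.frame(cohort)
  required <- c("wc", "tg", "hdl", "sbp", "dbp", "glucose",
                "treated_htn", "diabetes", "sex")
  for (col in required) {
    if (any(is.na(df[[col]]))) {
      stop("classify_mets: missing required field '", col, "'", call. = FALSE)
    }
  }
  th <- thresholds
  wc_cut <- ifelse(df$sex == "M", th$wc_m, th$wc_f)
  hdl_cut <- ifelse(df$sex == "M", th$hdl_m, th$hdl_f)
  abdominal <- df$wc >= wc_cut
  hypertg <- df$tg >= th$tg
  low_hdl <- df$hdl < hdl_cut
  hypertension <- df$sbp >= th$sbp | df$dbp >= th$dbp | df$treated_htn
  hyperglycemia <- df$glucose >= th$glucose | df$diabetes
  flags <- cbind(abdominal, hypertg, low_hdl, hypertension, hyperglycemia)
  count <- as.integer(rowSums(flags))
  positive <- if (rule == "any3") count >= 3L else
    abdominal & (count - abdominal) >= 2L
  data.frame(id = df$id, abdominal = abdominal, hypertg = hypertg,
             low_hdl = low_hdl, hypertension = hypertension,
             hyperglycemia = hyperglycemia,
             count = count, positive = positive)
}

## Framingham 2008 general-CVD risk ---------------------------------------

#' Sex-specific 2008 Framingham general-CVD Cox coefficients
#'
#' Log-hazard coefficients, linear-predictor means and 10-year baseline
#' survival of the office-based general cardiovascular risk functions
#' (continuous covariates entered on the natural-log scale), shipped as a
#' plain-text table with the package.
#'
#' @return Data frame with columns `sex`, `term`, `value`.
#' @export
frs_coefficients <- function() {
  if (is.null(.frs_cache$coefs)) {
    path <- system.file("extdata", "frs2008_coefficients.csv",
                        package = "certscore", mustWork = TRUE)
    .frs_cache$coefs <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .frs_cache$coefs
}

.frs_cache <- new.env(parent = emptyenv())

.frs_lookup <- function(coefs, sex, term) {
  v <- coefs$value[coefs$sex == sex & coefs$term == term]
  if (length(v) != 1L) stop("FRS coefficient table corrupt: ", sex, "/", term,
                            call. = FALSE)
  v
}

#' 10-year general cardiovascular risk (Framingham 2008)
#'
#' Computes the sex-specific 10-year risk of a first general cardiovascular
#' event from age, total cholesterol, HDL-C, systolic blood pressure
#' (treated or untreated), smoking and diabetes status:
#' `risk = 1 - S0(10)^exp(L - mean(L))`, with `L` the Cox linear predictor
#' on log-transformed continuous covariates.
#'
#' The published model covers ages 30-74. Outside that range the linear
#' predictor is extrapolated; by default a warning is issued and the result
#' flagged, or an error raised when `extrapolate = FALSE`. (Extrapolation
#' below age 30 is also what the vascular-age construct requires.)
#'
#' @param age Years.
#' @param tc Total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param sbp Systolic blood pressure, mmHg.
#' @param treated_htn Logical, on antihypertensive treatment.
#' @param smoking Logical, current smoker.
#' @param diabetes Logical.
#' @param sex `"F"` or `"M"`.
#' @param extrapolate Allow ages outside 30-74 (warn + flag) instead of
#'   erroring.
#' @param quiet Suppress the extrapolation warning (used internally by the
#'   vascular-age root finder).
#' @return Numeric risk in percent (0-100), with attribute
#'   `"extrapolated"` (logical vector) marking out-of-range ages.
#' @export
frs_2008 <- function(age, tc, hdl, sbp, treated_htn, smoking, diabetes, sex,
                     extrapolate = TRUE, quiet = FALSE) {
  n <- max(length(age), length(tc), length(hdl), length(sbp),
           length(treated_htn), length(smoking), length(diabetes),
           length(sex))
  age <- rep_len(age, n); tc <- rep_len(tc, n); hdl <- rep_len(hdl, n)
  sbp <- rep_len(sbp, n); treated_htn <- rep_len(as.logical(treated_htn), n)
  smoking <- rep_len(as.logical(smoking), n)
  diabetes <- rep_len(as.logical(diabetes), n)
  sex <- rep_len(sex, n)
  if (any(is.na(c(age, tc, hdl, sbp))) ||
      any(c(age, tc, hdl, sbp) <= 0)) {
    stop("frs_2008: age, tc, hdl, sbp must be present and positive",
         call. = FALSE)
  }
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)
  out_of_range <- age < 30 | age > 74
  if (any(out_of_range)) {
    if (!extrapolate) {
      stop("frs_2008: age outside 30-74 validity range", call. = FALSE)
    }
    if (!quiet) warning("frs_2008: age outside 30-74; risk extrapolated",
                        call. = FALSE)
  }
  coefs <- frs_coefficients()
  risk <- numeric(n)
  for (s in unique(sex)) {
    i <- sex == s
    b_sbp <- ifelse(treated_htn[i],
                    .frs_lookup(coefs, s, "log_sbp_treated"),
                    .frs_lookup(coefs, s, "log_sbp_untreated"))
    lp <- .frs_lookup(coefs, s, "log_age") * log(age[i]) +
      .frs_lookup(coefs, s, "log_tc") * log(tc[i]) +
      .frs_lookup(coefs, s, "log_hdl") * log(hdl[i]) +
      b_sbp * log(sbp[i]) +
      .frs_lookup(coefs, s, "smoking") * smoking[i] +
      .frs_lookup(coefs, s, "diabetes") * diabetes[i]
    s0 <- .frs_lookup(coefs, s, "s0_10y")
    risk[i] <- 100 * (1 - s0^exp(lp - .frs_lookup(coefs, s, "mean_lp")))
  }
  attr(risk, "extrapolated") <- out_of_range
  risk
}

#' Reference "all-normal" risk-factor profile
#'
#' Risk-factor levels considered normal for the vascular-age construct:
#' non-smoker, non-diabetic, untreated, total cholesterol 160 mg/dL,
#' HDL-C 50 mg/dL, SBP 110 mmHg. Configurable.
#'
#' @return Named list of normal-profile values.
#' @export
normal_risk_profile <- function() {
  list(tc = 160, hdl = 50, sbp = 110,
       treated_htn = FALSE, smoking = FALSE, diabetes = FALSE)
}

#' Vascular age from a 10-year risk
#'
#' The age at which a person of the same sex with all other risk factors at
#' normal levels (see [normal_risk_profile()]) has the same predicted
#' 10-year general-CVD risk. Solved by monotone root finding on age to a
#' 0.1-year tolerance. Risks below (above) the risk achievable at the search
#' bounds are clamped to the bound and flagged.
#'
#' @param risk10y Risk in percent, as returned by [frs_2008()].
#' @param sex `"F"` or `"M"`.
#' @param profile Normal-profile list; default [normal_risk_profile()].
#' @param bounds Age search interval in years.
#' @return Vascular age(s) in years, attribute `"clamped"` flags values at
#'   a search bound.
#' @export
vascular_age <- function(risk10y, sex, profile = normal_risk_profile(),
                         bounds = c(1, 120)) {
  n <- max(length(risk10y), length(sex))
  risk10y <- rep_len(risk10y, n); sex <- rep_len(sex, n)
  risk_at <- function(a, s) {
    frs_2008(a, profile$tc, profile$hdl, profile$sbp, profile$treated_htn,
             profile$smoking, profile$diabetes, s, quiet = TRUE)
  }
  va <- numeric(n); clamped <- logical(n)
  for (k in seq_len(n)) {
    lo <- risk_at(bounds[1], sex[k]); hi <- risk_at(bounds[2], sex[k])
    if (risk10y[k] <= lo) { va[k] <- bounds[1]; clamped[k] <- TRUE; next }
    if (risk10y[k] >= hi) { va[k] <- bounds[2]; clamped[k] <- TRUE; next }
    va[k] <- stats::uniroot(function(a) risk_at(a, sex[k]) - risk10y[k],
                            interval = bounds, tol = 0.01)$root
  }
  attr(va, "clamped") <- clamped
  va
}
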