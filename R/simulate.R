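## Synthetic three-group cohorts from median/IQR summaries -----------------

# Variables drawn by the copula sampler, in fixed order. HOMA-IR and the
# ceramide ratios are derived quantities and are never simulated directly.
.sim_variables <- c("age", "bmi", "wc", "sbp", "dbp", "glucose", "insulin",
                    "tc", "hdl", "ldl", "tg", "crp",
                    "cer16", "cer18", "cer241", "cer240")

#' Published per-group marginal summaries (median and quartiles)
#'
#' The packaged summary table of the three-group study population
#' (normal-weight controls and obese subjects without/with metabolic
#' syndrome): per group and variable the median, 25th and 75th percentile
#' in the cohort schema's units. The normal-weight CRP lower quartile,
#' printed as 0, is replaced by the assay detection limit (0.03 mg/dL),
#' treating values below the limit as left-censored.
#'
#' @return Data frame with columns `group`, `variable`, `median`, `q25`,
#'   `q75`.
#' @export
table1_marginals <- function() {
  utils::read.csv(system.file("extdata", "table1_marginals.csv",
                              package = "certscore", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published group sizes and sex/smoking splits
#'
#' @return Data frame with columns `group`, `n`, `n_female`, `n_smoking`.
#' @export
table1_groups <- function() {
  utils::read.csv(system.file("extdata", "table1_groups.csv",
                              package = "certscore", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Fit a lognormal distribution to a median and quartile pair
#'
#' `mu = ln(median)`; `sigma = ln(q75/q25) / (2 * qnorm(0.75))` (the
#' denominator, 1.3490, is the distance between the standard-normal
#' quartiles). The fit reproduces the median exactly and the quartile
#' *ratio* exactly; when the printed quartiles are asymmetric about the
#' median on the log scale the individual quartiles deviate, and the
#' relative deviations are reported as an attribute.
#'
#' @param median,q25,q75 Summary values, `0 < q25 <= median <= q75`.
#' @return List `(mu, sigma)` with attribute `quartile_deviation` giving
#'   the relative error of the implied q25 and q75.
#' @export
fit_lognormal_from_quartiles <- function(median, q25, q75) {
  if (any(c(median, q25, q75) <= 0) || is.na(median + q25 + q75)) {
    stop("lognormal fit requires strictly positive median, q25, q75",
         call. = FALSE)
  }
  if (q25 > median || median > q75) {
    stop("quartiles must satisfy q25 <= median <= q75", call. = FALSE)
  }
  z75 <- stats::qnorm(0.75)
  mu <- log(median)
  sigma <- log(q75 / q25) / (2 * z75)
  implied <- exp(mu + c(-1, 1) * z75 * sigma)
  out <- list(mu = mu, sigma = sigma)
  attr(out, "quartile_deviation") <- c(q25 = implied[1] / q25 - 1,
                                       q75 = implied[2] / q75 - 1)
  out
}

#' Default rank-correlation structure of the generator
#'
#' Spearman correlations linking the ceramide axis to the clinical axis:
#' 0.4 between each of Cer 18:0 and Cer 24:1 and each of waist
#' circumference, insulin (the driver of HOMA-IR) and CRP; 0.3 among the
#' clinical trio; -0.3 between Cer 24:0 and waist circumference (very
#' long chain ceramide falls with adiposity); 0 elsewhere. These are
#' calibration values chosen to embody the qualitative association
#' structure, not estimates from any data set. The matrix is projected to
#' the nearest positive semi-definite correlation matrix if needed.
#'
#' @return Symmetric rank-correlation matrix over the simulated variables.
#' @export
default_dependence <- function() {
  v <- .sim_variables
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set_r <- function(R, a, b, r) { R[a, b] <- r; R[b, a] <- r; R }
  for (cer in c("cer18", "cer241")) {
    for (cl in c("wc", "insulin", "crp")) R <- set_r(R, cer, cl, 0.4)
  }
  R <- set_r(R, "wc", "insulin", 0.3)
  R <- set_r(R, "wc", "crp", 0.3)
  R <- set_r(R, "insulin", "crp", 0.3)
  R <- set_r(R, "cer240", "wc", -0.3)
  R
}

# Spearman-to-Pearson conversion for the Gaussian copula, with nearest-PSD
# repair of the resulting correlation matrix.
.copula_correlation <- function(spearman) {
  P <- 2 * sin(pi * spearman / 6)
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    P <- as.matrix(Matrix::nearPD(P, corr = TRUE)$mat)
    dimnames(P) <- dimnames(spearman)
  } else if (min(ev) < 0) {
    P <- P + diag(1e-8, nrow(P))
  }
  P
}

#' Build a group-level simulation specification
#'
#' @param group Group label (see [cohort_groups()]).
#' @param n Group size; default the published size.
#' @param marginals Summary table as from [table1_marginals()].
#' @param groups Group metadata as from [table1_groups()].
#' @param p_treated_htn,p_diabetes Prevalence of antihypertensive treatment
#'   and diagnosed diabetes; both default to 0 (the study excluded treated
#'   or otherwise diseased subjects).
#' @return A `group_spec` list.
#' @export
group_spec <- function(group, n = NULL,
                       marginals = table1_marginals(),
                       groups = table1_groups(),
                       p_treated_htn = 0, p_diabetes = 0) {
  if (!group %in% groups$group) stop("unknown group: ", group, call. = FALSE)
  meta <- groups[groups$group == group, ]
  marg <- marginals[marginals$group == group &
                      marginals$variable %in% .sim_variables, ]
  miss <- setdiff(.sim_variables, marg$variable)
  if (length(miss) > 0L) {
    stop("marginal summaries missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(marg$q25 > marg$median | marg$median > marg$q75) ||
      any(marg$q25 <= 0)) {
    stop("invalid marginal summary (need 0 < q25 <= median <= q75)",
         call. = FALSE)
  }
  if (is.null(n)) n <- meta$n
  if (n <= 0) stop("group size must be positive", call. = FALSE)
  scale <- n / meta$n
  structure(list(group = group, n = as.integer(n),
                 marginals = marg[match(.sim_variables, marg$variable), ],
                 n_female = as.integer(round(meta$n_female * scale)),
                 n_smoking = as.integer(round(meta$n_smoking * scale)),
                 p_treated_htn = p_treated_htn, p_diabetes = p_diabetes),
            class = "group_spec")
}

# inverse-CDF transforms per variable: lognormal for positive analytes,
# truncated normal for age, 5-mmHg grid for blood pressure
.sim_transform <- function(variable, u, median, q25, q75) {
  if (variable == "age") {
    m <- median; s <- (q75 - q25) / (2 * stats::qnorm(0.75))
    lo <- stats::pnorm(18, m, s); hi <- stats::pnorm(65, m, s)
    return(stats::qnorm(lo + u * (hi - lo), m, s))
  }
  fit <- fit_lognormal_from_quartiles(median, q25, q75)
  x <- stats::qlnorm(u, fit$mu, fit$sigma)
  if (variable %in% c("sbp", "dbp")) x <- pmax(5 * round(x / 5), 5)
  x
}

#' Draw one synthetic group through a Gaussian copula
#'
#' Samples standard-normal deviates with the Pearson correlation implied by
#' the target Spearman matrix, maps them to uniforms, and applies each
#' variable's fitted marginal (lognormal for positive analytes; truncated
#' normal on 18-65 years for age; blood pressure snapped to the 5-mmHg
#' measurement grid). Sex and smoking are assigned by the published counts
#' and shuffled. Deterministic given `seed`; with `seed = NULL` the current
#' RNG stream is used (so a caller can seed once for a whole study).
#'
#' @param spec A `group_spec`.
#' @param dependence Spearman target matrix; default [default_dependence()].
#' @param seed Integer seed or `NULL`.
#' @param id_prefix Prefix for subject ids.
#' @return A validated `cohort` data frame of `spec$n` subjects.
#' @export
generate_group <- function(spec, dependence = default_dependence(),
                           seed = NULL, id_prefix = spec$group) {
  stopifnot(inherits(spec, "group_spec"))
  if (is.null(dimnames(dependence))) {
    if (!all(dim(dependence) == length(.sim_variables))) {
      stop("unnamed dependence matrix must be ", length(.sim_variables),
           " x ", length(.sim_variables), call. = FALSE)
    }
    dimnames(dependence) <- list(.sim_variables, .sim_variables)
  } else if (!identical(rownames(dependence), .sim_variables)) {
    dependence <- dependence[.sim_variables, .sim_variables]
  }
  if (!isTRUE(all.equal(dependence, t(dependence))) ||
      any(diag(dependence) != 1)) {
    stop("dependence must be symmetric with unit diagonal", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  P <- .copula_correlation(dependence)
  Z <- MASS::mvrnorm(n, mu = rep(0, ncol(P)), Sigma = P)
  if (n == 1L) Z <- matrix(Z, nrow = 1)
  U <- stats::pnorm(Z)
  colnames(U) <- .sim_variables
  out <- data.frame(id = sprintf("%s-%03d", id_prefix, seq_len(n)))
  m <- spec$marginals
  for (j in seq_along(.sim_variables)) {
    v <- .sim_variables[j]
    out[[v]] <- .sim_transform(v, U[, v], m$median[j], m$q25[j], m$q75[j])
  }
  out$group <- spec$group
  out$sex <- sample(rep(c("F", "M"), c(spec$n_female, n - spec$n_female)))
  out$smoking <- sample(rep(c(TRUE, FALSE),
                            c(spec$n_smoking, n - spec$n_smoking)))
  out$treated_htn <- stats::runif(n) < spec$p_treated_htn
  out$diabetes <- stats::runif(n) < spec$p_diabetes
  cohort_frame(out, provenance = paste0("simulated group ", spec$group,
                                        if (!is.null(seed)) paste0(", seed ", seed)))
}

#' Generate the default three-group study cohort
#'
#' Concatenates synthetic normal-weight (n = 30), obese-without-MetS
#' (n = 24) and obese-with-MetS (n = 30) groups, 84 subjects in total, with
#' the published sex and smoking splits, each group drawn from its own
#' fitted marginals under a shared dependence structure.
#'
#' @param seed Integer seed (one seed drives the whole cohort).
#' @param n Optional named vector overriding group sizes, e.g.
#'   `c(NW = 300, OB_METS_NEG = 240, OB_METS_POS = 300)`.
#' @param dependence Spearman target matrix; default [default_dependence()].
#' @param marginals,groups Summary tables; defaults are the packaged ones.
#' @return A validated `cohort` data frame.
#' @export
generate_study_cohort <- function(seed, n = NULL,
                                  dependence = default_dependence(),
                                  marginals = table1_marginals(),
                                  groups = table1_groups()) {
  set.seed(seed)
  parts <- lapply(groups$group, function(g) {
    ng <- if (!is.null(n) && g %in% names(n)) n[[g]] else NULL
    generate_group(group_spec(g, n = ng, marginals = marginals,
                              groups = groups),
                   dependence = dependence, seed = NULL)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  cohort_frame(out, provenance = paste0("simulated study cohort, seed ", seed))
}
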