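#' @keywords internal
"_PACKAGE"

## Canonical subject-level schema ------------------------------------------

# Column order and types of a cohort data frame. Units are fixed by the
# schema, not per-file: concentrations in mg/dL except insulin (uIU/mL) and
# ceramides (umol/L); pressures in mmHg; wc in cm; age in years.
.cohort_numeric_cols <- c(
  "age", "bmi", "wc", "sbp", "dbp", "glucose", "insulin",
  "tc", "hdl", "ldl", "tg", "crp",
  "cer16", "cer18", "cer241", "cer240"
)
.cohort_logical_cols <- c("smoking", "treated_htn", "diabetes")
.cohort_cols <- c("id", "group", "sex",
                  .cohort_logical_cols, .cohort_numeric_cols)

#' Group labels of the three-arm study design
#'
#' Normal-weight controls (`NW`), obese without metabolic syndrome
#' (`OB_METS_NEG`), obese with metabolic syndrome (`OB_METS_POS`);
#' `UNASSIGNED` marks subjects not yet allocated.
#'
#' @return Character vector of the four valid group labels.
#' @export
cohort_groups <- function() c("NW", "OB_METS_NEG", "OB_METS_POS", "UNASSIGNED")

#' Construct and validate a subject-level cohort
#'
#' A cohort is an ordered data frame with one row per participant carrying
#' demographics (`age`, `sex`, `smoking`), anthropometrics (`bmi`, `wc`),
#' blood pressure (`sbp`, `dbp`), biochemistry (`glucose` mg/dL, `insulin`
#' uIU/mL, `tc`, `hdl`, `ldl`, `tg` mg/dL, `crp` mg/dL), the four plasma
#' ceramide concentrations in umol/L (`cer16`, `cer18`, `cer241`, `cer240`),
#' and treatment/diabetes flags. Missing optional measurements are `NA`;
#' operations that require a missing value raise rather than impute.
#'
#' @param data Data frame with (at least) the canonical columns; extra
#'   columns are dropped.
#' @param provenance Free-text origin (file path or simulation seed).
#' @return A validated `cohort` data frame.
#' @export
cohort_frame <- function(data, provenance = "unspecified") {
  missing_cols <- setdiff(.cohort_cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(data)[, .cohort_cols]
  out$id <- as.character(out$id)
  out$group <- as.character(out$group)
  out$sex <- as.character(out$sex)
  for (col in .cohort_logical_cols) out[[col]] <- as.logical(out[[col]])
  for (col in .cohort_numeric_cols) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- which(!is.na(as.character(v)) & nzchar(trimws(as.character(v))) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("parse error: non-numeric value in column '%s' for subject '%s'",
                     col, out$id[bad[1L]]), call. = FALSE)
      }
      out[[col]] <- num
    }
  }
  if (anyDuplicated(out$id)) {
    stop("cohort validation: subject ids are not unique", call. = FALSE)
  }
  bad_group <- setdiff(unique(out$group), cohort_groups())
  if (length(bad_group) > 0L) {
    stop("cohort validation: unknown group label(s): ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (!all(out$sex %in% c("F", "M"))) {
    stop("cohort validation: sex must be 'F' or 'M'", call. = FALSE)
  }
  # strictly positive where present
  for (col in .cohort_numeric_cols) {
    v <- out[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("cohort validation: non-positive value in '%s'", col),
           call. = FALSE)
    }
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("cohort", "data.frame")
  out
}

#' Read a subject-level cohort from CSV
#'
#' Comma-separated, UTF-8, one header row. Column names may be remapped via
#' `schema`, a named character vector `c(canonical = "file_column")`; columns
#' not mentioned are matched by canonical name. Units are those of the
#' canonical schema (see [cohort_frame()]); empty cells become `NA`.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector remapping file columns onto
#'   canonical names.
#' @return A validated `cohort` data frame; provenance records the path.
#' @export
read_cohort_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("cohort schema error: missing column(s): ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  cohort_frame(raw, provenance = path)
}

#' Write a cohort to CSV
#'
#' @param cohort A `cohort` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, .cohort_cols], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert glucose from mg/dL to mmol/L
#'
#' Uses the exact molar conversion for glucose (molecular weight
#' 180.16 g/mol, i.e. division by 18.016). The rounded clinical factor
#' 0.06 mmol/L per mg/dL can be requested for replication of reports that
#' used it, at the cost of an ~8% bias.
#'
#' @param mg_per_dl Glucose concentration(s) in mg/dL, non-negative.
#' @param factor Either `"exact"` (default, 1/18.016) or `"rounded"` (0.06).
#' @return Concentration(s) in mmol/L.
#' @export
convert_glucose <- function(mg_per_dl, factor = c("exact", "rounded")) {
  factor <- match.arg(factor)
  if (any(!is.na(mg_per_dl) & mg_per_dl < 0)) {
    stop("glucose concentration must be non-negative", call. = FALSE)
  }
  if (factor == "exact") mg_per_dl / 18.016 else mg_per_dl * 0.06
}
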