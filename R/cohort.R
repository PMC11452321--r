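## CohortTable: the raw analysis input. A data.frame with one row per
## patient, columns "<tp>-Q1".."<tp>-Q4" (component dialect) and/or
## "<tp>-OABSS" totals, plus patient_id and optionally true_cluster.

#' Construct a cohort table
#'
#' Assembles and validates the patient-by-timepoint OABSS table used by every
#' downstream stage. Scores may be supplied per component (Q1..Q4 at each
#' timepoint; totals are derived) or as totals only, in which case
#' component-level summaries and component-based networks are unavailable.
#'
#' @param df Data frame holding a `patient_id` column plus either
#'   `"T0-Q1"`..`"T24-Q4"` component columns or `"T0-OABSS"`..`"T24-OABSS"`
#'   total columns (the dialects may coexist; totals are checked against
#'   component sums). An optional integer `true_cluster` column carries the
#'   planted labels of synthetic cohorts.
#' @param validate Check score bounds, totals and completeness (default TRUE).
#'
#' @return An object of class `oab_cohort`: the data frame with totals
#'   populated and attributes `has_components` and `continuous`.
#' @export
cohort_table <- function(df, validate = TRUE) {
  if (!is.data.frame(df)) stop_format("cohort input must be a data.frame")
  if (nrow(df) == 0L) stop_format("cohort is empty (no patient rows)")
  if (!"patient_id" %in% names(df)) stop_format("missing column 'patient_id'")
  df$patient_id <- as.character(df$patient_id)

  tps <- oabss_timepoints()
  comp_names <- as.vector(outer(tps, .components(), comp_col))
  has_components <- all(comp_names %in% names(df))
  if (!has_components && any(comp_names %in% names(df))) {
    missing <- setdiff(comp_names, names(df))
    stop_format("incomplete component columns; missing: ",
                paste(missing, collapse = ", "))
  }

  if (has_components) {
    for (tp in tps) {
      df[[total_col(tp)]] <- rowSums(df[, comp_col(tp, .components())])
    }
  } else {
    missing <- setdiff(vapply(tps, total_col, ""), names(df))
    if (length(missing) > 0L) {
      stop_format("missing timepoint column(s): ", paste(missing, collapse = ", "))
    }
  }

  keep <- c("patient_id",
            if (has_components) comp_names,
            vapply(tps, total_col, ""),
            if ("true_cluster" %in% names(df)) "true_cluster")
  out <- df[, keep, drop = FALSE]
  rownames(out) <- NULL
  cohort <- structure(out,
                      class = c("oab_cohort", "data.frame"),
                      has_components = has_components,
                      continuous = isTRUE(attr(df, "continuous")))
  if (validate) validate_cohort(cohort)
  cohort
}

#' Validate a cohort table
#'
#' Checks patient-id uniqueness, per-component score bounds (Q1 0-2, Q2 0-3,
#' Q3 0-5, Q4 0-5), total bounds (0-15), and that each total equals the sum
#' of its components. Continuous (non-discretized) synthetic cohorts skip the
#' bound and integrality checks.
#'
#' @param cohort An `oab_cohort`.
#' @return The cohort, invisibly; errors describe the offending row/column.
#' @export
validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$patient_id)) {
    stop_validation("duplicate patient_id values")
  }
  tps <- oabss_timepoints()
  continuous <- isTRUE(attr(cohort, "continuous"))
  bounds <- oabss_component_max()
  for (tp in tps) {
    if (attr(cohort, "has_components")) {
      for (comp in .components()) {
        x <- cohort[[comp_col(tp, comp)]]
        if (anyNA(x)) {
          stop_validation("missing value in ", comp_col(tp, comp))
        }
        if (!continuous) {
          bad <- which(x < 0 | x > bounds[[comp]] | x != round(x))
          if (length(bad) > 0L) {
            stop_validation("score out of bounds in ", comp_col(tp, comp),
                            " for patient ", cohort$patient_id[bad[1L]],
                            " (value ", x[bad[1L]], ", bound 0-", bounds[[comp]], ")")
          }
        }
      }
      tot <- rowSums(cohort[, comp_col(tp, .components())])
      if (max(abs(tot - cohort[[total_col(tp)]])) > 1e-9) {
        stop_validation("total does not equal component sum at ", tp)
      }
    }
    x <- cohort[[total_col(tp)]]
    if (anyNA(x)) stop_validation("missing value in ", total_col(tp))
    if (!continuous) {
      bad <- which(x < 0 | x > 15)
      if (length(bad) > 0L) {
        stop_validation("total score out of bounds at ", tp,
                        " for patient ", cohort$patient_id[bad[1L]],
                        " (value ", x[bad[1L]], ", bound 0-15)")
      }
    }
  }
  invisible(cohort)
}

#' @export
print.oab_cohort <- function(x, ...) {
  cat("OABSS cohort: ", nrow(x), " patients, 5 timepoints, ",
      if (attr(x, "has_components")) "component" else "totals-only",
      " dialect", if (isTRUE(attr(x, "continuous"))) " (continuous scores)",
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Writes the component dialect when components are present (columns
#' `patient_id`, `T0-Q1`..`T24-Q4`, optional `true_cluster`), otherwise the
#' totals dialect (`patient_id`, `T0-OABSS`..`T24-OABSS`). UTF-8, header row.
#'
#' @param cohort An `oab_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  tps <- oabss_timepoints()
  cols <- c("patient_id",
            if (attr(cohort, "has_components")) {
              as.vector(outer(tps, .components(), comp_col))
            } else {
              vapply(tps, total_col, "")
            },
            if ("true_cluster" %in% names(cohort)) "true_cluster")
  utils::write.csv(as.data.frame(cohort)[, cols, drop = FALSE],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Accepts both dialects written by [write_cohort_csv()]: the component
#' dialect (`T0-Q1`..`T24-Q4`) and the totals-only dialect
#' (`T0-OABSS`..`T24-OABSS`). A file with neither full set of columns is a
#' format error naming the missing columns; out-of-bounds scores are
#' validation errors naming the patient.
#'
#' @param path CSV file path.
#' @return An `oab_cohort`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"patient_id" %in% names(df)) {
    ## totals-only files in the wild may lack an id column; synthesize one
    df$patient_id <- sprintf("P%03d", seq_len(nrow(df)))
  }
  cohort_table(df)
}
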