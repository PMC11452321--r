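## ScoreMatrix: patients x timepoints total-score matrix, optionally
## standardized per column (population SD, divisor n).

#' Extract the total-score matrix from a cohort
#'
#' Returns the n x 5 matrix of total OABSS per patient and timepoint, row
#' order matching the cohort.
#'
#' @param cohort An `oab_cohort`.
#' @return A `score_matrix`: numeric matrix with patient ids as rownames,
#'   timepoints as colnames, attribute `standardized = FALSE`.
#' @export
extract_totals <- function(cohort) {
  if (!inherits(cohort, "oab_cohort")) stop_format("expected an oab_cohort")
  if (nrow(cohort) == 0L) stop_format("cohort is empty")
  tps <- oabss_timepoints()
  m <- as.matrix(as.data.frame(cohort)[, vapply(tps, total_col, "")])
  dimnames(m) <- list(cohort$patient_id, tps)
  structure(m, standardized = FALSE, class = c("score_matrix", "matrix", "array"))
}

#' Standardize a score matrix
#'
#' Per-column z-scores using the population SD (divisor n), matching the
#' conventional machine-learning scaler. Constant columns cannot be scaled
#' and are mapped to all zeros with a warning. Idempotent on non-constant
#' columns.
#'
#' @param matrix A `score_matrix` (or plain numeric matrix) with at least
#'   two rows.
#' @return A `score_matrix` with `standardized = TRUE`.
#' @export
standardize_scores <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || !is.numeric(m)) stop_format("expected a numeric matrix")
  if (nrow(m) < 2L) {
    stop_format("standardization needs at least 2 rows (population SD undefined)")
  }
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  const <- sd_pop <= .Machine$double.eps * 10
  if (any(const)) {
    warning("constant column(s) mapped to zeros: ",
            paste(colnames(m)[const], collapse = ", "))
    sd_pop[const] <- 1
  }
  z <- sweep(sweep(m, 2L, mu), 2L, sd_pop, "/")
  z[, const] <- 0
  structure(z, standardized = TRUE, class = c("score_matrix", "matrix", "array"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score matrix: ", nrow(x), " patients x ", ncol(x), " timepoints",
      if (isTRUE(attr(x, "standardized"))) " (standardized)", "\n", sep = "")
  print(utils::head(unclass(x), 5L))
  invisible(x)
}
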