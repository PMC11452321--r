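## Change-from-baseline summaries per OABSS item and total, and the
## severity banding of total scores.

#' Change-from-baseline summary
#'
#' For every follow-up timepoint and every measure (Q1..Q4 and the total, or
#' total only for a totals-only cohort), computes each patient's change
#' `score(t) - score(T0)`, then the cohort mean and sample SD (divisor
#' n - 1). Improvement is a negative change. By linearity, the mean total
#' change equals the sum of the component mean changes exactly.
#'
#' @param cohort An `oab_cohort` with all five timepoints.
#' @return A `change_summary` data frame: `timepoint`, `measure`,
#'   `mean_change`, `sd_change`, `n`.
#' @export
change_summary <- function(cohort) {
  if (!inherits(cohort, "oab_cohort")) stop_format("expected an oab_cohort")
  df <- as.data.frame(cohort)
  followups <- setdiff(oabss_timepoints(), "T0")
  measures <- c(if (attr(cohort, "has_components")) .components(), "total")

  col_for <- function(tp, m) {
    if (m == "total") total_col(tp) else comp_col(tp, m)
  }
  out <- do.call(rbind, lapply(followups, function(tp) {
    do.call(rbind, lapply(measures, function(m) {
      change <- df[[col_for(tp, m)]] - df[[col_for("T0", m)]]
      data.frame(timepoint = tp,
                 measure = m,
                 mean_change = mean(change),
                 sd_change = stats::sd(change),
                 n = length(change),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("change_summary", "data.frame")
  out
}

#' @export
print.change_summary <- function(x, ...) {
  df <- as.data.frame(x)
  wide <- lapply(split(df, factor(df$timepoint, levels = unique(df$timepoint))),
                 function(d) {
                   stats::setNames(sprintf("%.4f ± %.4f",
                                           d$mean_change, d$sd_change),
                                   d$measure)
                 })
  cat("Change from baseline (mean ± SD), n = ", df$n[1L], "\n", sep = "")
  print(do.call(rbind, wide), quote = FALSE)
  invisible(x)
}

#' Export the change summary as CSV
#'
#' One row per timepoint, one `"mean ± sd"` cell per measure, mirroring the
#' usual cohort summary-table layout.
#'
#' @param summary A `change_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_change_summary_csv <- function(summary, path) {
  df <- as.data.frame(summary)
  tps <- unique(df$timepoint)
  measures <- unique(df$measure)
  wide <- data.frame(timepoint = tps, stringsAsFactors = FALSE)
  for (m in measures) {
    d <- df[df$measure == m, ]
    wide[[m]] <- sprintf("%.4f ± %.4f",
                         d$mean_change[match(tps, d$timepoint)],
                         d$sd_change[match(tps, d$timepoint)])
  }
  utils::write.csv(wide, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Severity band of a total OABSS
#'
#' The clinical bands as published: mild below 5, moderate 6-11, severe 12
#' and above. As printed, the bands leave a total of exactly 5 unassigned;
#' rather than silently binning it, such scores are labeled
#' `"unclassified"`.
#'
#' @param total Integer total score(s) in `[0, 15]`.
#' @return Character vector of `"mild"`, `"unclassified"`, `"moderate"`,
#'   `"severe"`.
#' @export
severity_band <- function(total) {
  if (any(!is.finite(total)) || any(total < 0 | total > 15)) {
    stop_validation("total score must lie in [0, 15]")
  }
  ifelse(total < 5, "mild",
         ifelse(total == 5, "unclassified",
                ifelse(total <= 11, "moderate", "severe")))
}
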