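## Shared internal helpers: timepoint/component vocabulary, seeded RNG scope,
## score discretization.

#' OABSS timepoint labels
#'
#' The five assessment timepoints: baseline and 6, 12, 18, 24 months.
#'
#' @return Character vector `c("T0","T6","T12","T18","T24")`.
#' @export
oabss_timepoints <- function() c("T0", "T6", "T12", "T18", "T24")

#' OABSS component labels and score bounds
#'
#' The four questionnaire items: Q1 daytime frequency (0-2), Q2 nighttime
#' frequency (0-3), Q3 urgency (0-5), Q4 urgency incontinence (0-5).
#' The total score is their sum (0-15).
#'
#' @return Named integer vector of per-component maxima.
#' @export
oabss_component_max <- function() c(Q1 = 2L, Q2 = 3L, Q3 = 5L, Q4 = 5L)

.components <- function() c("Q1", "Q2", "Q3", "Q4")

## Column naming for the CSV dialects: "T6-Q3", "T6-OABSS".
comp_col <- function(tp, comp) paste0(tp, "-", comp)
total_col <- function(tp) paste0(tp, "-OABSS")

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Half-away-from-zero rounding (base round() rounds half to even, which
## would bias integer scores generated around x.5 means).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(...) {
  stop(structure(
    class = c("oabnet_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("oabnet_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_validation <- function(...) {
  stop(structure(
    class = c("oabnet_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
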