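## Per-timepoint patient similarity graphs: nodes are patients, edges are
## Pearson correlations above a threshold, edge length = (1/r - 1) * 1000.

#' Correlation-to-length transform for network edges
#'
#' Converts a positive Pearson correlation into an edge length,
#' `(1/r - 1) * 1000`: perfectly correlated patients sit at length 0 and
#' length grows without bound as r approaches 0. Strictly decreasing in r.
#' Nonpositive correlations have no defined length — such pairs are simply
#' not edges.
#'
#' @param r Correlation(s) in `(0, 1]`.
#' @return Nonnegative length(s), unitless.
#' @export
edge_length <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("edge_length is defined for r in (0, 1] only")
  }
  (1 / r - 1) * 1000
}

#' Pearson similarity between two patients' score vectors
#'
#' @param a,b Numeric score vectors of equal length >= 2.
#' @return The Pearson correlation in `[-1, 1]`, or `NA` with a warning when
#'   either vector is constant (correlation undefined; such pairs are
#'   excluded from graphs).
#' @export
patient_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("score vectors must have equal length >= 2")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant score vector: correlation undefined, pair excluded")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Build the patient similarity graph at one timepoint
#'
#' Nodes are patients; an edge joins two patients whenever the Pearson
#' correlation of their score vectors exceeds `r_min` (strictly — exact ties
#' at the threshold are excluded for determinism). Edge attributes are the
#' correlation `r` and the length `(1/r - 1) * 1000`. Negative, zero and
#' undefined correlations never form edges.
#'
#' Two similarity bases are supported, because a per-timepoint graph built
#' from whole-trajectory correlations would be identical at every timepoint:
#' \describe{
#'   \item{`components_at_t`}{correlate the two patients' four item scores
#'     (Q1..Q4) at that timepoint — the default, giving genuinely
#'     time-varying graphs. Requires the component dialect.}
#'   \item{`trajectory_up_to_t`}{correlate total-score trajectories over all
#'     timepoints up to and including `timepoint`. At T0 a single total is
#'     not a vector, so the graph falls back to `components_at_t` with a
#'     warning.}
#' }
#'
#' @param cohort An `oab_cohort`.
#' @param timepoint One of `"T0","T6","T12","T18","T24"`.
#' @param mode `"components_at_t"` (default) or `"trajectory_up_to_t"`.
#' @param r_min Edge inclusion threshold in `[0, 1)` (default 0.7).
#' @param clusters Optional cluster labels stored as a node attribute,
#'   matched by patient id name or by position.
#' @return A `patient_graph`: list with the `igraph` graph and the
#'   `timepoint`, `mode`, `r_min` and `n_excluded_undefined` metadata.
#' @export
build_graph <- function(cohort, timepoint,
                        mode = c("components_at_t", "trajectory_up_to_t"),
                        r_min = 0.7, clusters = NULL) {
  mode <- match.arg(mode)
  if (!timepoint %in% oabss_timepoints()) {
    stop_config("unknown timepoint: ", timepoint)
  }
  if (!is.numeric(r_min) || r_min < 0 || r_min >= 1) {
    stop_config("r_min must lie in [0, 1)")
  }

  used_mode <- mode
  if (mode == "trajectory_up_to_t" && timepoint == "T0") {
    warning("trajectory_up_to_t needs >= 2 timepoints; using components_at_t at T0")
    used_mode <- "components_at_t"
  }
  if (used_mode == "components_at_t" && !attr(cohort, "has_components")) {
    stop_format("mode components_at_t requires the component dialect, ",
                "but this cohort has totals only")
  }

  df <- as.data.frame(cohort)
  if (used_mode == "components_at_t") {
    feat <- as.matrix(df[, comp_col(timepoint, .components())])
  } else {
    tps <- oabss_timepoints()
    upto <- tps[seq_len(match(timepoint, tps))]
    feat <- as.matrix(df[, vapply(upto, total_col, "")])
  }
  rownames(feat) <- cohort$patient_id

  C <- suppressWarnings(stats::cor(t(feat)))
  n <- nrow(feat)
  constant <- apply(feat, 1L, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    message(sum(constant), " patient(s) with constant score vectors at ",
            timepoint, ": their pairs carry undefined correlations and are excluded")
  }

  idx <- which(upper.tri(C) & !is.na(C) & C > r_min, arr.ind = TRUE)
  edges <- data.frame(
    from = cohort$patient_id[idx[, 1L]],
    to = cohort$patient_id[idx[, 2L]],
    r = C[idx],
    stringsAsFactors = FALSE
  )
  edges$length <- if (nrow(edges) > 0L) edge_length(edges$r) else numeric(0)

  vertices <- data.frame(name = cohort$patient_id, stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    vertices$cluster <- if (!is.null(names(clusters))) {
      as.integer(unname(clusters[vertices$name]))
    } else {
      as.integer(unname(clusters))
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g,
                 timepoint = timepoint,
                 mode = used_mode,
                 r_min = r_min,
                 n_excluded_undefined = sum(is.na(C[upper.tri(C)]))),
            class = "patient_graph")
}

#' Build the similarity graph at every timepoint
#'
#' @inheritParams build_graph
#' @return Named list of `patient_graph`s, one per timepoint, sharing the
#'   cohort's node set.
#' @export
build_graphs <- function(cohort, mode = c("components_at_t", "trajectory_up_to_t"),
                         r_min = 0.7, clusters = NULL) {
  mode <- match.arg(mode)
  tps <- oabss_timepoints()
  stats::setNames(lapply(tps, function(tp) {
    build_graph(cohort, tp, mode = mode, r_min = r_min, clusters = clusters)
  }), tps)
}

#' Binary adjacency matrix of a patient graph
#'
#' @param pg A `patient_graph`.
#' @return Symmetric 0/1 matrix with zero diagonal, patients as dimnames.
#' @export
adjacency_matrix <- function(pg) {
  A <- as.matrix(igraph::as_adjacency_matrix(pg$graph, sparse = FALSE))
  storage.mode(A) <- "double"
  A
}

#' @export
print.patient_graph <- function(x, ...) {
  cat("patient graph at ", x$timepoint, " (mode ", x$mode,
      ", r_min ", x$r_min, "): ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  invisible(x)
}

#' Export a patient graph
#'
#' `write_graphml()` writes GraphML with node attributes (`name`, `cluster`
#' when present) and edge attributes (`r`, `length`); `write_edges_csv()`
#' writes the edge list `(u, v, r, length)`.
#'
#' @param pg A `patient_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(pg, path) {
  igraph::write_graph(pg$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edges_csv <- function(pg, path) {
  e <- igraph::as_data_frame(pg$graph, what = "edges")
  names(e)[1:2] <- c("u", "v")
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}
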