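## Per-cluster network statistics over time: average degree centrality,
## edge density, and the adjacency/Laplacian/eigenvector-centrality algebra.

as_igraph <- function(x) {
  if (inherits(x, "patient_graph")) return(x$graph)
  if (igraph::is_igraph(x)) return(x)
  stop_format("expected a patient_graph or igraph object")
}

resolve_members <- function(g, members) {
  nodes <- igraph::V(g)$name
  if (is.character(members)) {
    bad <- setdiff(members, nodes)
    if (length(bad) > 0L) stop("unknown node(s): ", paste(bad, collapse = ", "))
    members
  } else {
    nodes[members]
  }
}

#' Average degree centrality of a cluster
#'
#' The mean over cluster members of `deg(v) / (|V| - 1)`. The degree counts
#' every incident edge, within- and between-cluster alike, so the measure
#' reflects how connected the cluster's patients are to the whole network.
#'
#' @param graph A `patient_graph` or igraph graph with at least 2 nodes.
#' @param members Non-empty set of node names (or indices).
#' @return A value in `[0, 1]`.
#' @export
avg_degree_centrality <- function(graph, members) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2L) stop("average degree centrality needs at least 2 nodes")
  members <- resolve_members(g, members)
  if (length(members) == 0L) stop("cluster members must be non-empty")
  deg <- igraph::degree(g)
  mean(deg[members] / (n - 1))
}

#' Edge density of a cluster's induced subgraph
#'
#' Edges among the members divided by `|C| (|C| - 1) / 2`. Unlike
#' [avg_degree_centrality()], between-cluster edges are ignored. Clusters of
#' size 0 or 1 have no possible edges and return 0.
#'
#' @inheritParams avg_degree_centrality
#' @return A value in `[0, 1]`.
#' @export
edge_density <- function(graph, members) {
  g <- as_igraph(graph)
  members <- resolve_members(g, members)
  m <- length(members)
  possible <- m * (m - 1) / 2
  if (possible <= 0) return(0)
  sub <- igraph::induced_subgraph(g, members)
  igraph::ecount(sub) / possible
}

#' Per-cluster network statistics across all timepoints
#'
#' Evaluates [avg_degree_centrality()] and [edge_density()] for every
#' (cluster, timepoint) pair over a set of per-timepoint graphs sharing one
#' node set — the dynamic-network trajectory.
#'
#' @param graphs Named list of `patient_graph`s (one per timepoint) on the
#'   same node set, e.g. from [build_graphs()].
#' @param clusters A `cluster_model` or a named 0-based label vector
#'   covering every node.
#' @return A `trajectory_metrics` data frame: `timepoint`, `cluster`,
#'   `avg_degree_centrality`, `edge_density`, plus the `r_min` and `mode`
#'   each graph was built with.
#' @export
centrality_trajectory <- function(graphs, clusters) {
  labels <- if (inherits(clusters, "cluster_model")) clusters$labels else clusters
  if (is.null(names(labels))) stop_format("cluster labels must be named by patient id")

  node_sets <- lapply(graphs, function(pg) sort(igraph::V(as_igraph(pg))$name))
  for (i in seq_along(node_sets)) {
    if (!identical(node_sets[[i]], node_sets[[1L]])) {
      stop_format("graphs must share one node set (mismatch at ",
                  names(graphs)[i], ")")
    }
  }
  if (!setequal(names(labels), node_sets[[1L]])) {
    stop_format("cluster labels must cover exactly the graph's nodes")
  }

  out <- do.call(rbind, lapply(names(graphs), function(tp) {
    pg <- graphs[[tp]]
    do.call(rbind, lapply(sort(unique(labels)), function(cl) {
      members <- names(labels)[labels == cl]
      data.frame(
        timepoint = tp,
        cluster = cl,
        avg_degree_centrality = avg_degree_centrality(pg, members),
        edge_density = edge_density(pg, members),
        r_min = if (inherits(pg, "patient_graph")) pg$r_min else NA_real_,
        mode = if (inherits(pg, "patient_graph")) pg$mode else NA_character_,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("trajectory_metrics", "data.frame")
  out
}

#' Adjacency, degree and Laplacian matrices of a graph
#'
#' Returns the binary adjacency matrix A, the diagonal degree matrix D and
#' the graph Laplacian L = D - A (rows sum to zero; positive semi-definite).
#'
#' @param graph A `patient_graph` or igraph graph.
#' @return List with elements `A`, `D`, `L`.
#' @export
adjacency_and_laplacian <- function(graph) {
  g <- as_igraph(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(A) <- "double"
  D <- diag(rowSums(A), nrow = nrow(A))
  dimnames(D) <- dimnames(A)
  list(A = A, D = D, L = D - A)
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of the adjacency matrix — node scores
#' satisfying `A x = lambda x` with `lambda` the largest eigenvalue — by
#' power iteration on `A + I` (the shift leaves eigenvectors unchanged while
#' preventing oscillation on bipartite graphs). Defined on the largest
#' connected component; nodes outside it score 0 (noted via a message).
#' Scores are nonnegative and L2-normalized over the component.
#'
#' @param graph A non-empty `patient_graph` or igraph graph.
#' @param tol Convergence tolerance on the iterate (default 1e-10).
#' @param max_iter Iteration cap (default 1000); non-convergence is an error
#'   reporting the iteration count.
#' @return Named numeric vector of per-node scores with attribute
#'   `eigenvalue`.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 1000L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph must be non-empty")
  nodes <- igraph::V(g)$name
  scores <- stats::setNames(numeric(n), nodes)

  comps <- igraph::components(g)
  if (comps$no > 1L) {
    message("graph has ", comps$no,
            " components; centrality computed on the largest, zeros elsewhere")
  }
  main <- which(comps$membership == which.max(comps$csize))
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, main), sparse = FALSE))
  storage.mode(A) <- "double"
  m <- nrow(A)
  if (sum(A) == 0) {
    ## largest component is a single isolated node: no edges, score 0
    attr(scores, "eigenvalue") <- 0
    return(scores)
  }

  x <- rep(1 / sqrt(m), m)
  M <- A + diag(m)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- drop(M %*% x)
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    stop("power iteration did not converge within ", max_iter, " iterations")
  }
  lambda <- drop(crossprod(x, A %*% x))
  scores[nodes[main]] <- x
  attr(scores, "eigenvalue") <- lambda
  scores
}

#' Export the trajectory metrics as CSV
#'
#' @param metrics A `trajectory_metrics` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' Line plot of per-cluster network statistics over time
#'
#' @param metrics A `trajectory_metrics` data frame.
#' @param metric Which column to plot: `"avg_degree_centrality"` (default)
#'   or `"edge_density"`.
#' @return A ggplot object, one series per cluster.
#' @export
plot_trajectory <- function(metrics, metric = c("avg_degree_centrality",
                                                "edge_density")) {
  metric <- match.arg(metric)
  df <- as.data.frame(metrics)
  df$timepoint <- factor(df$timepoint, levels = oabss_timepoints())
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data[[metric]],
                                   colour = .data$cluster,
                                   group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Timepoint",
                  y = gsub("_", " ", metric),
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}
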