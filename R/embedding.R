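## 2-component PCA embedding of the score matrix (cluster visualization).

#' Two-component PCA
#'
#' Projects the (typically standardized) score matrix on the top two
#' principal components of its covariance matrix. The eigenvector sign is
#' fixed deterministically: each component's largest-magnitude loading is
#' made positive, so embeddings are stable across runs and platforms.
#'
#' @param matrix A `score_matrix` with at least 3 rows and 2 columns.
#' @return An `embedding2d` list: `coords` (n x 2, rows named by patient),
#'   `explained_variance_ratio` (length 2, non-increasing),
#'   `loadings` (timepoints x 2, orthonormal columns) and `all_variances`
#'   (every component's variance, for conservation checks). Rank-deficient
#'   input yields a zero-variance second component with a warning.
#' @export
pca_2d <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) < 3L || ncol(m) < 2L) {
    stop_format("PCA needs at least 3 rows and 2 columns")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  vars <- p$sdev^2
  if (vars[1L] <= 0) {
    warning("input has zero total variance; embedding is degenerate")
  } else if (length(vars) < 2L || vars[2L] / vars[1L] < 1e-12) {
    warning("input is rank-deficient; second component has ~zero variance")
  }
  evr <- vars / sum(vars)

  coords <- p$x[, 1:2, drop = FALSE]
  loadings <- p$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- colnames(loadings) <- c("PC1", "PC2")
  rownames(coords) <- rownames(m)

  structure(list(coords = coords,
                 explained_variance_ratio = evr[1:2],
                 loadings = loadings,
                 all_variances = vars),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat("2-component PCA embedding: ", nrow(x$coords), " points\n",
      "  explained variance ratio: ",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Export an embedding as CSV
#'
#' @param embedding An `embedding2d`.
#' @param path Output CSV path (`patient_id, pc1, pc2[, cluster]`).
#' @param clusters Optional labels (e.g. `model$labels`) matched by name or
#'   position.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(embedding, path, clusters = NULL) {
  df <- data.frame(patient_id = rownames(embedding$coords),
                   pc1 = embedding$coords[, 1L],
                   pc2 = embedding$coords[, 2L])
  if (!is.null(clusters)) {
    df$cluster <- if (!is.null(names(clusters))) {
      unname(clusters[df$patient_id])
    } else {
      unname(clusters)
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of the PCA embedding colored by cluster
#'
#' @param embedding An `embedding2d`.
#' @param clusters Optional cluster labels, matched by name or position.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, clusters = NULL) {
  df <- data.frame(pc1 = embedding$coords[, 1L],
                   pc2 = embedding$coords[, 2L])
  evr <- embedding$explained_variance_ratio
  if (!is.null(clusters)) {
    lab <- if (!is.null(names(clusters))) {
      clusters[rownames(embedding$coords)]
    } else {
      clusters
    }
    df$cluster <- factor(unname(lab))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                          colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2))
  }
  p + ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("Principal component 1 (%.1f%%)", 100 * evr[1L]),
      y = sprintf("Principal component 2 (%.1f%%)", 100 * evr[2L]),
      colour = "Cluster") +
    ggplot2::theme_minimal()
}
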