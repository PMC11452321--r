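## Cluster pipeline: Euclidean distances, Ward linkage, elbow selection of k,
## K-means assignment with canonical size-ordered labels.

#' Pairwise Euclidean distance matrix
#'
#' @param matrix A `score_matrix` (or numeric matrix) with at least 2 rows.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
distance_matrix <- function(matrix) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) < 2L) stop_format("need a matrix with >= 2 rows")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`, which applies Ward's
#' criterion correctly to unsquared distances). Merge heights are
#' non-decreasing.
#'
#' @param D Distance matrix from [distance_matrix()] (or a `dist`).
#' @return An `hclust` merge tree.
#' @export
ward_linkage <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  stats::hclust(d, method = "ward.D2")
}

#' Cut a Ward tree into k clusters
#'
#' @param linkage An `hclust` from [ward_linkage()].
#' @param k Number of clusters.
#' @return Integer vector of 0-based labels, canonically ordered by
#'   descending cluster size (ties broken by lowest member index).
#' @export
ward_cut <- function(linkage, k) {
  canonical_relabel(stats::cutree(linkage, k = k))
}

## Relabel arbitrary cluster labels to 0..k-1 by descending size, ties by
## first member index. K-means labels are permutation-arbitrary; reports
## need stable identities.
canonical_relabel <- function(lab) {
  u <- unique(lab)
  sizes <- vapply(u, function(l) sum(lab == l), 0L)
  first <- vapply(u, function(l) which(lab == l)[1L], 0L)
  ord <- order(-sizes, first)
  new <- integer(length(lab))
  for (i in seq_along(ord)) new[lab == u[ord[i]]] <- i - 1L
  new
}

## k-means++ seeding: first center uniform, later centers with probability
## proportional to squared distance from the chosen set.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(j)])
      idx[j + 1L] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j + 1L], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Fit K-means with k-means++ restarts and canonical labels
#'
#' Lloyd's algorithm (via [stats::kmeans()]) from `n_restarts` k-means++
#' seedings, keeping the solution with the lowest within-cluster sum of
#' squares J. Labels are relabeled canonically: clusters ordered by
#' descending size, ties by lowest member index. Deterministic given `seed`.
#'
#' @param matrix A `score_matrix` (typically standardized).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer RNG seed for the seeding draws (default 42).
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @param extra_centers Optional matrix of additional initial centers tried
#'   as one more restart (used internally for warm starts along the elbow
#'   curve).
#' @return A `cluster_model` list: `k`, `labels` (named 0-based integers),
#'   `centroids` (k x timepoints, canonical order), `sse` (the objective J),
#'   `seed`.
#' @export
kmeans_fit <- function(matrix, k, seed = 42L, n_restarts = 10L,
                       extra_centers = NULL) {
  x <- unclass(matrix)
  if (!is.matrix(x)) x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L || k > n) stop_config("k must be in [1, n] (k=", k, ", n=", n, ")")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop_config("k=", k, " exceeds the number of distinct rows (", n_distinct, ")")
  }

  run_one <- function(centers) {
    tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 200L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
  }

  best <- NULL
  with_seed(seed, {
    starts <- lapply(seq_len(n_restarts), function(i) kmeanspp_centers(x, k))
    if (!is.null(extra_centers)) starts <- c(starts, list(extra_centers))
    for (centers in starts) {
      fit <- run_one(centers)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) stop("K-means failed for every restart (k=", k, ")")

  lab <- canonical_relabel(best$cluster)
  centroids <- matrix(NA_real_, nrow = k, ncol = ncol(x),
                      dimnames = list(NULL, colnames(x)))
  for (j in seq_len(k)) {
    centroids[j, ] <- colMeans(x[lab == (j - 1L), , drop = FALSE])
  }
  labels <- stats::setNames(lab, rownames(x))
  structure(list(k = as.integer(k),
                 labels = labels,
                 centroids = centroids,
                 sse = best$tot.withinss,
                 seed = as.integer(seed)),
            class = "cluster_model")
}

#' Elbow selection of the cluster count
#'
#' Fits K-means for every k in `k_range` (fixed seed, k-means++ restarts
#' plus a warm start splitting the previous solution, which keeps the SSE
#' curve non-increasing) and picks the elbow: the interior k maximizing the
#' discrete second difference `SSE(k-1) - 2 SSE(k) + SSE(k+1)`, i.e. where
#' the decrease in within-cluster SSE slows most sharply.
#'
#' @param matrix A `score_matrix`.
#' @param k_range Consecutive integers within `[1, n-1]`, length >= 3
#'   (default `1:8`).
#' @param seed Integer RNG seed (default 42).
#' @param n_restarts Restarts per k (default 10).
#' @return List with `k` (the elbow), `sse_curve` (data frame `k`, `sse`)
#'   and `models` (the fitted `cluster_model` per k).
#' @export
elbow_select <- function(matrix, k_range = 1:8, seed = 42L, n_restarts = 10L) {
  x <- unclass(matrix)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) {
    stop_config("k_range must contain at least 3 candidate values")
  }
  if (any(diff(k_range) != 1L)) {
    stop_config("k_range must be consecutive integers")
  }
  if (k_range[1L] < 1L || k_range[length(k_range)] > nrow(x) - 1L) {
    stop_config("k_range must lie within [1, n-1]")
  }

  models <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    warm <- NULL
    if (!is.null(prev)) {
      ## split candidate: previous centroids plus the worst-fit point
      d2 <- rowSums((x - prev$centroids[prev$labels + 1L, , drop = FALSE])^2)
      warm <- rbind(prev$centroids, x[which.max(d2), ])
      if (anyDuplicated(warm)) warm <- NULL
    }
    models[[i]] <- kmeans_fit(matrix, k_range[i], seed = seed,
                              n_restarts = n_restarts, extra_centers = warm)
    prev <- models[[i]]
  }
  sse <- vapply(models, function(m) m$sse, 0)
  curve <- data.frame(k = k_range, sse = sse)

  if (length(k_range) >= 3L) {
    interior <- 2:(length(k_range) - 1L)
    d2 <- sse[interior - 1L] - 2 * sse[interior] + sse[interior + 1L]
    k_hat <- k_range[interior[which.max(d2)]]
  }
  list(k = k_hat, sse_curve = curve, models = models)
}

#' Run the full cluster stage
#'
#' Distance matrix, Ward linkage, elbow selection (unless `k` is given) and
#' the final K-means assignment, bundled into one model.
#'
#' @param matrix A `score_matrix` (standardized unless you are reproducing
#'   the raw-feature variant).
#' @param k Cluster count; `NULL` (default) selects it by [elbow_select()].
#' @param k_range Candidate range for the elbow (default `1:8`).
#' @param seed Integer RNG seed (default 42).
#' @param n_restarts K-means restarts (default 10).
#' @return A `cluster_model` with additional fields `sse_curve`, `linkage`
#'   (the Ward tree) and `ward_labels` (canonical labels from cutting the
#'   Ward tree at the same k, for comparison with the K-means labels).
#' @export
fit_clusters <- function(matrix, k = NULL, k_range = 1:8, seed = 42L,
                         n_restarts = 10L) {
  D <- distance_matrix(matrix)
  linkage <- ward_linkage(D)
  sse_curve <- NULL
  if (is.null(k)) {
    sel <- elbow_select(matrix, k_range = k_range, seed = seed,
                        n_restarts = n_restarts)
    k <- sel$k
    sse_curve <- sel$sse_curve
  }
  model <- kmeans_fit(matrix, k, seed = seed, n_restarts = n_restarts)
  model$sse_curve <- sse_curve
  model$linkage <- linkage
  model$ward_labels <- stats::setNames(ward_cut(linkage, k), rownames(matrix))
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  sizes <- table(x$labels)
  cat("K-means cluster model: k = ", x$k, ", J = ", format(x$sse, digits = 6),
      "\n  sizes: ", paste(sprintf("cluster %s: %d", names(sizes), sizes),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export cluster assignments and the SSE curve as CSV
#'
#' @param model A `cluster_model` from [fit_clusters()] or [kmeans_fit()].
#' @param assignments_path CSV path for `(patient_id, cluster)`.
#' @param sse_path Optional CSV path for `(k, sse)`; skipped when the model
#'   carries no elbow curve.
#' @return `assignments_path`, invisibly.
#' @export
write_cluster_csv <- function(model, assignments_path, sse_path = NULL) {
  utils::write.csv(data.frame(patient_id = names(model$labels),
                              cluster = unname(model$labels)),
                   assignments_path, row.names = FALSE)
  if (!is.null(sse_path) && !is.null(model$sse_curve)) {
    utils::write.csv(model$sse_curve, sse_path, row.names = FALSE)
  }
  invisible(assignments_path)
}
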