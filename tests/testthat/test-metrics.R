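named_graph <- function(A, ids = NULL) {
  n <- nrow(A)
  dimnames(A) <- list(ids %||% paste0("P", seq_len(n)),
                      ids %||% paste0("P", seq_len(n)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

test_that("average degree centrality matches hand counts", {
  ## path a-b-c-d, cluster {a,b}: (1/3 + 2/3)/2 = 0.5
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  A <- A + t(A)
  g <- named_graph(A, c("a", "b", "c", "d"))
  expect_equal(avg_degree_centrality(g, c("a", "b")), 0.5)

  ## complete graph: every cluster scores 1
  K5 <- named_graph(matrix(1, 5, 5) - diag(5))
  expect_equal(avg_degree_centrality(K5, c("P1", "P3")), 1)
  expect_equal(avg_degree_centrality(K5, paste0("P", 1:5)), 1)

  ## empty graph: 0
  empty <- named_graph(matrix(0, 4, 4))
  expect_equal(avg_degree_centrality(empty, c("P1", "P2")), 0)

  expect_error(avg_degree_centrality(g, character(0)), "non-empty")
  expect_error(avg_degree_centrality(named_graph(matrix(0, 1, 1)), "P1"),
               "at least 2")
})

test_that("edge density covers triangles, gaps and singletons", {
  tri <- named_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(edge_density(tri, paste0("P", 1:3)), 1)
  expect_equal(edge_density(tri, "P1"), 0)  # singleton: no possible edges

  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 3] <- 1
  A <- A + t(A)
  expect_equal(edge_density(named_graph(A), paste0("P", 1:3)), 2 / 3)
})

test_that("metrics match brute-force counting oracles on random graphs", {
  set.seed(50)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < runif(1, 0.2, 0.8))
    A <- A + t(A)
    g <- named_graph(A)
    members <- sample(n, sample(2:n, 1))
    ids <- paste0("P", members)
    expect_equal(avg_degree_centrality(g, ids), brute_adc(A, members),
                 tolerance = 1e-12)
    expect_equal(edge_density(g, ids), brute_density(A, members),
                 tolerance = 1e-12)
    mats <- adjacency_and_laplacian(g)
    expect_equal(unname(mats$A), A)
    expect_equal(unname(mats$L), brute_laplacian(A))
  }
})

test_that("whole-network average centrality equals global density", {
  set.seed(51)
  for (i in 1:10) {
    g <- random_igraph(sample(5:12, 1), runif(1, 0.2, 0.8))
    n <- igraph::vcount(g)
    adc <- avg_degree_centrality(g, igraph::V(g)$name)
    expect_equal(adc, 2 * igraph::ecount(g) / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases any cluster's centrality", {
  set.seed(52)
  for (i in 1:10) {
    n <- 8
    g <- random_igraph(n, 0.4)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    absent <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
    g2 <- named_graph(A2)
    clusters <- split(paste0("P", 1:n), rep(1:2, each = 4))
    for (cl in clusters) {
      expect_gte(avg_degree_centrality(g2, cl), avg_degree_centrality(g, cl))
    }
  }
})

test_that("the Laplacian has the K3 spectrum and component-count kernel", {
  tri <- named_graph(matrix(1, 3, 3) - diag(3))
  mats <- adjacency_and_laplacian(tri)
  expect_equal(unname(diag(mats$L)), c(2, 2, 2))
  expect_equal(sort(eigen(mats$L, symmetric = TRUE)$values), c(0, 3, 3),
               tolerance = 1e-10)

  empty <- named_graph(matrix(0, 3, 3))
  expect_equal(unname(adjacency_and_laplacian(empty)$L), matrix(0, 3, 3))

  set.seed(53)
  for (i in 1:10) {
    g <- random_igraph(sample(4:10, 1), runif(1, 0.15, 0.6))
    mats <- adjacency_and_laplacian(g)
    expect_equal(unname(rowSums(mats$L)), rep(0, nrow(mats$L)))
    ev <- eigen(mats$L, symmetric = TRUE)$values
    expect_true(all(ev > -1e-10))  # positive semi-definite
    n_zero <- sum(abs(ev) < 1e-8)
    expect_equal(n_zero, igraph::components(g)$no)
  }
})

test_that("eigenvector centrality is exact on symmetric graphs", {
  K4 <- named_graph(matrix(1, 4, 4) - diag(4))
  x <- eigenvector_centrality(K4)
  expect_equal(as.numeric(x), rep(0.5, 4), tolerance = 1e-9)

  ## star: center strictly dominates the leaves
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- A[2:5, 1] <- 1
  star <- named_graph(A)
  xs <- eigenvector_centrality(star)
  expect_true(all(xs["P1"] > xs[paste0("P", 2:5)]))
})

test_that("eigenvector centrality matches the dense eigen oracle", {
  set.seed(54)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < 0.45)
    A <- A + t(A)
    if (sum(A) == 0) next
    g <- named_graph(A)
    x <- suppressMessages(eigenvector_centrality(g))
    expect_equal(as.numeric(x), brute_eigcent(A), tolerance = 1e-7)
    ## the defining equation A x = lambda x on the support
    lambda <- attr(x, "eigenvalue")
    expect_lt(max(abs(A %*% x - lambda * x)), 1e-8)
    expect_true(all(x >= 0))
  }
})

test_that("trajectories are flat when all five graphs are identical", {
  base <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(0, 1, 5, 2),
                c(2, 0, 1, 3), c(1, 3, 2, 0))
  co <- make_cohort(base[, rep(1:4, times = 5)])  # constant over time
  labels <- stats::setNames(c(0L, 0L, 0L, 1L, 1L), co$patient_id)
  graphs <- build_graphs(co, r_min = 0.3, clusters = labels)
  tm <- centrality_trajectory(graphs, labels)
  for (cl in 0:1) {
    vals <- tm$avg_degree_centrality[tm$cluster == cl]
    expect_equal(length(unique(round(vals, 12))), 1L)
  }
})

## scenario: cluster X's members progressively align on one symptom profile
## after treatment, so X's within-cluster similarity (and hence centrality)
## rises from T6 onward
aligning_cohort <- function() {
  aligned <- c(1, 2, 3, 4)
  bases <- list(c(2, 2, 5, 0), c(2, 0, 1, 0), c(2, 3, 1, 3),
                c(0, 3, 1, 0), c(2, 2, 1, 0))
  outsiders <- list(c(2, 0, 0, 5), c(2, 1, 0, 1), c(2, 0, 3, 2), c(2, 0, 0, 5))
  n_aligned <- c(1, 2, 3, 4, 5)  # per timepoint
  rows <- matrix(0L, 9, 20)
  for (ti in 1:5) {
    for (p in 1:5) {
      prof <- if (p <= n_aligned[ti]) aligned else bases[[p]]
      rows[p, (ti - 1) * 4 + 1:4] <- prof
    }
    for (o in 1:4) {
      rows[5 + o, (ti - 1) * 4 + 1:4] <- outsiders[[o]]
    }
  }
  make_cohort(rows)
}

test_that("a cluster that aligns after T6 gains centrality monotonically", {
  co <- aligning_cohort()
  labels <- stats::setNames(c(rep(0L, 5), rep(1L, 4)), co$patient_id)
  graphs <- build_graphs(co, r_min = 0.7, clusters = labels)
  tm <- centrality_trajectory(graphs, labels)
  x <- tm$avg_degree_centrality[tm$cluster == 0L]
  expect_true(all(diff(x[match(c("T6", "T12", "T18", "T24"),
                               tm$timepoint[tm$cluster == 0L])]) > 0))
  ## the outsider cluster stays flat
  y <- tm$edge_density[tm$cluster == 1L]
  expect_equal(length(unique(round(y, 12))), 1L)
})

test_that("trajectory values equal per-node degree counting on every graph", {
  co <- suppressMessages(generate_cohort(preset_config("study_sizes", seed = 20)))
  sm <- standardize_scores(extract_totals(co))
  model <- kmeans_fit(sm, 3, seed = 42)
  graphs <- suppressMessages(build_graphs(co, r_min = 0.7, clusters = model$labels))
  tm <- centrality_trajectory(graphs, model)
  for (row in sample(nrow(tm), 6)) {
    pg <- graphs[[tm$timepoint[row]]]
    A <- adjacency_matrix(pg)
    members <- match(names(model$labels)[model$labels == tm$cluster[row]],
                     rownames(A))
    expect_equal(tm$avg_degree_centrality[row], brute_adc(A, members),
                 tolerance = 1e-12)
    expect_equal(tm$edge_density[row], brute_density(A, members),
                 tolerance = 1e-12)
  }
})

test_that("mismatched node sets across timepoints are an error", {
  base <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(0, 1, 5, 2))
  co <- make_cohort(base[, rep(1:4, 5)])
  co2 <- make_cohort(base[1:2, rep(1:4, 5)])
  g1 <- build_graph(co, "T0", r_min = 0.3)
  g2 <- build_graph(co2, "T6", r_min = 0.3)
  labels <- stats::setNames(c(0L, 0L, 1L), co$patient_id)
  expect_error(centrality_trajectory(list(T0 = g1, T6 = g2), labels),
               "node set")
})
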