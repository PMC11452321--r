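## Independent brute-force oracles and fixture builders shared by the suite.
## Oracles deliberately use element-wise loops / dense linear algebra, not
## the package's code paths.

brute_dist <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  D
}

brute_cor <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

## mean over members of deg/(n-1), counting all incident edges
brute_adc <- function(A, members) {
  n <- nrow(A)
  vals <- vapply(members, function(i) sum(A[i, ]) / (n - 1), 0)
  sum(vals) / length(vals)
}

brute_density <- function(A, members) {
  m <- length(members)
  if (m <= 1L) return(0)
  e <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      e <- e + A[members[i], members[j]]
    }
  }
  e / (m * (m - 1) / 2)
}

brute_laplacian <- function(A) {
  diag(rowSums(A)) - A
}

## leading eigenvector (nonnegative, L2-normalized) of the largest connected
## component via dense eigendecomposition; zeros elsewhere
brute_eigcent <- function(A) {
  n <- nrow(A)
  ## connected components by BFS
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      comp[s] <- cid
      while (length(queue) > 0L) {
        v <- queue[1L]
        queue <- queue[-1L]
        nb <- which(A[v, ] > 0 & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  main <- which(comp == which.max(tabulate(comp)))
  x <- rep(0, n)
  if (sum(A[main, main]) > 0) {
    e <- eigen(A[main, main, drop = FALSE], symmetric = TRUE)
    v <- e$vectors[, 1L]
    if (sum(v) < 0) v <- -v
    x[main] <- abs(v) / sqrt(sum(v^2))
  }
  x
}

## random undirected graph as a patient-graph-compatible igraph
random_igraph <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

## small component-dialect cohort from a patients x (5*4) integer matrix,
## columns grouped by timepoint
make_cohort <- function(score_rows, ids = NULL) {
  tps <- oabss_timepoints()
  comps <- c("Q1", "Q2", "Q3", "Q4")
  n <- nrow(score_rows)
  df <- data.frame(patient_id = ids %||% sprintf("P%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  k <- 0L
  for (tp in tps) {
    for (comp in comps) {
      k <- k + 1L
      df[[paste0(tp, "-", comp)]] <- score_rows[, k]
    }
  }
  cohort_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## a valid 3-patient fixture used across files
fixture_cohort3 <- function() {
  set.seed(99)
  m <- matrix(0L, nrow = 3, ncol = 20)
  for (j in 1:20) {
    comp <- ((j - 1) %% 4) + 1
    maxv <- c(2, 3, 5, 5)[comp]
    m[, j] <- sample(0:maxv, 3, replace = TRUE)
  }
  make_cohort(m)
}
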