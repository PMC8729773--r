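# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own code paths.

# --- beta-partition oracle: explicit set counting on presence/absence ---
oracle_decompose <- function(x, y) {
  sx <- which(x > 0); sy <- which(y > 0)
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  den <- a + b + cc
  c(similarity = a / den,
    replacement = 2 * min(b, cc) / den,
    richness_difference = abs(b - cc) / den)
}

# --- topology oracle: adjacency-matrix arithmetic ---
oracle_topology <- function(A) {
  N <- nrow(A)
  k <- rowSums(A)
  E <- sum(A) / 2
  clust <- vapply(seq_len(N), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  # Floyd-Warshall shortest paths
  D <- ifelse(A == 1, 1, Inf); diag(D) <- 0
  for (m in seq_len(N)) {
    D <- pmin(D, outer(D[, m], D[m, ], `+`))
  }
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  list(
    density = if (N < 2) 0 else 2 * E / (N * (N - 1)),
    avg_neighbors = if (N == 0) 0 else 2 * E / N,
    centralization = if (N < 3) 0 else sum(max(k) - k) / ((N - 1) * (N - 2)),
    heterogeneity = if (mean(k) == 0) 0 else sqrt(mean(k^2) - mean(k)^2) / mean(k),
    clustering = mean(clust),
    path_length = if (length(finite)) mean(finite) else NA_real_
  )
}

# --- robustness oracle: reachability recount after each removal ---
# connected pairs by boolean reachability (BFS from every node)
oracle_connected_pairs <- function(A) {
  N <- nrow(A)
  if (N == 0) return(0)
  seen <- rep(FALSE, N)
  total <- 0
  for (s in seq_len(N)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    while (length(frontier)) {
      nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE] == 1) > 0), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    seen[comp] <- TRUE
    total <- total + length(comp) * (length(comp) - 1) / 2
  }
  total
}

# loss curve given an explicit removal order of row/col names
oracle_loss_curve <- function(A, order_ids) {
  p0 <- oracle_connected_pairs(A)
  L <- numeric(length(order_ids) + 1)
  cur <- A
  for (m in seq_along(order_ids)) {
    keep <- setdiff(rownames(cur), order_ids[m])
    cur <- cur[keep, keep, drop = FALSE]
    L[m + 1] <- 1 - oracle_connected_pairs(cur) / p0
  }
  L
}

# --- fixture builders ---
random_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# small count table with named samples/OTUs
toy_table <- function(n = 6, p = 8, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("OTU_%02d", seq_len(p))))
  m
}
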