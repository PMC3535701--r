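# Independent brute-force oracles and small fixture builders shared across
# the test files. Every oracle is written from the defining formula, not
# from the implementation it checks.

# small ExpressionProfiles from a matrix (types default to "gene")
make_profiles <- function(values, types = NULL, labels = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("n%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(types))
    types <- stats::setNames(rep("gene", nrow(values)), rownames(values))
  if (is.null(labels))
    labels <- stats::setNames(rep(c("NM", "M"), length.out = ncol(values)),
                              colnames(values))
  expression_profiles(values, types, labels)
}

# mutual information by direct summation over a joint count table
oracle_mi_table <- function(counts, base = exp(1)) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]), base)
  mi
}

# CLR scores by explicit loops (sample SD over each row's off-diagonal)
oracle_clr <- function(mi) {
  n <- nrow(mi)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    off <- mi[i, -i]
    mu <- mean(off); sig <- sd(off)
    for (j in seq_len(n)) {
      if (i == j || sig == 0) next
      z[i, j] <- max(0, (mi[i, j] - mu) / sig)
    }
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  out
}

# hypergeometric upper tail P(X >= k) by exhaustive summation
oracle_hyper_tail <- function(n_universe, n_a, n_b, k) {
  total <- 0
  for (x in seq(k, min(n_a, n_b))) {
    total <- total + choose(n_b, x) * choose(n_universe - n_b, n_a - x)
  }
  total / choose(n_universe, n_a)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# all shortest directed paths between two nodes (tiny graphs only)
all_shortest_paths_brute <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in which(adj[u, ] == 1))
      if (dist[v] == Inf) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t])) return(list())
  grow <- function(path) {
    u <- path[length(path)]
    if (u == t) return(list(path))
    out <- list()
    for (v in which(adj[u, ] == 1))
      if (dist[v] == dist[u] + 1 && dist[t] >= dist[v])
        out <- c(out, grow(c(path, v)))
    out
  }
  Filter(function(p) p[length(p)] == t, grow(s))
}

# node and edge betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  node_b <- rep(0, n)
  edge_b <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_shortest_paths_brute(adj, s, t)
    if (!length(paths)) next
    np <- length(paths)
    for (p in paths) {
      if (length(p) > 2)
        for (v in p[-c(1, length(p))]) node_b[v] <- node_b[v] + 1 / np
      for (i in seq_len(length(p) - 1))
        edge_b[p[i], p[i + 1]] <- edge_b[p[i], p[i + 1]] + 1 / np
    }
  }
  list(node = node_b, edge = edge_b)
}

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

# best achievable Gini impurity decrease over all single splits
oracle_best_gini_decrease <- function(X, y) {
  n <- length(y)
  parent <- gini_impurity(y)
  best <- 0
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (cut in (v[-1] + v[-length(v)]) / 2) {
      left <- X[, j] < cut
      dec <- parent - (sum(left) / n) * gini_impurity(y[left]) -
        (sum(!left) / n) * gini_impurity(y[!left])
      best <- max(best, dec)
    }
  }
  best
}
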