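# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the chord criterion is the literal geometric
# transcription, and the path/betweenness oracles are Floyd-Warshall with
# path counting, not Dijkstra.

# Edge (i, j) iff every intermediate sample lies strictly below the straight
# chord from (i, x_i) to (j, x_j). 0-based indices, sorted by (i, j).
chord_edges <- function(x) {
  n <- length(x)
  from <- integer(0); to <- integer(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- TRUE
      if (j - i > 1) {
        k <- (i + 1):(j - 1)
        line <- x[i] + (x[j] - x[i]) * (k - i) / (j - i)
        ok <- all(x[k] < line)
      }
      if (ok) { from <- c(from, i - 1L); to <- c(to, j - 1L) }
    }
  }
  data.frame(i = from, j = to)
}

random_series <- function(kind, n, seed) {
  set.seed(seed)
  switch(kind,
         gaussian = rnorm(n),
         uniform = runif(n, -1, 1),
         ar1 = as.numeric(stats::filter(rnorm(n), 0.8,
                                        method = "recursive")),
         stop("unknown kind"))
}

# Undirected all-pairs shortest paths (weight = length) by Floyd-Warshall,
# with geodesic counting for betweenness.
fw_paths <- function(n, edges) {
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  diag(d) <- 0
  diag(sig) <- 1
  for (r in seq_len(nrow(edges))) {
    a <- edges$i[r] + 1L; b <- edges$j[r] + 1L
    w <- edges$weight[r]
    if (w < d[a, b]) { d[a, b] <- d[b, a] <- w; sig[a, b] <- sig[b, a] <- 1 }
  }
  for (k in seq_len(n)) {
    for (a in seq_len(n)) {
      if (a == k || !is.finite(d[a, k])) next
      for (b in seq_len(n)) {
        if (b == k || b == a || !is.finite(d[k, b])) next
        alt <- d[a, k] + d[k, b]
        if (alt < d[a, b] - 1e-12) {
          d[a, b] <- alt
          sig[a, b] <- sig[a, k] * sig[k, b]
        } else if (abs(alt - d[a, b]) <= 1e-12) {
          sig[a, b] <- sig[a, b] + sig[a, k] * sig[k, b]
        }
      }
    }
  }
  list(d = d, sigma = sig)
}

brute_global_efficiency <- function(n, edges) {
  d <- fw_paths(n, edges)$d
  off <- row(d) != col(d)
  sum(1 / d[off]) / (n * (n - 1))
}

brute_avg_path_length <- function(n, edges) {
  d <- fw_paths(n, edges)$d
  off <- row(d) != col(d)
  mean(d[off][is.finite(d[off])])
}

# Endpoint-excluded betweenness, normalised by (n-1)(n-2)/2, averaged.
brute_avg_betweenness <- function(n, edges) {
  fp <- fw_paths(n, edges)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(fp$d[s, t])) next
        if (abs(fp$d[s, v] + fp$d[v, t] - fp$d[s, t]) <= 1e-12)
          tot <- tot + fp$sigma[s, v] * fp$sigma[v, t] / fp$sigma[s, t]
      }
    }
    bc[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  mean(bc)
}

# Modularity objective evaluated by the textbook formula on a given
# membership vector (undirected weighted graph from a 0-based edge list).
brute_modularity <- function(n, edges, membership) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    a <- edges$i[r] + 1L; b <- edges$j[r] + 1L
    A[a, b] <- A[a, b] + edges$weight[r]
    A[b, a] <- A[b, a] + edges$weight[r]
  }
  k <- rowSums(A)
  two_m <- sum(k)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / two_m)[same]) / two_m
}

# O(m^2) Gini double loop, the literal formula.
brute_gini <- function(w) {
  n <- length(w)
  if (mean(w) == 0) return(0)
  sum(abs(outer(w, w, "-"))) / (2 * n^2 * mean(w))
}

# Exhaustive optimum of a subset fitness over all subsets of sizes in
# `sizes` from `n_features` features.
exhaustive_optimum <- function(fitness_fn, n_features = 15, sizes = 4:8) {
  best <- -Inf
  best_subset <- NULL
  for (s in sizes) {
    cols <- utils::combn(n_features, s)
    for (c in seq_len(ncol(cols))) {
      f <- fitness_fn(cols[, c])
      if (f > best) { best <- f; best_subset <- cols[, c] }
    }
  }
  list(subset = best_subset, fitness = best)
}

# Planted subset-selection problem. The per-feature epsilon penalty makes
# the optimum unique (good features plus the cheapest filler needed to
# reach the minimum subset size).
planted_fitness <- function(good = c(1, 7, 14)) {
  function(subset) {
    extras <- setdiff(subset, good)
    length(intersect(subset, good)) / length(good) -
      sum(0.05 + 0.001 * extras)
  }
}
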