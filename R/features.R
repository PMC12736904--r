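# Population moments of the edge-weight distribution; skewness and kurtosis
# of a zero-variance distribution are defined as 0 (not NaN).
weight_moments <- function(w) {
  n <- length(w)
  mu <- mean(w)
  v <- mean((w - mu)^2)
  s <- sqrt(v)
  list(mean = mu, var = v,
       skew = if (s > 0) mean((w - mu)^3) / s^3 else 0,
       kurt = if (s > 0) mean((w - mu)^4) / s^4 - 3 else 0)
}

# Gini of the edge weights, sum_{i,j} |w_i - w_j| / (2 n^2 mu), computed by
# the sorted-weights identity to stay O(n log n) in the edge count.
gini_index <- function(w) {
  n <- length(w)
  mu <- mean(w)
  if (n == 0 || mu == 0) return(0)
  ws <- sort(w)
  sum((2 * seq_len(n) - n - 1) * ws) / (n^2 * mu)
}

#' Weighted Angular Irregularity Index (WAII)
#'
#' Mean over nodes of the coefficient of variation (population standard
#' deviation over mean) of each node's outgoing edge weights. Nodes with
#' out-degree 0 or 1 contribute 0 — the spread of a single weight is
#' degenerate. WAII is the only feature that keeps the left-to-right
#' orientation of the ARC graph; it quantifies how unevenly connection
#' strength is distributed locally, which rises with angular instability of
#' the underlying signal.
#'
#' @param network An [build_network()] result.
#' @return Nonnegative scalar; scale-invariant (multiplying all weights by
#'   c > 0 leaves it unchanged).
#' @export
waii <- function(network) {
  stopifnot(inherits(network, "arc_network"))
  groups <- split(network$edges$weight, network$edges$i)
  total <- 0
  for (w in groups) {
    m <- length(w)
    if (m > 1) {
      mu <- mean(w)
      if (mu != 0) total <- total + sqrt(mean((w - mu)^2)) / mu
    }
  }
  total / network$n
}

#' Curvature-Based Edge Feature Index (CBEFI)
#'
#' Mean over edges of the normalised absolute second difference
#' \eqn{\kappa_{ij} = |x_j - 2 x_k + x_i| / (j - i)^2} with
#' \eqn{k = \lfloor (i + j) / 2 \rfloor} and time in sample units. It is a
#' curvature-energy measure: smooth trajectories give small values, sharp
#' transients (e.g. triangular spikes) create second-difference
#' discontinuities that raise it.
#'
#' @param network An [build_network()] result.
#' @return Nonnegative scalar; 0 for a constant series, 1 for the linear
#'   series x_t = t (whose ARC graph is the chain).
#' @export
cbefi <- function(network) {
  stopifnot(inherits(network, "arc_network"))
  if (nrow(network$edges) == 0) stop("undefined on an empty edge set")
  mean(network$edges$kappa)
}

#' The 13 classical graph features
#'
#' Computes edge count, the four population moments of the edge-weight
#' distribution (kurtosis is excess kurtosis), the Gini index of the
#' weights, global efficiency, modularity of a greedy
#' modularity-maximisation partition, weighted average degree, average
#' degree, average betweenness centrality, average node strength and
#' average shortest path length. All path-based quantities and community
#' detection operate on the undirected weighted view with edge length =
#' weight (the ARC digraph is a DAG, so directed distances would be
#' infinite for half the ordered pairs); unreachable pairs contribute 0 to
#' efficiency and are excluded from the mean path length. Betweenness
#' excludes endpoints and is normalised by (N-1)(N-2)/2. Weighted average
#' degree and average node strength share one formula (mean undirected node
#' strength) and are emitted as two entries for fidelity to the standard
#' 15-feature ordering.
#'
#' @param network An [build_network()] result.
#' @param path_length_mode Edge length used for shortest paths:
#'   `"weight"` (default, weight-as-cost) or `"inverse"` (1/weight, for
#'   sensitivity checks where strong edges should read as short).
#' @return Named numeric vector of length 13: `edge_count`,
#'   `weight_kurtosis`, `weight_mean`, `weight_skewness`, `weight_variance`,
#'   `gini`, `global_efficiency`, `modularity`, `weighted_avg_degree`,
#'   `avg_degree`, `avg_betweenness`, `avg_strength`, `avg_path_length`.
#' @export
classical_features <- function(network,
                               path_length_mode = c("weight", "inverse")) {
  stopifnot(inherits(network, "arc_network"))
  path_length_mode <- match.arg(path_length_mode)
  w <- network$edges$weight
  n <- network$n
  mom <- weight_moments(w)
  g <- as_igraph(network, directed = FALSE)
  len <- if (path_length_mode == "weight") igraph::E(g)$weight
         else 1 / igraph::E(g)$weight

  d <- igraph::distances(g, weights = len)
  off <- row(d) != col(d)
  inv <- 1 / d[off]                       # unreachable: 1/Inf = 0
  e_glob <- sum(inv) / (n * (n - 1))
  finite_d <- d[off][is.finite(d[off])]
  l_avg <- if (length(finite_d)) mean(finite_d) else 0

  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  q <- igraph::modularity(g, igraph::membership(comm),
                          weights = igraph::E(g)$weight)

  bc <- igraph::betweenness(g, directed = FALSE, weights = len,
                            normalized = TRUE)
  strength <- igraph::strength(g, weights = igraph::E(g)$weight)

  c(edge_count = nrow(network$edges),
    weight_kurtosis = mom$kurt,
    weight_mean = mom$mean,
    weight_skewness = mom$skew,
    weight_variance = mom$var,
    gini = gini_index(w),
    global_efficiency = e_glob,
    modularity = q,
    weighted_avg_degree = mean(strength),
    avg_degree = 2 * nrow(network$edges) / n,
    avg_betweenness = mean(bc),
    avg_strength = mean(strength),
    avg_path_length = l_avg)
}

#' The full 15-entry feature vector
#'
#' Indices 1--13 are the classical features of [classical_features()] in
#' their canonical order; index 14 is [waii()], index 15 is [cbefi()].
#'
#' @param network An [build_network()] result.
#' @return Named numeric vector `feat_01` ... `feat_15`, all finite.
#' @seealso [arc_feature_names()] for the index-to-name table.
#' @export
feature_vector <- function(network) {
  v <- c(classical_features(network), waii = waii(network),
         cbefi = cbefi(network))
  stopifnot(length(v) == 15, all(is.finite(v)))
  names(v) <- sprintf("feat_%02d", 1:15)
  v
}

#' Feature index-to-name table
#'
#' @return A data.frame with columns `index` (1--15), `name` (column name
#'   used in feature tables) and `description`.
#' @export
arc_feature_names <- function() {
  data.frame(
    index = 1:15,
    name = sprintf("feat_%02d", 1:15),
    description = c("Edge count", "Edge weight kurtosis", "Edge weight mean",
                    "Edge weight skewness", "Edge weight variance",
                    "Gini index", "Global efficiency", "Modularity",
                    "Weighted average degree", "Average degree",
                    "Average betweenness centrality", "Average node strength",
                    "Average shortest path length",
                    "Weighted Angular Irregularity Index (WAII)",
                    "Curvature-Based Edge Feature Index (CBEFI)"),
    stringsAsFactors = FALSE)
}

#' Read/write feature tables
#'
#' The on-disk form of a labeled feature dataset: CSV with columns
#' `feat_01` ... `feat_15`, `label`, `subject`, `channel`.
#'
#' @param features A feature data.frame (as from [extract_features()]).
#' @param path File path.
#' @return `write_features()` returns the path invisibly; `read_features()`
#'   returns the data.frame with `label` as a factor.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(sprintf("feat_%02d", 1:15), "label", "subject", "channel")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  d$label <- factor(d$label)
  d
}
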