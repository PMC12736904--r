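#' ARC edge-weight parameters
#'
#' The weight of an ARC edge \eqn{i \to j} combines three terms:
#' \deqn{w_{ij} = \alpha |x_j - x_i| + \beta \frac{1}{j - i} +
#'   \gamma |\arctan((x_j - x_i)/(j - i))|}
#' an amplitude difference, a temporal-separation penalty and an angular
#' (slope) component. Time is measured in sample-index units, so the weight
#' depends on the amplitude scale relative to the unit sample step. The
#' defaults (0.5, 0.3, 0.2) are the reference operating point; the ranges
#' usually explored when tuning are alpha 0.3--0.7, beta 0.1--0.4,
#' gamma 0.1--0.3.
#'
#' With `signed_weights = TRUE` the absolute values are dropped and the
#' amplitude and angular terms keep their sign; downstream features assume
#' nonnegative weights, so this is for sensitivity checks only.
#'
#' @param alpha Weight of the amplitude-difference term (unitless, >= 0).
#' @param beta Weight of the temporal term (>= 0). Any positive beta makes
#'   every edge weight strictly positive.
#' @param gamma Weight of the angular term (>= 0).
#' @param signed_weights Keep the sign of the amplitude/angle terms
#'   (default `FALSE`).
#' @return An object of class `arc_params`.
#' @examples
#' arc_params()
#' arc_params(alpha = 0.7, beta = 0.1, gamma = 0.2)
#' @export
arc_params <- function(alpha = 0.5, beta = 0.3, gamma = 0.2,
                       signed_weights = FALSE) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1, length(beta) == 1, length(gamma) == 1)
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("alpha, beta and gamma must be nonnegative")
  if (alpha == 0 && beta == 0 && gamma == 0)
    stop("at least one of alpha, beta, gamma must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 signed_weights = isTRUE(signed_weights)),
            class = "arc_params")
}

#' @export
print.arc_params <- function(x, ...) {
  cat(sprintf("ARC edge-weight parameters: alpha = %g, beta = %g, gamma = %g%s\n",
              x$alpha, x$beta, x$gamma,
              if (x$signed_weights) " (signed)" else ""))
  invisible(x)
}

as_amplitudes <- function(x) {
  if (inherits(x, "eeg_segment")) x <- x$x
  if (!is.numeric(x)) stop("expected a numeric series or an eeg_segment")
  if (length(x) < 2) stop("degenerate input: need at least 2 samples, got ",
                          length(x))
  if (!all(is.finite(x))) stop("amplitude series contains non-finite values")
  as.numeric(x)
}

#' ARC rule: edges of the angle-relation connection graph
#'
#' Connects time points \eqn{i \to j} (with \eqn{j > i}, 0-based indices)
#' whenever the chord angle \eqn{\theta_{ij} = \arctan((x_j - x_i)/(j - i))}
#' strictly exceeds \eqn{\theta_{ik}} for every intermediate index
#' \eqn{i < k < j}. Adjacent pairs connect vacuously, so the graph always
#' contains the temporal chain and is connected. The condition is equivalent
#' to every intermediate sample lying strictly below the straight chord from
#' \eqn{(i, x_i)} to \eqn{(j, x_j)} — the natural-visibility criterion
#' restricted to the left-to-right direction.
#'
#' `arc_edges()` is the \eqn{O(n^2)} running-maximum sweep;
#' `arc_edges_bruteforce()` is a literal \eqn{O(n^3)} transcription of the
#' angular monotonicity condition kept as an independent reference (use it
#' for n up to a few hundred). Both return identical edge sets.
#'
#' @param x Numeric amplitude series or an [eeg_segment].
#' @return A data.frame with columns `i`, `j` (0-based node indices, sorted
#'   by `(i, j)`) and `theta` (chord angle, radians, in (-pi/2, pi/2)).
#' @examples
#' arc_edges(c(1, 3, 2, 4))
#' arc_edges_bruteforce(c(0, 1, 4, 9))  # strictly convex: all 6 pairs
#' @export
arc_edges <- function(x) {
  x <- as_amplitudes(x)
  e <- .arc_edges_sweep(x)
  arc_edge_frame(e)
}

#' @rdname arc_edges
#' @export
arc_edges_bruteforce <- function(x) {
  x <- as_amplitudes(x)
  e <- .arc_edges_brute(x)
  arc_edge_frame(e)
}

arc_edge_frame <- function(e) {
  d <- data.frame(i = e$i, j = e$j, theta = e$theta)
  d[order(d$i, d$j), , drop = FALSE]
}

#' ARC composite edge weight
#'
#' Evaluates the edge-weight function for node pairs `i < j` with amplitudes
#' `x_i`, `x_j`; see [arc_params()] for the formula. Vectorised over its
#' first four arguments.
#'
#' @param x_i,x_j Amplitudes at the source and target nodes.
#' @param i,j Node indices (any units proportional to sample index; `j > i`).
#' @param params An [arc_params()] object.
#' @return Numeric vector of weights; strictly positive when `beta > 0` and
#'   `signed_weights = FALSE`.
#' @examples
#' edge_weight(3, 4, 1, 3, arc_params())  # 0.5*1 + 0.3*0.5 + 0.2*atan(0.5)
#' @export
edge_weight <- function(x_i, x_j, i, j, params = arc_params()) {
  stopifnot(inherits(params, "arc_params"))
  if (any(j <= i)) stop("edge ordering violated: need j > i")
  dt <- j - i
  dx <- x_j - x_i
  ang <- atan(dx / dt)
  if (params$signed_weights) {
    params$alpha * dx + params$beta / dt + params$gamma * ang
  } else {
    params$alpha * abs(dx) + params$beta / dt + params$gamma * abs(ang)
  }
}

#' Build the weighted ARC network of a segment
#'
#' Applies the ARC rule ([arc_edges()]) and attaches the composite edge
#' weight ([edge_weight()]) and local curvature
#' \eqn{\kappa_{ij} = |x_j - 2 x_k + x_i| / (j - i)^2}, \eqn{k} the integer
#' midpoint, to every edge. The result is a directed acyclic graph on the
#' time indices, oriented left to right, stored as an edge list (a dense
#' adjacency is never materialised; on strictly convex segments the edge
#' count approaches \eqn{n^2/2}).
#'
#' @param x Numeric amplitude series or an [eeg_segment].
#' @param params An [arc_params()] object.
#' @return An object of class `arc_network`: list with `n` (node count),
#'   `x` (node amplitudes), `edges` (data.frame `i`, `j`, `weight`, `theta`,
#'   `kappa`; 0-based indices) and `params`.
#' @examples
#' net <- build_network(c(156.20, 161.28, 160.55, 161.87))
#' net$edges
#' @export
build_network <- function(x, params = arc_params()) {
  amps <- as_amplitudes(x)
  e <- arc_edges(amps)
  ii <- e$i
  jj <- e$j
  kk <- (ii + jj) %/% 2L
  e$weight <- edge_weight(amps[ii + 1L], amps[jj + 1L], ii, jj, params)
  e$kappa <- abs(amps[jj + 1L] - 2 * amps[kk + 1L] + amps[ii + 1L]) /
    (jj - ii)^2
  e <- e[, c("i", "j", "weight", "theta", "kappa")]
  rownames(e) <- NULL
  structure(list(n = length(amps), x = amps, edges = e, params = params),
            class = "arc_network")
}

#' @export
print.arc_network <- function(x, ...) {
  cat(sprintf("ARC network: %d nodes, %d edges (DAG, left-to-right)\n",
              x$n, nrow(x$edges)))
  cat(sprintf("  params: alpha = %g, beta = %g, gamma = %g\n",
              x$params$alpha, x$params$beta, x$params$gamma))
  invisible(x)
}

#' Convert an ARC network to an igraph object
#'
#' @param network An [build_network()] result.
#' @param directed Keep the left-to-right orientation (`TRUE`) or take the
#'   undirected view used by the path-based features (`FALSE`, default).
#' @return An igraph graph with edge attribute `weight`.
#' @export
as_igraph <- function(network, directed = FALSE) {
  stopifnot(inherits(network, "arc_network"))
  g <- igraph::make_empty_graph(n = network$n, directed = directed)
  g <- igraph::add_edges(g, rbind(network$edges$i + 1L, network$edges$j + 1L))
  igraph::E(g)$weight <- network$edges$weight
  g
}

#' Export an ARC network edge list
#'
#' `write_edges_tsv()` writes the 0-based edge list as TSV with columns
#' `i`, `j`, `weight`, `theta`; `write_adjacency_mtx()` writes the weighted
#' adjacency in MatrixMarket coordinate format (1-based, as the format
#' requires) for interoperability with external graph tooling.
#'
#' @param network An `arc_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  stopifnot(inherits(network, "arc_network"))
  utils::write.table(network$edges[, c("i", "j", "weight", "theta")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
write_adjacency_mtx <- function(network, path) {
  stopifnot(inherits(network, "arc_network"))
  m <- Matrix::sparseMatrix(i = network$edges$i + 1L,
                            j = network$edges$j + 1L,
                            x = network$edges$weight,
                            dims = c(network$n, network$n))
  Matrix::writeMM(m, path)
  invisible(path)
}
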