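#' Ant Colony Optimization configuration
#'
#' The wrapper selector samples, per ant, a subset size uniformly in
#' `[subset_min, subset_max]` and that many distinct features with
#' probability proportional to their pheromone levels. All subsets are
#' scored by cross-validated classifier accuracy; pheromones evaporate by
#' `(1 - evaporation)` each iteration and the iteration-best subset is
#' reinforced by `deposit * fitness`. Pheromones start uniform at 1 and no
#' heuristic-desirability term is used — subset sampling depends on the
#' pheromone state only.
#'
#' @param n_ants Ants per iteration (default 30).
#' @param n_iterations Iterations (default 50).
#' @param subset_min,subset_max Subset-size range (defaults 4 and 8).
#' @param evaporation Evaporation rate rho in (0, 1) (default 0.1).
#' @param deposit Pheromone reward scaling Q (default 1).
#' @param fitness_folds CV folds for the fitness classifier (default 5).
#' @param use_heuristic Multiply sampling probabilities by a per-feature
#'   ANOVA F-score desirability term (default `FALSE`: pheromone only).
#' @param seed Integer seed.
#' @return An object of class `aco_config`.
#' @export
aco_config <- function(n_ants = 30L, n_iterations = 50L, subset_min = 4L,
                       subset_max = 8L, evaporation = 0.1, deposit = 1,
                       fitness_folds = 5L, use_heuristic = FALSE,
                       seed = 1L) {
  stopifnot(n_ants >= 1, n_iterations >= 1,
            subset_min >= 1, subset_min <= subset_max,
            evaporation > 0, evaporation < 1, deposit > 0,
            fitness_folds >= 2)
  structure(list(n_ants = as.integer(n_ants),
                 n_iterations = as.integer(n_iterations),
                 subset_min = as.integer(subset_min),
                 subset_max = as.integer(subset_max),
                 evaporation = evaporation, deposit = deposit,
                 fitness_folds = as.integer(fitness_folds),
                 use_heuristic = isTRUE(use_heuristic),
                 seed = as.integer(seed)),
            class = "aco_config")
}

# Per-feature one-way ANOVA F statistic (feature ~ class), the optional
# desirability term.
anova_f_scores <- function(features, n_features) {
  vapply(seq_len(n_features), function(f) {
    fit <- stats::aov(features[[sprintf("feat_%02d", f)]] ~ features$label)
    stats::summary.aov(fit)[[1]][["F value"]][1]
  }, numeric(1))
}

#' Cross-validated fitness of a feature subset
#'
#' Mean accuracy of a seeded 250-tree random forest over stratified,
#' group-aware (subject-level) k-fold cross-validation restricted to the
#' subset's columns. This is the fitness the ACO wrapper maximises.
#'
#' @param features Feature data.frame ([extract_features()] schema).
#' @param subset Nonempty vector of feature indices (1--15).
#' @param folds CV folds (default 5).
#' @param seed Integer seed.
#' @param trees Forest size (default 250).
#' @return Fitness in \[0, 1\]; deterministic for fixed arguments.
#' @export
evaluate_subset <- function(features, subset, folds = 5L, seed = 1L,
                            trees = 250L) {
  if (length(subset) == 0) stop("empty feature subset")
  cv_accuracy(features, subset, folds = folds, seed = seed, trees = trees)
}

#' Run the ACO feature-subset search
#'
#' @param features Feature data.frame; ignored when `fitness_fn` is given.
#' @param config An [aco_config()].
#' @param fitness_fn Optional injected fitness `function(subset) -> number`
#'   (used for testing the search on problems with a known optimum).
#' @param n_features Size of the feature pool (default 15).
#' @return An object of class `aco_result`: `selected` (sorted best-ever
#'   subset), `fitness`, `trace` (best-so-far per iteration,
#'   nondecreasing), `pheromone` (final tau), `n_evaluations` (distinct
#'   subsets scored), `config`.
#' @export
run_aco <- function(features = NULL, config = aco_config(),
                    fitness_fn = NULL, n_features = 15L) {
  stopifnot(inherits(config, "aco_config"))
  if (config$subset_max > n_features)
    stop("subset_max exceeds the number of features")
  if (is.null(fitness_fn)) {
    if (is.null(features)) stop("need a feature table or a fitness_fn")
    fitness_fn <- function(subset)
      evaluate_subset(features, subset, folds = config$fitness_folds,
                      seed = config$seed)
  }
  memo <- new.env(parent = emptyenv())
  score <- function(subset) {
    key <- paste(sort(subset), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- fitness_fn(sort(subset))
    memo[[key]] <- val
    val
  }
  eta <- rep(1, n_features)
  if (config$use_heuristic) {
    if (is.null(features))
      stop("use_heuristic needs a feature table to score")
    eta <- anova_f_scores(features, n_features)
    eta <- pmax(eta, 1e-6)
  }
  sizes <- config$subset_min:config$subset_max
  tau <- rep(1, n_features)
  best_subset <- NULL
  best_fit <- -Inf
  trace <- numeric(config$n_iterations)
  with_seed(config$seed, {
    for (it in seq_len(config$n_iterations)) {
      iter_best <- NULL
      iter_fit <- -Inf
      for (a in seq_len(config$n_ants)) {
        size <- sizes[sample.int(length(sizes), 1)]
        subset <- sample.int(n_features, size, prob = tau * eta)
        fit <- score(subset)
        if (fit > iter_fit) {
          iter_fit <- fit
          iter_best <- subset
        }
      }
      if (iter_fit > best_fit) {
        best_fit <- iter_fit
        best_subset <- iter_best
      }
      tau <- (1 - config$evaporation) * tau
      tau[iter_best] <- tau[iter_best] + config$deposit * max(iter_fit, 0)
      tau <- pmax(tau, 1e-12)     # guard against negative injected fitness
      trace[it] <- best_fit
    }
  })
  structure(list(selected = sort(best_subset), fitness = best_fit,
                 trace = trace, pheromone = tau,
                 n_evaluations = length(ls(memo)), config = config),
            class = "aco_result")
}

#' @export
print.aco_result <- function(x, ...) {
  cat(sprintf("ACO selection: features {%s}, fitness %.4f (%d subsets scored)\n",
              paste(x$selected, collapse = ", "), x$fitness,
              x$n_evaluations))
  invisible(x)
}

#' Feature selection frequency over repeated ACO runs
#'
#' Repeats the ACO search with seeds derived from the configuration's
#' master seed and reports, per feature, the percentage of runs whose
#' final selected subset contains it.
#'
#' @inheritParams run_aco
#' @param n_runs Number of independent runs (>= 1).
#' @return Named numeric vector (`feat_01` ... ) of percentages in
#'   \[0, 100\].
#' @export
selection_frequency <- function(features = NULL, config = aco_config(),
                                n_runs = 50L, fitness_fn = NULL,
                                n_features = 15L) {
  stopifnot(n_runs >= 1)
  hits <- numeric(n_features)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, r)
    res <- run_aco(features, cfg, fitness_fn = fitness_fn,
                   n_features = n_features)
    hits[res$selected] <- hits[res$selected] + 1
  }
  out <- 100 * hits / n_runs
  names(out) <- sprintf("feat_%02d", seq_len(n_features))
  out
}
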