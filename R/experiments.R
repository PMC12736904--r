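task_classes <- function(task) {
  switch(task,
         AD_FTD_HC = c("AD", "FTD", "HC"),
         AD_HC = c("AD", "HC"),
         AD_FTD = c("AD", "FTD"),
         FTD_HC = c("FTD", "HC"),
         stop("unknown task '", task, "'"))
}

# Reported positive class for the binary tasks: the (first) disease class.
task_positive <- function(task) {
  if (task == "AD_FTD_HC") "macro" else task_classes(task)[1]
}

#' Run one classification experiment
#'
#' Filters the feature table to the task's classes, splits it
#' (subject-grouped by default), optionally runs the ACO selector on the
#' training side only — the held-out test split never touches selection —
#' and evaluates the classifier on the held-out rows. Binary tasks report
#' metrics with the disease class positive; the multiclass task reports
#' macro-averaged one-vs-rest metrics.
#'
#' @param features Feature data.frame ([extract_features()] schema).
#' @param task One of `"AD_FTD_HC"`, `"AD_HC"`, `"AD_FTD"`, `"FTD_HC"`.
#' @param use_aco Run ACO feature selection on the training split
#'   (default `FALSE` = all 15 features).
#' @param model A [model_config()].
#' @param seed Integer seed driving the split, the selector and the
#'   classifier.
#' @param aco An [aco_config()] for the selector (its seed is re-derived
#'   from `seed`).
#' @param split_mode,test_fraction Passed to [split_dataset()].
#' @param subset Feature indices used when `use_aco = FALSE`.
#' @return A `metrics_report` with `task`, `selected` and `n_features`
#'   fields.
#' @export
run_experiment <- function(features, task = "AD_FTD_HC", use_aco = FALSE,
                           model = model_config(), seed = 1L,
                           aco = aco_config(),
                           split_mode = "grouped_subject",
                           test_fraction = 0.2, subset = 1:15) {
  classes <- task_classes(task)
  if (!all(classes %in% features$label))
    stop("feature table lacks classes: ",
         paste(setdiff(classes, unique(features$label)), collapse = ", "))
  d <- features[features$label %in% classes, , drop = FALSE]
  d$label <- droplevels(factor(d$label, levels = classes))
  parts <- split_dataset(d, mode = split_mode,
                         test_fraction = test_fraction, seed = seed)
  if (use_aco) {
    aco$seed <- derive_seed(seed, 17L)
    subset <- run_aco(parts$train, aco)$selected
  }
  model$seed <- derive_seed(seed, 29L)
  rep <- train_and_eval(parts$train, parts$test, model, subset,
                        positive_class = task_positive(task))
  rep$task <- task
  rep$use_aco <- use_aco
  rep
}

#' Ablation over feature-set configurations and tasks
#'
#' Evaluates five feature configurations — the 13 classical features
#' alone, +WAII, +CBEFI, +both, and +both with ACO selection — on the four
#' tasks (three binary, one multiclass). The same split is reused across
#' configurations within a task so the comparison is paired.
#'
#' @inheritParams run_experiment
#' @param tasks Character vector of tasks to cover.
#' @return Data.frame with columns `config`, `task`, `accuracy`, `f1`,
#'   `n_features`.
#' @export
run_ablation <- function(features, seed = 1L, model = model_config(),
                         aco = aco_config(),
                         tasks = c("AD_FTD", "FTD_HC", "AD_HC",
                                   "AD_FTD_HC"),
                         split_mode = "grouped_subject",
                         test_fraction = 0.2) {
  configs <- list(baseline13 = 1:13, plus_waii = c(1:13, 14L),
                  plus_cbefi = c(1:13, 15L), plus_both = 1:15,
                  plus_both_aco = NULL)  # NULL = ACO-selected
  out <- list()
  for (task in tasks) {
    classes <- task_classes(task)
    d <- features[features$label %in% classes, , drop = FALSE]
    d$label <- droplevels(factor(d$label, levels = classes))
    parts <- split_dataset(d, mode = split_mode,
                           test_fraction = test_fraction, seed = seed)
    for (cfg in names(configs)) {
      subset <- configs[[cfg]]
      if (is.null(subset)) {
        aco_task <- aco
        aco_task$seed <- derive_seed(seed, 17L, match(task, tasks))
        subset <- run_aco(parts$train, aco_task)$selected
      }
      model$seed <- derive_seed(seed, 29L)
      rep <- train_and_eval(parts$train, parts$test, model, subset,
                            positive_class = task_positive(task))
      out[[length(out) + 1L]] <-
        data.frame(config = cfg, task = task, accuracy = rep$accuracy,
                   f1 = rep$f1, n_features = length(subset),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Random-forest accuracy over a trees-by-folds cross-validation grid
#'
#' Group-aware stratified CV accuracy of the random forest for each
#' (ensemble size, fold count) cell.
#'
#' @inheritParams run_experiment
#' @param trees_list Forest sizes (default 150, 200, 250, 300).
#' @param folds_list Fold counts (default 5 and 10).
#' @param subset Feature indices to use (default all 15).
#' @return Numeric matrix, rows = trees, columns = folds, entries in
#'   \[0, 1\].
#' @export
cv_grid <- function(features, trees_list = c(150L, 200L, 250L, 300L),
                    folds_list = c(5L, 10L), seed = 1L, subset = 1:15) {
  stopifnot(length(trees_list) >= 1, length(folds_list) >= 1)
  grid <- matrix(NA_real_, length(trees_list), length(folds_list),
                 dimnames = list(paste0("trees_", trees_list),
                                 paste0("folds_", folds_list)))
  for (ti in seq_along(trees_list))
    for (fi in seq_along(folds_list))
      grid[ti, fi] <- cv_accuracy(features, subset,
                                  folds = folds_list[fi],
                                  seed = derive_seed(seed, fi),
                                  trees = trees_list[ti])
  grid
}
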