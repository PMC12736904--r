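test_that("metrics from hand-computed confusion counts are exact", {
  m <- metrics_from_counts(tp = 9, fp = 1, tn = 8, fn = 2)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 9 / 11, tolerance = 1e-12)
  expect_equal(m$specificity, 8 / 9, tolerance = 1e-12)
  expect_equal(m$f1, 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11), tolerance = 1e-12)
  expect_equal(m$f1, 0.8571, tolerance = 1e-4)
  # identity: accuracy * N = TP + TN
  expect_equal(m$accuracy * m$n, 9 + 8)
})

test_that("perfect and degenerate predictions hit the boundary values", {
  y <- factor(c("AD", "HC", "AD", "HC"))
  m <- confusion_metrics(y, y, positive_class = "AD")
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1, f1 = 1))
  # all-negative predictions: precision undefined -> 0, flagged
  m0 <- confusion_metrics(y, factor(rep("HC", 4), levels(y)),
                          positive_class = "AD")
  expect_equal(m0$precision, 0)
  expect_true("precision" %in% m0$undefined)
  expect_error(confusion_metrics(factor(), factor()), "empty")
  expect_error(confusion_metrics(y, y[1:2]), "equal length")
})

test_that("macro metrics match caret's one-vs-rest averages", {
  skip_if_not_installed("caret")
  for (s in 1:10) {
    set.seed(s)
    lev <- c("AD", "FTD", "HC")
    y_true <- factor(sample(lev, 60, replace = TRUE), lev)
    y_pred <- factor(sample(lev, 60, replace = TRUE), lev)
    m <- confusion_metrics(y_true, y_pred)
    cm <- caret::confusionMatrix(y_pred, y_true)
    expect_equal(m$accuracy, unname(cm$overall["Accuracy"]),
                 tolerance = 1e-12)
    byc <- cm$byClass
    byc[is.na(byc)] <- 0                    # caret NA == our 0 convention
    expect_equal(m$sensitivity, unname(mean(byc[, "Sensitivity"])),
                 tolerance = 1e-12)
    expect_equal(m$specificity, unname(mean(byc[, "Specificity"])),
                 tolerance = 1e-12)
    expect_equal(m$precision, unname(mean(byc[, "Precision"])),
                 tolerance = 1e-12)
  }
})

test_that("stratified splits preserve class proportions", {
  tab <- fake_feature_table(subjects_per_class = 17, rows_per_subject = 2,
                            classes = c("AD", "FTD", "HC"))
  parts <- split_dataset(tab, mode = "stratified_record",
                         test_fraction = 0.2, seed = 1)
  expect_equal(nrow(parts$test) + nrow(parts$train), nrow(tab))
  per_class <- table(parts$test$label)
  expect_true(all(per_class >= 6 & per_class <= 8))  # 34 rows/class * 0.2
  # determinism
  again <- split_dataset(tab, mode = "stratified_record",
                         test_fraction = 0.2, seed = 1)
  expect_identical(rownames(parts$test), rownames(again$test))
})

test_that("grouped splits never let a subject straddle the boundary", {
  tab <- fake_feature_table(subjects_per_class = 8,
                            classes = c("AD", "FTD", "HC"))
  parts <- split_dataset(tab, mode = "grouped_subject", seed = 3)
  expect_length(intersect(unique(parts$train$subject),
                          unique(parts$test$subject)), 0)
  expect_setequal(unique(as.character(parts$test$label)),
                  c("AD", "FTD", "HC"))
  expect_error(split_dataset(tab, test_fraction = 0), "test_fraction")
  expect_error(split_dataset(tab[tab$label == "AD", ], seed = 1),
               "at least 2 classes")
})

test_that("all five classifiers learn a separable synthetic problem", {
  tab <- fake_feature_table(subjects_per_class = 15, informative = c(2, 9),
                            sep = 3, seed = 5)
  parts <- split_dataset(tab, seed = 1)
  for (kind in c("random_forest", "adaboost", "bagged_trees", "knn",
                 "rbf_svm")) {
    m <- train_and_eval(parts$train, parts$test,
                        model_config(kind, trees = 100, seed = 1))
    expect_gte(m$accuracy, 0.8)
  }
})

test_that("training is deterministic given the seed", {
  tab <- fake_feature_table(subjects_per_class = 8, informative = 1,
                            sep = 1, seed = 6)
  parts <- split_dataset(tab, seed = 2)
  for (kind in c("random_forest", "adaboost", "knn")) {
    a <- train_and_eval(parts$train, parts$test,
                        model_config(kind, trees = 60, seed = 7))
    b <- train_and_eval(parts$train, parts$test,
                        model_config(kind, trees = 60, seed = 7))
    expect_identical(a$accuracy, b$accuracy)
  }
  expect_error(train_and_eval(parts$train[parts$train$label == "AD", ],
                              parts$test, model_config()),
               "single class")
  expect_error(train_and_eval(parts$train, parts$test, model_config(),
                              subset = integer(0)), "empty")
})

test_that("label-permuted training lands in the chance band", {
  accs <- vapply(1:10, function(s) {
    tab <- fake_feature_table(subjects_per_class = 10,
                              informative = 4, sep = 3, seed = s)
    set.seed(s)
    tab$label <- sample(tab$label)          # destroy the signal
    parts <- split_dataset(tab, mode = "stratified_record", seed = s)
    train_and_eval(parts$train, parts$test,
                   model_config(trees = 100, seed = s))$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("experiments filter to their task's classes", {
  tab <- fake_feature_table(subjects_per_class = 8,
                            classes = c("AD", "FTD", "HC"),
                            informative = 2, sep = 2, seed = 8)
  m <- run_experiment(tab, task = "AD_HC", seed = 1,
                      model = model_config(trees = 50))
  expect_equal(m$task, "AD_HC")
  expect_false("FTD" %in% m$per_class$class)
  expect_error(run_experiment(tab[tab$label != "FTD", ], task = "AD_FTD"),
               "lacks classes")
  expect_error(run_experiment(tab, task = "bogus"), "unknown task")
})

test_that("ACO-driven experiments report 4 to 8 selected features", {
  tab <- fake_feature_table(subjects_per_class = 8,
                            classes = c("AD", "HC"),
                            informative = c(3, 12), sep = 3, seed = 9)
  m <- run_experiment(tab, task = "AD_HC", use_aco = TRUE, seed = 1,
                      model = model_config(trees = 50),
                      aco = aco_config(n_ants = 5, n_iterations = 3))
  expect_gte(m$n_features, 4)
  expect_lte(m$n_features, 8)
  expect_length(m$selected, m$n_features)
})

test_that("the ablation grid is complete and masks what it claims to", {
  tab <- fake_feature_table(subjects_per_class = 8,
                            classes = c("AD", "FTD", "HC"),
                            informative = c(2, 14, 15), sep = 2, seed = 10)
  ab <- run_ablation(tab, seed = 1, model = model_config(trees = 50),
                     aco = aco_config(n_ants = 5, n_iterations = 3))
  expect_equal(nrow(ab), 5 * 4)
  expect_setequal(unique(ab$task), c("AD_FTD", "FTD_HC", "AD_HC",
                                     "AD_FTD_HC"))
  expect_setequal(unique(ab$config),
                  c("baseline13", "plus_waii", "plus_cbefi", "plus_both",
                    "plus_both_aco"))
  expect_equal(ab$n_features[ab$config == "baseline13"], rep(13L, 4))
  # the baseline must ignore columns 14-15 entirely
  mangled <- tab
  mangled$feat_14 <- rev(mangled$feat_14)
  mangled$feat_15 <- 0
  ab2 <- run_ablation(mangled, seed = 1, model = model_config(trees = 50),
                      aco = aco_config(n_ants = 5, n_iterations = 3))
  base <- ab$config == "baseline13"
  expect_equal(ab2$accuracy[base], ab$accuracy[base])
})

test_that("the CV grid covers trees x folds with accuracies in [0, 1]", {
  tab <- fake_feature_table(subjects_per_class = 12, rows_per_subject = 1,
                            classes = c("AD", "HC"), informative = 6,
                            sep = 2, seed = 11)
  g <- cv_grid(tab, trees_list = c(150, 200, 250, 300),
               folds_list = c(5, 10), seed = 1)
  expect_equal(dim(g), c(4L, 2L))
  expect_true(all(g >= 0 & g <= 1))
  g2 <- cv_grid(tab, trees_list = c(150, 200, 250, 300),
                folds_list = c(5, 10), seed = 1)
  expect_identical(g, g2)
})
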