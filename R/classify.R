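`%||%` <- function(a, b) if (is.null(a)) b else a

feature_cols <- function(subset) sprintf("feat_%02d", as.integer(subset))

#' Classifier configuration
#'
#' The five evaluation classifiers: random forest and bagged trees (ranger
#' ensembles; bagging uses `mtry = p`, i.e. plain bootstrap aggregation of
#' unpruned trees), AdaBoost (SAMME with depth-1 rpart stumps), k-nearest
#' neighbours and an RBF-kernel SVM. Features are z-scored (train-fit) for
#' kNN and the SVM only; tree ensembles see the raw columns.
#'
#' @param kind One of `"random_forest"`, `"adaboost"`, `"bagged_trees"`,
#'   `"knn"`, `"rbf_svm"`.
#' @param trees Ensemble size (trees or boosting rounds; default 250).
#' @param k Neighbours for kNN (default 5).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma SVM RBF width; default `NULL` means
#'   1 / (n_features * mean feature variance) computed on the standardised
#'   training block.
#' @param seed Integer seed for the stochastic learners.
#' @return An object of class `model_config`.
#' @export
model_config <- function(kind = c("random_forest", "adaboost",
                                  "bagged_trees", "knn", "rbf_svm"),
                         trees = 250L, k = 5L, cost = 1, gamma = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(trees >= 1, k >= 1)
  structure(list(kind = kind, trees = as.integer(trees), k = as.integer(k),
                 cost = cost, gamma = gamma, seed = as.integer(seed)),
            class = "model_config")
}

#' Train/test split of a feature table
#'
#' `"stratified_record"` preserves class proportions over rows;
#' `"grouped_subject"` assigns whole subjects to one side (no subject
#' straddles the split) while approximating class proportions — the
#' default sample unit for subject-level separation. Deterministic per
#' seed.
#'
#' @param features Feature data.frame (see [extract_features()]).
#' @param mode Split mode.
#' @param test_fraction Fraction of rows (or subjects) held out
#'   (default 0.2).
#' @param seed Integer seed.
#' @param max_retries Grouped mode: number of re-draws allowed when a class
#'   ends up absent from one side.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(features, mode = c("grouped_subject",
                                             "stratified_record"),
                          test_fraction = 0.2, seed = 1L,
                          max_retries = 20L) {
  mode <- match.arg(mode)
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (length(unique(features$label)) < 2)
    stop("need at least 2 classes to split")
  features$label <- droplevels(factor(features$label))
  if (mode == "stratified_record") {
    test_idx <- with_seed(seed, {
      unlist(lapply(split(seq_len(nrow(features)), features$label),
                    function(rows) {
                      rows <- sample(rows)
                      n_test <- max(1L, round(length(rows) * test_fraction))
                      rows[seq_len(n_test)]
                    }), use.names = FALSE)
    })
  } else {
    subj_label <- vapply(split(as.character(features$label),
                               features$subject),
                         function(l) l[[1]], character(1))
    for (attempt in 0:max_retries) {
      test_subj <- with_seed(derive_seed(seed, attempt), {
        unlist(lapply(split(names(subj_label), subj_label),
                      function(subjects) {
                        subjects <- sample(subjects)
                        n_test <- max(1L,
                                      round(length(subjects) * test_fraction))
                        subjects[seq_len(n_test)]
                      }), use.names = FALSE)
      })
      test_idx <- which(features$subject %in% test_subj)
      ok <- setequal(unique(features$label[test_idx]),
                     levels(features$label)) &&
        setequal(unique(features$label[-test_idx]),
                 levels(features$label))
      if (ok) break
      if (attempt == max_retries)
        stop("could not produce a grouped split with every class on both ",
             "sides; a class may have too few subjects")
      warning("grouped split left a class one-sided; re-drawing")
    }
  }
  list(train = features[-test_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

#' Confusion-matrix metrics
#'
#' `metrics_from_counts()` evaluates accuracy, sensitivity (recall),
#' specificity, precision and F1 from raw TP/FP/TN/FN counts.
#' `confusion_metrics()` computes them from label vectors: binary with a
#' stated positive class, or macro-averaged one-vs-rest for multiclass
#' (`positive_class = "macro"`), with accuracy always the overall fraction
#' correct. Ratios with zero denominator are reported as 0 and flagged in
#' the `undefined` field.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return An object of class `metrics_report` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `n`, `per_class`
#'   (multiclass only) and `undefined`.
#' @examples
#' m <- metrics_from_counts(tp = 9, fp = 1, tn = 8, fn = 2)
#' m$accuracy  # 0.85
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  safe <- function(num, den) if (den > 0) num / den else 0
  undefined <- character(0)
  if (tp + fp == 0) undefined <- c(undefined, "precision")
  if (tp + fn == 0) undefined <- c(undefined, "sensitivity")
  if (tn + fp == 0) undefined <- c(undefined, "specificity")
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  structure(list(accuracy = safe(tp + tn, tp + tn + fp + fn),
                 sensitivity = sensitivity,
                 specificity = safe(tn, tn + fp),
                 precision = precision, f1 = f1,
                 n = tp + tn + fp + fn,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 undefined = undefined),
            class = "metrics_report")
}

#' @rdname metrics_from_counts
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class Label of the positive class, or `"macro"` for
#'   macro-averaged one-vs-rest metrics.
#' @export
confusion_metrics <- function(y_true, y_pred, positive_class = "macro") {
  if (length(y_true) == 0) stop("empty label vectors")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  if (!identical(positive_class, "macro")) {
    if (!positive_class %in% lev)
      stop("positive class '", positive_class, "' not among labels")
    tp <- sum(y_true == positive_class & y_pred == positive_class)
    fp <- sum(y_true != positive_class & y_pred == positive_class)
    tn <- sum(y_true != positive_class & y_pred != positive_class)
    fn <- sum(y_true == positive_class & y_pred != positive_class)
    return(metrics_from_counts(tp, fp, tn, fn))
  }
  per <- lapply(lev, function(cls) {
    m <- confusion_metrics(y_true, y_pred, positive_class = cls)
    data.frame(class = cls, sensitivity = m$sensitivity,
               specificity = m$specificity, precision = m$precision,
               f1 = m$f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = mean(y_true == y_pred),
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 precision = mean(per$precision),
                 f1 = mean(per$f1),
                 n = length(y_true),
                 per_class = per,
                 undefined = character(0)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%%  F1 %.2f%%  (n = %d)\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$precision, 100 * x$f1, x$n))
  if (!is.null(x$n_features))
    cat(sprintf("  features used: %d (%s)\n", x$n_features,
                paste(x$selected, collapse = ", ")))
  invisible(x)
}

# SAMME AdaBoost with depth-1 rpart stumps (multiclass-capable).
fit_adaboost <- function(X, y, rounds) {
  n <- nrow(X)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, X, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = -1, xval = 0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 0) {                 # perfect stump: dominate and stop
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 1 - 1 / K) break     # worse than chance for SAMME
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {        # fall back to the single best stump
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    stumps <- list(fit)
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(model, X) {
  votes <- matrix(0, nrow(X), length(model$levels),
                  dimnames = list(NULL, model$levels))
  df <- as.data.frame(X, check.names = FALSE)
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(X)), as.integer(pred))] + model$alphas[m]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

fit_predict <- function(X_train, y_train, X_test, model) {
  if (model$kind %in% c("knn", "rbf_svm")) {
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X_train <- scale(X_train, center = mu, scale = sdv)
    X_test <- scale(X_test, center = mu, scale = sdv)
  }
  switch(model$kind,
    random_forest = {
      fit <- ranger::ranger(x = X_train, y = y_train,
                            num.trees = model$trees, seed = model$seed,
                            num.threads = 1)
      predict(fit, X_test, num.threads = 1, seed = model$seed)$predictions
    },
    bagged_trees = {
      fit <- ranger::ranger(x = X_train, y = y_train,
                            num.trees = model$trees, mtry = ncol(X_train),
                            min.node.size = 1, seed = model$seed,
                            num.threads = 1)
      predict(fit, X_test, num.threads = 1, seed = model$seed)$predictions
    },
    adaboost = with_seed(model$seed, {
      predict_adaboost(fit_adaboost(X_train, y_train, model$trees), X_test)
    }),
    knn = with_seed(model$seed, {
      class::knn(X_train, X_test, cl = y_train, k = model$k)
    }),
    rbf_svm = {
      gamma <- model$gamma %||%
        (1 / (ncol(X_train) * mean(apply(X_train, 2, stats::var))))
      fit <- e1071::svm(x = X_train, y = y_train, kernel = "radial",
                        cost = model$cost, gamma = gamma, scale = FALSE)
      predict(fit, X_test)
    })
}

#' Train a classifier on a feature subset and evaluate it
#'
#' @param train,test Feature data.frames sharing the `feat_01` ...
#'   `feat_15`, `label` schema.
#' @param model A [model_config()].
#' @param subset Feature indices (1--15) to use.
#' @param positive_class Passed to [confusion_metrics()].
#' @return A `metrics_report` with `n_features` and `selected` attached.
#' @export
train_and_eval <- function(train, test, model = model_config(),
                           subset = 1:15, positive_class = "macro") {
  if (length(subset) == 0) stop("empty feature subset")
  lev <- levels(droplevels(factor(train$label)))
  if (length(lev) < 2) stop("training set contains a single class")
  cols <- feature_cols(subset)
  y_train <- factor(as.character(train$label), levels = lev)
  y_true <- factor(as.character(test$label), levels = lev)
  X_train <- as.matrix(train[, cols, drop = FALSE])
  X_test <- as.matrix(test[, cols, drop = FALSE])
  y_pred <- fit_predict(X_train, y_train, X_test, model)
  rep <- confusion_metrics(y_true, y_pred, positive_class)
  rep$n_features <- length(subset)
  rep$selected <- sort(as.integer(subset))
  rep$model <- model$kind
  rep$seed <- model$seed
  rep
}

# Group-aware stratified fold assignment: subjects of each class are
# shuffled and dealt round-robin to folds, so no subject straddles folds
# and every training part keeps all classes (requires >= 2 subjects per
# class).
make_group_folds <- function(labels, groups, k, seed) {
  labels <- as.character(labels)
  groups <- as.character(groups)
  subj_label <- vapply(split(labels, groups), function(l) l[[1]],
                       character(1))
  per_class_rows <- table(labels)
  if (any(per_class_rows < k))
    stop("a class has fewer rows (", min(per_class_rows),
         ") than folds (", k, "); use fewer folds")
  if (any(table(subj_label) < 2) && k > 1)
    stop("every class needs at least 2 subjects for group-aware folds")
  fold_of_subj <- with_seed(seed, {
    out <- integer(0)
    offset <- 0L
    for (cls in unique(subj_label)) {
      subjects <- sample(names(subj_label)[subj_label == cls])
      f <- ((seq_along(subjects) - 1L + offset) %% k) + 1L
      names(f) <- subjects
      out <- c(out, f)
      offset <- offset + length(subjects)
    }
    out
  })
  unname(fold_of_subj[groups])
}

# Group-aware k-fold CV accuracy of a seeded random forest on a feature
# subset; the ACO fitness function and the CV grid both route through here.
cv_accuracy <- function(features, subset, folds, seed, trees = 250L) {
  fold_id <- make_group_folds(features$label, features$subject, folds, seed)
  cols <- feature_cols(subset)
  lev <- levels(droplevels(factor(features$label)))
  y <- factor(as.character(features$label), levels = lev)
  X <- as.matrix(features[, cols, drop = FALSE])
  acc <- vapply(seq_len(folds), function(f) {
    hold <- fold_id == f
    if (!any(hold)) return(NA_real_)
    fit <- ranger::ranger(x = X[!hold, , drop = FALSE], y = y[!hold],
                          num.trees = trees, seed = derive_seed(seed, f),
                          num.threads = 1)
    mean(predict(fit, X[hold, , drop = FALSE], seed = derive_seed(seed, f),
                 num.threads = 1)$predictions == y[hold])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}
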