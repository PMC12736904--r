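# Shared fixtures. The full-size cohort feature tables take a couple of
# minutes each, so they are computed once per session and cached on disk
# in tempdir().

COHORT_SEED <- 1L

cohort_features <- function(name = c("easy", "geometry")) {
  name <- match.arg(name)
  cache <- file.path(tempdir(), sprintf("arcnet-%s-features.rds", name))
  if (file.exists(cache)) return(readRDS(cache))
  profiles <- if (name == "easy") easy_profiles() else geometry_profiles()
  cohort <- generate_cohort(profiles, subjects_per_class = 10,
                            channels = 2, n = 2000, fs = 500,
                            seed = COHORT_SEED)
  features <- extract_features(cohort)
  saveRDS(features, cache)
  features
}

# Cheap synthetic feature table for classifier/selector unit tests: 15
# standard-normal noise columns; `informative` columns get a per-class
# mean shift of `sep`. Two rows (channels) per subject.
fake_feature_table <- function(subjects_per_class = 10,
                               classes = c("AD", "HC"),
                               rows_per_subject = 2,
                               informative = integer(0), sep = 2,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (ci in seq_along(classes)) {
    for (s in seq_len(subjects_per_class)) {
      for (r in seq_len(rows_per_subject)) {
        v <- rnorm(15)
        v[informative] <- v[informative] + ci * sep
        rows[[length(rows) + 1L]] <- data.frame(
          t(setNames(v, sprintf("feat_%02d", 1:15))),
          label = classes[ci],
          subject = sprintf("%s-%02d", classes[ci], s),
          channel = sprintf("ch%02d", r))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label)
  out
}

# A hand-rolled arc_network with prescribed edges, for feature formula
# tests that need full control of the weights.
manual_network <- function(n, x, i, j, weight,
                           theta = rep(0, length(i)),
                           kappa = rep(0, length(i))) {
  structure(list(n = n, x = x,
                 edges = data.frame(i = i, j = j, weight = weight,
                                    theta = theta, kappa = kappa),
                 params = arc_params()),
            class = "arc_network")
}
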