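test_that("WAII follows the out-weight coefficient-of-variation definition", {
  # chain: every out-degree <= 1, all nodes take the zero branch
  expect_equal(waii(build_network(rep(2, 8))), 0)

  # node 0 with out-weights {1, 3}: population std 1, mean 2, N = 3
  net <- manual_network(3, c(0, 0, 0), i = c(0L, 0L), j = c(1L, 2L),
                        weight = c(1, 3))
  expect_equal(waii(net), (1 / 2) / 3, tolerance = 1e-12)

  # a node whose outgoing weights are all equal contributes 0
  net <- manual_network(3, c(0, 0, 0), i = c(0L, 0L), j = c(1L, 2L),
                        weight = c(2, 2))
  expect_equal(waii(net), 0)
})

test_that("WAII is invariant to rescaling all edge weights", {
  net <- build_network(random_series("gaussian", 80, seed = 11))
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 37.5
  expect_equal(waii(scaled), waii(net), tolerance = 1e-12)
})

test_that("CBEFI matches the floor-midpoint second-difference formula", {
  # [0, 1, 4]: edges (0,1), (1,2), (0,2) with kappa 1, 3, 0.5
  net <- build_network(c(0, 1, 4))
  expect_equal(sort(net$edges$kappa), c(0.5, 1, 3), tolerance = 1e-12)
  expect_equal(cbefi(net), 1.5, tolerance = 1e-12)

  # literal independent transcription on a random network
  x <- random_series("uniform", 50, seed = 3)
  net <- build_network(x)
  kap <- vapply(seq_len(nrow(net$edges)), function(r) {
    i <- net$edges$i[r]; j <- net$edges$j[r]; k <- floor((i + j) / 2)
    abs(x[j + 1] - 2 * x[k + 1] + x[i + 1]) / (j - i)^2
  }, numeric(1))
  expect_equal(cbefi(net), mean(kap), tolerance = 1e-12)

  # constant series: zero curvature; linear series: every kappa = 1
  expect_equal(cbefi(build_network(rep(4, 10))), 0)
  expect_equal(cbefi(build_network(as.numeric(0:9))), 1, tolerance = 1e-12)
})

test_that("a triangular spike strictly increases CBEFI", {
  prof <- class_profile("smooth", data.frame(freq = 8, amp = 1),
                        ar_coeff = 0.3, noise_sd = 0.05)
  for (s in 1:5) {
    seg <- generate_segment(prof, n = 400, fs = 500, seed = s)
    base <- cbefi(build_network(seg))
    spiked <- seg$x
    p <- 150 + 20 * s
    spiked[p + (-4:4)] <- spiked[p + (-4:4)] + 3 * (1 - abs(-4:4) / 5)
    expect_gt(cbefi(build_network(eeg_segment(spiked, fs = 500))), base)
  }
})

test_that("edge-weight moments use population denominators", {
  net <- manual_network(5, numeric(5), i = 0:3, j = 1:4,
                        weight = c(1, 1, 1, 3))
  f <- classical_features(net)
  expect_equal(unname(f["weight_mean"]), 1.5)
  expect_equal(unname(f["weight_variance"]), 0.75)
  expect_equal(unname(f["weight_kurtosis"]), 1.3125 / 0.5625 - 3,
               tolerance = 1e-12)
  expect_equal(unname(f["weight_skewness"]), 0.75 / 0.75^1.5,
               tolerance = 1e-12)
  # moment identity: var = E[w^2] - E[w]^2
  w <- net$edges$weight
  expect_equal(unname(f["weight_variance"]), mean(w^2) - mean(w)^2)
})

test_that("zero-variance weight distributions take the 0 convention", {
  f <- classical_features(build_network(rep(1, 7)))
  expect_equal(unname(f["weight_skewness"]), 0)
  expect_equal(unname(f["weight_kurtosis"]), 0)
  expect_equal(unname(f["weight_variance"]), 0)
  expect_equal(unname(f["gini"]), 0)
})

test_that("Gini matches the double-loop formula and stays in [0, 1]", {
  for (s in 1:5) {
    set.seed(s)
    w <- rexp(40)
    net <- manual_network(41, numeric(41), i = 0:39, j = 1:40, weight = w)
    g <- unname(classical_features(net)["gini"])
    expect_equal(g, brute_gini(w), tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
})

test_that("path metrics match a Floyd-Warshall brute-force oracle", {
  for (s in 1:8) {
    x <- random_series(c("gaussian", "uniform")[s %% 2 + 1],
                       n = 8 + 4 * s, seed = 100 + s)
    net <- build_network(x)
    f <- classical_features(net)
    expect_equal(unname(f["global_efficiency"]),
                 brute_global_efficiency(net$n, net$edges),
                 tolerance = 1e-9)
    expect_equal(unname(f["avg_path_length"]),
                 brute_avg_path_length(net$n, net$edges),
                 tolerance = 1e-9)
    expect_equal(unname(f["avg_betweenness"]),
                 brute_avg_betweenness(net$n, net$edges),
                 tolerance = 1e-9)
  }
})

test_that("modularity equals the textbook objective on the same partition", {
  for (s in 1:4) {
    net <- build_network(random_series("ar1", 40 + 5 * s, seed = 200 + s))
    g <- as_igraph(net)
    comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    q_hand <- brute_modularity(net$n, net$edges,
                               as.integer(igraph::membership(comm)))
    expect_equal(unname(classical_features(net)["modularity"]), q_hand,
                 tolerance = 1e-9)
  }
})

test_that("the 15-entry vector has the canonical layout and closed forms", {
  fv <- feature_vector(build_network(rep(3.3, 10)))
  expect_named(fv, sprintf("feat_%02d", 1:15))
  expect_equal(unname(fv["feat_01"]), 9)             # chain edge count
  expect_equal(unname(fv["feat_05"]), 0)             # constant weights
  expect_equal(unname(fv["feat_06"]), 0)
  expect_equal(unname(fv["feat_10"]), 2 * 9 / 10)    # 2|E|/N
  expect_equal(unname(fv["feat_14"]), 0)
  expect_equal(unname(fv["feat_15"]), 0)
  expect_true(all(is.finite(fv)))
  # indices 9 and 12 share one formula by construction
  expect_equal(unname(fv["feat_09"]), unname(fv["feat_12"]))
})

test_that("feature computation is invariant to edge-list row order", {
  net <- build_network(random_series("gaussian", 50, seed = 5))
  perm <- net
  set.seed(1)
  perm$edges <- perm$edges[sample(nrow(perm$edges)), ]
  expect_equal(waii(perm), waii(net), tolerance = 1e-12)
  expect_equal(cbefi(perm), cbefi(net), tolerance = 1e-12)
  expect_equal(classical_features(perm), classical_features(net),
               tolerance = 1e-9)
})

test_that("feature tables round-trip through CSV", {
  tab <- fake_feature_table(subjects_per_class = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  expect_equal(back$feat_07, tab$feat_07, tolerance = 1e-12)
  expect_equal(as.character(back$label), as.character(tab$label))
  expect_error(read_features(write_features(tab[, 1:5], path)), "missing")
})

test_that("inverse path lengths flip which pairs read as close", {
  net <- build_network(random_series("gaussian", 40, seed = 21))
  fw <- classical_features(net, path_length_mode = "weight")
  fi <- classical_features(net, path_length_mode = "inverse")
  # moments and community structure are unaffected; path metrics move
  expect_equal(fw["weight_mean"], fi["weight_mean"])
  expect_equal(fw["modularity"], fi["modularity"])
  expect_false(isTRUE(all.equal(fw["avg_path_length"],
                                fi["avg_path_length"])))
  expect_equal(unname(fi["avg_path_length"]),
               brute_avg_path_length(net$n, transform(net$edges,
                                                      weight = 1 / weight)),
               tolerance = 1e-9)
})
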