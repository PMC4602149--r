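test_that("normalization min-max scales open-range columns and passes intrinsic ones", {
  params <- tibble::tibble(cell_id = 1:3, bias_index = c(-0.5, 0, 1),
                           latency_s = c(0.1, 0.3, 0.5),
                           transience = c(0.2, 0.5, 0.9),
                           ds_index = c(0, 0.3, 0.7),
                           speed_index = c(0.2, 0.4, 0.9))
  nm <- normalize_parameters(params)
  expect_equal(nm$latency_s, c(0, 0.5, 1))
  expect_equal(nm$bias_index, params$bias_index)
  expect_equal(nm$transience, params$transience)
  # idempotence: re-normalizing a normalized matrix is the identity
  nm2 <- normalize_parameters(dplyr::mutate(nm, cell_id = 1:3))
  expect_equal(as.data.frame(nm2), as.data.frame(nm), ignore_attr = TRUE)
  # constant column scaled to 0 with a warning
  params$latency_s <- 0.2
  expect_warning(nm3 <- normalize_parameters(params), "constant")
  expect_true(all(nm3$latency_s == 0))
})

test_that("silhouette: separated pairs near 1, random labels near 0", {
  x <- rbind(matrix(rnorm(10, sd = 0.01), 5, 2),
             matrix(rnorm(10, sd = 0.01) + 50, 5, 2))
  expect_gt(silhouette_mean(x, rep(1:2, each = 5)), 0.95)
  set.seed(2)
  y <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(silhouette_mean(y, sample(1:3, 500, replace = TRUE))), 0.1)
  expect_error(silhouette_mean(y, rep(1, 500)), "single cluster")
})

test_that("silhouette equals the brute-force oracle on random instances", {
  set.seed(31)
  worst <- 0
  for (rep in 1:25) {
    n <- sample(6:50, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    labels <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    worst <- max(worst, abs(silhouette_mean(x, labels) -
                              silhouette_brute(x, labels)))
  }
  expect_lt(worst, 1e-12)
})

test_that("silhouette agrees with the cluster package implementation", {
  set.seed(5)
  x <- matrix(rnorm(120), 40, 3)
  labels <- sample(1:3, 40, replace = TRUE)
  ours <- silhouette_mean(x, labels)
  ref <- mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("sweep_k finds planted cluster counts and improves with restarts", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60, sd = 0.05), 30, 2),
             matrix(rnorm(60, sd = 0.05) + 3, 30, 2),
             matrix(rnorm(60, sd = 0.05) + c(6, 0), 30, 2))
  model <- sweep_k(x, k_range = 2:6, restarts = 10, seed = 1)
  expect_equal(model$k, 3)
  expect_true(all(tabulate(model$labels, 3) > 0))
  # best-of-restarts objective is non-increasing in the restart budget
  set.seed(9)
  hard <- matrix(rnorm(400), 100, 4)
  o1 <- rgctyper:::with_seed(7, rgctyper:::kmeans_best(hard, 8, 1))$tot.withinss
  o50 <- rgctyper:::with_seed(7, rgctyper:::kmeans_best(hard, 8, 50))$tot.withinss
  expect_lte(o50, o1)
  expect_warning(sweep_k(x[1:5, ], k_range = 2:10, restarts = 2, seed = 1),
                 "skipping")
})

test_that("fisher separation matches its definition and invariances", {
  # 1-D groups at 0 and 4 with unit projection SDs
  g1 <- c(-1.5, -0.5, 0.5, 1.5) / stats::sd(c(-1.5, -0.5, 0.5, 1.5))
  x <- matrix(c(g1, g1 + 4), ncol = 1)
  labels <- rep(1:2, each = 4)
  expect_equal(as.numeric(fisher_separation(x, labels, c(1, 2))), 4,
               tolerance = 1e-9)
  # identical groups: zero separation
  x2 <- matrix(rep(g1, 2), ncol = 1)
  expect_equal(as.numeric(fisher_separation(x2, labels, c(1, 2))), 0)
  # two 5-D Gaussians with means 3 sigma apart: separation close to 3
  set.seed(12)
  a <- matrix(rnorm(200 * 5), 200, 5)
  b <- matrix(rnorm(200 * 5), 200, 5); b[, 1] <- b[, 1] + 3
  xx <- rbind(a, b); ll <- rep(1:2, each = 200)
  sep <- as.numeric(fisher_separation(xx, ll, c(1, 2)))
  expect_lt(abs(sep - 3) / 3, 0.1)
  # symmetry, translation and rotation invariance
  expect_equal(as.numeric(fisher_separation(xx, ll, c(2, 1))), sep)
  expect_equal(as.numeric(fisher_separation(xx + 7, ll, c(1, 2))), sep)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(as.numeric(fisher_separation(xx %*% q, ll, c(1, 2))), sep,
               tolerance = 1e-9)
  # degenerate projections: capped sentinel
  x0 <- matrix(rep(c(0, 4), each = 3), ncol = 1)
  expect_equal(as.numeric(fisher_separation(x0, rep(1:2, each = 3), c(1, 2))),
               1e6)
  m <- separation_matrix(xx, ll)
  expect_equal(m[1, 2], m[2, 1])
  expect_equal(diag(m), c(`1` = 0, `2` = 0))
})

test_that("group characteristics suggest sensible type labels", {
  params <- tibble::tibble(
    bias_index = c(rep(0.9, 5), rep(-0.9, 5), rep(0.05, 5)),
    latency_s = c(rep(0.12, 5), rep(0.3, 5), rep(0.12, 5)),
    transience = c(rep(0.15, 5), rep(0.4, 5), rep(0.15, 5)),
    rf_diameter_um = 270, ds_index = c(rep(0.6, 5), rep(0.05, 10)),
    speed_index = 0.5, width_index = 0.4
  )
  labels <- rep(1:3, each = 5)
  g <- group_characteristics(params, labels)
  expect_match(g$suggested_label[1], "^ON DS")
  expect_match(g$suggested_label[2], "^OFF")
  expect_match(g$suggested_label[3], "^ON-OFF")
  # median-split labels are invariant to monotone latency rescaling
  g2 <- group_characteristics(dplyr::mutate(params, latency_s = latency_s^2),
                              labels)
  expect_equal(grepl("brisk", g2$suggested_label),
               grepl("brisk", g$suggested_label))
})

test_that("tiling report: exact tiling gives full coverage and zero overlap", {
  # four circles of radius 50 centred on a 2x2 lattice cover the inscribed
  # squares; use a rect inside the union
  params <- tibble::tibble(rf_x = c(50, 150, 50, 150), rf_y = c(50, 50, 150, 150),
                           rf_diameter_um = 100 * sqrt(2))
  rep1 <- tiling_report(params, rep(1, 4), rect = c(20, 180, 20, 180))
  expect_gt(rep1$coverage, 0.99)
  expect_lt(rep1$mean_overlap, 0.1)
  # single cell: overlap reported 0 and flagged undefined
  rep2 <- tiling_report(params[1, ], 1, rect = c(0, 100, 0, 100))
  expect_equal(rep2$mean_overlap, 0)
  expect_false(rep2$overlap_defined)
})

test_that("polar summary counts planted direction lobes", {
  planted3 <- rep(c(10, 130, 250), each = 20) + rep(seq(-4, 4, length.out = 20), 3)
  s3 <- ds_polar_summary(planted3)
  expect_equal(s3$n_modes, 3)
  expect_false(s3$inconclusive)
  planted4 <- rep(c(0, 90, 180, 270), each = 15) + rep(seq(-4, 4, length.out = 15), 4)
  expect_equal(ds_polar_summary(planted4)$n_modes, 4)
  # near-uniform directions: flagged inconclusive
  expect_true(ds_polar_summary(seq(0, 359, by = 3))$inconclusive)
})

test_that("archetype recovery: clustering the default population is pure and k = 7", {
  protocols <- stimulus_protocols(seed = 0)
  pop <- sample_population(n_per_archetype = 25, seed = 61)
  params <- responsiveness_filter(expected_parameters(pop, protocols))
  expect_gt(nrow(params), 160)
  model <- cluster_cells(params, k_range = 4:12, restarts = 100, seed = 3)
  expect_equal(model$k, 7)
  # majority-matching purity of clusters against generating archetypes
  arch <- params$archetype
  purity <- sum(vapply(seq_len(model$k), function(cl) {
    max(table(arch[model$labels == cl]))
  }, numeric(1))) / length(arch)
  expect_gte(purity, 0.9)
  # broom-style accessors
  expect_equal(nrow(tidy(model)), 7)
  expect_equal(glance(model)$k, 7)
  aug <- augment(model)
  expect_equal(nrow(aug), nrow(params))
  expect_true(".cluster" %in% names(aug))
})
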