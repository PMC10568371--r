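test_that("window selection: white noise gives the floor of 2", {
  set.seed(21)
  ss <- spectrum_set(1:500, matrix(rnorm(5 * 500), nrow = 5))
  k <- suppressMessages(select_window_size(ss))
  expect_equal(as.integer(k), 2L)
})

test_that("window selection on an AR(1) series agrees with a direct PACF", {
  set.seed(22)
  x <- t(replicate(4, ar1_noise(2000, 0.9, 1)))
  ss <- spectrum_set(1:2000, x)
  k <- suppressMessages(select_window_size(ss))
  expect_lte(as.integer(k), 4L)           # PACF cuts off after lag 1
  # the built-in PACF matches a Durbin-Levinson computation
  series <- colMeans(x)
  mine <- as.numeric(stats::pacf(series, lag.max = 10, plot = FALSE)$acf)
  brute <- oracle_pacf(series, 10)
  expect_equal(mine, brute, tolerance = 1e-6)
})

test_that("landscape equals the brute-force pairwise oracle", {
  set.seed(23)
  # 3 x 6 toy with k = 3: mean of 3 pairwise correlations per window
  x <- matrix(rnorm(18), nrow = 3)
  ss <- spectrum_set(1:6, x)
  ls <- correlation_landscape(ss, 3)
  expect_equal(ls$values, oracle_landscape(x, 3), tolerance = 1e-12)
  # random instances up to 50 variables, several window sizes, 1e-10
  for (rep in 1:5) {
    n <- sample(4:12, 1); p <- sample(10:50, 1)
    x <- matrix(rnorm(n * p), nrow = n)
    x[, sample(p, 2)] <- 5               # include zero-variance columns
    k <- sample(2:min(8, p), 1)
    ss <- spectrum_set(seq_len(p), x)
    expect_equal(correlation_landscape(ss, k)$values,
                 oracle_landscape(x, k), tolerance = 1e-10)
  }
})

test_that("landscape limiting cases: identical columns 1, independent noise ~0", {
  set.seed(24)
  v <- rnorm(30)
  same <- spectrum_set(1:5, matrix(rep(v, 5), ncol = 5))
  expect_equal(correlation_landscape(same, 5)$values[1], 1)
  big <- spectrum_set(1:40, matrix(rnorm(500 * 40), ncol = 40))
  vals <- correlation_landscape(big, 5)$values
  expect_lt(max(abs(vals), na.rm = TRUE), 0.1)
  # positions within k-1 of the end are undefined
  expect_true(all(is.na(vals[(40 - 3):40])))
})

test_that("kernel weights match their closed forms", {
  expect_equal(nmrspa:::kernel_weight(0, "epanechnikov"), 0.75)
  expect_equal(nmrspa:::kernel_weight(1, "epanechnikov"), 0)
  expect_equal(nmrspa:::kernel_weight(0.5, "epanechnikov"),
               0.75 * (1 - 0.25))
  expect_equal(nmrspa:::kernel_weight(0, "tricube"), 1)
  expect_equal(nmrspa:::kernel_weight(1, "tricube"), 0)
  expect_equal(nmrspa:::kernel_weight(-0.5, "tricube"), (1 - 0.125)^3)
})

test_that("smoothing preserves constants and stays inside local bounds", {
  ss <- toy_block_spectra()
  ls <- correlation_landscape(ss, 3)
  const <- ls; const$values[!is.na(const$values)] <- 0.6
  sm <- smooth_landscape(const, "tricube", 4)
  expect_equal(sm$values[!is.na(sm$values)],
               rep(0.6, sum(!is.na(sm$values))))
  expect_error(smooth_landscape(ls, "box"), "arg")
  sm2 <- smooth_landscape(ls, "epanechnikov", 3)
  v <- ls$values
  for (i in which(!is.na(sm2$values))) {
    lo <- max(1, i - 2); hi <- min(length(v), i + 2)
    win <- v[lo:hi]
    expect_gte(sm2$values[i], min(win, na.rm = TRUE) - 1e-12)
    expect_lte(sm2$values[i], max(win, na.rm = TRUE) + 1e-12)
  }
})

test_that("cluster extraction is run-length thresholding", {
  ls <- structure(list(values = c(0.9, 0.9, 0.1, 0.9, 0.9),
                       window_size = 2L, kernel = "tricube",
                       smoothed = TRUE, bandwidth = 2,
                       ppm = 1:5),
                  class = "correlation_landscape")
  cs <- extract_clusters(ls, 0.5, min_size = 2)
  expect_equal(cs$clusters$start_idx, c(1L, 4L))
  expect_equal(cs$clusters$end_idx, c(2L, 5L))
  low <- ls; low$values <- rep(0.1, 5)
  expect_equal(nrow(extract_clusters(low, 0.5, 1)$clusters), 0)
})

test_that("every cluster lies above threshold and gaps below, pointwise", {
  ss <- toy_block_spectra(blocks = c(6, 4, 8), gap = 4, seed = 31)
  ls <- smooth_landscape(correlation_landscape(ss, 3), "tricube")
  cs <- extract_clusters(ls, 0.5, min_size = 2)
  lab <- nmrspa:::cluster_labels(cs, cs$p)
  above <- !is.na(ls$values) & ls$values >= 0.5
  runs <- nmrspa:::index_runs(which(above))
  keep <- runs[runs$end_idx - runs$start_idx + 1 >= 2, ]
  expect_equal(sum(lab > 0), sum(keep$end_idx - keep$start_idx + 1))
  for (r in seq_len(nrow(cs$clusters)))
    expect_true(all(above[cs$clusters$start_idx[r]:cs$clusters$end_idx[r]]))
})

test_that("raising lambda only shrinks or splits clusters, never merges", {
  set.seed(32)
  for (rep in 1:100) {
    p <- sample(20:60, 1)
    vals <- runif(p)
    ls <- structure(list(values = vals, window_size = 2L,
                         kernel = "tricube", smoothed = TRUE,
                         bandwidth = 2, ppm = seq_len(p)),
                    class = "correlation_landscape")
    l1 <- runif(1, 0.1, 0.5); l2 <- runif(1, l1 + 1e-6, 0.95)
    c1 <- nmrspa:::cluster_labels(extract_clusters(ls, l1, 1), p)
    c2 <- nmrspa:::cluster_labels(extract_clusters(ls, l2, 1), p)
    # every high-threshold cluster is contained in one low-threshold cluster
    for (id in setdiff(unique(c2), 0L)) {
      parents <- unique(c1[c2 == id])
      expect_length(parents, 1)
      expect_true(all(parents != 0L))
    }
  }
})

test_that("prediction strength matches the exhaustive pair oracle", {
  # <= 12 variables, hand-enumerable co-membership
  scored <- structure(list(
    clusters = data.frame(cluster_id = 1:2,
                          start_idx = c(1L, 7L), end_idx = c(5L, 10L),
                          start_ppm = c(1, 7), end_ppm = c(5, 10),
                          n_points = c(5L, 4L)),
    ppm = 1:12, p = 12L), class = "cluster_set")
  # other half clusters with one boundary disagreement
  labels_other <- c(1L, 1L, 1L, 1L, 0L, 0L, 2L, 2L, 2L, 0L, 0L, 0L)
  got <- nmrspa:::pd_one_direction(scored, labels_other)
  want <- oracle_pd(data.frame(start = c(1, 7), end = c(5, 10)),
                    labels_other, 12)
  expect_equal(got, want)
  # identical clusterings give 1, all-singleton opposition gives 0
  expect_equal(nmrspa:::pd_one_direction(
    scored, c(1L, 1L, 1L, 1L, 1L, 0L, 2L, 2L, 2L, 2L, 0L, 0L)), 1)
  expect_equal(nmrspa:::pd_one_direction(scored, rep(0L, 12)), 0)
  # random instances against the oracle, to 1e-10
  set.seed(33)
  for (rep in 1:20) {
    p <- sample(8:50, 1)
    st <- sort(sample(seq_len(p - 3), 2))
    cl <- data.frame(cluster_id = 1:2,
                     start_idx = c(st[1], st[2] + 2L),
                     end_idx = c(st[2], min(p, st[2] + 3L)))
    cl <- cl[cl$start_idx <= cl$end_idx, ]
    cl$n_points <- cl$end_idx - cl$start_idx + 1L
    sc <- structure(list(clusters = cbind(cl, start_ppm = 0, end_ppm = 0),
                         ppm = seq_len(p), p = p), class = "cluster_set")
    lab <- sample(0:3, p, replace = TRUE)
    expect_equal(nmrspa:::pd_one_direction(sc, lab),
                 oracle_pd(data.frame(start = cl$start_idx,
                                      end = cl$end_idx), lab, p),
                 tolerance = 1e-10)
  }
})

test_that("prediction strength is 1 for stable block structure", {
  ss <- toy_block_spectra(n = 40, blocks = c(8, 8), gap = 5,
                          seed = 34, noise = 0.01)
  ps <- prediction_strength(ss, lambda = 0.6, k = 3, n_folds = 3,
                            seed = 99)
  expect_equal(ps$mean, 1)
  expect_equal(ps$se, 0)
})

test_that("one-SE threshold selection follows the stated rule", {
  ss <- toy_block_spectra(n = 40, blocks = c(8, 8), gap = 5,
                          seed = 35, noise = 0.01)
  # flat prediction strength: the smallest grid value is chosen
  res <- select_threshold(ss, lambda_grid = c(0.4, 0.6, 0.8), k = 3,
                          n_folds = 3, seed = 7)
  expect_equal(res$chosen_lambda, 0.4)
  expect_true(all(res$mean_strength >= 0 & res$mean_strength <= 1))
  # chosen lambda is the smallest within one SE of the max, by construction
  i_max <- which.max(res$mean_strength)
  ok <- res$lambda_grid[res$mean_strength >=
                          res$mean_strength[i_max] - res$se_strength[i_max]]
  expect_equal(res$chosen_lambda, min(ok))
  # all-zero strengths are rejected
  flat <- spectrum_set(1:100, matrix(rnorm(100 * 8), nrow = 8))
  expect_error(select_threshold(flat, lambda_grid = 0.99, k = 2,
                                min_size = 50, n_folds = 2, seed = 1),
               "no stable clustering")
})

test_that("automatic threshold recovers near-oracle coverage on simulation", {
  cfg <- simulation_config(L = 10, n = 50, seed = 77)
  ref <- build_reference_spectra(cfg)
  sim <- simulate_spectra(cfg, ref)
  sp <- baseline_zero(sim$observed, c(0.5, 0.65), 5)$spectra
  fit <- suppressMessages(spa(sp, seed = 177))
  truth_cov <- score_coverage(fit$clusters, ref)
  # oracle: best grid lambda by exhaustive evaluation against ground truth
  ls <- fit$landscape
  grid <- seq(0.30, 0.95, by = 0.05)
  best <- max(vapply(grid, function(l)
    score_coverage(extract_clusters(ls, l, fit$k), ref)$true_coverage,
    numeric(1)))
  expect_gte(truth_cov$true_coverage, 0.95 * best)
})
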