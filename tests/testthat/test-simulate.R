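test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(rho = 1), "rho")
  expect_error(simulation_config(gamma = 0), "gamma")
  bad <- diag(2); bad[1, 2] <- bad[2, 1] <- 1.5   # not PSD
  expect_error(simulation_config(L = 2, sigma_matrix = bad),
               "positive semi-definite")
  off <- diag(2); off[1, 1] <- 2
  expect_error(simulation_config(L = 2, sigma_matrix = off),
               "unit diagonal")
})

test_that("reference builder: degenerate singlet, determinism, row scaling", {
  cfg1 <- simulation_config(L = 1, p = 500, seed = 5)
  ref1 <- build_reference_spectra(cfg1, clusters_per_metabolite = 1,
                                  multiplicity_probs = c(1, 0, 0),
                                  linewidth = 0.01)
  expect_equal(nrow(ref1$M), 1)
  expect_equal(max(ref1$M), 1)
  runs <- nmrspa:::index_runs(ref1$true_regions[[1]])
  expect_equal(nrow(runs), 1)          # one contiguous support region

  cfg <- simulation_config(L = 10, seed = 11)
  a <- build_reference_spectra(cfg)
  b <- build_reference_spectra(cfg)
  expect_identical(a$M, b$M)           # bit-identical under fixed seed
  expect_identical(a$library$clusters, b$library$clusters)

  cfg50 <- simulation_config(L = 50, seed = 2)
  ref50 <- build_reference_spectra(cfg50)
  expect_equal(nrow(ref50$M), 50)
  expect_equal(unname(apply(ref50$M, 1, max)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(ref50$M >= 0 & ref50$M <= 1))
  expect_true(all(lengths(ref50$true_regions) > 0))
})

test_that("reference builder rejects an unresolvable linewidth", {
  cfg <- simulation_config(L = 1, p = 50)   # 0.07 ppm grid step
  expect_error(build_reference_spectra(cfg, linewidth = 0.0015),
               "resolve")
})

test_that("no variation and no noise gives identical spectra alpha^T M", {
  cfg <- simulation_config(L = 3, n = 5, p = 800, phi = 0, noise_sd = 0,
                           seed = 9)
  ref <- build_reference_spectra(cfg, linewidth = 0.006)
  sim <- simulate_spectra(cfg, ref)
  obs <- sim$observed$intensities
  for (i in 2:5) expect_equal(obs[i, ], obs[1, ], ignore_attr = TRUE)
  expect_equal(obs[1, ], as.numeric(sim$alpha %*% ref$M),
               ignore_attr = TRUE)
  expect_equal(obs, sim$signal$intensities)
})

test_that("concentration law has chi-squared(gamma) moments", {
  # chi-squared(60) has mean 60 and variance 120; check the pooled draws
  # of alpha over many replicates within 3 standard errors
  alphas <- unlist(lapply(1:20, function(s) {
    cfg <- simulation_config(L = 50, n = 2, p = 700, ppm_min = 0,
                             ppm_max = 1, seed = s)
    ref <- build_reference_spectra(cfg, clusters_per_metabolite = 1)
    simulate_spectra(cfg, ref)$alpha
  }))
  n <- length(alphas)
  se_mean <- sqrt(120 / n)
  expect_lt(abs(mean(alphas) - 60), 3 * se_mean)
  se_var <- sqrt(2 * 120^2 / (n - 1))   # approx SE of sample variance
  expect_lt(abs(stats::var(alphas) - 120), 3 * se_var)
})

test_that("noise generator is stationary AR(1) with the requested rho", {
  x <- ar1_noise(2e5, rho = 0.9, sd = 1, seed = 123)
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(r1 - 0.9), 0.01)
  expect_lt(abs(stats::sd(x) - 1), 0.02)
  # per-sample fitted lag-1 coefficient within 3 SE of rho for p >= 3000
  cfg <- simulation_config(L = 2, n = 4, p = 3500, seed = 31)
  ref <- build_reference_spectra(cfg)
  sim <- simulate_spectra(cfg, ref)
  noise <- sim$observed$intensities - sim$signal$intensities
  for (i in 1:4) {
    fit <- stats::ar(noise[i, ], order.max = 1, aic = FALSE, method = "ols")
    se <- sqrt((1 - 0.9^2) / 3500)
    expect_lt(abs(fit$ar[1] - 0.9), 3 * se)
  }
})

test_that("with phi=0 column covariance reduces to the noise covariance", {
  # no per-sample variation: the signal is constant across samples, so the
  # covariance between any two columns equals that of the noise alone
  covs <- replicate(30, {
    cfg <- simulation_config(L = 2, n = 40, p = 400, phi = 0,
                             seed = sample.int(1e6, 1))
    ref <- build_reference_spectra(cfg, clusters_per_metabolite = 1,
                                   linewidth = 0.01)
    sim <- simulate_spectra(cfg, ref)
    i1 <- ref$true_regions[[1]][1]; i2 <- ref$true_regions[[2]][1]
    noise <- sim$observed$intensities - sim$signal$intensities
    c(stats::cov(sim$observed$intensities[, i1],
                 sim$observed$intensities[, i2]),
      stats::cov(noise[, i1], noise[, i2]))
  })
  expect_equal(covs[1, ], covs[2, ], tolerance = 1e-10)
  expect_lt(abs(mean(covs[1, ])), 0.2)   # noise cov at long lag is ~0
})

test_that("empirical SNR behaves like a variance ratio", {
  sig <- matrix(0, 4, 100)
  noise <- matrix(rnorm(400), 4)
  expect_equal(compute_snr(sig, noise), 0)
  sig2 <- matrix(rnorm(400, sd = 3), 4)
  expect_equal(compute_snr(sig2, 2 * noise),
               compute_snr(sig2, noise) / 4)
  expect_error(compute_snr(sig2, matrix(1, 4, 100)), "zero")
  # larger phi gives strictly larger SNR (Monte-Carlo over replicates)
  snr_at <- function(phi, s) {
    cfg <- simulation_config(L = 10, n = 50, p = 600, phi = phi, seed = s)
    ref <- build_reference_spectra(cfg, linewidth = 0.006)
    compute_snr(simulate_spectra(cfg, ref))
  }
  s12 <- vapply(1:20, function(s) snr_at(12, s), numeric(1))
  s25 <- vapply(1:20, function(s) snr_at(25, s), numeric(1))
  expect_gt(mean(s25), mean(s12))
})

test_that("ground-truth sidecar file is written and readable", {
  cfg <- simulation_config(L = 3, p = 700, seed = 4)
  ref <- build_reference_spectra(cfg, linewidth = 0.0075)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(ref, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# peaks", lines)))
  expect_true(any(grepl("^# true_regions", lines)))
})
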