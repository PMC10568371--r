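#' Simulation scenario configuration
#'
#' Collects the parameters of the spectrum simulation model. Each observed
#' spectrum is `y_i(f) = S_i(f) + N_i(f)`, where the signal matrix is
#' `S = (H %*% Sigma + 1 %*% t(alpha)) %*% M`: `M` holds per-metabolite
#' reference spectra scaled to maximum 1, `alpha` (one draw per dataset) are
#' chi-squared(`gamma`) population mean concentrations, `H` is i.i.d.
#' `N(0, phi^2)` per-sample metabolite variation, and the noise `N_i` is a
#' stationary AR(1) sequence along the ppm axis.
#'
#' @param L Number of metabolites (>= 1).
#' @param n Number of samples (>= 2).
#' @param p Number of datapoints on the uniform ppm grid (default 3500 over
#'   0.5-4.0 ppm, i.e. 0.001 ppm per point).
#' @param ppm_min,ppm_max Chemical-shift bounds (ppm).
#' @param gamma Degrees of freedom of the chi-squared concentration law
#'   (default 60).
#' @param phi Standard deviation of the per-sample metabolite variation
#'   (default 12, concentration units).
#' @param rho AR(1) coefficient of the noise, `|rho| < 1` (default 0.9).
#' @param sigma_matrix `L x L` metabolite correlation matrix (default
#'   identity); must be symmetric positive semi-definite with unit diagonal.
#' @param noise_sd Stationary standard deviation of the noise process
#'   (intensity units, default 1). The innovation SD is derived as
#'   `noise_sd * sqrt(1 - rho^2)`.
#' @param seed RNG seed used by [build_reference_spectra()] and (offset by
#'   one) [simulate_spectra()].
#'
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(L = 10, n = 50, p = 3500,
                              ppm_min = 0.5, ppm_max = 4.0,
                              gamma = 60, phi = 12, rho = 0.9,
                              sigma_matrix = NULL, noise_sd = 1,
                              seed = 1L) {
  stopifnot(L >= 1, n >= 2, p >= 2, ppm_min < ppm_max,
            gamma > 0, phi >= 0, abs(rho) < 1, noise_sd >= 0)
  if (is.null(sigma_matrix)) sigma_matrix <- diag(L)
  sigma_matrix <- as.matrix(sigma_matrix)
  if (!isTRUE(all.equal(dim(sigma_matrix), c(L, L))))
    stop("sigma_matrix must be ", L, " x ", L)
  if (!isSymmetric(unname(sigma_matrix), tol = 1e-8))
    stop("sigma_matrix must be symmetric")
  if (max(abs(diag(sigma_matrix) - 1)) > 1e-8)
    stop("sigma_matrix must have unit diagonal")
  ev <- eigen(sigma_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("sigma_matrix must be positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  structure(list(L = as.integer(L), n = as.integer(n), p = as.integer(p),
                 ppm_min = ppm_min, ppm_max = ppm_max,
                 gamma = gamma, phi = phi, rho = rho,
                 sigma_matrix = sigma_matrix, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> L=%d n=%d p=%d  %.2f-%.2f ppm\n",
                     "  gamma=%g phi=%g rho=%g noise_sd=%g seed=%d\n"),
              x$L, x$n, x$p, x$ppm_min, x$ppm_max,
              x$gamma, x$phi, x$rho, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a stationary AR(1) noise sequence
#'
#' Draws `x[1]` from the stationary law `N(0, sd^2)` and recurses
#' `x[t] = rho * x[t-1] + e[t]` with innovation SD `sd * sqrt(1 - rho^2)`,
#' so the whole sequence is exactly stationary with marginal SD `sd` and
#' lag-1 autocorrelation `rho`.
#'
#' @param p Sequence length.
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @param sd Stationary standard deviation.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `p`.
#' @export
ar1_noise <- function(p, rho = 0.9, sd = 1, seed = NULL) {
  stopifnot(p >= 1, abs(rho) < 1, sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(numeric(p))
  x0 <- stats::rnorm(1, 0, sd)
  e <- stats::rnorm(p, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive", init = x0))
}

## Lorentzian / Gaussian line shapes, unit height at the centre.
## hw is the half-width at half-maximum in ppm.
line_shape <- function(ppm, center, hw, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (shape == "lorentzian") {
    hw^2 / ((ppm - center)^2 + hw^2)
  } else {
    exp(-log(2) * ((ppm - center) / hw)^2)
  }
}

#' Build a synthetic metabolite reference-spectrum matrix
#'
#' Synthesizes the `L x p` matrix `M` of per-metabolite reference spectra
#' with realistic multiplet structure: each metabolite resonates in 1-9
#' clusters placed at random positions within the ppm range, each cluster a
#' singlet, doublet or triplet of Lorentzian (or Gaussian) lines. Every row
#' is scaled to a maximum of exactly 1. The true peak positions per cluster
#' are recorded so a matching ground-truth [metabolite_library()] can be
#' emitted, and the support of each metabolite (`true_regions`) is taken as
#' the datapoints where its reference intensity exceeds
#' `support_threshold` times the row maximum.
#'
#' @param config A [simulation_config()].
#' @param clusters_per_metabolite Integer vector of admissible cluster
#'   counts per metabolite (sampled uniformly; default `1:9`).
#' @param multiplicity_probs Probabilities of a cluster being a singlet,
#'   doublet or triplet (default `c(0.4, 0.35, 0.25)`).
#' @param linewidth Half-width at half-maximum of each line, in ppm
#'   (default 0.0015, i.e. 1.2 Hz at 800 MHz).
#' @param j_spacing_range Range (ppm) of the within-multiplet peak spacing
#'   (default `c(0.008, 0.015)`, ~6-12 Hz at 800 MHz).
#' @param shape `"lorentzian"` (default) or `"gaussian"` line shape.
#' @param support_threshold Fraction of the row maximum defining the true
#'   signal support (default 0.01).
#' @param seed RNG seed; defaults to `config$seed`.
#'
#' @return An object of class `"reference_spectra"`: list with `ppm`,
#'   `M` (`L x p`, row maxima exactly 1), `metabolite_names`,
#'   `true_regions` (list of integer index vectors), `library` (a
#'   [metabolite_library()] of the true cluster peak positions) and
#'   `support_threshold`.
#' @export
build_reference_spectra <- function(config,
                                    clusters_per_metabolite = 1:9,
                                    multiplicity_probs = c(0.4, 0.35, 0.25),
                                    linewidth = 0.0015,
                                    j_spacing_range = c(0.008, 0.015),
                                    shape = c("lorentzian", "gaussian"),
                                    support_threshold = 0.01,
                                    seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"),
            all(clusters_per_metabolite >= 1), linewidth > 0,
            length(multiplicity_probs) == 3, all(multiplicity_probs >= 0))
  shape <- match.arg(shape)
  ppm <- seq(config$ppm_min, config$ppm_max, length.out = config$p)
  dx <- ppm[2] - ppm[1]
  if (dx > linewidth)
    stop("grid too coarse to resolve linewidth: step ", format(dx),
         " ppm > half-width ", format(linewidth), " ppm; increase p")
  if (!is.null(seed)) set.seed(seed)
  L <- config$L
  margin <- 0.05 * (config$ppm_max - config$ppm_min)
  names <- sprintf("M%02d", seq_len(L))
  M <- matrix(0, L, config$p, dimnames = list(names, NULL))
  lib_rows <- list()
  for (l in seq_len(L)) {
    n_clust <- if (length(clusters_per_metabolite) == 1L)
      clusters_per_metabolite else sample(clusters_per_metabolite, 1)
    centers <- stats::runif(n_clust, config$ppm_min + margin,
                            config$ppm_max - margin)
    amps <- stats::runif(n_clust, 0.3, 1)
    row <- numeric(config$p)
    for (cl in seq_len(n_clust)) {
      mult <- sample(1:3, 1, prob = multiplicity_probs)
      jsp <- stats::runif(1, j_spacing_range[1], j_spacing_range[2])
      offsets <- switch(mult, 0, c(-0.5, 0.5) * jsp, c(-1, 0, 1) * jsp)
      heights <- switch(mult, 1, c(1, 1), c(0.5, 1, 0.5))
      pk_ppm <- centers[cl] + offsets
      for (q in seq_along(pk_ppm))
        row <- row + amps[cl] * heights[q] *
          line_shape(ppm, pk_ppm[q], linewidth, shape)
      lib_rows[[length(lib_rows) + 1L]] <-
        data.frame(metabolite = names[l],
                   cluster_id = sprintf("%s_c%d", names[l], cl),
                   peak_ppm = pk_ppm)
    }
    M[l, ] <- row / max(row)
  }
  true_regions <- lapply(seq_len(L),
                         function(l) which(M[l, ] > support_threshold))
  names(true_regions) <- names
  lib <- metabolite_library(do.call(rbind, lib_rows),
                            ppm_window = c(config$ppm_min, config$ppm_max))
  structure(list(ppm = ppm, M = M, metabolite_names = names,
                 true_regions = true_regions, library = lib,
                 support_threshold = support_threshold),
            class = "reference_spectra")
}

#' @export
print.reference_spectra <- function(x, ...) {
  cat(sprintf("<reference_spectra> %d metabolites x %d datapoints, %d library clusters\n",
              nrow(x$M), ncol(x$M),
              length(unique(paste(x$library$clusters$metabolite,
                                  x$library$clusters$cluster_id)))))
  invisible(x)
}

#' Simulate a set of NMR spectra
#'
#' Draws `alpha ~ chi-squared(gamma)` once (population mean concentrations,
#' shared across samples through the `1 %*% t(alpha)` term), per-sample
#' variation `H ~ N(0, phi^2)`, forms the signal
#' `S = (H %*% Sigma + 1 %*% t(alpha)) %*% M`, and adds an independent
#' stationary AR(1) noise sequence along the ppm axis of each sample.
#'
#' @param config A [simulation_config()].
#' @param ref A [build_reference_spectra()] result on the same grid.
#' @param seed RNG seed; defaults to `config$seed + 1` so that reference
#'   building and spectrum generation use distinct streams.
#' @return An object of class `"nmr_simulation"`: list with `observed` and
#'   `signal` ([spectrum_set()]s), `concentrations` (the realized `n x L`
#'   matrix `H %*% Sigma + 1 %*% t(alpha)`), `alpha`, `ref` and `config`.
#' @export
simulate_spectra <- function(config, ref = build_reference_spectra(config),
                             seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ref, "reference_spectra"))
  if (length(ref$ppm) != config$p)
    stop("reference grid has ", length(ref$ppm),
         " points but config$p = ", config$p)
  if (!is.null(seed)) set.seed(seed)
  L <- config$L; n <- config$n; p <- config$p
  alpha <- stats::rchisq(L, df = config$gamma)
  H <- matrix(stats::rnorm(n * L, 0, config$phi), n, L)
  conc <- H %*% config$sigma_matrix +
    matrix(alpha, n, L, byrow = TRUE)
  S <- conc %*% ref$M
  noise <- t(vapply(seq_len(n),
                    function(i) ar1_noise(p, config$rho, config$noise_sd),
                    numeric(p)))
  ids <- sprintf("S%03d", seq_len(n))
  structure(list(observed = spectrum_set(ref$ppm, S + noise, ids),
                 signal = spectrum_set(ref$ppm, S, ids),
                 concentrations = conc, alpha = alpha,
                 ref = ref, config = config),
            class = "nmr_simulation")
}

#' @export
print.nmr_simulation <- function(x, ...) {
  cat(sprintf("<nmr_simulation> %d samples x %d datapoints, L=%d, SNR=%.1f\n",
              x$config$n, x$config$p, x$config$L, compute_snr(x)))
  invisible(x)
}

#' Empirical signal-to-noise ratio of a simulation
#'
#' Variance of the signal component divided by the variance of the noise
#' component, both taken over all `n x p` matrix entries.
#'
#' @param signal An `"nmr_simulation"` object, or the signal matrix.
#' @param noise The noise matrix (ignored when `signal` is a simulation,
#'   in which case `observed - signal` is used).
#' @return Nonnegative scalar.
#' @export
compute_snr <- function(signal, noise = NULL) {
  if (inherits(signal, "nmr_simulation")) {
    noise <- signal$observed$intensities - signal$signal$intensities
    signal <- signal$signal$intensities
  }
  if (is.null(noise)) stop("noise matrix required")
  vn <- stats::var(as.vector(noise))
  if (!is.finite(vn) || vn == 0)
    stop("noise variance is zero; SNR undefined")
  stats::var(as.vector(signal)) / vn
}

#' Write simulation ground truth as a sidecar file
#'
#' Emits one delimited-text file holding, per metabolite cluster, the true
#' peak ppm positions, and per metabolite the true-region index ranges.
#'
#' @param ref A [build_reference_spectra()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ref, path) {
  stopifnot(inherits(ref, "reference_spectra"))
  lib <- ref$library$clusters
  runs <- lapply(ref$metabolite_names, function(nm) {
    idx <- ref$true_regions[[nm]]
    r <- index_runs(idx)
    if (nrow(r)) cbind(metabolite = nm, r) else NULL
  })
  runs <- do.call(rbind, runs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# peaks: metabolite,cluster_id,peak_ppm", con)
  utils::write.table(lib, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  writeLines("# true_regions: metabolite,start_idx,end_idx", con)
  utils::write.table(runs, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

## maximal runs of consecutive integers -> data.frame(start_idx, end_idx)
index_runs <- function(idx) {
  if (!length(idx)) return(data.frame(start_idx = integer(),
                                      end_idx = integer()))
  idx <- sort(unique(as.integer(idx)))
  brk <- which(diff(idx) > 1L)
  data.frame(start_idx = idx[c(1L, brk + 1L)],
             end_idx = idx[c(brk, length(idx))])
}
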