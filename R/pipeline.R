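#' Run the full identification pipeline
#'
#' Chains the stages end to end: optional preprocessing (probabilistic
#' quotient normalization, baseline zeroing), spatial clustering with
#' automatic window-size and threshold selection, STOCSY grouping of the
#' cluster representative intensities, and library matching. All automatic
#' choices (window size `k`, landscape threshold `lambda`, STOCSY
#' threshold) are recorded in the returned provenance so they can be
#' audited, and a fixed `seed` makes the run fully reproducible.
#'
#' @param spectra A [spectrum_set()] or a path readable by
#'   [read_spectra()].
#' @param library A [metabolite_library()] or a path readable by
#'   [read_metabolite_library()].
#' @param pqn Apply PQN (default `FALSE`; simulated spectra carry no
#'   dilution factor).
#' @param noise_region Optional ppm interval for [baseline_zero()]; `NULL`
#'   skips baseline zeroing.
#' @param baseline_k Baseline multiplier (default 5).
#' @param k,lambda Window size and landscape threshold; `NULL` selects them
#'   automatically (PACF / prediction strength).
#' @param kernel Smoothing kernel (default tricube).
#' @param min_size Minimum cluster size; defaults to `k`.
#' @param lambda_grid,n_folds Prediction-strength search settings.
#' @param stocsy_threshold STOCSY grouping threshold (default 0.8), or
#'   `"auto"` to calibrate on a reference compound (the correlation level
#'   at which all its resonances are captured in one group).
#' @param reference_metabolite Library name of the calibration reference
#'   compound (internal standard or a known abundant metabolite); its
#'   spatial clusters are located with [find_reference_clusters()].
#' @param reference_cluster_ids Alternatively, explicit spatial cluster ids
#'   of the calibration reference.
#' @param tolerance,detection_threshold,singlet_filter Matching settings,
#'   see [match_metabolites()].
#' @param seed RNG seed for the prediction-strength fold splits.
#' @param out_dir Optional directory; when given, all stage outputs
#'   (clusters, correlation matrix, groups, report, unannotated candidates,
#'   provenance) are written there as delimited text.
#' @return An object of class `"nmrspa_pipeline"`: list with `report`
#'   ([match_metabolites()]), `spa` ([spa()]), `groups`
#'   ([group_clusters()]), `intensities`, `peaks`, `spectra` (as analyzed)
#'   and `provenance`.
#' @export
run_pipeline <- function(spectra, library,
                         pqn = FALSE, noise_region = NULL, baseline_k = 5,
                         k = NULL, lambda = NULL,
                         kernel = c("tricube", "epanechnikov"),
                         min_size = NULL,
                         lambda_grid = seq(0.30, 0.95, by = 0.05),
                         n_folds = 5,
                         stocsy_threshold = 0.8,
                         reference_metabolite = NULL,
                         reference_cluster_ids = NULL,
                         tolerance = 0.025, detection_threshold = 0.55,
                         singlet_filter = TRUE,
                         seed = NULL, out_dir = NULL) {
  kernel <- match.arg(kernel)
  if (is.character(spectra)) spectra <- read_spectra(spectra)
  if (is.character(library)) library <- read_metabolite_library(library)
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(library, "metabolite_library"))

  if (pqn) spectra <- pqn_normalize(spectra)
  baseline <- NULL
  if (!is.null(noise_region)) {
    bz <- baseline_zero(spectra, noise_region, baseline_k)
    spectra <- bz$spectra
    baseline <- bz$baseline
  }

  fit <- spa(spectra, k = k, lambda = lambda, kernel = kernel,
             min_size = min_size, lambda_grid = lambda_grid,
             n_folds = n_folds, seed = seed)
  if (nrow(fit$clusters$clusters) == 0)
    stop("pipeline stage 'spa': no clusters found at lambda = ",
         format(fit$lambda))

  intens <- cluster_intensities(spectra, fit$clusters)
  corr <- stocsy_correlate(intens)
  if (identical(stocsy_threshold, "auto")) {
    if (is.null(reference_cluster_ids) && !is.null(reference_metabolite))
      reference_cluster_ids <- find_reference_clusters(fit$clusters, library,
                                                       reference_metabolite)
    if (length(reference_cluster_ids) >= 2) {
      stocsy_threshold <- tryCatch(
        calibrate_threshold(corr, reference_cluster_ids),
        error = function(e) {
          warning("STOCSY calibration failed (", conditionMessage(e),
                  "); falling back to 0.8")
          0.8
        })
    } else {
      warning("fewer than 2 reference clusters located; ",
              "using default STOCSY threshold 0.8")
      stocsy_threshold <- 0.8
    }
  }
  groups <- group_clusters(corr, stocsy_threshold)

  peaks <- detect_cluster_peaks(spectra, fit$clusters)
  report <- match_metabolites(groups, peaks, library,
                              tolerance = tolerance,
                              detection_threshold = detection_threshold,
                              singlet_filter = singlet_filter)

  prov <- list(package_version = as.character(utils::packageVersion("nmrspa")),
               n_samples = nrow(spectra$intensities),
               n_datapoints = length(spectra$ppm),
               pqn = pqn, baseline = baseline,
               k = fit$k, lambda = fit$lambda, kernel = kernel,
               min_size = fit$params$min_size, n_folds = n_folds,
               stocsy_threshold = stocsy_threshold,
               tolerance = tolerance,
               detection_threshold = detection_threshold,
               singlet_filter = singlet_filter, seed = seed)

  out <- structure(list(report = report, spa = fit, groups = groups,
                        intensities = intens, peaks = peaks,
                        spectra = spectra, provenance = prov),
                   class = "nmrspa_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.nmrspa_pipeline <- function(x, ...) {
  cat(sprintf("<nmrspa_pipeline> k=%d lambda=%.2f stocsy=%.2f: %d clusters -> %d groups\n",
              x$provenance$k, x$provenance$lambda,
              x$provenance$stocsy_threshold,
              nrow(x$spa$clusters$clusters), length(x$groups$groups)))
  print(x$report)
  invisible(x)
}

write_pipeline_artifacts <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters(x$spa$clusters, file.path(out_dir, "clusters.csv"))
  utils::write.csv(data.frame(cluster_id = x$groups$cluster_ids,
                              group_id = x$groups$membership),
                   file.path(out_dir, "groups.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(round(x$groups$correlation, 6),
                   file.path(out_dir, "stocsy_correlation.csv"),
                   quote = FALSE)
  write_report(x$report, file.path(out_dir, "report.csv"),
               file.path(out_dir, "unannotated.csv"))
  prov <- x$provenance
  writeLines(paste0(names(prov), "=",
                    vapply(prov, function(v)
                      if (is.null(v)) "" else paste(format(v), collapse = ","),
                      character(1))),
             file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}
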