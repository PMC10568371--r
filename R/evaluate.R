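#' Coverage of simulation ground truth by a clustering
#'
#' Per-datapoint set arithmetic against the simulator's ground truth: the
#' signal set is the union of every metabolite's true resonance region, the
#' noise set its complement. True-signal coverage is the percentage of
#' signal datapoints covered by any cluster; noise coverage the percentage
#' of noise datapoints covered. Under this per-datapoint definition,
#' true coverage is the true-positive rate and noise coverage the
#' false-positive rate, and both are reported under both names.
#'
#' @param clusters A `"cluster_set"` (from [extract_clusters()] or
#'   [srv_cluster()]).
#' @param truth A [build_reference_spectra()] result, or a list of integer
#'   index vectors of true regions on the same grid.
#' @return A list of class `"coverage_result"`: `true_coverage`,
#'   `noise_coverage`, `tpr`, `fpr` (all percentages), `n_true_points`,
#'   `n_noise_points`.
#' @export
score_coverage <- function(clusters, truth) {
  stopifnot(inherits(clusters, "cluster_set"))
  regions <- if (inherits(truth, "reference_spectra"))
    truth$true_regions else truth
  if (!length(regions)) stop("empty ground truth")
  p <- clusters$p
  signal <- logical(p)
  signal[unique(unlist(regions, use.names = FALSE))] <- TRUE
  if (!any(signal)) stop("ground-truth regions are empty")
  covered <- cluster_labels(clusters, p) > 0L
  n_true <- sum(signal); n_noise <- p - n_true
  structure(list(
    true_coverage = 100 * sum(covered & signal) / n_true,
    noise_coverage = if (n_noise > 0)
      100 * sum(covered & !signal) / n_noise else 0,
    tpr = 100 * sum(covered & signal) / n_true,
    fpr = if (n_noise > 0) 100 * sum(covered & !signal) / n_noise else 0,
    n_true_points = n_true, n_noise_points = n_noise),
    class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> true coverage %.1f%% (n=%d), noise coverage %.1f%% (n=%d)\n",
              x$true_coverage, x$n_true_points,
              x$noise_coverage, x$n_noise_points))
  invisible(x)
}

#' Score identification calls against the simulated metabolite set
#'
#' @param report An [match_metabolites()] report (or a character vector of
#'   identified metabolite names).
#' @param truth_names Names of the metabolites actually present.
#' @return List with `n_correct`, `n_missed`, `n_false` and the
#'   corresponding name sets.
#' @export
score_identification <- function(report, truth_names) {
  stopifnot(length(truth_names) >= 1)
  identified <- if (inherits(report, "identification_report"))
    report$report$metabolite[report$report$identified] else
    as.character(report)
  truth_names <- as.character(truth_names)
  list(n_correct = length(intersect(identified, truth_names)),
       n_missed = length(setdiff(truth_names, identified)),
       n_false = length(setdiff(identified, truth_names)),
       correct = intersect(identified, truth_names),
       missed = setdiff(truth_names, identified),
       false_positive = setdiff(identified, truth_names))
}
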