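#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution: each spectrum is first normalized to unit
#' total integral, a reference spectrum is taken as the median spectrum of
#' the integral-normalized set, and each spectrum is then divided by the
#' median of its pointwise quotients against that reference (quotients are
#' formed only where the reference is positive).
#'
#' PQN is idempotent up to numerical tolerance: a second application leaves
#' the spectra unchanged.
#'
#' @param spectra A [spectrum_set()] with at least 2 samples.
#' @return A [spectrum_set()] of the same shape.
#' @export
pqn_normalize <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  x <- spectra$intensities
  if (nrow(x) < 2) stop("PQN needs at least 2 spectra")
  tot <- rowSums(x)
  bad <- which(tot <= 0 | apply(x, 1, function(r) all(r == 0)))
  if (length(bad))
    stop("all-zero or non-positive-integral spectrum: ",
         paste(spectra$sample_ids[bad], collapse = ", "))
  xi <- x / tot                       # integral normalization
  ref <- apply(xi, 2, stats::median)
  pos <- ref > 0
  if (!any(pos)) stop("median reference spectrum is nonpositive everywhere")
  q <- apply(xi, 1, function(r) stats::median(r[pos] / ref[pos]))
  if (any(!is.finite(q) | q == 0))
    stop("degenerate median quotient for sample: ",
         paste(spectra$sample_ids[!is.finite(q) | q == 0], collapse = ", "))
  spectrum_set(spectra$ppm, xi / q, spectra$sample_ids)
}

#' Baseline zeroing from a noise region
#'
#' Estimates the baseline level as `baseline_k` standard deviations of the
#' intensities in a user-chosen noise region (pooled over all samples) and
#' sets every datapoint below that level to zero. Points at or above the
#' level are left untouched.
#'
#' @param spectra A [spectrum_set()].
#' @param noise_region Length-2 numeric, the ppm interval used to estimate
#'   the noise SD. Must contain at least 10 datapoints.
#' @param baseline_k Multiplier of the noise SD (default 5).
#' @return A list with the thresholded [spectrum_set()] (`spectra`), the
#'   `baseline` level and the pooled `noise_sd`.
#' @export
baseline_zero <- function(spectra, noise_region, baseline_k = 5) {
  stopifnot(inherits(spectra, "spectrum_set"), baseline_k > 0,
            length(noise_region) == 2)
  noise_region <- sort(as.numeric(noise_region))
  sel <- spectra$ppm >= noise_region[1] & spectra$ppm <= noise_region[2]
  if (sum(sel) < 10)
    stop("noise region [", noise_region[1], ", ", noise_region[2],
         "] ppm contains ", sum(sel), " datapoints (need >= 10)")
  noise_sd <- stats::sd(as.vector(spectra$intensities[, sel, drop = FALSE]))
  baseline <- baseline_k * noise_sd
  x <- spectra$intensities
  x[x < baseline] <- 0
  list(spectra = spectrum_set(spectra$ppm, x, spectra$sample_ids),
       baseline = baseline, noise_sd = noise_sd)
}
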