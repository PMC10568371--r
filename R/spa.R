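#' Select the correlation-landscape window size from the PACF
#'
#' The window size `k` is the smallest lag at which the partial
#' autocorrelation of the spectrum (as a series along the ppm axis) falls
#' inside the `alpha` confidence band `+/- z / sqrt(p)`. It is computed on
#' the mean spectrum and cross-checked against the median of the per-sample
#' selections; a floor of 2 is applied (a window must contain at least one
#' pair of variables).
#'
#' @param spectra A [spectrum_set()] with `p >= 50`.
#' @param alpha Confidence level of the PACF band (default 0.95).
#' @param max_lag Largest lag examined (default 50). If the PACF never
#'   enters the band, `max_lag` is returned with a warning.
#' @return Integer window size `k >= 2`, with attributes
#'   `"per_sample_median"` and `"band"`.
#' @export
select_window_size <- function(spectra, alpha = 0.95, max_lag = 50) {
  stopifnot(inherits(spectra, "spectrum_set"))
  p <- length(spectra$ppm)
  if (p < 50) stop("need at least 50 datapoints for PACF selection")
  band <- stats::qnorm(1 - (1 - alpha) / 2) / sqrt(p)
  first_inside <- function(series) {
    pa <- as.numeric(stats::pacf(series, lag.max = max_lag,
                                 plot = FALSE)$acf)
    hit <- which(abs(pa) < band)
    if (!length(hit)) NA_integer_ else hit[1]
  }
  k_mean <- first_inside(colMeans(spectra$intensities))
  k_each <- apply(spectra$intensities, 1, first_inside)
  k_consensus <- stats::median(k_each, na.rm = TRUE)
  if (is.na(k_mean)) {
    warning("PACF never entered the confidence band up to lag ", max_lag,
            "; returning max_lag")
    k_mean <- max_lag
  }
  k <- max(2L, as.integer(k_mean))
  if (is.finite(k_consensus) && abs(k_consensus - k_mean) > 2)
    message("window size from mean spectrum (", k_mean,
            ") differs from per-sample median (", k_consensus, ")")
  structure(k, per_sample_median = k_consensus, band = band)
}

#' Moving-window correlation landscape
#'
#' For each window start `j`, the landscape value is the average of all
#' `k*(k-1)/2` pairwise Pearson correlations among the `k` consecutive
#' spectral variables `j, ..., j+k-1`. Windows extending past the end of the
#' spectrum are undefined (`NA`): the landscape carries values at positions
#' `1, ..., p-k+1`. Pairs involving a zero-variance column contribute 0
#' (baseline-zeroed regions read as "no dependence").
#'
#' @param spectra A [spectrum_set()] with at least 3 samples.
#' @param k Window size in datapoints (`2 <= k <= p`).
#' @return An object of class `"correlation_landscape"`: list with
#'   `values` (length `p`, `NA` at undefined tail positions),
#'   `window_size`, `kernel` (`"none"`), `smoothed` (`FALSE`) and `ppm`.
#' @export
correlation_landscape <- function(spectra, k) {
  stopifnot(inherits(spectra, "spectrum_set"))
  x <- spectra$intensities
  n <- nrow(x); p <- ncol(x)
  k <- as.integer(k)
  if (n < 3) stop("correlation landscape needs >= 3 samples")
  if (k < 2 || k > p) stop("window size k must be in [2, p]")
  mu <- colMeans(x)
  sdv <- sqrt(colSums((t(t(x) - mu))^2))
  z <- t(t(x) - mu)
  ok <- sdv > 0
  z[, ok] <- t(t(z[, ok, drop = FALSE]) / sdv[ok])
  z[, !ok] <- 0                       # zero-variance columns contribute 0
  npos <- p - k + 1L
  q <- numeric(npos)
  for (d in seq_len(k - 1L)) {
    r_d <- colSums(z[, 1:(p - d), drop = FALSE] *
                   z[, (1 + d):p, drop = FALSE])
    # windowed sum of r_d over the k-d in-window positions at each start j
    cs <- c(0, cumsum(r_d))
    w <- k - d
    q <- q + (cs[(w + 1):(w + npos)] - cs[1:npos])
  }
  vals <- c(q * 2 / (k * (k - 1)), rep(NA_real_, k - 1L))
  structure(list(values = vals, window_size = k, kernel = "none",
                 smoothed = FALSE, bandwidth = NA_real_,
                 ppm = spectra$ppm),
            class = "correlation_landscape")
}

#' @export
print.correlation_landscape <- function(x, ...) {
  cat(sprintf("<correlation_landscape> %d positions, k=%d, kernel=%s%s\n",
              length(x$values), x$window_size, x$kernel,
              if (x$smoothed) " (smoothed)" else ""))
  invisible(x)
}

## kernel weight functions of |t|, zero outside |t| < 1
kernel_weight <- function(t, kernel = c("epanechnikov", "tricube")) {
  kernel <- match.arg(kernel)
  t <- abs(t)
  w <- numeric(length(t))
  inside <- t <= 1
  w[inside] <- switch(kernel,
                      epanechnikov = 0.75 * (1 - t[inside]^2),
                      tricube = (1 - t[inside]^3)^3)
  w
}

#' Kernel-smooth a correlation landscape
#'
#' Replaces each landscape position by the kernel-weighted average of its
#' neighbours, with `t = |distance in datapoints| / bandwidth` and weights
#' renormalized to sum to 1 over the defined neighbours within the support.
#' The Epanechnikov kernel is `(3/4)(1 - t^2)` and the tricube kernel
#' `(1 - t^3)^3`, both zero for `|t| >= 1`. Undefined (`NA`) positions stay
#' undefined and are excluded from neighbouring averages.
#'
#' @param landscape A [correlation_landscape()].
#' @param kernel `"tricube"` (default) or `"epanechnikov"`.
#' @param bandwidth Kernel bandwidth in datapoints; defaults to the
#'   landscape's window size.
#' @return A smoothed `"correlation_landscape"`.
#' @export
smooth_landscape <- function(landscape,
                             kernel = c("tricube", "epanechnikov"),
                             bandwidth = landscape$window_size) {
  stopifnot(inherits(landscape, "correlation_landscape"), bandwidth >= 1)
  kernel <- match.arg(kernel)
  v <- landscape$values
  offsets <- seq.int(-ceiling(bandwidth) + 1L, ceiling(bandwidth) - 1L)
  w <- kernel_weight(offsets / bandwidth, kernel)
  keep <- w > 0
  offsets <- offsets[keep]; w <- w[keep]
  p <- length(v)
  num <- numeric(p); den <- numeric(p)
  defined <- !is.na(v)
  v0 <- ifelse(defined, v, 0)
  for (m in seq_along(offsets)) {
    src <- seq_len(p) + offsets[m]
    valid <- src >= 1L & src <= p
    srcv <- src[valid]
    num[valid] <- num[valid] + w[m] * v0[srcv] * defined[srcv]
    den[valid] <- den[valid] + w[m] * defined[srcv]
  }
  out <- ifelse(defined & den > 0, num / den, NA_real_)
  structure(list(values = out, window_size = landscape$window_size,
                 kernel = kernel, smoothed = TRUE, bandwidth = bandwidth,
                 ppm = landscape$ppm),
            class = "correlation_landscape")
}

#' Extract contiguous spatial clusters from a landscape
#'
#' Clusters are the maximal contiguous runs of landscape positions at or
#' above the threshold `lambda`; undefined positions count as below.
#' Runs shorter than `min_size` datapoints are discarded.
#'
#' @param landscape A [correlation_landscape()] (normally smoothed).
#' @param lambda Threshold in (0, 1).
#' @param min_size Minimum cluster size in datapoints (default: the
#'   landscape's window size, the natural resolution floor).
#' @return An object of class `"cluster_set"`: list with `clusters` (a
#'   data.frame with `cluster_id`, `start_idx`, `end_idx` (1-based,
#'   inclusive), `start_ppm`, `end_ppm`, `n_points`), `ppm` and `p`.
#' @export
extract_clusters <- function(landscape, lambda,
                             min_size = landscape$window_size) {
  stopifnot(inherits(landscape, "correlation_landscape"),
            lambda > 0, lambda < 1, min_size >= 1)
  v <- landscape$values
  above <- !is.na(v) & v >= lambda
  runs <- index_runs(which(above))
  if (nrow(runs))
    runs <- runs[runs$end_idx - runs$start_idx + 1L >= min_size, ,
                 drop = FALSE]
  ppm <- landscape$ppm
  cl <- data.frame(cluster_id = seq_len(nrow(runs)),
                   start_idx = runs$start_idx, end_idx = runs$end_idx,
                   start_ppm = if (nrow(runs)) ppm[runs$start_idx] else numeric(),
                   end_ppm = if (nrow(runs)) ppm[runs$end_idx] else numeric(),
                   n_points = runs$end_idx - runs$start_idx + 1L,
                   row.names = NULL)
  structure(list(clusters = cl, ppm = ppm, p = length(v)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters covering %d of %d datapoints\n",
              nrow(x$clusters), sum(x$clusters$n_points), x$p))
  invisible(x)
}

#' Write a cluster set as delimited text
#' @param x A [extract_clusters()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_set"))
  utils::write.csv(x$clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## membership labels over the grid: 0 = unclustered, else cluster_id
cluster_labels <- function(clusters, p) {
  lab <- integer(p)
  cl <- clusters$clusters
  for (i in seq_len(nrow(cl)))
    lab[cl$start_idx[i]:cl$end_idx[i]] <- cl$cluster_id[i]
  lab
}

## split sample indices into two (near-)equal halves, n_folds times
make_half_splits <- function(n, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_folds), function(f) {
    perm <- sample.int(n)
    half <- floor(n / 2)
    list(a = perm[seq_len(half)], b = perm[(half + 1):n])
  })
}

## median fraction of within-cluster pairs of `scored` that are co-clustered
## under `labels_other`; singleton clusters are skipped (their pair set is
## empty); zero scorable clusters -> 0
pd_one_direction <- function(scored, labels_other) {
  cl <- scored$clusters
  sizes <- cl$n_points
  keep <- which(sizes >= 2L)
  if (!length(keep)) return(0)
  fracs <- vapply(keep, function(i) {
    lab <- labels_other[cl$start_idx[i]:cl$end_idx[i]]
    lab <- lab[lab > 0L]
    if (!length(lab)) return(0)
    cnt <- tabulate(lab)
    m <- sizes[i]
    sum(cnt * (cnt - 1)) / (m * (m - 1))
  }, numeric(1))
  stats::median(fracs)
}

## smoothed landscapes for both halves of each fold (shared across lambdas)
fold_landscapes <- function(spectra, k, kernel, bandwidth, splits) {
  half_ls <- function(idx) {
    sub <- spectrum_set(spectra$ppm,
                        spectra$intensities[idx, , drop = FALSE],
                        spectra$sample_ids[idx])
    smooth_landscape(correlation_landscape(sub, k), kernel, bandwidth)
  }
  lapply(splits, function(s) list(a = half_ls(s$a), b = half_ls(s$b)))
}

## symmetrized prediction strength of one fold at one lambda
pd_fold <- function(ls_pair, lambda, min_size) {
  ca <- extract_clusters(ls_pair$a, lambda, min_size)
  cb <- extract_clusters(ls_pair$b, lambda, min_size)
  if (nrow(ca$clusters) == 0 || nrow(cb$clusters) == 0) return(0)
  la <- cluster_labels(ca, ca$p)
  lb <- cluster_labels(cb, cb$p)
  (pd_one_direction(ca, lb) + pd_one_direction(cb, la)) / 2
}

#' Prediction strength of a clustering threshold
#'
#' Cluster-stability statistic: the samples are split into two halves, each
#' half is clustered independently (landscape, smoothing, thresholding at
#' `lambda`), and each cluster of one half with `m >= 2` variables is scored
#' by the fraction of its within-cluster variable pairs that are also
#' co-clustered in the other half; the per-half statistic is the median of
#' those fractions over clusters. Both scoring directions are averaged, and
#' the procedure is repeated over `n_folds` random splits.
#'
#' @param spectra A [spectrum_set()] with `n >= 4`.
#' @param lambda Threshold in (0, 1).
#' @param k Window size.
#' @param kernel Smoothing kernel.
#' @param bandwidth Kernel bandwidth (default `k`).
#' @param min_size Minimum cluster size (default `k`).
#' @param n_folds Number of random half-splits (default 5).
#' @param seed RNG seed for the splits.
#' @return List with `mean`, `se` and per-fold values `folds`.
#' @export
prediction_strength <- function(spectra, lambda, k,
                                kernel = c("tricube", "epanechnikov"),
                                bandwidth = k, min_size = k,
                                n_folds = 5, seed = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"),
            lambda > 0, lambda < 1)
  kernel <- match.arg(kernel)
  n <- nrow(spectra$intensities)
  if (n < 4) stop("prediction strength needs n >= 4 samples")
  splits <- make_half_splits(n, n_folds, seed)
  lss <- fold_landscapes(spectra, k, kernel, bandwidth, splits)
  folds <- vapply(lss, pd_fold, numeric(1),
                  lambda = lambda, min_size = min_size)
  list(mean = mean(folds),
       se = stats::sd(folds) / sqrt(n_folds),
       folds = folds)
}

#' Select the clustering threshold by the one-standard-error rule
#'
#' Evaluates the prediction strength over a grid of candidate thresholds
#' (using the same random half-splits for every candidate) and chooses the
#' lowest threshold whose mean prediction strength is within one standard
#' error of the maximum mean. Ties break toward the smallest threshold.
#'
#' @inheritParams prediction_strength
#' @param lambda_grid Ascending candidate thresholds in (0, 1); default
#'   `seq(0.30, 0.95, by = 0.05)`.
#' @return An object of class `"threshold_search"`: list with
#'   `lambda_grid`, `mean_strength`, `se_strength`, `chosen_lambda`.
#' @export
select_threshold <- function(spectra,
                             lambda_grid = seq(0.30, 0.95, by = 0.05),
                             k, kernel = c("tricube", "epanechnikov"),
                             bandwidth = k, min_size = k,
                             n_folds = 5, seed = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"), length(lambda_grid) >= 1,
            all(lambda_grid > 0 & lambda_grid < 1),
            !is.unsorted(lambda_grid))
  kernel <- match.arg(kernel)
  n <- nrow(spectra$intensities)
  if (n < 4) stop("threshold selection needs n >= 4 samples")
  splits <- make_half_splits(n, n_folds, seed)
  lss <- fold_landscapes(spectra, k, kernel, bandwidth, splits)
  per_fold <- vapply(lss, function(lp)
    vapply(lambda_grid, function(l) pd_fold(lp, l, min_size), numeric(1)),
    numeric(length(lambda_grid)))
  per_fold <- matrix(per_fold, nrow = length(lambda_grid))
  mean_s <- rowMeans(per_fold)
  se_s <- apply(per_fold, 1, stats::sd) / sqrt(n_folds)
  if (all(mean_s == 0))
    stop("no stable clustering: prediction strength is zero on the whole grid")
  i_max <- which.max(mean_s)
  ok <- which(mean_s >= mean_s[i_max] - se_s[i_max])
  chosen <- lambda_grid[min(ok)]
  structure(list(lambda_grid = lambda_grid, mean_strength = mean_s,
                 se_strength = se_s, chosen_lambda = chosen,
                 per_fold = per_fold),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> chosen lambda = %.2f (grid %.2f-%.2f, max mean Pd = %.3f)\n",
              x$chosen_lambda, min(x$lambda_grid), max(x$lambda_grid),
              max(x$mean_strength)))
  invisible(x)
}

#' Run the full spatial clustering algorithm
#'
#' Convenience wrapper: selects the window size from the PACF (unless
#' given), computes and smooths the correlation landscape, selects the
#' threshold by prediction strength (unless given), and extracts clusters.
#'
#' @param spectra A [spectrum_set()].
#' @param k Window size, or `NULL` to select automatically.
#' @param lambda Threshold, or `NULL` to select automatically.
#' @param kernel Smoothing kernel (default tricube).
#' @param min_size Minimum cluster size; defaults to `k`.
#' @param lambda_grid Candidate thresholds for automatic selection.
#' @param n_folds Folds for the prediction-strength search.
#' @param seed RNG seed for the fold splits.
#' @return An object of class `"spa_result"`: list with `clusters` (a
#'   [extract_clusters()] cluster set), `landscape` (smoothed), `k`,
#'   `lambda`, `threshold_search` (or `NULL`) and `params`.
#' @export
spa <- function(spectra, k = NULL, lambda = NULL,
                kernel = c("tricube", "epanechnikov"),
                min_size = NULL,
                lambda_grid = seq(0.30, 0.95, by = 0.05),
                n_folds = 5, seed = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"))
  kernel <- match.arg(kernel)
  if (is.null(k)) k <- as.integer(select_window_size(spectra))
  if (is.null(min_size)) min_size <- k
  search <- NULL
  if (is.null(lambda)) {
    search <- select_threshold(spectra, lambda_grid, k = k, kernel = kernel,
                               min_size = min_size, n_folds = n_folds,
                               seed = seed)
    lambda <- search$chosen_lambda
  }
  ls <- smooth_landscape(correlation_landscape(spectra, k), kernel)
  clusters <- extract_clusters(ls, lambda, min_size)
  structure(list(clusters = clusters, landscape = ls, k = k,
                 lambda = lambda, threshold_search = search,
                 params = list(kernel = kernel, min_size = min_size,
                               n_folds = n_folds, seed = seed)),
            class = "spa_result")
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> k=%d lambda=%.2f: %d clusters\n",
              x$k, x$lambda, nrow(x$clusters$clusters)))
  invisible(x)
}
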