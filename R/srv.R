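#' SRV variance landscape
#'
#' The statistical-recoupling-of-variables landscape between consecutive
#' spectral variables: the ratio of their covariance to their correlation,
#' which reduces to `L_j = sqrt(var(x_j) * var(x_{j+1}))` for
#' `j = 1, ..., p-1` (variances with the 1/n convention).
#'
#' @param spectra A [spectrum_set()] with `n >= 3`, `p >= 3`.
#' @return Numeric vector of length `p - 1`, nonnegative.
#' @export
srv_landscape <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  x <- spectra$intensities
  n <- nrow(x); p <- ncol(x)
  if (n < 3 || p < 3) stop("SRV needs n >= 3 and p >= 3")
  v <- colMeans(x^2) - colMeans(x)^2   # population (1/n) variance
  v[v < 0] <- 0
  sqrt(v[-p] * v[-1])
}

#' SRV spatial clustering
#'
#' Clusters are the segments of the ppm grid between successive local
#' minima of the SRV landscape (strict minima; plateau minima cut at the
#' plateau midpoint). Segments with fewer than `min_cluster_size` variables
#' are discarded. A flat landscape with no local minima yields a single
#' cluster spanning the spectrum.
#'
#' @param spectra A [spectrum_set()].
#' @param min_cluster_size Minimum variables per cluster (default 10).
#' @return A `"cluster_set"` (same class as [extract_clusters()]), with the
#'   landscape attached as attribute `"landscape"`.
#' @export
srv_cluster <- function(spectra, min_cluster_size = 10) {
  stopifnot(min_cluster_size >= 1)
  L <- srv_landscape(spectra)
  p <- length(spectra$ppm)
  minima <- local_maxima(-L)           # strict local minima of L
  # a minimum at landscape position j cuts between variables j and j+1
  bounds <- c(0L, minima, p)
  segs <- data.frame(start_idx = bounds[-length(bounds)] + 1L,
                     end_idx = bounds[-1])
  segs <- segs[segs$end_idx - segs$start_idx + 1L >= min_cluster_size, ,
               drop = FALSE]
  cl <- data.frame(cluster_id = seq_len(nrow(segs)),
                   start_idx = segs$start_idx, end_idx = segs$end_idx,
                   start_ppm = if (nrow(segs)) spectra$ppm[segs$start_idx] else numeric(),
                   end_ppm = if (nrow(segs)) spectra$ppm[segs$end_idx] else numeric(),
                   n_points = segs$end_idx - segs$start_idx + 1L,
                   row.names = NULL)
  out <- structure(list(clusters = cl, ppm = spectra$ppm, p = p),
                   class = "cluster_set")
  attr(out, "landscape") <- L
  out
}

#' Aggregate SRV clusters into super-clusters
#'
#' Representative cluster intensities (the per-sample mean of the member
#' variables) are chained left to right: a cluster joins the running chain
#' while its correlation with the previous cluster exceeds `r`, up to `cap`
#' clusters per chain.
#'
#' @param clusters A [srv_cluster()] result.
#' @param spectra The [spectrum_set()] the clusters came from.
#' @param r Aggregation correlation threshold (default 0.9, strict `>`).
#' @param cap Maximum clusters per super-cluster (default 3).
#' @return Integer vector: super-cluster id per cluster (a partition).
#' @export
srv_superclusters <- function(clusters, spectra, r = 0.9, cap = 3) {
  stopifnot(inherits(clusters, "cluster_set"), cap >= 1)
  cl <- clusters$clusters
  if (nrow(cl) == 0) return(integer())
  reps <- vapply(seq_len(nrow(cl)), function(j)
    rowMeans(spectra$intensities[, cl$start_idx[j]:cl$end_idx[j],
                                 drop = FALSE]),
    numeric(nrow(spectra$intensities)))
  assign <- integer(nrow(cl))
  assign[1] <- 1L
  chain_len <- 1L
  for (j in seq_len(nrow(cl))[-1]) {
    rr <- suppressWarnings(stats::cor(reps[, j - 1], reps[, j]))
    if (is.finite(rr) && rr > r && chain_len < cap) {
      assign[j] <- assign[j - 1]
      chain_len <- chain_len + 1L
    } else {
      assign[j] <- assign[j - 1] + 1L
      chain_len <- 1L
    }
  }
  assign
}
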