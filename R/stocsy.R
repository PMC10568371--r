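## strict local maxima of a vector; plateaus take their midpoint.
## Returns positions relative to the vector (integer indices).
local_maxima <- function(y) {
  m <- length(y)
  if (m < 3) return(integer())
  out <- integer()
  i <- 2L
  while (i <= m - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < m && y[j + 1L] == y[i]) j <- j + 1L  # plateau
      if (j <= m - 1L && y[j + 1L] < y[i]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Representative intensities of spatial clusters
#'
#' For each sample and cluster, detects local maxima (strict two-neighbour
#' comparison, plateau apexes at the plateau midpoint) within the cluster's
#' index range and averages their intensities. A cluster with no interior
#' local maximum (e.g. a monotone ramp) falls back to its maximum
#' intensity.
#'
#' @param spectra A [spectrum_set()].
#' @param clusters A [extract_clusters()] cluster set on the same grid.
#' @return A `n_samples x n_clusters` matrix with cluster ids as column
#'   names, of class `"cluster_intensities"` (plain matrix with an extra
#'   class tag).
#' @export
cluster_intensities <- function(spectra, clusters) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  p <- length(spectra$ppm)
  if (nrow(cl) && (min(cl$start_idx) < 1 || max(cl$end_idx) > p))
    stop("cluster indices outside the spectrum grid")
  x <- spectra$intensities
  out <- matrix(NA_real_, nrow(x), nrow(cl),
                dimnames = list(spectra$sample_ids,
                                as.character(cl$cluster_id)))
  for (j in seq_len(nrow(cl))) {
    rng <- cl$start_idx[j]:cl$end_idx[j]
    for (i in seq_len(nrow(x))) {
      seg <- x[i, rng]
      pk <- local_maxima(seg)
      out[i, j] <- if (length(pk)) mean(seg[pk]) else max(seg)
    }
  }
  class(out) <- c("cluster_intensities", class(out))
  out
}

#' STOCSY correlation matrix of cluster intensities
#'
#' Pearson correlation between the representative intensities of every
#' pair of clusters, across samples. A zero-variance cluster column gets
#' zero off-diagonal correlations (with a warning) rather than `NA`.
#'
#' @param intensities A [cluster_intensities()] matrix (samples x clusters).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
stocsy_correlate <- function(intensities) {
  x <- unclass(intensities)
  if (nrow(x) < 3) stop("STOCSY needs >= 3 samples")
  sdv <- apply(x, 2, stats::sd)
  flat <- sdv == 0
  r <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  if (any(!flat))
    r[!flat, !flat] <- stats::cor(x[, !flat, drop = FALSE])
  if (any(flat)) {
    warning(sum(flat), " zero-variance cluster column(s); correlations set to 0")
  }
  diag(r) <- 1
  r
}

#' Group clusters by thresholded correlation
#'
#' Builds a graph with an edge wherever the cluster-cluster correlation is
#' at or above the threshold and returns its connected components: the
#' STOCSY groups of clusters putatively belonging to the same metabolite.
#' Grouping uses the signed correlation (`r >= threshold`), not `|r|`:
#' under a concentration-driven model, same-molecule clusters co-vary
#' positively.
#'
#' @param correlation Symmetric correlation matrix ([stocsy_correlate()]).
#' @param threshold Grouping threshold in (0, 1] (default 0.8).
#' @return An object of class `"stocsy_groups"`: list with `correlation`,
#'   `threshold`, `groups` (list of integer vectors of cluster ids, ordered
#'   by smallest member), `membership` (group id per cluster) and
#'   `singleton` (logical per group).
#' @export
group_clusters <- function(correlation, threshold = 0.8) {
  stopifnot(is.matrix(correlation), nrow(correlation) == ncol(correlation),
            threshold > 0, threshold <= 1)
  nc <- nrow(correlation)
  adj <- (correlation >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- if (!is.null(rownames(correlation)))
    suppressWarnings(as.integer(rownames(correlation))) else seq_len(nc)
  if (anyNA(ids)) ids <- seq_len(nc)
  groups <- split(ids, comp)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  names(groups) <- NULL
  membership <- integer(nc)
  for (gidx in seq_along(groups))
    membership[match(groups[[gidx]], ids)] <- gidx
  structure(list(correlation = correlation, threshold = threshold,
                 groups = groups, membership = membership,
                 cluster_ids = ids,
                 singleton = lengths(groups) == 1L),
            class = "stocsy_groups")
}

#' @export
print.stocsy_groups <- function(x, ...) {
  cat(sprintf("<stocsy_groups> %d clusters -> %d groups (threshold %.2f, %d singletons)\n",
              length(x$membership), length(x$groups), x$threshold,
              sum(x$singleton)))
  invisible(x)
}

#' Locate the spatial clusters of a calibration reference compound
#'
#' Maps the library resonance clusters of a known compound (an internal
#' standard such as DSS, or a metabolite known to be present at high
#' concentration) to the spatial clusters covering their peak positions, so
#' the STOCSY grouping threshold can be calibrated on them with
#' [calibrate_threshold()].
#'
#' @param clusters A `"cluster_set"`.
#' @param library A [metabolite_library()].
#' @param metabolite Name of the reference compound in the library.
#' @param slack Positional slack in ppm when locating a peak inside a
#'   cluster's range (default 0.005).
#' @return Integer vector of spatial cluster ids (one per located library
#'   cluster; library clusters whose peaks fall outside every spatial
#'   cluster are dropped).
#' @export
find_reference_clusters <- function(clusters, library, metabolite,
                                    slack = 0.005) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(library, "metabolite_library"))
  lib <- library$clusters
  lib <- lib[lib$metabolite == metabolite, , drop = FALSE]
  if (!nrow(lib)) stop("metabolite not in library: ", metabolite)
  cl <- clusters$clusters
  ids <- unlist(lapply(unique(lib$cluster_id), function(cid) {
    pp <- lib$peak_ppm[lib$cluster_id == cid][1]
    hit <- which(cl$start_ppm - slack <= pp & cl$end_ppm + slack >= pp)
    if (length(hit)) cl$cluster_id[hit[1]] else NULL
  }))
  unique(ids)
}

#' Calibrate the STOCSY grouping threshold on reference resonances
#'
#' Scans a descending grid of candidate thresholds and returns the largest
#' one at which all supplied reference clusters (e.g. the resonances of an
#' internal standard such as DSS, or of a known abundant metabolite) fall
#' into a single group.
#'
#' @param intensities A [cluster_intensities()] matrix, or a precomputed
#'   correlation matrix.
#' @param reference_cluster_ids At least two cluster ids known to belong to
#'   the same compound.
#' @param grid Descending candidate thresholds (default
#'   `seq(0.95, 0.30, by = -0.05)`).
#' @return The calibrated threshold (largest grid value that co-groups all
#'   reference clusters).
#' @export
calibrate_threshold <- function(intensities, reference_cluster_ids,
                                grid = seq(0.95, 0.30, by = -0.05)) {
  stopifnot(length(reference_cluster_ids) >= 2, !is.unsorted(rev(grid)))
  r <- if (is.matrix(intensities) &&
           nrow(intensities) == ncol(intensities) &&
           isTRUE(all.equal(unname(diag(intensities)),
                            rep(1, ncol(intensities)))))
    intensities else stocsy_correlate(intensities)
  ids_chr <- as.character(reference_cluster_ids)
  if (!all(ids_chr %in% rownames(r)))
    stop("unknown reference cluster id(s): ",
         paste(setdiff(ids_chr, rownames(r)), collapse = ", "))
  for (th in grid) {
    gr <- group_clusters(r, th)
    gid <- gr$membership[match(as.integer(reference_cluster_ids),
                               gr$cluster_ids)]
    if (length(unique(gid)) == 1L) return(th)
  }
  sub <- r[ids_chr, ids_chr]
  stop("reference clusters never co-group, even at threshold ",
       min(grid), "; pairwise correlations:\n",
       paste(utils::capture.output(print(round(sub, 3))), collapse = "\n"))
}
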