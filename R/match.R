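#' Construct a metabolite resonance library
#'
#' A reference library is a table of known resonance clusters: one row per
#' reference peak, with the metabolite name, a cluster identifier (one
#' metabolite has one or more clusters, each holding one or more peaks) and
#' the peak chemical shift.
#'
#' @param peaks A data.frame with columns `metabolite`, `cluster_id`,
#'   `peak_ppm`.
#' @param ppm_window Length-2 numeric scoring range (default
#'   `c(0.5, 4.0)` ppm); only library clusters with at least one peak in
#'   this window count toward detection ratios.
#' @return An object of class `"metabolite_library"`.
#' @export
metabolite_library <- function(peaks, ppm_window = c(0.5, 4.0)) {
  req <- c("metabolite", "cluster_id", "peak_ppm")
  if (!is.data.frame(peaks) || !all(req %in% names(peaks)))
    stop("library needs columns: ", paste(req, collapse = ", "))
  peaks <- peaks[req]
  peaks$metabolite <- as.character(peaks$metabolite)
  peaks$cluster_id <- as.character(peaks$cluster_id)
  peaks$peak_ppm <- as.numeric(peaks$peak_ppm)
  if (anyNA(peaks$peak_ppm)) {
    stop("non-numeric peak_ppm at library row(s): ",
         paste(which(is.na(peaks$peak_ppm)), collapse = ", "))
  }
  ppm_window <- sort(as.numeric(ppm_window))
  in_win <- peaks$peak_ppm >= ppm_window[1] & peaks$peak_ppm <= ppm_window[2]
  n_in <- tapply(in_win, peaks$metabolite, sum)
  if (any(n_in == 0))
    stop("metabolite(s) with no peak inside the ppm window: ",
         paste(names(n_in)[n_in == 0], collapse = ", "))
  structure(list(clusters = peaks, ppm_window = ppm_window),
            class = "metabolite_library")
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf("<metabolite_library> %d metabolites, %d clusters, %d peaks (window %.2f-%.2f ppm)\n",
              length(unique(x$clusters$metabolite)),
              length(unique(paste(x$clusters$metabolite, x$clusters$cluster_id))),
              nrow(x$clusters), x$ppm_window[1], x$ppm_window[2]))
  invisible(x)
}

#' Read a metabolite library from delimited text
#'
#' @param path CSV file with header `metabolite,cluster_id,peak_ppm`.
#' @param ppm_window Scoring window passed to [metabolite_library()].
#' @return A [metabolite_library()].
#' @export
read_metabolite_library <- function(path, ppm_window = c(0.5, 4.0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  metabolite_library(df, ppm_window)
}

#' Write a metabolite library as delimited text
#' @param library A [metabolite_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_library <- function(library, path) {
  stopifnot(inherits(library, "metabolite_library"))
  utils::write.csv(library$clusters, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect peaks of each spatial cluster
#'
#' Peaks are strict local maxima of the mean spectrum within each cluster's
#' index range (plateau apexes at the plateau midpoint). A cluster with no
#' interior local maximum contributes its maximum-intensity position.
#'
#' @param spectra A [spectrum_set()].
#' @param clusters A [extract_clusters()] cluster set on the same grid.
#' @return Named list (by cluster id) of numeric vectors of peak ppm
#'   positions.
#' @export
detect_cluster_peaks <- function(spectra, clusters) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(clusters, "cluster_set"))
  mu <- colMeans(spectra$intensities)
  cl <- clusters$clusters
  out <- vector("list", nrow(cl))
  names(out) <- as.character(cl$cluster_id)
  for (j in seq_len(nrow(cl))) {
    rng <- cl$start_idx[j]:cl$end_idx[j]
    seg <- mu[rng]
    pk <- local_maxima(seg)
    if (!length(pk)) pk <- which.max(seg)
    out[[j]] <- spectra$ppm[rng[pk]]
  }
  out
}

#' Match STOCSY groups against a metabolite library
#'
#' For each STOCSY group, the detected peaks of all its member clusters are
#' pooled. A library cluster counts as detected by a group when at least
#' one of its reference peaks lies within `tolerance` ppm of a detected
#' peak of that group. Each metabolite's detection ratio is the maximum
#' over groups of (detected library clusters in the scoring window) /
#' (library clusters in the window); the metabolite is called identified
#' when the ratio strictly exceeds `detection_threshold`. With
#' `singlet_filter = TRUE`, a single-cluster metabolite is identified only
#' when its matching group is a singleton (self-correlated only). Groups
#' whose peaks match no library cluster at all are reported as unannotated
#' candidates.
#'
#' @param groups A [group_clusters()] result.
#' @param peaks Per-cluster peak ppm lists from [detect_cluster_peaks()].
#' @param library A [metabolite_library()].
#' @param tolerance Matching tolerance in ppm (default 0.025).
#' @param detection_threshold Detection-ratio threshold (default 0.55;
#'   identification requires ratio strictly greater).
#' @param singlet_filter Apply the single-cluster filter (default `TRUE`).
#' @return An object of class `"identification_report"`: list with
#'   `report` (data.frame: `metabolite`, `n_library_clusters`,
#'   `n_detected_clusters`, `detection_ratio`, `identified`,
#'   `matched_group_id`, `singlet_filtered`), `unannotated` (data.frame of
#'   candidate groups with their peak ppms) and `params`.
#' @export
match_metabolites <- function(groups, peaks, library,
                              tolerance = 0.025,
                              detection_threshold = 0.55,
                              singlet_filter = TRUE) {
  stopifnot(inherits(groups, "stocsy_groups"),
            inherits(library, "metabolite_library"),
            tolerance >= 0,
            detection_threshold > 0, detection_threshold < 1)
  lib <- library$clusters
  win <- library$ppm_window
  lib <- lib[lib$peak_ppm >= win[1] & lib$peak_ppm <= win[2], , drop = FALSE]
  mets <- unique(lib$metabolite)
  group_peaks <- lapply(groups$groups, function(ids)
    sort(unlist(peaks[as.character(ids)], use.names = FALSE)))
  n_groups <- length(group_peaks)
  group_hit <- logical(n_groups)

  rows <- vector("list", length(mets))
  for (mi in seq_along(mets)) {
    sub <- lib[lib$metabolite == mets[mi], , drop = FALSE]
    clusters_m <- unique(sub$cluster_id)
    n_lib <- length(clusters_m)
    best <- 0L; best_group <- NA_integer_
    if (n_groups > 0 && n_lib > 0) {
      for (g in seq_len(n_groups)) {
        gp <- group_peaks[[g]]
        if (!length(gp)) next
        det <- vapply(clusters_m, function(cid) {
          ref <- sub$peak_ppm[sub$cluster_id == cid]
          any(vapply(ref, function(r) any(abs(gp - r) <= tolerance),
                     logical(1)))
        }, logical(1))
        nd <- sum(det)
        if (nd > 0) group_hit[g] <- TRUE
        if (nd > best) { best <- nd; best_group <- g }
      }
    }
    ratio <- if (n_lib > 0) best / n_lib else 0
    identified <- ratio > detection_threshold
    filtered <- FALSE
    if (identified && singlet_filter && n_lib == 1L && !is.na(best_group) &&
        !groups$singleton[best_group]) {
      # a non-singleton group still counts as self-correlated when every
      # member cluster matches this same resonance (a multiplet split into
      # adjacent fragments), i.e. the group carries no foreign evidence
      ref <- sub$peak_ppm
      member_hits <- vapply(groups$groups[[best_group]], function(cid) {
        cp <- peaks[[as.character(cid)]]
        length(cp) > 0 &&
          all(vapply(cp, function(x) any(abs(ref - x) <= tolerance),
                     logical(1)))
      }, logical(1))
      if (!all(member_hits)) {
        identified <- FALSE
        filtered <- TRUE
      }
    }
    rows[[mi]] <- data.frame(metabolite = mets[mi],
                             n_library_clusters = n_lib,
                             n_detected_clusters = best,
                             detection_ratio = ratio,
                             identified = identified,
                             matched_group_id = best_group,
                             singlet_filtered = filtered)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(), n_library_clusters = integer(),
               n_detected_clusters = integer(), detection_ratio = numeric(),
               identified = logical(), matched_group_id = integer(),
               singlet_filtered = logical())
  un_idx <- which(!group_hit & lengths(group_peaks) > 0)
  unannotated <- data.frame(
    group_id = un_idx,
    cluster_ids = vapply(un_idx, function(g)
      paste(groups$groups[[g]], collapse = ";"), character(1)),
    peak_ppms = vapply(un_idx, function(g)
      paste(format(group_peaks[[g]], digits = 5, trim = TRUE),
            collapse = ";"), character(1)))
  structure(list(report = report, unannotated = unannotated,
                 params = list(tolerance = tolerance,
                               detection_threshold = detection_threshold,
                               singlet_filter = singlet_filter)),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> %d/%d metabolites identified, %d unannotated candidate group(s)\n",
              sum(x$report$identified), nrow(x$report), nrow(x$unannotated)))
  invisible(x)
}

#' Write an identification report as delimited text
#'
#' Writes the per-metabolite report to `path` and, when there are
#' unannotated candidate groups, those to `unannotated_path`.
#'
#' @param x An [match_metabolites()] report.
#' @param path Output path for the per-metabolite table.
#' @param unannotated_path Optional path for unannotated candidate groups.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, unannotated_path = NULL) {
  stopifnot(inherits(x, "identification_report"))
  utils::write.csv(x$report, path, row.names = FALSE, quote = FALSE)
  if (!is.null(unannotated_path))
    utils::write.csv(x$unannotated, unannotated_path,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
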