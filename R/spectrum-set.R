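#' Construct a spectrum set
#'
#' The universal exchange object of the package: an ordered chemical-shift
#' (ppm) axis together with a samples x datapoints intensity matrix.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#'   Descending axes are accepted and silently reversed so that internal
#'   storage is always ascending.
#' @param intensities Numeric matrix, one row per sample, `length(ppm)`
#'   columns.
#' @param sample_ids Optional character vector of sample labels; defaults to
#'   `"S1"`, `"S2"`, ...
#'
#' @return An object of class `"spectrum_set"`: a list with elements `ppm`,
#'   `intensities` (rows named by `sample_ids`) and `sample_ids`.
#' @examples
#' ss <- spectrum_set(seq(0.5, 4, length.out = 100),
#'                    matrix(rnorm(300), nrow = 3))
#' ss
#' @export
spectrum_set <- function(ppm, intensities, sample_ids = NULL) {
  ppm <- as.numeric(ppm)
  if (is.data.frame(intensities)) intensities <- as.matrix(intensities)
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1)
  storage.mode(intensities) <- "double"
  if (length(ppm) != ncol(intensities))
    stop("length(ppm) [", length(ppm), "] != ncol(intensities) [",
         ncol(intensities), "]")
  d <- diff(ppm)
  if (length(d) && all(d < 0)) {        # descending axis: reverse
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  } else if (any(d <= 0)) {
    stop("ppm axis must be strictly monotone")
  }
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stop("sample_ids length must equal the number of spectra")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  rownames(intensities) <- sample_ids
  structure(list(ppm = ppm, intensities = intensities,
                 sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d datapoints, %.3f-%.3f ppm\n",
              nrow(x$intensities), length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

#' Read a spectrum set from delimited text
#'
#' Expects a comma-delimited file whose first row is `ppm,<values...>` and
#' whose remaining rows are `sample_id,<intensities...>`.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return A [spectrum_set()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           blank.lines.skip = TRUE)
  if (nrow(raw) < 2)
    stop("spectrum file needs a ppm row and at least one sample row")
  ppm <- suppressWarnings(as.numeric(raw[1, -1]))
  if (anyNA(ppm))
    stop("non-numeric ppm values in header row (columns ",
         paste(which(is.na(ppm)) + 1L, collapse = ", "), ")")
  ids <- as.character(raw[-1, 1])
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[-1, -1, drop = FALSE])),
           nrow = nrow(raw) - 1L))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric intensity at data row ", bad[1],
         ", column ", bad[2] + 1L)
  }
  spectrum_set(ppm, vals, ids)
}

#' Write a spectrum set as delimited text
#'
#' @param x A [spectrum_set()].
#' @param path Output file path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("ppm", format(x$ppm, digits = 15, trim = TRUE)),
                   collapse = sep), con)
  for (i in seq_len(nrow(x$intensities)))
    writeLines(paste(c(x$sample_ids[i],
                       format(x$intensities[i, ], digits = 15, trim = TRUE)),
                     collapse = sep), con)
  invisible(path)
}

## index of the grid point nearest to each requested ppm
ppm_to_index <- function(ppm_axis, ppm) {
  vapply(ppm, function(v) which.min(abs(ppm_axis - v)), integer(1))
}
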