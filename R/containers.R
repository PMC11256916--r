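#' Contact map container
#'
#' A `contact_map` holds a dense symmetric matrix of binned chromatin
#' interaction counts for one chromosome, together with the bin width and a
#' record of which normalization steps have been applied. Bin `i` (0-based in
#' all on-disk formats) covers the half-open genomic interval
#' `[i * resolution, (i + 1) * resolution)`.
#'
#' @param matrix square symmetric numeric matrix of interaction values.
#' @param chrom chromosome label, e.g. `"chr7"`.
#' @param resolution bin width in bp (default 50000).
#' @param norm_state one of `"raw"`, `"libnorm"`, `"denoised"`, `"minmax"`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(matrix, chrom = "chr1", resolution = 50000L,
                        norm_state = c("raw", "libnorm", "denoised", "minmax")) {
  norm_state <- match.arg(norm_state)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != ncol(matrix)) {
    stop("shape error: contact matrix must be square")
  }
  if (max(abs(matrix - t(matrix))) > 1e-8) {
    stop("contact matrix must be symmetric within 1e-8")
  }
  if (norm_state == "raw" && any(matrix < 0)) {
    stop("invalid contact value: negative entries in a raw map")
  }
  if (norm_state == "minmax" && (min(matrix) < 0 || max(matrix) > 1)) {
    stop("minmax map must lie in [0, 1]")
  }
  structure(
    list(chrom = as.character(chrom), resolution = as.integer(resolution),
         matrix = matrix, norm_state = norm_state),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d bins @ %d bp [%s], total signal %.4g\n",
              x$chrom, nrow(x$matrix), x$resolution, x$norm_state,
              sum(x$matrix)))
  invisible(x)
}

#' Number of bins of a contact map
#' @param map a `contact_map`.
#' @return integer bin count.
#' @export
n_bins <- function(map) nrow(map$matrix)

#' Aligned per-bin 1-D signal tracks
#'
#' A `track_set` carries the five guide channels used for prediction, in the
#' fixed order scRNA+ , scRNA-, CTCF+, CTCF-, CpG, each a numeric vector with
#' one value per 50 kb (by default) bin of the paired contact map.
#'
#' @param channels a numeric matrix with one column per channel (bins in
#'   rows), or a list of 5 equal-length numeric vectors.
#' @param chrom chromosome label.
#' @param resolution bin width in bp.
#' @param norm_state normalization state tag (see [contact_map()]).
#' @return an object of class `track_set`.
#' @export
track_set <- function(channels, chrom = "chr1", resolution = 50000L,
                      norm_state = "raw") {
  if (is.list(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) != 1L) stop("all channels must have equal length")
    channels <- do.call(cbind, channels)
  }
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (ncol(channels) != 5L) stop("track_set requires exactly 5 channels")
  colnames(channels) <- track_channel_names()
  structure(
    list(chrom = as.character(chrom), resolution = as.integer(resolution),
         channels = channels, norm_state = norm_state),
    class = "track_set"
  )
}

#' Canonical channel order of a track set
#' @return character vector of the 5 channel names in their fixed order.
#' @export
track_channel_names <- function() {
  c("scRNA_plus", "scRNA_minus", "CTCF_plus", "CTCF_minus", "CpG")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %s: %d bins x 5 channels @ %d bp [%s]\n",
              x$chrom, nrow(x$channels), x$resolution, x$norm_state))
  invisible(x)
}

#' TAD boundary set
#'
#' Stores the sorted 0-based bin indices called as TAD boundaries on one
#' chromosome; a boundary at bin `b` separates bins `b - 1` and `b`.
#'
#' @param boundaries integer vector of 0-based bin indices, strictly
#'   increasing after sorting; duplicates are an error.
#' @param chrom chromosome label.
#' @param n_bins total bins on the chromosome (used for validation; optional).
#' @return an object of class `boundary_set`.
#' @export
boundary_set <- function(boundaries, chrom = "chr1", n_bins = NULL) {
  boundaries <- sort(as.integer(boundaries))
  if (anyDuplicated(boundaries)) stop("duplicate boundary indices")
  if (length(boundaries) && boundaries[1] < 0L) {
    stop("boundary indices must be >= 0")
  }
  if (!is.null(n_bins) && length(boundaries) &&
      boundaries[length(boundaries)] >= n_bins) {
    stop("boundary index beyond chromosome end")
  }
  structure(list(chrom = as.character(chrom), boundaries = boundaries,
                 n_bins = if (is.null(n_bins)) NA_integer_ else as.integer(n_bins)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set> %s: %d boundaries\n", x$chrom,
              length(x$boundaries)))
  invisible(x)
}
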