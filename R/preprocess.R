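#' Pseudo-bulk a cell-by-gene UMI table onto stranded genome tracks
#'
#' All cells of one pseudo-bulk are summed per gene; each gene's total UMI
#' count is then contributed to every bin its body overlaps on the track of
#' its strand, and each bin averages the contributions it received. Bins
#' overlapped by no gene are 0.
#'
#' @param cell_by_gene numeric matrix, cells in rows, genes in columns
#'   (column names identify genes).
#' @param gene_annotations data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @param chrom chromosome to build tracks for.
#' @param resolution bin width in bp.
#' @param n_bins bins on the chromosome.
#' @return list with numeric vectors `plus` and `minus` of length `n_bins`.
#' @export
pseudobulk_expression <- function(cell_by_gene, gene_annotations,
                                  chrom = "chr1", resolution = 50000L,
                                  n_bins) {
  cell_by_gene <- as.matrix(cell_by_gene)
  if (nrow(cell_by_gene) == 0L) stop("empty pseudo-bulk: no cells")
  totals <- colSums(cell_by_gene)
  known <- gene_annotations$chrom %in% chrom
  skipped <- setdiff(unique(gene_annotations$chrom), chrom)
  if (length(skipped) && any(!known)) {
    warning("genes on other chromosomes skipped: ",
            paste(utils::head(skipped, 3), collapse = ", "))
  }
  ann <- gene_annotations[known, , drop = FALSE]
  out <- list(plus = numeric(n_bins), minus = numeric(n_bins))
  cnt <- list(plus = numeric(n_bins), minus = numeric(n_bins))
  for (r in seq_len(nrow(ann))) {
    g <- as.character(ann$gene[r])
    if (!g %in% names(totals)) next
    b0 <- ann$start[r] %/% resolution
    b1 <- (ann$end[r] - 1L) %/% resolution
    b0 <- max(b0, 0L); b1 <- min(b1, n_bins - 1L)
    if (b1 < b0) next
    side <- if (ann$strand[r] == "+") "plus" else "minus"
    idx <- (b0:b1) + 1L
    out[[side]][idx] <- out[[side]][idx] + totals[g]
    cnt[[side]][idx] <- cnt[[side]][idx] + 1
  }
  for (side in c("plus", "minus")) {
    nz <- cnt[[side]] > 0
    out[[side]][nz] <- out[[side]][nz] / cnt[[side]][nz]
  }
  out
}

#' Library-size normalization
#'
#' Maps raw counts `T` to `log(T / sum(T) * alpha + pseudocount)` (natural
#' log), so pseudo-bulks with different cell counts end up on a comparable
#' read-likelihood scale. The pseudocount keeps empty bins finite.
#'
#' @param x non-negative numeric vector or matrix with positive total.
#' @param alpha library-size scale (default 25000).
#' @param pseudocount small positive value added inside the log
#'   (default 1e-8).
#' @return normalized array of the same shape, finite everywhere.
#' @export
library_size_normalize <- function(x, alpha = 25000, pseudocount = 1e-8) {
  stopifnot(alpha > 0, pseudocount > 0)
  if (any(x < 0)) stop("negative entries in count input")
  tot <- sum(x)
  if (tot <= 0) stop("empty library: input sums to zero")
  log(x / tot * alpha + pseudocount)
}

#' Normalize a contact map's library size
#'
#' @param map a [contact_map()].
#' @inheritParams library_size_normalize
#' @return a [contact_map()] with `norm_state = "libnorm"`.
#' @export
libnorm_contact_map <- function(map, alpha = 25000, pseudocount = 1e-8) {
  m <- library_size_normalize(map$matrix, alpha, pseudocount)
  contact_map(symmetrize_exact((m + t(m)) / 2), chrom = map$chrom,
              resolution = map$resolution, norm_state = "libnorm")
}

#' Eigenvalue soft-threshold denoising
#'
#' Decomposes a symmetric contact matrix into eigenvectors `P` and
#' eigenvalues, shrinks each eigenvalue by `sign(l) * max(|l| - t, 0)`, and
#' reconstructs `P %*% diag(l') %*% t(P)`. Small-magnitude eigenvalues carry
#' the high-frequency experimental noise of sparse scHi-C maps; shrinking
#' them suppresses that noise while never increasing the Frobenius norm.
#'
#' @param map a [contact_map()] (symmetric by construction).
#' @param threshold soft-threshold `t >= 0` (default 0.5).
#' @return a [contact_map()] with `norm_state = "denoised"`; entries may be
#'   negative (handled by the subsequent min-max step).
#' @export
eigen_denoise <- function(map, threshold = 0.5) {
  stopifnot(threshold >= 0)
  m <- map$matrix
  if (max(abs(m - t(m))) > 1e-8) stop("eigen_denoise requires a symmetric matrix")
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- sign(eg$values) * pmax(abs(eg$values) - threshold, 0)
  rec <- eg$vectors %*% (lam * t(eg$vectors))
  rec <- symmetrize_exact((rec + t(rec)) / 2)
  structure(list(chrom = map$chrom, resolution = map$resolution,
                 matrix = rec, norm_state = "denoised"),
            class = "contact_map")
}

#' Min-max scaling to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant input maps to all zeros.
#'
#' @param x numeric vector or matrix, non-empty.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (!length(x)) stop("empty input")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Min-max scale a contact map
#' @param map a [contact_map()].
#' @return a [contact_map()] with `norm_state = "minmax"`.
#' @export
minmax_contact_map <- function(map) {
  m <- minmax_normalize(map$matrix)
  structure(list(chrom = map$chrom, resolution = map$resolution,
                 matrix = symmetrize_exact(m), norm_state = "minmax"),
            class = "contact_map")
}

#' Min-max scale every channel of a track set
#' @param ts a [track_set()].
#' @param per_channel scale each channel independently (default) or jointly.
#' @return a [track_set()] with `norm_state = "minmax"`.
#' @export
minmax_track_set <- function(ts, per_channel = TRUE) {
  ch <- ts$channels
  if (per_channel) {
    ch <- apply(ch, 2, minmax_normalize)
  } else {
    ch <- minmax_normalize(ch)
  }
  track_set(ch, chrom = ts$chrom, resolution = ts$resolution,
            norm_state = "minmax")
}

#' The full target-map preprocessing stack
#'
#' Order of operations: library-size normalization, then (for sparse scHi-C
#' targets only) eigenvalue soft-threshold denoising, then min-max scaling.
#' Bulk Hi-C maps are deeply covered, so they skip the denoising step.
#'
#' @param map a raw [contact_map()].
#' @param denoise apply [eigen_denoise()] (TRUE for scHi-C targets, FALSE
#'   for bulk Hi-C).
#' @param alpha,pseudocount see [library_size_normalize()].
#' @param threshold see [eigen_denoise()].
#' @return a [contact_map()] with `norm_state = "minmax"`, values in [0, 1].
#' @export
preprocess_contact_map <- function(map, denoise = FALSE, alpha = 25000,
                                   pseudocount = 1e-8, threshold = 0.5) {
  out <- libnorm_contact_map(map, alpha = alpha, pseudocount = pseudocount)
  if (denoise) out <- eigen_denoise(out, threshold = threshold)
  minmax_contact_map(out)
}

#' Tiling specification
#'
#' @param window_bins square window size in bins (default 128, i.e. 6.4 Mbp
#'   at 50 kb).
#' @param stride_bins offset between consecutive windows; 16 for prediction
#'   inputs, 32 for bulk training tiles.
#' @param start_bin 0-based offset of the first window.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(window_bins = 128L, stride_bins = 16L, start_bin = 0L) {
  stopifnot(stride_bins > 0L, stride_bins <= window_bins, start_bin >= 0L)
  structure(list(window_bins = as.integer(window_bins),
                 stride_bins = as.integer(stride_bins),
                 start_bin = as.integer(start_bin)),
            class = "tile_spec")
}

#' Cut a chromosome into diagonal-aligned tiles
#'
#' Emits windows starting at `start_bin + k * stride_bins`; windows that
#' would overrun the chromosome are dropped, so short chromosome tails are
#' never padded.
#'
#' @param map a [contact_map()].
#' @param tracks a [track_set()] aligned to `map` (or NULL to omit feature
#'   blocks).
#' @param spec a [tile_spec()].
#' @return list of tiles, each `list(start_bin, matrix, features)` where
#'   `start_bin` is 0-based, `matrix` is the `window x window` submatrix and
#'   `features` the matching `window x 5` track block.
#' @export
tile_region <- function(map, tracks = NULL, spec = tile_spec()) {
  nb <- n_bins(map)
  w <- spec$window_bins
  if (!is.null(tracks) && nrow(tracks$channels) != nb) {
    stop("map and tracks have different bin counts")
  }
  if (nb < w) {
    warning("chromosome shorter than one window: no tiles emitted")
    return(list())
  }
  starts <- seq.int(spec$start_bin, nb - w, by = spec$stride_bins)
  lapply(starts, function(s) {
    idx <- (s + 1L):(s + w)
    list(start_bin = s,
         matrix = map$matrix[idx, idx, drop = FALSE],
         features = if (is.null(tracks)) NULL else
           tracks$channels[idx, , drop = FALSE])
  })
}

#' Train/test chromosome split
#'
#' By default chromosomes 7 and 11 (the most gene-dense mouse autosomes) are
#' held out for testing and the sex and mitochondrial chromosomes are
#' excluded from both sets.
#'
#' @param chroms character vector of chromosome labels.
#' @param test_chroms labels to hold out (default `c("chr7", "chr11")`;
#'   labels without the `chr` prefix are matched too).
#' @param exclude labels always dropped (default X, Y, MT).
#' @return list with character vectors `train` and `test`.
#' @export
split_chromosomes <- function(chroms, test_chroms = c("chr7", "chr11"),
                              exclude = c("X", "Y", "MT", "M")) {
  strip <- function(x) sub("^chr", "", x)
  keep <- !(toupper(strip(chroms)) %in% toupper(exclude))
  chroms <- chroms[keep]
  is_test <- strip(chroms) %in% strip(test_chroms)
  list(train = chroms[!is_test], test = chroms[is_test])
}
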