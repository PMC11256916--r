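#' Read a contact map from disk
#'
#' Three dialects are supported and auto-detected:
#' \describe{
#'   \item{cooler-style container}{a directory holding `bins.tsv`
#'     (chrom / start / end, 0-based half-open), `pixels.tsv`
#'     (bin1_id / bin2_id / count, upper triangle, global bin ids) and
#'     `info.json`; mirrors the single-resolution cooler schema as plain
#'     text tables.}
#'   \item{sparse text}{tab-separated with header line `# bin_i bin_j count`;
#'     0-based bin indices, upper triangle (`i <= j`); records below the
#'     diagonal are accepted and mirrored.}
#'   \item{dense text}{a whitespace-separated square matrix, optionally
#'     preceded by `# key=value` comment lines.}
#' }
#' Duplicate unordered pairs in sparse input are an error rather than summed,
#' so upstream double-counting bugs cannot slip through silently.
#'
#' @param path file (sparse/dense) or directory (cooler-style container).
#' @param chrom chromosome label to load; `NULL` (default for single-chrom
#'   files) takes the label recorded in the file header. The cooler-style
#'   container can hold several chromosomes, so there `chrom` is required.
#' @param resolution bin width in bp.
#' @param n_bins optional bin count; inferred from the file when absent.
#' @return a [contact_map()] with `norm_state = "raw"` unless the file header
#'   records another state.
#' @export
load_contact_map <- function(path, chrom = NULL, resolution = 50000L,
                             n_bins = NULL) {
  if (dir.exists(path)) {
    if (is.null(chrom)) stop("chrom is required for cooler-style containers")
    return(load_cooler_text(path, chrom))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header_meta(lines)
  if (is.null(chrom)) {
    chrom <- if (!is.null(meta$chrom)) meta$chrom else "chr1"
  } else if (!is.null(meta$chrom) && !identical(meta$chrom, chrom)) {
    stop("chromosome not found: ", chrom, " (file holds ", meta$chrom, ")")
  }
  if (!is.null(meta$resolution)) resolution <- as.integer(meta$resolution)
  if (!is.null(meta$n_bins) && is.null(n_bins)) n_bins <- as.integer(meta$n_bins)
  norm_state <- if (is.null(meta$norm_state)) "raw" else meta$norm_state

  is_sparse <- any(grepl("^#\\s*bin_i\\b", lines))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (is_sparse) {
    mat <- parse_sparse_records(body, n_bins)
  } else {
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    ncols <- unique(lengths(rows))
    if (length(ncols) != 1L || ncols != length(rows)) {
      stop("shape error: dense contact matrix must be square")
    }
    mat <- do.call(rbind, rows)
  }
  if (any(!is.finite(mat))) stop("invalid contact value: non-finite entry")
  if (norm_state == "raw" && any(mat < 0)) {
    stop("invalid contact value: negative count")
  }
  mat <- (mat + t(mat)) / 2
  mat <- symmetrize_exact(mat)
  contact_map(mat, chrom = chrom, resolution = resolution,
              norm_state = norm_state)
}

parse_header_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, gregexpr("[A-Za-z_]+=[^[:space:]]+", h))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- parts[2]
    }
  }
  meta
}

parse_sparse_records <- function(body, n_bins) {
  if (!length(body)) {
    if (is.null(n_bins)) stop("empty sparse file and no n_bins given")
    return(matrix(0, n_bins, n_bins))
  }
  rec <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(rec) != 3L) stop("sparse records must have 3 columns")
  i <- as.integer(rec[, 1]); j <- as.integer(rec[, 2]); v <- rec[, 3]
  if (any(i < 0L | j < 0L)) stop("negative bin index")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    if (lo[key == dup][1] == hi[key == dup][1]) {
      stop("duplicate diagonal record at bin ", dup)
    }
    stop("duplicate off-diagonal record for pair (", dup, ")")
  }
  nb <- if (is.null(n_bins)) max(hi) + 1L else as.integer(n_bins)
  if (any(hi >= nb)) stop("bin index beyond n_bins")
  mat <- matrix(0, nb, nb)
  mat[cbind(lo + 1L, hi + 1L)] <- v
  mat[cbind(hi + 1L, lo + 1L)] <- v
  mat
}

# Upper-triangle copy onto the lower triangle: exact symmetry, no tolerance.
symmetrize_exact <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

load_cooler_text <- function(path, chrom) {
  bins_f <- file.path(path, "bins.tsv")
  pix_f <- file.path(path, "pixels.tsv")
  info_f <- file.path(path, "info.json")
  if (!file.exists(bins_f) || !file.exists(pix_f)) {
    stop("not a cooler-style container: ", path)
  }
  info <- if (file.exists(info_f)) jsonlite::read_json(info_f) else list()
  bins <- utils::read.table(bins_f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  pix <- utils::read.table(pix_f, header = TRUE, sep = "\t")
  sel <- which(bins$chrom == chrom)
  if (!length(sel)) stop("chromosome not found: ", chrom)
  offset <- sel[1] - 1L
  nb <- length(sel)
  keep <- pix$bin1_id >= offset & pix$bin1_id < offset + nb &
    pix$bin2_id >= offset & pix$bin2_id < offset + nb
  pix <- pix[keep, , drop = FALSE]
  i <- pix$bin1_id - offset; j <- pix$bin2_id - offset
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) stop("duplicate off-diagonal record in pixels")
  mat <- matrix(0, nb, nb)
  mat[cbind(lo + 1L, hi + 1L)] <- pix$count
  mat[cbind(hi + 1L, lo + 1L)] <- pix$count
  res <- if (!is.null(info$resolution)) as.integer(info$resolution) else
    as.integer(bins$end[sel[1]] - bins$start[sel[1]])
  norm_state <- if (!is.null(info$norm_state)) info$norm_state else "raw"
  contact_map(mat, chrom = chrom, resolution = res, norm_state = norm_state)
}

#' Write a contact map to disk
#'
#' @param map a [contact_map()].
#' @param path output file (or directory for `format = "cooler"`).
#' @param format one of `"sparse_text"`, `"dense"`, `"cooler"`.
#' @return invisibly, `path`.
#' @seealso [load_contact_map()] for the dialects.
#' @export
write_contact_map <- function(map, path,
                              format = c("sparse_text", "dense", "cooler")) {
  format <- match.arg(format)
  m <- map$matrix
  nb <- nrow(m)
  if (format == "dense") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# chrom=%s resolution=%d n_bins=%d norm_state=%s",
                       map$chrom, map$resolution, nb, map$norm_state), con)
    utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                       con, sep = " ", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (format == "sparse_text") {
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# chrom=%s resolution=%d n_bins=%d norm_state=%s",
                         map$chrom, map$resolution, nb, map$norm_state),
                 "# bin_i bin_j count"), con)
    if (nrow(idx)) {
      writeLines(sprintf("%d\t%d\t%.12g", idx[, 1] - 1L, idx[, 2] - 1L,
                         m[idx]), con)
    }
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    starts <- (seq_len(nb) - 1L) * map$resolution
    utils::write.table(
      data.frame(chrom = map$chrom, start = starts,
                 end = starts + map$resolution),
      file.path(path, "bins.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    pix <- data.frame(bin1_id = idx[, 1] - 1L, bin2_id = idx[, 2] - 1L,
                      count = m[idx])
    con <- file(file.path(path, "pixels.tsv"), "w")
    writeLines("bin1_id\tbin2_id\tcount", con)
    if (nrow(pix)) {
      writeLines(sprintf("%d\t%d\t%.12g", pix$bin1_id, pix$bin2_id,
                         pix$count), con)
    }
    close(con)
    jsonlite::write_json(
      list(format = "cooler-text-v1", resolution = map$resolution,
           norm_state = map$norm_state),
      file.path(path, "info.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read the five guide tracks from bedGraph files
#'
#' Each bedGraph is binned onto the chromosome's 50 kb (by default) grid by
#' distributing interval signal in proportion to overlap length: the value of
#' bin `b` is `sum(value * overlap_bp) / resolution`, so uncovered stretches
#' contribute 0 and total signal mass is conserved for fully covered
#' chromosomes.
#'
#' @param paths character vector of 5 bedGraph paths in the fixed channel
#'   order scRNA+, scRNA-, CTCF+, CTCF-, CpG.
#' @param chrom chromosome label.
#' @param resolution bin width in bp.
#' @param n_bins number of bins on the chromosome.
#' @return a [track_set()].
#' @export
load_tracks <- function(paths, chrom = "chr1", resolution = 50000L,
                        n_bins) {
  if (length(paths) != 5L) stop("load_tracks requires exactly 5 paths")
  channels <- vapply(paths, function(p) {
    bin_bedgraph(p, chrom, resolution, n_bins)
  }, numeric(n_bins))
  track_set(channels, chrom = chrom, resolution = resolution)
}

bin_bedgraph <- function(path, chrom, resolution, n_bins) {
  if (!file.exists(path)) stop("track file not found: ", path)
  out <- numeric(n_bins)
  info <- file.info(path)
  if (info$size == 0) return(out)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (!length(gr)) return(out)
  # 0-based half-open coordinates
  starts <- GenomicRanges::start(gr) - 1L
  ends <- GenomicRanges::end(gr)
  vals <- gr$score
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]; vals <- vals[ord]
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("overlapping bedGraph intervals in ", path)
  }
  chrom_end <- n_bins * resolution
  if (any(ends > chrom_end)) {
    warning("interval beyond chromosome end clipped in ", path)
    starts <- pmin(starts, chrom_end)
    ends <- pmin(ends, chrom_end)
  }
  for (r in seq_along(vals)) {
    if (ends[r] <= starts[r]) next
    b0 <- starts[r] %/% resolution
    b1 <- (ends[r] - 1L) %/% resolution
    for (b in b0:b1) {
      ov <- min(ends[r], (b + 1) * resolution) - max(starts[r], b * resolution)
      out[b + 1L] <- out[b + 1L] + vals[r] * ov / resolution
    }
  }
  out
}

#' Write one track channel as bedGraph
#'
#' Bins with value 0 are omitted, following bedGraph sparsity conventions.
#'
#' @param values numeric per-bin vector.
#' @param path output path.
#' @param chrom chromosome label.
#' @param resolution bin width in bp.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(values, path, chrom = "chr1",
                           resolution = 50000L) {
  nb <- length(values)
  keep <- which(values != 0)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (keep - 1L) * resolution + 1L,
                              width = resolution),
    score = values[keep])
  GenomeInfoDb_safe_seqlengths(gr, chrom, nb * resolution)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# seqlengths are cosmetic for bedGraph export; ignore failures quietly.
GenomeInfoDb_safe_seqlengths <- function(gr, chrom, len) {
  try(suppressWarnings({
    sl <- stats::setNames(len, chrom)
    GenomicRanges::seqlengths(gr) <- sl
  }), silent = TRUE)
  invisible(gr)
}

#' Write a boundary set as BED3
#'
#' Each boundary is written as its bin's genomic interval.
#'
#' @param bs a [boundary_set()].
#' @param path output path.
#' @param resolution bin width in bp.
#' @return invisibly, `path`.
#' @export
write_boundaries <- function(bs, path, resolution = 50000L) {
  df <- data.frame(chrom = bs$chrom,
                   start = bs$boundaries * resolution,
                   end = (bs$boundaries + 1) * resolution)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
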