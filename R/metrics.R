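#' GenomeDISCO-style concordance score
#'
#' Models each contact map as a graph, row-normalizes it into a random-walk
#' transition matrix, and compares the smoothed structure of the two maps by
#' the L1 distance between their `t`-step transition matrices:
#' `score = 1 - mean_t( ||A^t - B^t||_1 / n_informative_rows ) / 2`,
#' where informative rows are rows nonzero in at least one map; zero rows
#' stay zero (no uniform fallback). 1 means identical hierarchical
#' organization; the score is floored at -1.
#'
#' @param A,B [contact_map()]s (or plain symmetric non-negative matrices)
#'   of the same shape.
#' @param t_steps random-walk step counts (default 3; the mean over steps is
#'   returned when several are given).
#' @return numeric score in `[-1, 1]`.
#' @export
genomedisco_score <- function(A, B, t_steps = 3L) {
  A <- as_map_matrix(A); B <- as_map_matrix(B)
  if (!all(dim(A) == dim(B))) stop("shape mismatch between contact maps")
  if (min(A) < 0 || min(B) < 0) stop("contact maps must be non-negative")
  Ta <- row_normalize(A)
  Tb <- row_normalize(B)
  informative <- sum(rowSums(A) > 0 | rowSums(B) > 0)
  if (informative == 0) stop("both maps are empty")
  d <- vapply(t_steps, function(t) {
    sum(abs(mat_power(Ta, t) - mat_power(Tb, t))) / informative
  }, numeric(1))
  max(1 - mean(d) / 2, -1)
}

as_map_matrix <- function(x) {
  if (inherits(x, "contact_map")) x$matrix else as.matrix(x)
}

row_normalize <- function(M) {
  rs <- rowSums(M)
  M / ifelse(rs > 0, rs, 1)
}

mat_power <- function(M, t) {
  out <- M
  for (i in seq_len(t - 1L)) out <- out %*% M
  out
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Compares two contact maps stratified by diagonal distance, as in HiCRep:
#' for each offset `s` in `1..max_stratum` the paired entries of that
#' diagonal give a Pearson correlation `rho_s`, weighted by
#' `N_s * sqrt(var(rank(x_s)) * var(rank(y_s)))` (the variance-stabilized
#' rank statistic); `SCC = sum(w_s rho_s) / sum(w_s)`. Strata degenerate in
#' either map are skipped. An optional mean-filter smoothing with half-width
#' `smooth_h` can be applied first (off by default: at 50 kb resolution the
#' maps are already coarse).
#'
#' @param A,B [contact_map()]s or matrices of the same shape.
#' @param max_stratum largest diagonal offset compared; default
#'   `min(n - 1, 64)`, i.e. up to 3.2 Mbp at 50 kb (half the model window).
#' @param smooth_h mean-filter half-width in bins (default 0 = none).
#' @return numeric score in `[-1, 1]`.
#' @export
scc_score <- function(A, B, max_stratum = NULL, smooth_h = 0L) {
  A <- as_map_matrix(A); B <- as_map_matrix(B)
  if (!all(dim(A) == dim(B))) stop("shape mismatch between contact maps")
  n <- nrow(A)
  if (is.null(max_stratum)) max_stratum <- min(n - 1L, 64L)
  if (max_stratum >= n) stop("max_stratum must be smaller than n_bins")
  if (smooth_h > 0L) {
    A <- mean_filter(A, smooth_h)
    B <- mean_filter(B, smooth_h)
  }
  num <- 0; den <- 0
  for (s in seq_len(max_stratum)) {
    idx <- seq_len(n - s)
    x <- A[cbind(idx, idx + s)]
    y <- B[cbind(idx, idx + s)]
    if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) next
    r <- stats::cor(x, y)
    w <- length(x) * sqrt(stats::var(rank(x)) * stats::var(rank(y)))
    num <- num + w * r
    den <- den + w
  }
  if (den == 0) stop("no informative strata")
  num / den
}

mean_filter <- function(M, h) {
  n <- nrow(M)
  out <- M
  for (i in seq_len(n)) {
    ri <- max(1L, i - h):min(n, i + h)
    for (j in seq_len(n)) {
      rj <- max(1L, j - h):min(n, j + h)
      out[i, j] <- mean(M[ri, rj])
    }
  }
  out
}

#' Insulation-score TAD boundary caller
#'
#' Computes, for each bin `b`, the mean contact frequency in the
#' `window x window` square straddling the diagonal at `b` (rows
#' `b-window..b-1`, columns `b..b+window-1`, 0-based); TAD boundaries are the
#' local minima of this insulation profile with topographic prominence of at
#' least `min_prominence` standard deviations of the profile. Prominence is
#' measured relative to the profile's spread, so uniform rescaling of the
#' map leaves the calls unchanged.
#'
#' @param map a [contact_map()] or symmetric matrix.
#' @param window square size in bins (default 10, i.e. 500 kb at 50 kb).
#' @param min_prominence minimum prominence in units of the profile standard
#'   deviation (default 0.1).
#' @return a [boundary_set()] of 0-based bin indices.
#' @export
call_tad_boundaries <- function(map, window = 10L, min_prominence = 0.1) {
  chrom <- if (inherits(map, "contact_map")) map$chrom else "chr1"
  M <- as_map_matrix(map)
  n <- nrow(M)
  if (2L * window > n) stop("window too large for this map")
  # profile[b + 1] is the insulation at boundary position b (0-based)
  profile <- rep(NA_real_, n)
  for (b in window:(n - window)) {
    profile[b + 1L] <- mean(M[(b - window + 1L):b,
                              (b + 1L):(b + window), drop = FALSE])
  }
  valid <- which(!is.na(profile))
  p <- profile[valid]
  sdp <- stats::sd(p)
  if (!is.finite(sdp) || sdp == 0) {
    return(boundary_set(integer(0), chrom = chrom, n_bins = n))
  }
  mins <- local_minima(p)
  prom <- vapply(mins, function(i) prominence_at(p, i), numeric(1))
  keep <- mins[prom >= min_prominence * sdp]
  boundary_set(valid[keep] - 1L, chrom = chrom, n_bins = n)
}

local_minima <- function(p) {
  n <- length(p)
  if (n < 3L) return(integer(0))
  idx <- which(p[2:(n - 1L)] < p[1:(n - 2L)] & p[2:(n - 1L)] <= p[3:n]) + 1L
  idx
}

# topographic prominence of an (inverted) peak at index i: the smaller of
# the highest barriers separating it from deeper minima (or the ends)
prominence_at <- function(p, i) {
  n <- length(p)
  left_max <- -Inf
  j <- i - 1L
  while (j >= 1L) {
    left_max <- max(left_max, p[j])
    if (p[j] < p[i]) break
    j <- j - 1L
  }
  if (j < 1L) left_max <- max(p[seq_len(max(i - 1L, 1L))])
  right_max <- -Inf
  j <- i + 1L
  while (j <= n) {
    right_max <- max(right_max, p[j])
    if (p[j] < p[i]) break
    j <- j + 1L
  }
  if (j > n) right_max <- max(p[i:n])
  min(left_max, right_max) - p[i]
}

#' TAD boundary F1 comparison
#'
#' Greedy one-to-one nearest-first matching of predicted to target
#' boundaries within `tol` bins (ties broken by the lower coordinate);
#' matched pairs are true positives, unmatched predictions false positives,
#' unmatched targets false negatives, and
#' `F1 = 2 TP / (2 TP + FP + FN)`.
#'
#' @param pred,target [boundary_set()]s (or integer vectors of 0-based
#'   bins).
#' @param tol matching tolerance in bins (default 1, i.e. 50 kb).
#' @return list with `TP`, `FP`, `FN`, `f1`.
#' @export
tad_f1 <- function(pred, target, tol = 1L) {
  p <- if (inherits(pred, "boundary_set")) pred$boundaries else
    sort(as.integer(pred))
  t_ <- if (inherits(target, "boundary_set")) target$boundaries else
    sort(as.integer(target))
  if (!length(p) && !length(t_)) {
    return(list(TP = 0L, FP = 0L, FN = 0L, f1 = 1))
  }
  pairs <- expand.grid(pi = seq_along(p), ti = seq_along(t_))
  if (nrow(pairs)) {
    pairs$dist <- abs(p[pairs$pi] - t_[pairs$ti])
    pairs <- pairs[pairs$dist <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, p[pairs$pi], t_[pairs$ti]), ,
                   drop = FALSE]
  }
  used_p <- logical(length(p)); used_t <- logical(length(t_))
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$pi[r]; j <- pairs$ti[r]
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used_p); fn <- sum(!used_t)
  f1 <- if (tp == 0L && (fp + fn) > 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  list(TP = tp, FP = as.integer(fp), FN = as.integer(fn), f1 = f1)
}
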