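#' Symmetric normalized Laplacian of a contact-map graph
#'
#' Treats a (sub)matrix of bulk Hi-C as a weighted graph: nodes are bins,
#' edge weights are the off-diagonal contact values (self-loops are excluded
#' because the matrix diagonal carries no structural information). Returns
#' `I - D^{-1/2} A D^{-1/2}` with `D` the weighted degree; rows of zero
#' degree reduce to the identity row so sparse tiles stay well-defined.
#'
#' @param H square symmetric non-negative matrix.
#' @return symmetric normalized Laplacian matrix of the same size.
#' @export
normalized_laplacian <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) stop("Laplacian input must be square")
  if (max(abs(H - t(H))) > 1e-8) stop("Laplacian input must be symmetric")
  if (min(H) < 0) stop("Laplacian input must be non-negative")
  A <- H
  diag(A) <- 0
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -A * (inv_sqrt %o% inv_sqrt)
  diag(L) <- 1
  symmetrize_exact((L + t(L)) / 2)
}

#' Laplacian eigenvector positional encodings
#'
#' Eigendecomposes the normalized Laplacian of a bulk Hi-C (sub)matrix and
#' returns the `k` eigenvectors of smallest eigenvalue as node coordinates.
#' These low-frequency components encode the coarse topology of the contact
#' graph (compartments, TAD blocks), giving each bin a position in the 3-D
#' organization rather than along the 1-D sequence. Each column's sign is
#' fixed so its largest-magnitude entry is positive (ties broken by lowest
#' index), making the encodings reproducible across platforms.
#'
#' @param H square symmetric non-negative matrix (the tile's bulk Hi-C).
#' @param k number of components (default 16); must be `< nrow(H)`.
#' @param largest take the largest-eigenvalue eigenvectors instead
#'   (default FALSE, i.e. smallest).
#' @return list with `vectors` (`n x k` matrix, columns ordered by ascending
#'   eigenvalue) and `values` (the corresponding eigenvalues).
#' @export
positional_encodings <- function(H, k = 16L, largest = FALSE) {
  n <- nrow(as.matrix(H))
  if (k >= n) stop("k must be smaller than the number of nodes")
  L <- normalized_laplacian(H)
  eg <- eigen(L, symmetric = TRUE)
  # eigen() returns descending order; flip to ascending
  ord <- rev(seq_len(n))
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  sel <- if (largest) seq.int(n - k + 1L, n) else seq_len(k)
  vals <- vals[sel]
  vecs <- vecs[, sel, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))  # lowest index wins ties
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(vectors = vecs, values = vals)
}

#' Assemble a per-tile region graph
#'
#' Combines a 128 x 128 (by default) bulk Hi-C tile with the matching
#' 128 x 5 guide-track block: node features are the 5 channels concatenated
#' with `k` Laplacian positional-encoding components, and the edge set is
#' the strictly off-diagonal nonzero entries of the tile.
#'
#' @param bulk_tile square symmetric non-negative matrix.
#' @param feature_block matrix with one row per node and 5 columns.
#' @param k positional-encoding components (default 16).
#' @return object of class `region_graph`: `n_nodes`, `edge_weights`
#'   (zero-diagonal symmetric matrix), `node_features`
#'   (`n x (5 + k)`), `pe_values`.
#' @export
build_region_graph <- function(bulk_tile, feature_block, k = 16L) {
  bulk_tile <- as.matrix(bulk_tile)
  feature_block <- as.matrix(feature_block)
  if (any(!is.finite(bulk_tile)) || any(!is.finite(feature_block))) {
    stop("NaN/Inf in region graph inputs")
  }
  n <- nrow(bulk_tile)
  if (nrow(feature_block) != n) stop("feature block rows must match tile bins")
  pe <- positional_encodings(bulk_tile, k = k)
  E <- bulk_tile
  diag(E) <- 0
  structure(list(n_nodes = n, edge_weights = E,
                 node_features = cbind(feature_block, pe$vectors),
                 pe_values = pe$values),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %d nodes, %d edges, feature width %d\n",
              x$n_nodes, sum(x$edge_weights[upper.tri(x$edge_weights)] != 0),
              ncol(x$node_features)))
  invisible(x)
}
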