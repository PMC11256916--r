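#' Model architecture configuration
#'
#' Holds every architecture hyperparameter with its default. The published
#' geometry (128-bin windows, 5 guide channels, 16 positional-encoding
#' components, a single window-16 Conv1D filter) is fixed by the defaults;
#' hidden widths and depths are deliberately small so the model trains in
#' minutes on one CPU and can be widened via this config.
#'
#' @param conv_window Conv1D window size in bins (default 16).
#' @param conv_filters output channels of the Conv1D layer (default NULL =
#'   `d_model`). When it differs from `d_model` a learned linear lift maps
#'   the filter outputs to the transformer width; `conv_filters = 1`
#'   selects the literal single-filter variant, which squeezes every bin
#'   through one scalar and is kept only as an ablation (it starves the
#'   downstream attention of node identity).
#' @param d_model latent width (default 64; the node-latent rank available
#'   to the inner-product decoder for a 128-bin window).
#' @param n_transformer_blocks_nfp encoder blocks in the node feature
#'   processor (default 2).
#' @param n_transformer_blocks_map encoder blocks in the mapping stage
#'   (default 2; 0 makes the mapping an identity).
#' @param n_attention_heads heads per attention layer (default 4); must
#'   divide `d_model`.
#' @param n_gat_layers graph attention layers (default 1).
#' @param n_residual_blocks 2-D convolutional residual blocks in the decoder
#'   (default 2).
#' @param n_residual_channels channels inside the decoder blocks (default 4).
#' @param pe_k positional-encoding components (default 16).
#' @param dropout dropout rate during training (default 0.1).
#' @param seed integer seed controlling weight initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(conv_window = 16L, conv_filters = NULL,
                         d_model = 64L,
                         n_transformer_blocks_nfp = 2L,
                         n_transformer_blocks_map = 2L,
                         n_attention_heads = 4L, n_gat_layers = 1L,
                         n_residual_blocks = 2L, n_residual_channels = 4L,
                         pe_k = 16L, dropout = 0.1, seed = 1L) {
  if (d_model %% n_attention_heads != 0L) {
    stop("d_model must be divisible by n_attention_heads")
  }
  if (is.null(conv_filters)) conv_filters <- d_model
  stopifnot(conv_window >= 1L, conv_filters >= 1L, n_gat_layers >= 1L,
            n_residual_blocks >= 1L, pe_k >= 1L, dropout >= 0, dropout < 1)
  structure(list(
    conv_window = as.integer(conv_window),
    conv_filters = as.integer(conv_filters),
    d_model = as.integer(d_model),
    n_transformer_blocks_nfp = as.integer(n_transformer_blocks_nfp),
    n_transformer_blocks_map = as.integer(n_transformer_blocks_map),
    n_attention_heads = as.integer(n_attention_heads),
    n_gat_layers = as.integer(n_gat_layers),
    n_residual_blocks = as.integer(n_residual_blocks),
    n_residual_channels = as.integer(n_residual_channels),
    pe_k = as.integer(pe_k),
    d_k = as.integer(d_model) %/% as.integer(n_attention_heads),
    dropout = dropout, seed = as.integer(seed)), class = "model_config")
}

glorot <- function(n_in, n_out, shape = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(shape), -lim, lim), shape)
}

init_transformer_block <- function(p, prefix, d) {
  p[[paste0(prefix, "Wq")]] <- glorot(d, d)
  p[[paste0(prefix, "Wk")]] <- glorot(d, d)
  p[[paste0(prefix, "Wv")]] <- glorot(d, d)
  p[[paste0(prefix, "Wo")]] <- glorot(d, d)
  p[[paste0(prefix, "ln1_g")]] <- rep(1, d)
  p[[paste0(prefix, "ln1_b")]] <- rep(0, d)
  p[[paste0(prefix, "W1")]] <- glorot(d, 2L * d)
  p[[paste0(prefix, "b1")]] <- rep(0, 2L * d)
  p[[paste0(prefix, "W2")]] <- glorot(2L * d, d)
  p[[paste0(prefix, "b2")]] <- rep(0, d)
  p[[paste0(prefix, "ln2_g")]] <- rep(1, d)
  p[[paste0(prefix, "ln2_b")]] <- rep(0, d)
  p
}

#' Initialize a graph-deconvolution model
#'
#' Builds the full parameter set of the architecture: node feature processor
#' (Conv1D + linear lift + transformer encoder blocks), graph attention
#' deconvolution layer(s), mapping transformer blocks, and the inner-product
#' decoder with residual 2-D convolutional refinement. Initialization is
#' Glorot-uniform and fully determined by `config$seed`.
#'
#' @param config a [model_config()].
#' @return object of class `scghd_model` with elements `config`, `params`,
#'   and a training `history` (empty until [train_model()] is run).
#' @export
scghd_model <- function(config = model_config()) {
  set.seed(config$seed)
  d <- config$d_model
  cf <- config$conv_filters
  feat_width <- 5L + config$pe_k
  p <- list()
  p$conv_W <- glorot(config$conv_window * feat_width, cf,
                     c(config$conv_window, feat_width, cf))
  p$conv_b <- rep(0, cf)
  if (cf != d) {
    p$lift_W <- glorot(cf, d)
    p$lift_b <- rep(0, d)
  }
  for (b in seq_len(config$n_transformer_blocks_nfp)) {
    p <- init_transformer_block(p, sprintf("nfp%d_", b), d)
  }
  for (g in seq_len(config$n_gat_layers)) {
    pre <- sprintf("gat%d_", g)
    p[[paste0(pre, "W1")]] <- glorot(d, d)
    p[[paste0(pre, "W2")]] <- glorot(d, d)
    p[[paste0(pre, "w3")]] <- stats::runif(d, -0.1, 0.1)
    p[[paste0(pre, "a")]] <- stats::runif(d, -0.1, 0.1)
  }
  for (b in seq_len(config$n_transformer_blocks_map)) {
    p <- init_transformer_block(p, sprintf("map%d_", b), d)
  }
  # decoder input projection: frees the node latents from the unit-norm
  # manifold that the encoder blocks' final layer normalization imposes, so
  # inner products can carry per-node magnitude
  p$dec_proj_W <- glorot(d, d)
  p$dec_proj_b <- rep(0, d)
  # skip connection from the raw node features (guide tracks + positional
  # encodings) into the decoder latent: keeps a live gradient path when the
  # encoder output degenerates toward rank one (the Gram-decoder saddle)
  p$dec_skip_W <- glorot(feat_width, d)
  # decoder convolutions start at 0.3x Glorot scale so the pre-sigmoid
  # activations begin near 0 (output ~0.5) instead of in the saturated
  # tails where gradients vanish
  cch <- config$n_residual_channels
  # two input channels: the inner-product likelihood map and the bulk tile
  # itself — the refinement modulates the bulk prior instead of having to
  # reconstruct its sharp boundary structure from the latents alone
  p$dec_in_K <- 0.3 * glorot(18L, cch, c(3L, 3L, 2L, cch))
  p$dec_in_b <- rep(0, cch)
  for (r in seq_len(config$n_residual_blocks)) {
    pre <- sprintf("res%d_", r)
    p[[paste0(pre, "K1")]] <- 0.3 * glorot(9L * cch, cch,
                                           c(3L, 3L, cch, cch))
    p[[paste0(pre, "b1")]] <- rep(0, cch)
    p[[paste0(pre, "K2")]] <- 0.3 * glorot(9L * cch, cch,
                                           c(3L, 3L, cch, cch))
    p[[paste0(pre, "b2")]] <- rep(0, cch)
  }
  p$dec_out_K <- 0.3 * glorot(9L * cch, 1L, c(3L, 3L, cch, 1L))
  p$dec_out_b <- 0
  structure(list(config = config, params = p, history = numeric(0)),
            class = "scghd_model")
}

## ---- staged forward passes ---------------------------------------------

#' Node feature processor
#'
#' A single Conv1D filter (window `conv_window`) slides along the bin axis of
#' the node feature set (guide channels + positional encodings), extracting a
#' localized signal that a learned linear lift widens to `d_model`; stacked
#' transformer encoder blocks then mix features across all bins.
#'
#' @param model a [scghd_model()].
#' @param X node feature matrix, `n x (5 + pe_k)`.
#' @param train apply dropout (default FALSE).
#' @return `n x d_model` matrix of processed node features. Internally used
#'   with a cache for backpropagation.
#' @export
node_feature_processor <- function(model, X, train = FALSE) {
  nfp_forward(model$params, model$config, X, train)$Y
}

nfp_forward <- function(p, cfg, X, train = FALSE) {
  if (any(!is.finite(X))) stop("NaN in node feature input")
  cv <- conv1d_forward(X, p$conv_W, p$conv_b)
  Fset <- cv$Y
  Z <- if (is.null(p$lift_W)) Fset else
    sweep(Fset %*% p$lift_W, 2, p$lift_b, `+`)
  blocks <- vector("list", cfg$n_transformer_blocks_nfp)
  for (b in seq_len(cfg$n_transformer_blocks_nfp)) {
    tb <- transformer_block_forward(Z, p, sprintf("nfp%d_", b),
                                    cfg$n_attention_heads, cfg$dropout, train)
    Z <- tb$Y
    blocks[[b]] <- tb$cache
  }
  list(Y = Z, cache = list(conv = cv$cache, F = Fset, blocks = blocks))
}

nfp_backward <- function(dZ, p, cfg, cache) {
  gr <- list()
  for (b in rev(seq_len(cfg$n_transformer_blocks_nfp))) {
    tb <- transformer_block_backward(dZ, cache$blocks[[b]],
                                     sprintf("nfp%d_", b))
    dZ <- tb$dX
    gr <- c(gr, tb$grads)
  }
  if (!is.null(p$lift_W)) {
    gr$lift_W <- t(cache$F) %*% dZ
    gr$lift_b <- colSums(dZ)
    dZ <- dZ %*% t(p$lift_W)
  }
  cb <- conv1d_backward(dZ, cache$conv)
  gr$conv_W <- cb$dW
  gr$conv_b <- cb$db
  list(grads = gr)
}

#' Graph attention deconvolution layer
#'
#' Aggregates each bin's neighbors in the bulk Hi-C graph, weighting every
#' edge by a softmax-normalized additive attention logit
#' `a . LeakyReLU(W1 z_i + W2 z_j + w3 e_ij)`. Self-loops are excluded from
#' the softmax (the map diagonal is structurally uninformative); the source
#' node contributes through a fixed-coefficient `W1 z_i` self-term instead.
#' The attention coefficients are the deconvolution: they prune bulk edges
#' that the cell-type-specific guide signal does not support.
#'
#' @param model a [scghd_model()].
#' @param graph a [build_region_graph()] result (edge weights used).
#' @param Z node states, `n x d_model` (e.g. [node_feature_processor()]
#'   output).
#' @param layer which GAT layer's parameters to use (default 1).
#' @return list with `Z` (updated node states) and `alpha` (dense attention
#'   matrix; rows sum to 1 over each node's neighborhood).
#' @export
gat_layer <- function(model, graph, Z, layer = 1L) {
  pre <- sprintf("gat%d_", layer)
  p <- model$params
  out <- gat_forward(Z, graph$edge_weights, p[[paste0(pre, "W1")]],
                     p[[paste0(pre, "W2")]], p[[paste0(pre, "w3")]],
                     p[[paste0(pre, "a")]])
  list(Z = out$Y, alpha = out$alpha)
}

#' Mapping encoder
#'
#' Stacked transformer encoder blocks that map the GAT output into the node
#' latent space whose inner products encode contact likelihoods. With
#' `n_transformer_blocks_map = 0` this stage is the identity.
#'
#' @param model a [scghd_model()].
#' @param Z node states, `n x d_model`.
#' @param train apply dropout (default FALSE).
#' @return `n x d_model` latent matrix.
#' @export
mapping_encoder <- function(model, Z, train = FALSE) {
  map_forward(model$params, model$config, Z, train)$Y
}

map_forward <- function(p, cfg, Z, train = FALSE) {
  blocks <- vector("list", cfg$n_transformer_blocks_map)
  for (b in seq_len(cfg$n_transformer_blocks_map)) {
    tb <- transformer_block_forward(Z, p, sprintf("map%d_", b),
                                    cfg$n_attention_heads, cfg$dropout, train)
    Z <- tb$Y
    blocks[[b]] <- tb$cache
  }
  list(Y = Z, cache = blocks)
}

map_backward <- function(dZ, cfg, cache) {
  gr <- list()
  for (b in rev(seq_len(cfg$n_transformer_blocks_map))) {
    tb <- transformer_block_backward(dZ, cache[[b]], sprintf("map%d_", b))
    dZ <- tb$dX
    gr <- c(gr, tb$grads)
  }
  list(dX = dZ, grads = gr)
}

#' Graph decoder
#'
#' Takes the inner product `Z %*% t(Z)` of the node latents (a symmetric
#' contact-likelihood map), refines it with residual 2-D convolutional
#' blocks, applies a sigmoid, and symmetrizes the result by averaging with
#' its transpose.
#'
#' @param model a [scghd_model()].
#' @param Z node latent matrix, `n x d_model`.
#' @param features optional node feature block (guide tracks + positional
#'   encodings) for the decoder's skip connection; omitted, the decoder
#'   works from the latents alone.
#' @param bulk optional bulk tile conditioning the residual refinement
#'   (the model's prior); omitted, the refinement sees only the
#'   inner-product map.
#' @return symmetric `n x n` matrix with entries in (0, 1).
#' @export
graph_decoder <- function(model, Z, features = NULL, bulk = NULL) {
  decoder_forward(model$params, model$config, Z, features = features,
                  bulk = bulk)$Y
}

decoder_forward <- function(p, cfg, Z, features = NULL, bulk = NULL) {
  n <- nrow(Z)
  # learned projection off the layer-norm manifold (plus the node-feature
  # skip), then the inner-product likelihood map, scaled by 1/d so the
  # refinement convolutions start in the responsive range of the sigmoid
  Zp <- sweep(Z %*% p$dec_proj_W, 2, p$dec_proj_b, `+`)
  if (!is.null(features)) Zp <- Zp + features %*% p$dec_skip_W
  L <- Zp %*% t(Zp) / ncol(Zp)
  if (is.null(bulk)) bulk <- matrix(0, n, n)
  X_in <- array(c(L, bulk), c(n, n, 2L))
  c_in <- conv2d_forward(X_in, p$dec_in_K, p$dec_in_b)
  # note: `bulk` here is the conditioning channel; the full model passes
  # the attention-modulated bulk (n * sym(alpha) .* E), not the raw tile
  H <- c_in$Y
  blocks <- vector("list", cfg$n_residual_blocks)
  for (r in seq_len(cfg$n_residual_blocks)) {
    pre <- sprintf("res%d_", r)
    c1 <- conv2d_forward(H, p[[paste0(pre, "K1")]], p[[paste0(pre, "b1")]])
    A <- relu(c1$Y)
    c2 <- conv2d_forward(A, p[[paste0(pre, "K2")]], p[[paste0(pre, "b2")]])
    blocks[[r]] <- list(c1 = c1$cache, pre_relu = c1$Y, c2 = c2$cache)
    H <- H + c2$Y
  }
  c_out <- conv2d_forward(H, p$dec_out_K, p$dec_out_b)
  Q <- sigmoid(c_out$Y[, , 1L])
  Y <- (Q + t(Q)) / 2
  list(Y = symmetrize_exact(Y),
       cache = list(Z = Z, Zp = Zp, proj_W = p$dec_proj_W,
                    features = features, c_in = c_in$cache,
                    blocks = blocks, c_out = c_out$cache, Q = Q, n = n))
}

decoder_backward <- function(dY, cfg, cache) {
  n <- cache$n
  gr <- list()
  dQ <- (dY + t(dY)) / 2
  dPre <- dQ * cache$Q * (1 - cache$Q)
  co <- conv2d_backward(array(dPre, c(n, n, 1L)), cache$c_out)
  gr$dec_out_K <- co$dK; gr$dec_out_b <- co$db
  dH <- co$dX
  for (r in rev(seq_len(cfg$n_residual_blocks))) {
    pre <- sprintf("res%d_", r)
    blk <- cache$blocks[[r]]
    c2b <- conv2d_backward(dH, blk$c2)
    gr[[paste0(pre, "K2")]] <- c2b$dK; gr[[paste0(pre, "b2")]] <- c2b$db
    dA <- c2b$dX * (blk$pre_relu > 0)
    c1b <- conv2d_backward(dA, blk$c1)
    gr[[paste0(pre, "K1")]] <- c1b$dK; gr[[paste0(pre, "b1")]] <- c1b$db
    dH <- dH + c1b$dX
  }
  ci <- conv2d_backward(dH, cache$c_in)
  gr$dec_in_K <- ci$dK; gr$dec_in_b <- ci$db
  dCond <- matrix(ci$dX[, , 2L], n, n)
  dL <- matrix(ci$dX[, , 1L], n, n)
  dZp <- (dL + t(dL)) %*% cache$Zp / ncol(cache$Zp)
  gr$dec_proj_W <- t(cache$Z) %*% dZp
  gr$dec_proj_b <- colSums(dZp)
  if (!is.null(cache$features)) {
    gr$dec_skip_W <- t(cache$features) %*% dZp
  }
  dZ <- dZp %*% t(cache$proj_W)
  list(dZ = dZ, dCond = dCond, grads = gr)
}

## ---- full forward / backward -------------------------------------------

model_forward <- function(p, cfg, bulk_tile, features, train = FALSE) {
  graph <- build_region_graph(bulk_tile, features, k = cfg$pe_k)
  nfp <- nfp_forward(p, cfg, graph$node_features, train)
  gat_caches <- vector("list", cfg$n_gat_layers)
  Z <- nfp$Y
  alpha <- NULL
  for (g in seq_len(cfg$n_gat_layers)) {
    pre <- sprintf("gat%d_", g)
    gt <- gat_forward(Z, graph$edge_weights, p[[paste0(pre, "W1")]],
                      p[[paste0(pre, "W2")]], p[[paste0(pre, "w3")]],
                      p[[paste0(pre, "a")]])
    Z <- gt$Y
    alpha <- gt$alpha
    gat_caches[[g]] <- gt$cache
  }
  mp <- map_forward(p, cfg, Z, train)
  # deconvolved prior: bulk edges rescaled by the (symmetrized) attention
  # coefficients; at uniform attention this is the bulk tile itself
  n <- graph$n_nodes
  cond <- n * (alpha + t(alpha)) / 2 * graph$edge_weights
  dec <- decoder_forward(p, cfg, mp$Y, features = graph$node_features,
                         bulk = cond)
  list(Y = dec$Y,
       cache = list(nfp = nfp$cache, gat = gat_caches, map = mp$cache,
                    dec = dec$cache, E = graph$edge_weights, n = n))
}

model_backward <- function(dY, p, cfg, cache) {
  db <- decoder_backward(dY, cfg, cache$dec)
  gr <- db$grads
  # gradient through the attention-modulated conditioning channel
  dA_extra <- cache$n * (db$dCond + t(db$dCond)) / 2 * cache$E
  mb <- map_backward(db$dZ, cfg, cache$map)
  gr <- c(gr, mb$grads)
  dZ <- mb$dX
  for (g in rev(seq_len(cfg$n_gat_layers))) {
    pre <- sprintf("gat%d_", g)
    gb <- gat_backward(dZ, cache$gat[[g]],
                       dA_extra = if (g == cfg$n_gat_layers) dA_extra
                       else NULL)
    gr[[paste0(pre, "W1")]] <- gb$dW1
    gr[[paste0(pre, "W2")]] <- gb$dW2
    gr[[paste0(pre, "w3")]] <- gb$dw3
    gr[[paste0(pre, "a")]] <- gb$da
    dZ <- gb$dX
  }
  nb <- nfp_backward(dZ, p, cfg, cache$nfp)
  c(gr, nb$grads)
}

#' Predict one tile
#'
#' Full forward pass: region graph with positional encodings, node feature
#' processor, graph attention deconvolution, mapping encoder, inner-product
#' decoder. Deterministic in inference mode.
#'
#' @param model a [scghd_model()].
#' @param bulk_tile square symmetric non-negative matrix (min-max scale).
#' @param features matching `n x 5` guide-track block.
#' @return symmetric matrix of the tile's predicted contact intensities in
#'   (0, 1).
#' @export
predict_tile <- function(model, bulk_tile, features) {
  if (nrow(as.matrix(features)) != nrow(as.matrix(bulk_tile))) {
    stop("shape mismatch between bulk tile and feature block")
  }
  model_forward(model$params, model$config, bulk_tile, features)$Y
}

#' @export
print.scghd_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0(
    "<scghd_model> d_model=%d heads=%d nfp_blocks=%d gat_layers=%d ",
    "map_blocks=%d res_blocks=%d pe_k=%d (%d parameters)\n"),
    x$config$d_model, x$config$n_attention_heads,
    x$config$n_transformer_blocks_nfp, x$config$n_gat_layers,
    x$config$n_transformer_blocks_map, x$config$n_residual_blocks,
    x$config$pe_k, np))
  if (length(x$history)) {
    cat(sprintf("  trained %d epochs, final MSE %.6g\n", length(x$history),
                x$history[length(x$history)]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.scghd_model <- function(object, ...) {
  print(object)
  sizes <- vapply(object$params, length, integer(1))
  cat("parameter blocks:\n")
  for (nm in names(sizes)) cat(sprintf("  %-12s %d\n", nm, sizes[nm]))
  invisible(object)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON (text) containers holding the config, every
#' parameter array with its dimensions, the loss history, and a format
#' version tag. Loading refuses checkpoints whose feature geometry
#' (`pe_k`, channel count) does not match the current format.
#'
#' @param model a [scghd_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format_version = "scghd-ckpt-1",
    config = unclass(model$config),
    history = model$history,
    params = lapply(model$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.numeric(p))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format_version, "scghd-ckpt-1")) {
    stop("unsupported checkpoint format: ", payload$format_version)
  }
  cfg_args <- payload$config
  cfg_args$d_k <- NULL
  cfg <- do.call(model_config, cfg_args)
  model <- scghd_model(cfg)
  stored <- payload$params
  if (!setequal(names(stored), names(model$params))) {
    stop("checkpoint parameter set does not match this configuration")
  }
  for (nm in names(model$params)) {
    v <- stored[[nm]]
    dm <- as.integer(v$dim)
    dat <- as.numeric(v$data)
    model$params[[nm]] <- if (length(dm) > 1L) array(dat, dm) else dat
  }
  model$history <- as.numeric(payload$history)
  model
}
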