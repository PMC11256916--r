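test_that("model configuration enforces geometry constraints", {
  expect_error(model_config(d_model = 30, n_attention_heads = 4),
               "divisible")
  cfg <- model_config()
  expect_identical(cfg$d_k, cfg$d_model %/% cfg$n_attention_heads)
  expect_identical(cfg$pe_k, 16L)
  expect_identical(cfg$conv_window, 16L)
  expect_identical(cfg$conv_filters, cfg$d_model)
})

test_that("initialization is fully seed-determined", {
  m1 <- scghd_model(tiny_model_cfg(seed = 21))
  m2 <- scghd_model(tiny_model_cfg(seed = 21))
  m3 <- scghd_model(tiny_model_cfg(seed = 22))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients agree with numerical differentiation", {
  for (cfg in list(tiny_model_cfg(),
                   model_config(conv_window = 5, conv_filters = 1,
                                d_model = 8, n_transformer_blocks_nfp = 1,
                                n_transformer_blocks_map = 1,
                                n_attention_heads = 2, n_residual_blocks = 1,
                                n_residual_channels = 2, pe_k = 3,
                                dropout = 0, seed = 11))) {
  m <- scghd_model(cfg)
  tt <- tiny_tile()
  lg <- scgraphdec:::tile_loss_grad(m$params, cfg, tt, train = FALSE)
  loss_fn <- function(params) {
    fw <- scgraphdec:::model_forward(params, cfg, tt$bulk, tt$features,
                                     train = FALSE)
    mean((fw$Y - tt$target)^2)
  }
  eps <- 1e-6
  set.seed(31)
  for (nm in names(m$params)) {
    k <- min(length(m$params[[nm]]), 3L)
    for (ii in sample(length(m$params[[nm]]), k)) {
      pp <- m$params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- m$params; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      ana <- lg$grads[[nm]][ii]
      # LeakyReLU kinks in the GAT logits leave a small residual; all other
      # parameters agree to ~1e-6
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 5e-3,
                label = sprintf("gradient of %s[%d]", nm, ii))
    }
  }
  }
})

test_that("node feature processor is order-aware and deterministic", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  set.seed(3)
  X <- matrix(rnorm(16 * 8), 16)  # 5 channels + pe_k = 3
  Z1 <- node_feature_processor(m, X)
  Z2 <- node_feature_processor(m, X)
  expect_identical(Z1, Z2)
  # a cyclic shift of the bins does not commute with the forward pass
  sh <- X[c(9:16, 1:8), ]
  Zs <- node_feature_processor(m, sh)
  expect_gt(max(abs(Zs - Z1[c(9:16, 1:8), ])), 1e-4)
  # zero input gives the bias-only pass: finite and constant across rows
  Z0 <- node_feature_processor(m, X * 0)
  expect_true(all(is.finite(Z0)))
  expect_equal(max(apply(Z0, 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-10)
})

test_that("self-attention reduces to the value mean at zero logits", {
  d <- 4L
  set.seed(9)
  X <- matrix(rnorm(6 * d), 6)
  out <- scgraphdec:::mha_forward(X, Wq = matrix(0, d, d),
                                  Wk = matrix(0, d, d), Wv = diag(d),
                                  Wo = diag(d), n_heads = 1L)
  expect_equal(out$Y, matrix(rep(colMeans(X), each = 6), 6),
               tolerance = 1e-12)
  # attention rows always sum to one
  A <- out$cache$heads[[1]]$A
  expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-12)
})

test_that("GAT attention is a proper masked softmax", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  d <- cfg$d_model
  # node 1 has exactly one neighbor (node 2); node 4 is isolated;
  # nodes 2 and 3 are each other's neighbors plus node 1
  E <- matrix(0, 4, 4)
  E[1, 2] <- E[2, 1] <- 0.7
  E[2, 3] <- E[3, 2] <- 0.4
  set.seed(5)
  Z <- matrix(rnorm(4 * d), 4)
  g <- list(edge_weights = E)
  out <- gat_layer(m, g, Z)
  a <- out$alpha
  expect_equal(a[1, 2], 1)                       # singleton softmax
  expect_equal(rowSums(a)[1:3], rep(1, 3))
  expect_equal(sum(a[4, ]), 0)                   # isolated node: empty row
  # isolated node output is the pure self-term W1 z_i
  expect_equal(out$Z[4, ], as.numeric(Z[4, ] %*% m$params$gat1_W1),
               tolerance = 1e-12)
})

test_that("identical neighbors with identical edges split attention evenly", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  d <- cfg$d_model
  E <- matrix(0, 3, 3)
  E[1, 2] <- E[2, 1] <- 0.5
  E[1, 3] <- E[3, 1] <- 0.5
  set.seed(6)
  z <- rnorm(d)
  Z <- rbind(rnorm(d), z, z)  # nodes 2 and 3 identical
  out <- gat_layer(m, list(edge_weights = E), Z)
  expect_equal(out$alpha[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(out$alpha[1, 3], 0.5, tolerance = 1e-12)
})

test_that("GAT attention rows recompute from raw logits on random graphs", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  tt <- tiny_tile(n = 10L, seed = 4)
  set.seed(7)
  Z <- matrix(rnorm(10 * cfg$d_model), 10)
  p <- m$params
  out <- scgraphdec:::gat_forward(Z, tt$bulk, p$gat1_W1, p$gat1_W2,
                                  p$gat1_w3, p$gat1_a)
  # explicit softmax recomputation from the additive logits
  S1 <- Z %*% p$gat1_W1; S2 <- Z %*% p$gat1_W2
  for (i in 1:10) {
    nb <- which(tt$bulk[i, ] != 0 & seq_len(10) != i)
    if (!length(nb)) next
    logit <- vapply(nb, function(j) {
      u <- S1[i, ] + S2[j, ] + p$gat1_w3 * tt$bulk[i, j]
      sum(p$gat1_a * ifelse(u > 0, u, 0.2 * u))
    }, numeric(1))
    expect_equal(out$alpha[i, nb], exp(logit) / sum(exp(logit)),
                 tolerance = 1e-10)
    expect_equal(sum(out$alpha[i, ]), 1, tolerance = 1e-10)
  }
})

test_that("GAT output is equivariant to node relabeling", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  tt <- tiny_tile(n = 9L, seed = 8)
  set.seed(9)
  Z <- matrix(rnorm(9 * cfg$d_model), 9)
  perm <- sample(9)
  o1 <- gat_layer(m, list(edge_weights = tt$bulk), Z)
  o2 <- gat_layer(m, list(edge_weights = tt$bulk[perm, perm]),
                  Z[perm, , drop = FALSE])
  expect_equal(o2$Z, o1$Z[perm, ], tolerance = 1e-10)
})

test_that("mapping encoder preserves shape and supports depth zero", {
  cfg0 <- model_config(conv_window = 5, d_model = 8,
                       n_transformer_blocks_nfp = 1,
                       n_transformer_blocks_map = 0,
                       n_attention_heads = 2, n_residual_blocks = 1,
                       n_residual_channels = 2, pe_k = 3, dropout = 0,
                       seed = 11)
  m0 <- scghd_model(cfg0)
  set.seed(10)
  Z <- matrix(rnorm(12 * 8), 12)
  expect_identical(mapping_encoder(m0, Z), Z)  # depth 0 is the identity
  m1 <- scghd_model(tiny_model_cfg())
  Z1 <- mapping_encoder(m1, Z)
  expect_identical(dim(Z1), dim(Z))
  expect_identical(Z1, mapping_encoder(m1, Z))
})

test_that("decoder output is symmetric, bounded, and handles Z = 0", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  set.seed(12)
  Z <- matrix(rnorm(14 * cfg$d_model), 14)
  P <- graph_decoder(m, Z)
  expect_identical(max(abs(P - t(P))), 0)
  expect_gt(min(P), 0)
  expect_lt(max(P), 1)
  P0 <- graph_decoder(m, Z * 0)
  expect_equal(diff(range(P0)), 0, tolerance = 1e-12)  # constant map
  expect_gt(min(P0), 0)
  expect_lt(max(P0), 1)
})

test_that("full forward produces a symmetric tile matching the window", {
  m <- scghd_model(model_config(seed = 4))
  set.seed(13)
  sp <- synthetic_spec(n_bins = 128, n_shared_tads = 2, n_specific_tads = 1,
                       seed = 14)
  gts <- make_ground_truth(sp)
  bulk <- preprocess_contact_map(sample_bulk(gts, sp))
  tr <- preprocess_track_set(make_tracks(sp, 1))
  P <- predict_tile(m, bulk$matrix, tr$channels)
  expect_identical(dim(P), c(128L, 128L))
  expect_identical(max(abs(P - t(P))), 0)
  expect_true(all(P > 0 & P < 1))
  # identical inputs and seed: bitwise identical inference
  expect_identical(P, predict_tile(m, bulk$matrix, tr$channels))
  # swapping in the other cell type's expression changes the prediction
  tr2 <- preprocess_track_set(make_tracks(sp, 2))
  P2 <- predict_tile(m, bulk$matrix, tr2$channels)
  expect_gt(max(abs(P2 - P)), 0)
  expect_error(predict_tile(m, bulk$matrix, tr$channels[1:64, ]),
               "shape mismatch")
})

test_that("checkpoints round-trip the model exactly", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  m$history <- c(0.5, 0.3)
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_equal(back$history, m$history)
  tt <- tiny_tile()
  expect_equal(predict_tile(back, tt$bulk, tt$features),
               predict_tile(m, tt$bulk, tt$features), tolerance = 1e-12)
  # geometry mismatches are refused
  other <- scghd_model(model_config(conv_window = 5, d_model = 8,
                                    n_transformer_blocks_nfp = 2,
                                    n_transformer_blocks_map = 1,
                                    n_attention_heads = 2,
                                    n_residual_blocks = 1,
                                    n_residual_channels = 2, pe_k = 3,
                                    dropout = 0, seed = 1))
  f2 <- withr::local_tempfile(fileext = ".json")
  payload <- jsonlite::read_json(f)
  payload$format_version <- "other"
  jsonlite::write_json(payload, f2, auto_unbox = TRUE)
  expect_error(load_checkpoint(f2), "unsupported checkpoint")
})

test_that("one gradient step on a tile strictly decreases its loss", {
  cfg <- tiny_model_cfg()
  m <- scghd_model(cfg)
  tt <- tiny_tile()
  lg0 <- scgraphdec:::tile_loss_grad(m$params, cfg, tt, train = FALSE)
  p2 <- m$params
  for (nm in names(p2)) p2[[nm]] <- p2[[nm]] - 1e-3 * lg0$grads[[nm]]
  fw <- scgraphdec:::model_forward(p2, cfg, tt$bulk, tt$features)
  expect_lt(mean((fw$Y - tt$target)^2), lg0$loss)
})
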