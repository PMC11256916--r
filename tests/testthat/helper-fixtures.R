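# Shared fixtures: all built in code, no files on disk.

random_sym_map <- function(n, seed = 1, sparsity = 0, chrom = "chr1") {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0, 10), n)
  m <- (m + t(m)) / 2
  if (sparsity > 0) m[m < stats::quantile(m, sparsity)] <- 0
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_map(m, chrom = chrom)
}

# a two-TAD block map: clean insulation structure for boundary tests
two_tad_map <- function(block = 8L, inside = 5, outside = 0.5) {
  n <- 2L * block
  m <- matrix(outside, n, n)
  m[1:block, 1:block] <- inside
  m[(block + 1):n, (block + 1):n] <- inside
  contact_map(m)
}

tiny_model_cfg <- function(seed = 11) {
  model_config(conv_window = 5L, d_model = 8L, n_transformer_blocks_nfp = 1L,
               n_transformer_blocks_map = 1L, n_attention_heads = 2L,
               n_residual_blocks = 1L, n_residual_channels = 2L, pe_k = 3L,
               dropout = 0, seed = seed)
}

tiny_tile <- function(n = 12L, seed = 2) {
  set.seed(seed)
  B <- matrix(stats::runif(n * n), n)
  B <- (B + t(B)) / 2
  diag(B) <- 0
  B[B < 0.3] <- 0
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  Fb <- matrix(stats::runif(n * 5), n)
  Tg <- matrix(stats::runif(n * n), n)
  Tg <- (Tg + t(Tg)) / 2
  Tg[lower.tri(Tg)] <- t(Tg)[lower.tri(Tg)]
  list(bulk = B, features = Fb, target = Tg)
}
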