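test_that("ground-truth maps are symmetric unit-mass pmfs with decay", {
  sp <- synthetic_spec(n_bins = 64, n_shared_tads = 1, n_specific_tads = 1,
                       seed = 2)
  gts <- make_ground_truth(sp)
  expect_length(gts, 2L)
  for (g in gts) {
    expect_equal(sum(g$matrix), 1)
    expect_gte(min(g$matrix), 0)
    expect_identical(max(abs(g$matrix - t(g$matrix))), 0)
  }
})

test_that("without TADs the backbone is a pure power law", {
  sp <- synthetic_spec(n_bins = 32, seed = 1, decay_exponent = 1,
                       n_shared_tads = 1, n_specific_tads = 1)
  sp$tad_layout <- list(data.frame(start = numeric(0), end = numeric(0),
                                   intensity = numeric(0),
                                   shared = logical(0)))
  sp$n_cell_types <- 1L
  sp$mixture_weights <- 1
  g <- make_ground_truth(sp)[[1]]$matrix
  # p(|i-j|=1) / p(|i-j|=3) = (1+1)^-1 / (1+3)^-1 = 2
  expect_equal(g[1, 2] / g[1, 4], 2, tolerance = 1e-12)
})

test_that("a TAD block enriches within-block contacts by its intensity", {
  sp <- synthetic_spec(n_bins = 64, seed = 1)
  sp$tad_layout <- list(data.frame(start = 0, end = 8, intensity = 2,
                                   shared = TRUE))
  sp$n_cell_types <- 1L
  sp$mixture_weights <- 1
  g <- make_ground_truth(sp)[[1]]$matrix
  # compare pairs at equal genomic distance inside vs outside the block
  inside <- mean(g[cbind(1:6, 3:8)])
  outside <- mean(g[cbind(31:36, 33:38)])
  expect_equal(inside / outside, 2, tolerance = 1e-12)
})

test_that("cell types sharing a layout produce identical ground truths", {
  sp <- synthetic_spec(n_bins = 64, seed = 3)
  sp$tad_layout <- list(sp$tad_layout[[1]], sp$tad_layout[[1]])
  gts <- make_ground_truth(sp)
  expect_identical(gts[[1]]$matrix, gts[[2]]$matrix)
})

test_that("contradictory (partially overlapping) TADs are rejected", {
  expect_error(
    synthetic_spec(n_bins = 64, tad_layout = list(
      data.frame(start = c(0, 4), end = c(8, 12), intensity = 2,
                 shared = TRUE))),
    "overlapping contradictory")
  # nested sub-TADs are fine
  sp <- synthetic_spec(n_bins = 64, n_cell_types = 1, mixture_weights = 1,
                       tad_layout = list(
                         data.frame(start = c(0, 2), end = c(12, 6),
                                    intensity = 2, shared = TRUE)))
  expect_s3_class(sp, "synthetic_spec")
})

test_that("bulk sampling respects degenerate mixture weights", {
  sp <- synthetic_spec(n_bins = 48, seed = 4, mixture_weights = c(1, 0),
                       read_depth_bulk = 2e4)
  gts <- make_ground_truth(sp)
  b1 <- sample_bulk(gts, sp, seed = 99)
  # a pure ct1 mixture equals sampling gt1 alone under the same stream
  b2 <- sample_bulk(list(gts[[1]], gts[[1]]), sp, seed = 99)
  expect_identical(b1$matrix, b2$matrix)
})

test_that("bulk counts match the multinomial expectation", {
  sp <- synthetic_spec(n_bins = 24, seed = 5, n_shared_tads = 1,
                       n_specific_tads = 1, read_depth_bulk = 2000)
  gts <- make_ground_truth(sp)
  mix <- 0.6 * gts[[1]]$matrix + 0.4 * gts[[2]]$matrix
  q <- ifelse(row(mix) == col(mix), 1, 2) * mix  # unordered-pair pmf
  n_draws <- 200
  acc <- matrix(0, 24, 24)
  for (i in seq_len(n_draws)) {
    acc <- acc + sample_bulk(gts, sp, seed = 1000 + i)$matrix
  }
  emp <- acc / n_draws
  expected <- 2000 * q
  se <- sqrt(2000 * q * (1 - q) / n_draws)
  ut <- upper.tri(mix, diag = TRUE)
  dev_ok <- abs(emp[ut] - expected[ut]) <= 3 * se[ut] + 1e-9
  # ~0.3% of entries may legitimately sit outside 3 standard errors
  expect_gte(mean(dev_ok), 0.97)
  expect_equal(sum(emp[ut]), 2000)
})

test_that("deep sampling converges to the mixture probability", {
  sp <- synthetic_spec(n_bins = 32, seed = 6, n_shared_tads = 1,
                       n_specific_tads = 1, read_depth_bulk = 1e6,
                       mixture_weights = c(0.6, 0.4))
  gts <- make_ground_truth(sp)
  mix <- 0.6 * gts[[1]]$matrix + 0.4 * gts[[2]]$matrix
  q <- ifelse(row(mix) == col(mix), 1, 2) * mix
  b <- sample_bulk(gts, sp)
  norm_emp <- b$matrix / 1e6
  expect_lt(sum(abs(norm_emp - q)[upper.tri(q, diag = TRUE)]), 0.05)
})

test_that("single-cell targets conserve reads and grow sparser when shallow", {
  sp <- synthetic_spec(n_bins = 48, seed = 7, n_shared_tads = 1,
                       n_specific_tads = 1)
  gts <- make_ground_truth(sp)
  zero <- sample_sc_target(gts[[1]],
                           synthetic_spec(n_bins = 48, seed = 7,
                                          n_shared_tads = 1,
                                          n_specific_tads = 1,
                                          read_depth_sc = 0))
  expect_true(all(zero$matrix == 0))
  frac_zero <- sapply(c(20000, 2000, 200), function(depth) {
    s2 <- sp; s2$read_depth_sc <- depth
    m <- sample_sc_target(gts[[1]], s2, seed = 11)$matrix
    ut <- upper.tri(m, diag = TRUE)
    expect_equal(sum(m[ut]), depth)
    mean(m == 0)
  })
  expect_true(all(diff(frac_zero) > 0))
})

test_that("noise-free expression is exactly the active-TAD indicator", {
  sp <- synthetic_spec(n_bins = 64, seed = 8, expr_coupling = 1,
                       noise_sd = 0, n_shared_tads = 1, n_specific_tads = 1)
  tr <- make_tracks(sp, 1)
  df <- sp$tad_layout[[1]]
  df <- df[df$active, ]
  ind <- rep(0, 64)
  for (r in seq_len(nrow(df))) ind[(df$start[r] + 1):df$end[r]] <- 1
  expect_equal(unname(tr$channels[, 1]), sp$expr_amplitude * ind / 2)
  expect_identical(tr$channels[, 1], tr$channels[, 2])
})

test_that("decoupled expression is independent of structure", {
  sp <- synthetic_spec(n_bins = 512, seed = 9, expr_coupling = 0,
                       n_shared_tads = 3, n_specific_tads = 2)
  tr <- make_tracks(sp, 1)
  df <- sp$tad_layout[[1]]
  df <- df[df$active, ]
  ind <- rep(0, 512)
  for (r in seq_len(nrow(df))) ind[(df$start[r] + 1):df$end[r]] <- 1
  expr <- tr$channels[, 1] + tr$channels[, 2]
  expect_lt(abs(stats::cor(expr, ind)), 0.1)
})

test_that("CTCF peaks sit exactly on shared boundaries when noise-free", {
  sp <- synthetic_spec(n_bins = 96, seed = 10, noise_sd = 0,
                       n_shared_tads = 2, n_specific_tads = 1)
  tr <- make_tracks(sp, 1)
  # the CTCF track is cell-type agnostic: peaks mark exactly the domain
  # edges common to every cell type's layout
  bnd <- shared_boundaries(sp)
  expect_identical(which(tr$channels[, 3] > 0) - 1L, as.integer(bnd))
  tr2 <- make_tracks(sp, 2)
  expect_identical(tr$channels[, 3], tr2$channels[, 3])
  # a cell-specific sub-TAD midpoint is not CTCF-marked
  own <- sp$tad_layout[[1]]
  own <- own[!own$shared, ]
  mids <- setdiff(unique(c(own$start, own$end)),
                  unique(c(own$start[1], own$end[nrow(own)])))
  expect_false(any(mids %in% bnd))
  # CpG tracks CTCF by construction
  expect_identical(tr$channels[, 5], tr$channels[, 3])
})

test_that("CpG stays strongly correlated with CTCF under default noise", {
  sp <- synthetic_spec(n_bins = 256, seed = 11)
  tr <- make_tracks(sp, 1)
  expect_gte(stats::cor(tr$channels[, 3], tr$channels[, 5]), 0.7)
})

test_that("datasets are reproducible and complete on disk", {
  sp <- synthetic_spec(n_bins = 64, seed = 12, n_cell_types = 3,
                       mixture_weights = c(0.5, 0.3, 0.2),
                       n_shared_tads = 1, n_specific_tads = 1,
                       read_depth_bulk = 5e4, read_depth_sc = 5e3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- make_dataset(sp, d1)
  m2 <- make_dataset(sp, d2)
  expect_identical(m1$spec, m2$spec)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_length(list.files(d1, pattern = "^target_"), 3L)
  expect_length(list.files(d1, pattern = "^tracks_"), 15L)
  # round-trip through data_io reproduces the maps
  bulk <- load_contact_map(file.path(d1, "bulk.tsv"), chrom = "bulk")
  expect_equal(sum(bulk$matrix[upper.tri(bulk$matrix, diag = TRUE)]), 5e4)
  t1 <- load_contact_map(file.path(d1, "target_ct1.tsv"), chrom = "ct1")
  expect_identical(max(abs(t1$matrix - t(t1$matrix))), 0)
})

test_that("bulk boundaries cover every sufficiently weighted TAD layout", {
  # deconvolution premise: the bulk mixture carries the union signature of
  # the per-cell-type TAD boundaries
  sp <- synthetic_spec(n_bins = 256, seed = 13, read_depth_bulk = 5e6,
                       mixture_weights = c(0.6, 0.4), tad_intensity = 4)
  gts <- make_ground_truth(sp)
  bulk <- preprocess_contact_map(sample_bulk(gts, sp))
  called <- call_tad_boundaries(bulk, window = 8)$boundaries
  for (ct in 1:2) {
    df <- sp$tad_layout[[ct]]
    own <- df[!df$shared, ]
    bnd <- unique(c(own$start, own$end))
    bnd <- bnd[bnd > 8 & bnd < 248]
    for (b in bnd) {
      expect_true(min(abs(called - b)) <= 2,
                  label = sprintf("boundary %d of ct%d detected", b, ct))
    }
  }
})
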