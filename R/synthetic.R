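#' Synthetic co-assay dataset specification
#'
#' Describes a simulated chromosome shared by several cell types: a common
#' distance-decay backbone, shared TADs present in every cell type, and
#' cell-type-specific TADs whose activity is signalled through the
#' expression tracks. The bulk map is a read-sampled mixture of the
#' cell-type ground truths, mirroring the deconvolution premise that bulk
#' Hi-C averages the cell population.
#'
#' @param n_bins bins on the simulated chromosome (default 256).
#' @param n_cell_types number of cell types (default 2).
#' @param mixture_weights simplex vector of cell-type proportions in the
#'   bulk (default `c(0.6, 0.4)`).
#' @param tad_layout optional explicit layout: a list with one element per
#'   cell type, each a data.frame with columns `start`, `end` (0-based
#'   half-open bin intervals), `intensity` (> 1 enrichment factor) and
#'   `shared` (logical). When NULL a random layout with `n_shared_tads`
#'   shared and `n_specific_tads` cell-type-specific TADs is drawn from the
#'   seed.
#' @param n_shared_tads,n_specific_tads layout richness used when
#'   `tad_layout` is NULL (defaults 3 and 2).
#' @param tad_intensity enrichment factor of generated TAD blocks
#'   (default 3, within the 2-5x enrichment typical of real TADs).
#' @param decay_exponent distance-decay power of the backbone (default 1).
#' @param read_depth_bulk,read_depth_sc expected total reads for the bulk
#'   map and each single-cell target (defaults 5e5 and 5e4).
#' @param expr_coupling strength in [0, 1] of the expression-structure
#'   association (default 0.8).
#' @param expr_amplitude expression level of active-TAD bins relative to a
#'   unit baseline (default 4).
#' @param noise_sd relative noise level of the guide tracks (default 0.1);
#'   0 disables track sampling noise entirely.
#' @param seed master seed; every artifact derives its own stream from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 256L, n_cell_types = 2L,
                           mixture_weights = NULL, tad_layout = NULL,
                           n_shared_tads = 3L, n_specific_tads = 2L,
                           tad_intensity = 3, decay_exponent = 1,
                           read_depth_bulk = 5e5, read_depth_sc = 5e4,
                           expr_coupling = 0.8, expr_amplitude = 4,
                           noise_sd = 0.1, seed = 1L) {
  n_cell_types <- as.integer(n_cell_types)
  if (is.null(mixture_weights)) {
    mixture_weights <- if (n_cell_types == 2L) c(0.6, 0.4) else
      rep(1 / n_cell_types, n_cell_types)
  }
  if (length(mixture_weights) != n_cell_types) {
    stop("mixture_weights length must equal n_cell_types")
  }
  if (abs(sum(mixture_weights) - 1) > 1e-8 || any(mixture_weights < 0)) {
    stop("mixture_weights must lie on the simplex")
  }
  stopifnot(read_depth_bulk >= 0, read_depth_sc >= 0,
            expr_coupling >= 0, expr_coupling <= 1, noise_sd >= 0,
            decay_exponent > 0, n_bins >= 16L)
  spec <- structure(list(
    n_bins = as.integer(n_bins), n_cell_types = n_cell_types,
    mixture_weights = mixture_weights, tad_layout = tad_layout,
    n_shared_tads = as.integer(n_shared_tads),
    n_specific_tads = as.integer(n_specific_tads),
    tad_intensity = tad_intensity, decay_exponent = decay_exponent,
    read_depth_bulk = read_depth_bulk, read_depth_sc = read_depth_sc,
    expr_coupling = expr_coupling, expr_amplitude = expr_amplitude,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "synthetic_spec")
  if (is.null(spec$tad_layout)) {
    spec$tad_layout <- random_tad_layout(spec)
  }
  validate_layout(spec$tad_layout, spec$n_bins)
  spec
}

# Deterministic sub-streams: artifact k of a spec seeded s uses
# seed_child(s, k). Keeps every artifact independently reproducible.
seed_child <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

random_tad_layout <- function(spec) {
  set.seed(seed_child(spec$seed, 0L))
  n <- spec$n_bins
  need <- spec$n_shared_tads + spec$n_cell_types * spec$n_specific_tads
  # segment sizes scale with the chromosome so any sane layout fits;
  # at the default 256 bins they span 12-40 bins (0.6-2 Mbp at 50 kb)
  lmin <- max(4L, min(12L, n %/% (3L * max(need, 1L))))
  lmax <- max(lmin + 2L, min(40L, n %/% max(need, 1L) - 1L))
  segs <- list()
  pos <- 0L
  while (pos < n) {
    len <- sample(lmin:lmax, 1L)
    segs[[length(segs) + 1L]] <- c(pos, min(pos + len, n))
    pos <- pos + len
  }
  if (length(segs) < need) {
    stop("n_bins too small for the requested TAD layout")
  }
  pick <- sample(length(segs), need)
  shared_idx <- pick[seq_len(spec$n_shared_tads)]
  rest <- pick[-seq_len(spec$n_shared_tads)]
  specific <- split(rest, rep(seq_len(spec$n_cell_types),
                              each = spec$n_specific_tads))
  # segments not picked as strong TADs become weak shared background
  # domains: chromosomes are tiled by domains, so the insulation profile
  # dips at every strong-TAD edge instead of drifting through flat gaps
  weak_int <- 1 + (spec$tad_intensity - 1) / 4
  seg_df <- function(idx, intensity, shared, active) {
    data.frame(start = vapply(segs[idx], `[`, numeric(1), 1),
               end = vapply(segs[idx], `[`, numeric(1), 2),
               intensity = intensity, shared = shared, active = active)
  }
  # a cell-type-specific domain is a strong domain SPLIT at its midpoint
  # into two sub-TADs. The outer edges sit on the shared segmentation
  # (CTCF-marked, present in every cell type), but the internal sub-TAD
  # boundary exists only in the cell type where the domain is active —
  # in all others the segment stays a weak background domain. The bulk
  # mixture therefore carries every cell type's sub-TAD boundaries, which
  # is precisely what deconvolution must disentangle.
  split_df <- function(idx, active) {
    out <- NULL
    for (i in idx) {
      s <- segs[[i]][1]; e <- segs[[i]][2]
      m <- s + floor((e - s) / 2)
      out <- rbind(out, data.frame(
        start = c(s, m), end = c(m, e),
        intensity = spec$tad_intensity, shared = FALSE, active = active))
    }
    out
  }
  layout <- vector("list", spec$n_cell_types)
  for (ct in seq_len(spec$n_cell_types)) {
    own <- if (spec$n_specific_tads > 0L) specific[[ct]] else integer(0)
    others <- if (spec$n_specific_tads > 0L)
      unlist(specific[-ct], use.names = FALSE) else integer(0)
    weak_idx <- c(setdiff(seq_along(segs), pick), others)
    df <- rbind(
      seg_df(shared_idx, spec$tad_intensity, TRUE, TRUE),
      if (length(own)) split_df(own, TRUE),
      if (length(weak_idx)) seg_df(weak_idx, weak_int, TRUE, FALSE))
    layout[[ct]] <- df[order(df$start, df$end), , drop = FALSE]
    rownames(layout[[ct]]) <- NULL
  }
  layout
}

validate_layout <- function(layout, n_bins) {
  for (df in layout) {
    stopifnot(all(df$start >= 0), all(df$end <= n_bins),
              all(df$end > df$start), all(df$intensity > 0))
    if (nrow(df) < 2L) next
    for (i in seq_len(nrow(df) - 1L)) for (j in (i + 1L):nrow(df)) {
      a <- df[i, ]; b <- df[j, ]
      disjoint <- a$end <= b$start || b$end <= a$start
      nested <- (a$start <= b$start && b$end <= a$end) ||
        (b$start <= a$start && a$end <= b$end)
      if (!disjoint && !nested) {
        stop("overlapping contradictory TADs in layout")
      }
    }
  }
  invisible(layout)
}

#' Per-cell-type ground-truth contact probability maps
#'
#' Base contact probability decays with genomic distance as
#' `(1 + |i - j|)^(-decay_exponent)`; TAD blocks multiply the probability of
#' their within-block pairs by their intensity (nested sub-TADs stack
#' multiplicatively). Each map is symmetric, non-negative and normalized to
#' total mass 1.
#'
#' @param spec a [synthetic_spec()].
#' @return list of [contact_map()]s (norm_state `"raw"`), one per cell
#'   type; probabilities, not counts.
#' @export
make_ground_truth <- function(spec) {
  n <- spec$n_bins
  dmat <- abs(outer(seq_len(n), seq_len(n), `-`))
  base <- (1 + dmat)^(-spec$decay_exponent)
  lapply(seq_len(spec$n_cell_types), function(ct) {
    m <- base
    df <- spec$tad_layout[[ct]]
    for (r in seq_len(nrow(df))) {
      idx <- (df$start[r] + 1L):df$end[r]
      m[idx, idx] <- m[idx, idx] * df$intensity[r]
    }
    m <- symmetrize_exact((m + t(m)) / 2)
    contact_map(m / sum(m), chrom = sprintf("ct%d", ct),
                resolution = 50000L, norm_state = "raw")
  })
}

# Multinomial read sampling over unordered bin pairs; the sampled count of
# an off-diagonal pair is written into both mirrored cells, so the upper
# triangle (with diagonal) sums exactly to the requested depth.
sample_reads <- function(prob_matrix, depth) {
  n <- nrow(prob_matrix)
  ut <- upper.tri(prob_matrix, diag = TRUE)
  q <- ifelse(row(prob_matrix) == col(prob_matrix), 1, 2) * prob_matrix
  qv <- q[ut]
  counts <- numeric(length(qv))
  if (depth > 0 && sum(qv) > 0) {
    counts <- as.numeric(stats::rmultinom(1L, size = depth,
                                          prob = qv / sum(qv)))
  }
  M <- matrix(0, n, n)
  M[ut] <- counts
  M <- M + t(M) - diag(diag(M))
  M
}

#' Sample a bulk Hi-C map from the cell-type mixture
#'
#' The bulk contact probability is the mixture `sum_c w_c p_c` of the
#' cell-type ground truths; reads are drawn multinomially at
#' `read_depth_bulk` so the total depth is exact and counts symmetric.
#'
#' @param ground_truths list of [contact_map()]s from [make_ground_truth()].
#' @param spec a [synthetic_spec()].
#' @param seed optional seed override (default: derived from the spec).
#' @return a raw [contact_map()] of bulk counts.
#' @export
sample_bulk <- function(ground_truths, spec, seed = NULL) {
  if (is.null(seed)) seed <- seed_child(spec$seed, 1L)
  set.seed(seed)
  mix <- Reduce(`+`, Map(function(gt, w) w * gt$matrix,
                         ground_truths, spec$mixture_weights))
  contact_map(sample_reads(mix, spec$read_depth_bulk), chrom = "bulk",
              resolution = 50000L, norm_state = "raw")
}

#' Sample a sparse scHi-C target for one cell type
#'
#' Multinomial read sampling at `read_depth_sc` (typically an order of
#' magnitude below the bulk depth), emulating the sparsity of pseudo-bulk
#' single-cell maps. Preprocessing (library-size normalization, denoising,
#' min-max) is applied downstream, not here.
#'
#' @param ground_truth one [contact_map()] from [make_ground_truth()].
#' @param spec a [synthetic_spec()].
#' @param seed optional seed override.
#' @return a raw [contact_map()] of counts.
#' @export
sample_sc_target <- function(ground_truth, spec, seed = NULL) {
  if (is.null(seed)) seed <- seed_child(spec$seed, 2L)
  set.seed(seed)
  contact_map(sample_reads(ground_truth$matrix, spec$read_depth_sc),
              chrom = ground_truth$chrom, resolution = 50000L,
              norm_state = "raw")
}

#' Cell-type-agnostic domain boundaries of a synthetic spec
#'
#' The domain edges present in every cell type's layout — the shared
#' segmentation backbone. Cell-type-specific sub-TAD midpoints are
#' excluded; these are the bins the CTCF track marks.
#'
#' @param spec a [synthetic_spec()].
#' @return sorted integer vector of interior boundary bins (0-based).
#' @export
shared_boundaries <- function(spec) {
  edge_sets <- lapply(spec$tad_layout, function(df) {
    unique(c(df$start, df$end))
  })
  bnd <- sort(Reduce(intersect, edge_sets))
  bnd[bnd > 0 & bnd < spec$n_bins]
}

#' Generate the five guide tracks for one cell type
#'
#' Expression (split across the two strand channels) is elevated inside the
#' TADs active in this cell type, mixed with `1 - expr_coupling` of
#' structure-independent background, and Poisson-sampled at a depth that
#' shrinks with `noise_sd` (with `noise_sd = 0` the tracks are noise-free).
#' CTCF peaks sit exactly on the shared-backbone TAD boundary bins
#' (cell-type agnostic), and the CpG channel is a CTCF-correlated copy with
#' additive noise, mirroring the strong genomic overlap of CTCF motifs and
#' CpG islands.
#'
#' @param spec a [synthetic_spec()].
#' @param cell_type index of the cell type (default 1).
#' @param seed optional seed override.
#' @return a raw [track_set()].
#' @export
make_tracks <- function(spec, cell_type = 1L, seed = NULL) {
  if (is.null(seed)) seed <- seed_child(spec$seed, 10L + cell_type)
  set.seed(seed)
  n <- spec$n_bins
  df <- spec$tad_layout[[cell_type]]
  act_rows <- if ("active" %in% names(df)) which(df$active) else
    seq_len(nrow(df))
  active <- rep(0, n)
  for (r in act_rows) {
    active[(df$start[r] + 1L):df$end[r]] <- 1
  }
  background <- stats::runif(n)
  mu <- spec$expr_coupling * active + (1 - spec$expr_coupling) * background
  expr <- spec$expr_amplitude * mu
  half <- expr / 2
  sample_track <- function(lambda) {
    if (spec$noise_sd <= 0) return(lambda)
    depth_factor <- 1 / spec$noise_sd
    stats::rpois(n, lambda * depth_factor) / depth_factor
  }
  rna_plus <- sample_track(half)
  rna_minus <- sample_track(half)
  bnd <- shared_boundaries(spec)
  ctcf <- rep(0, n)
  ctcf[bnd + 1L] <- 1
  add_noise <- function(x) {
    if (spec$noise_sd <= 0) return(x)
    pmax(x + stats::rnorm(n, 0, spec$noise_sd), 0)
  }
  ctcf_plus <- add_noise(ctcf)
  ctcf_minus <- add_noise(ctcf)
  cpg <- add_noise(ctcf)
  track_set(cbind(rna_plus, rna_minus, ctcf_plus, ctcf_minus, cpg),
            chrom = sprintf("ct%d", cell_type), resolution = 50000L)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates the bulk map, per-cell-type target maps and track sets, writes
#' them in the package's on-disk formats, and records the spec and seed in
#' a JSON manifest so the dataset is fully reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if absent).
#' @param map_format a [write_contact_map()] format (default
#'   `"sparse_text"`).
#' @return invisibly, the manifest list.
#' @export
make_dataset <- function(spec, out_dir, map_format = "sparse_text") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gts <- make_ground_truth(spec)
  bulk <- sample_bulk(gts, spec)
  ext <- if (map_format == "cooler") "" else ".tsv"
  write_contact_map(bulk, file.path(out_dir, paste0("bulk", ext)), map_format)
  files <- list(bulk = paste0("bulk", ext))
  for (ct in seq_len(spec$n_cell_types)) {
    target <- sample_sc_target(gts[[ct]], spec,
                               seed = seed_child(spec$seed, 2L + 100L * ct))
    tfile <- sprintf("target_ct%d%s", ct, ext)
    write_contact_map(target, file.path(out_dir, tfile), map_format)
    tracks <- make_tracks(spec, ct)
    tr_files <- character(5)
    for (ch in seq_len(5)) {
      tr_files[ch] <- sprintf("tracks_ct%d_%s.bedGraph", ct,
                              track_channel_names()[ch])
      write_bedgraph(tracks$channels[, ch],
                     file.path(out_dir, tr_files[ch]),
                     chrom = tracks$chrom)
    }
    files[[sprintf("target_ct%d", ct)]] <- tfile
    files[[sprintf("tracks_ct%d", ct)]] <- tr_files
  }
  manifest <- list(
    generator = "scgraphdec-synthetic-1",
    seed = spec$seed,
    spec = serialize_spec(spec),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

serialize_spec <- function(spec) {
  s <- unclass(spec)
  s$tad_layout <- lapply(s$tad_layout, function(df) as.list(df))
  s
}

#' Assemble preprocessed training and test data from a synthetic spec
#'
#' Draws `n_train + n_test` independent synthetic chromosomes (each with its
#' own random TAD layout derived from the master seed), preprocesses every
#' artifact (bulk: library-size + min-max; targets: library-size +
#' eigen-denoise + min-max; tracks: library-size on the expression channels,
#' then per-channel min-max), and cuts the training chromosomes into
#' (bulk tile, feature block, target tile) samples at the training stride.
#'
#' @param spec a [synthetic_spec()] acting as the template; chromosome `i`
#'   uses seed `seed_child(spec$seed, 1000 + i)` with a fresh layout.
#' @param n_train,n_test chromosome counts (defaults 2 and 1).
#' @param pe_k kept for interface symmetry (positional encodings are
#'   computed per tile at forward time).
#' @param stride_train training tile stride (default 32).
#' @param window tile window (default 128).
#' @return list with `train_tiles` (list of samples for [train_model()])
#'   and `test` (per-chromosome list with preprocessed `bulk`, `tracks`,
#'   `targets`, plus raw `bulk_raw`, `targets_raw`).
#' @export
prepare_synthetic_experiment <- function(spec, n_train = 2L, n_test = 1L,
                                         pe_k = 16L, stride_train = 32L,
                                         window = 128L) {
  train_tiles <- list()
  test <- list()
  total <- n_train + n_test
  for (i in seq_len(total)) {
    args <- unclass(spec)
    args$tad_layout <- NULL
    args$seed <- seed_child(spec$seed, 1000L + i)
    chrom_spec <- do.call(synthetic_spec, args)
    gts <- make_ground_truth(chrom_spec)
    bulk_raw <- sample_bulk(gts, chrom_spec)
    bulk <- preprocess_contact_map(bulk_raw, denoise = FALSE)
    bulk$chrom <- sprintf("s%d", i)
    targets <- list(); targets_raw <- list(); tracks <- list()
    for (ct in seq_len(chrom_spec$n_cell_types)) {
      raw <- sample_sc_target(gts[[ct]], chrom_spec,
                              seed = seed_child(chrom_spec$seed,
                                                2L + 100L * ct))
      nm <- sprintf("ct%d", ct)
      targets_raw[[nm]] <- raw
      targets[[nm]] <- preprocess_contact_map(raw, denoise = TRUE)
      tracks[[nm]] <- preprocess_track_set(make_tracks(chrom_spec, ct))
    }
    if (i <= n_train) {
      for (ct in names(tracks)) {
        spec_t <- tile_spec(window, stride_train)
        in_tiles <- tile_region(bulk, tracks[[ct]], spec_t)
        tg_tiles <- tile_region(targets[[ct]], NULL, spec_t)
        for (k in seq_along(in_tiles)) {
          train_tiles[[length(train_tiles) + 1L]] <- list(
            bulk = in_tiles[[k]]$matrix,
            features = in_tiles[[k]]$features,
            target = tg_tiles[[k]]$matrix)
        }
      }
    } else {
      test[[sprintf("s%d", i)]] <- list(
        bulk = bulk, bulk_raw = bulk_raw, tracks = tracks,
        targets = targets, targets_raw = targets_raw,
        layout = chrom_spec$tad_layout)
    }
  }
  list(train_tiles = train_tiles, test = test)
}

#' Preprocess a raw guide track set
#'
#' Library-size normalization (the expression channels only; CTCF/CpG are
#' motif scores, not read counts) followed by per-channel min-max scaling.
#'
#' @param ts a raw [track_set()].
#' @param alpha,pseudocount see [library_size_normalize()].
#' @return a [track_set()] with `norm_state = "minmax"`.
#' @export
preprocess_track_set <- function(ts, alpha = 25000, pseudocount = 1e-8) {
  ch <- ts$channels
  for (j in 1:2) {
    if (sum(ch[, j]) > 0) {
      ch[, j] <- library_size_normalize(ch[, j], alpha, pseudocount)
    }
  }
  ch <- apply(ch, 2, minmax_normalize)
  track_set(ch, chrom = ts$chrom, resolution = ts$resolution,
            norm_state = "minmax")
}
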