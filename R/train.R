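#' Training configuration
#'
#' @param epochs full passes over the tile dataset (the reference regime is
#'   300; the desk-scale default is 50).
#' @param batch_size tiles per gradient step (default 1, plain SGD).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed for shuffling and dropout.
#' @param stride_train training-tile stride in bins (default 32).
#' @param stride_predict prediction stride in bins (default 16).
#' @param checkpoint_every write a checkpoint every this many epochs when a
#'   checkpoint path is given (default 0 = off).
#' @param shuffle reshuffle tile order each epoch (default TRUE).
#' @param clip_norm global gradient-norm ceiling (default 1); gradients
#'   with larger norm are rescaled, which keeps occasional loss spikes from
#'   saturating the decoder sigmoid. `Inf` disables clipping.
#' @param stop_below optional early-stopping threshold: training ends as
#'   soon as an epoch's mean loss falls below it (default NULL = off; the
#'   reference regime trains a fixed number of epochs).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 1L, learning_rate = 1e-3,
                         seed = 1L, stride_train = 32L, stride_predict = 16L,
                         checkpoint_every = 0L, shuffle = TRUE,
                         clip_norm = 1, stop_below = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 stride_train = as.integer(stride_train),
                 stride_predict = as.integer(stride_predict),
                 checkpoint_every = as.integer(checkpoint_every),
                 shuffle = isTRUE(shuffle), clip_norm = clip_norm,
                 stop_below = stop_below),
            class = "train_config")
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

tile_loss_grad <- function(params, cfg, sample, train = TRUE) {
  fw <- model_forward(params, cfg, sample$bulk, sample$features, train)
  diff <- fw$Y - sample$target
  loss <- mean(diff^2)
  if (!is.finite(loss)) stop("NaN loss encountered; aborting training")
  dY <- 2 * diff / length(diff)
  grads <- model_backward(dY, params, cfg, fw$cache)
  list(loss = loss, grads = grads)
}

#' Train the model by MSE against target tiles
#'
#' Minimizes the mean squared error between predicted and target scHi-C
#' tiles with Adam. One epoch visits every tile; with `batch_size > 1`
#' gradients are averaged over the batch before each update. Loss histories
#' are exactly reproducible for a given seed.
#'
#' @param model a [scghd_model()].
#' @param dataset list of samples, each `list(bulk, features, target)` with
#'   `bulk` the tile's bulk Hi-C submatrix, `features` the `n x 5` guide
#'   block and `target` the scHi-C target tile in [0, 1].
#' @param cfg a [train_config()].
#' @param checkpoint_path optional path stem for periodic checkpoints.
#' @param verbose print the per-epoch loss (default FALSE).
#' @return the trained model; `model$history` holds the mean per-epoch
#'   training loss.
#' @export
train_model <- function(model, dataset, cfg = train_config(),
                        checkpoint_path = NULL, verbose = FALSE) {
  # force promises before touching the RNG: a model constructed in the call
  # itself would otherwise re-seed mid-stream
  params <- model$params
  mcfg <- model$config
  if (!length(dataset)) stop("empty training dataset")
  for (s in dataset) {
    if (min(s$target) < 0 || max(s$target) > 1) {
      stop("target tiles must lie in [0, 1]; run the preprocessing stack")
    }
  }
  set.seed(cfg$seed)
  state <- adam_init(params)
  history <- numeric(cfg$epochs)
  n <- length(dataset)
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + cfg$batch_size - 1L, n)]
      acc <- NULL
      batch_loss <- 0
      for (s_i in idx) {
        lg <- tile_loss_grad(params, mcfg, dataset[[s_i]], train = TRUE)
        batch_loss <- batch_loss + lg$loss
        if (is.null(acc)) {
          acc <- lg$grads
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
        }
      }
      if (length(idx) > 1L) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
      }
      acc <- clip_gradients(acc, cfg$clip_norm)
      upd <- adam_step(params, acc, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + batch_loss
      i <- i + cfg$batch_size
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d: mse %.6g", ep, history[ep]))
    if (!is.null(cfg$stop_below) && history[ep] < cfg$stop_below) {
      history <- history[seq_len(ep)]
      break
    }
    if (!is.null(checkpoint_path) && cfg$checkpoint_every > 0L &&
        ep %% cfg$checkpoint_every == 0L) {
      model$params <- params
      model$history <- history[seq_len(ep)]
      save_checkpoint(model, sprintf("%s_epoch%04d.json", checkpoint_path, ep))
    }
  }
  model$params <- params
  model$history <- history
  model
}

#' Predict a whole chromosome with overlap averaging
#'
#' Tiles the chromosome at the prediction stride, runs the model on each
#' tile and averages all predictions covering each bin pair. Bins in a
#' chromosome tail not reachable by a full window stay 0 and their count is
#' reported via an attribute.
#'
#' @param model a trained [scghd_model()].
#' @param bulk_map preprocessed (min-max) bulk [contact_map()].
#' @param tracks preprocessed [track_set()] aligned to `bulk_map`.
#' @param stride prediction stride in bins (default 16).
#' @param window window size in bins (default 128).
#' @return a [contact_map()] with `norm_state = "minmax"`; attribute
#'   `uncovered_bins` counts bins no full window reached.
#' @export
predict_chromosome <- function(model, bulk_map, tracks, stride = 16L,
                               window = 128L) {
  nb <- n_bins(bulk_map)
  if (nb < window) stop("region too short: fewer bins than one window")
  tiles <- tile_region(bulk_map, tracks, tile_spec(window, stride))
  sum_m <- matrix(0, nb, nb)
  cnt_m <- matrix(0, nb, nb)
  for (tl in tiles) {
    idx <- (tl$start_bin + 1L):(tl$start_bin + window)
    pred <- predict_tile(model, tl$matrix, tl$features)
    sum_m[idx, idx] <- sum_m[idx, idx] + pred
    cnt_m[idx, idx] <- cnt_m[idx, idx] + 1
  }
  out <- sum_m
  covered <- cnt_m > 0
  out[covered] <- out[covered] / cnt_m[covered]
  covered_bins <- unique(unlist(lapply(tiles, function(tl)
    (tl$start_bin + 1L):(tl$start_bin + window))))
  uncovered <- nb - length(covered_bins)
  out <- symmetrize_exact((out + t(out)) / 2)
  res <- structure(list(chrom = bulk_map$chrom,
                        resolution = bulk_map$resolution,
                        matrix = out, norm_state = "minmax"),
                   class = "contact_map")
  attr(res, "uncovered_bins") <- uncovered
  res
}

#' @export
predict.scghd_model <- function(object, bulk_map, tracks,
                                stride = 16L, window = 128L, ...) {
  predict_chromosome(object, bulk_map, tracks, stride = stride,
                     window = window)
}

#' Run a full experiment from a config
#'
#' Drives the whole pipeline: synthetic data generation (or loading),
#' preprocessing, training on the training chromosomes, prediction on the
#' held-out chromosomes, and metric evaluation, writing all artifacts and a
#' JSON metric report under `out_dir`.
#'
#' The config is a YAML file or a list with (all optional) keys:
#' `seed`, `out_dir`, `synthetic` (a list of [synthetic_spec()] arguments),
#' `n_train_chromosomes`, `n_test_chromosomes`, `model` (a list of
#' [model_config()] arguments), `train` (a list of [train_config()]
#' arguments), `out_format` (one of the [write_contact_map()] formats).
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return invisibly, the metric report list (also written as
#'   `report.json`).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- if (is.null(config$n_train_chromosomes)) 2L else
    as.integer(config$n_train_chromosomes)
  n_test <- if (is.null(config$n_test_chromosomes)) 1L else
    as.integer(config$n_test_chromosomes)
  out_format <- if (is.null(config$out_format)) "sparse_text" else
    config$out_format

  spec_args <- if (is.null(config$synthetic)) list() else config$synthetic
  mdl_args <- if (is.null(config$model)) list() else config$model
  trn_args <- if (is.null(config$train)) list() else config$train
  mdl_args$seed <- seed
  trn_args$seed <- seed

  spec <- do.call(synthetic_spec, c(spec_args, list(seed = seed)))
  mcfg <- do.call(model_config, mdl_args)
  tcfg <- do.call(train_config, trn_args)

  prep <- prepare_synthetic_experiment(spec, n_train, n_test, mcfg$pe_k)
  model <- scghd_model(mcfg)
  model <- train_model(model, prep$train_tiles, tcfg)
  save_checkpoint(model, file.path(out_dir, "checkpoint.json"))

  report <- list(seed = seed, loss_history = model$history, chromosomes = list())
  for (ch in names(prep$test)) {
    chrom_dat <- prep$test[[ch]]
    chrom_rep <- list()
    for (ct in names(chrom_dat$tracks)) {
      pred <- predict_chromosome(model, chrom_dat$bulk,
                                 chrom_dat$tracks[[ct]],
                                 stride = tcfg$stride_predict)
      write_contact_map(pred, file.path(out_dir, sprintf(
        "pred_%s_%s.%s", ch, ct,
        if (out_format == "cooler") "cool.d" else "tsv")), out_format)
      target <- chrom_dat$targets[[ct]]
      chrom_rep[[ct]] <- evaluate_pair(pred, target)
    }
    report$chromosomes[[ch]] <- chrom_rep
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Score a predicted map against a target with all three metrics
#'
#' @param pred,target [contact_map()]s of the same shape.
#' @return list with `gd`, `scc`, `tad_f1`.
#' @export
evaluate_pair <- function(pred, target) {
  list(gd = genomedisco_score(pred, target),
       scc = scc_score(pred, target),
       tad_f1 = tad_f1(call_tad_boundaries(pred),
                       call_tad_boundaries(target))$f1)
}
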