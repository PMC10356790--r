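# End-to-end optimization: Adam with warm-up + cosine learning-rate
# schedule, one random crop per training sample per epoch, center crops for
# validation, early stopping on the balanced label-smoothed cross-entropy
# of the validation split (without the entropy term), and stratified
# k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the reference recipe: peak learning rate 1e-4 reached
#' by linear warm-up over 5 epochs then cosine-annealed to zero at
#' `max_epochs`, mini-batches of 4, early stopping with patience 30,
#' entropy weight 0.01, five folds.
#'
#' @param max_epochs total epoch budget.
#' @param warmup_epochs linear warm-up length.
#' @param peak_lr learning rate at the end of warm-up.
#' @param batch_size mini-batch size.
#' @param patience epochs without validation improvement before stopping.
#' @param lambda entropy-regularizer weight.
#' @param seed integer seed governing shuffling, crops and fold splits.
#' @param folds number of cross-validation folds.
#' @param crop_size crop extent used for augmentation (3-vector or scalar);
#'   NULL disables cropping.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, warmup_epochs = 5L,
                         peak_lr = 1e-4, batch_size = 4L, patience = 30L,
                         lambda = 0.01, seed = 1L, folds = 5L,
                         crop_size = NULL) {
  stopifnot(max_epochs > warmup_epochs, warmup_epochs >= 1L,
            peak_lr > 0, batch_size >= 1L, patience >= 0L, lambda >= 0,
            folds >= 2L)
  structure(list(max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 peak_lr = peak_lr, batch_size = as.integer(batch_size),
                 patience = as.integer(patience), lambda = lambda,
                 seed = as.integer(seed), folds = as.integer(folds),
                 crop_size = crop_size),
            class = "train_config")
}

#' Learning-rate schedule: linear warm-up then cosine annealing
#'
#' For epoch e (0-based): during warm-up,
#' `peak_lr * (e + 1) / warmup_epochs`; afterwards
#' `peak_lr * 0.5 * (1 + cos(pi * (e - warmup) / (max_epochs - warmup)))`.
#' Continuous at the boundary and non-negative everywhere.
#'
#' @param epoch 0-based epoch index in `[0, max_epochs)`.
#' @param cfg a [train_config].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (any(epoch < 0 | epoch >= cfg$max_epochs))
    stop("epoch out of range [0, max_epochs)")
  w <- cfg$warmup_epochs
  ifelse(epoch < w,
         cfg$peak_lr * (epoch + 1) / w,
         cfg$peak_lr * 0.5 *
           (1 + cos(pi * (epoch - w) / (cfg$max_epochs - w))))
}

# ---- Adam ------------------------------------------------------------------

# Optimizer state lives on the layer environments (slots m_<p>, v_<p>).
adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (rec in model_layers(model)) {
    ly <- rec$layer
    for (pn in layer_param_names(ly)) {
      g <- get(layer_grad_name(pn), envir = ly)
      if (is.null(g)) next
      p <- get(pn, envir = ly)
      ms <- paste0("m_", pn); vs <- paste0("v_", pn)
      ts <- paste0("t_", pn)
      m <- if (exists(ms, envir = ly, inherits = FALSE)) get(ms, envir = ly) else g * 0
      v <- if (exists(vs, envir = ly, inherits = FALSE)) get(vs, envir = ly) else g * 0
      t <- if (exists(ts, envir = ly, inherits = FALSE)) get(ts, envir = ly) else 0L
      t <- t + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      assign(pn, p, envir = ly)
      assign(ms, m, envir = ly); assign(vs, v, envir = ly)
      assign(ts, t, envir = ly)
    }
  }
  invisible(model)
}

reset_optimizer <- function(model) {
  for (rec in model_layers(model)) {
    ly <- rec$layer
    for (pn in layer_param_names(ly))
      for (pre in c("m_", "v_", "t_")) {
        nm <- paste0(pre, pn)
        if (exists(nm, envir = ly, inherits = FALSE)) rm(list = nm, envir = ly)
      }
  }
  invisible(model)
}

# ---- datasets --------------------------------------------------------------

# a dataset is list(volumes = list of normalized volumes, labels = int vec)
check_dataset <- function(ds) {
  stopifnot(is.list(ds$volumes), length(ds$volumes) == length(ds$labels))
  invisible(ds)
}

subset_dataset <- function(ds, idx) {
  out <- list(volumes = ds$volumes[idx], labels = ds$labels[idx])
  if (!is.null(ds$pair_ids)) out$pair_ids <- ds$pair_ids[idx]
  out
}

# center-crop a dataset's volumes once and precompute the shared indicator
prepare_eval_set <- function(ds, model, cfg, full_extent) {
  spec_layers <- model$spec$layer_geoms
  if (is.null(cfg$crop_size)) {
    crp <- crop_spec(c(0L, 0L, 0L), full_extent)
  } else {
    crp <- sample_crop(full_extent, cfg$crop_size, mode = "center")
  }
  grid <- make_coordinate_grid(full_extent)
  ind <- extract_position_indicator(crop_grid(grid, crp), spec_layers)
  vols <- lapply(ds$volumes, crop_volume, spec = crp)
  list(volumes = vols, labels = ds$labels, indicator = ind, crop = crp)
}

eval_scores <- function(model, prepared) {
  vapply(prepared$volumes, function(v) {
    fw <- model_forward(model, v, indicator = prepared$indicator)
    fw$y_hat
  }, numeric(1))
}

# ---- single-fold training --------------------------------------------------

#' Train one fold
#'
#' Optimizes all parameter groups jointly with Adam under the warm-up +
#' cosine schedule. Each training sample receives one freshly sampled
#' random crop per epoch (image and coordinate grid cropped together);
#' validation uses center crops. Model selection and early stopping use
#' the mean balanced label-smoothed cross-entropy on the validation split,
#' without the entropy term. Fully reproducible from `cfg$seed`.
#'
#' @param train_ds,val_ds datasets: lists with `volumes` (normalized
#'   [volume]s of identical extent) and `labels`.
#' @param model_spec an [encoder_spec] (or patch size).
#' @param gating_mode gating mode passed to [build_model()].
#' @param cfg a [train_config].
#' @param fold_index integer tag recorded in the result.
#' @param fixed_gate optional fixed gate map for `fixed_gate` mode.
#' @param init_model optional `bagnet_model` to start from (transfer
#'   learning); must match `model_spec` and `gating_mode`. Its optimizer
#'   state is reset.
#' @param verbose print per-epoch progress.
#' @return object of class `fold_result`: `model` (best checkpoint),
#'   `best_val_loss`, `epoch_stopped`, `metrics` (acc/auroc on the
#'   validation split) and `history` (epoch, lr, train/val loss).
#' @export
train_fold <- function(train_ds, val_ds, model_spec, gating_mode, cfg,
                       fold_index = 1L, fixed_gate = NULL,
                       init_model = NULL, verbose = FALSE) {
  check_dataset(train_ds); check_dataset(val_ds)
  if (length(unique(train_ds$labels)) < 2L)
    stop("training split must contain both classes")
  full_extent <- dim(train_ds$volumes[[1L]]$data)
  if (!inherits(model_spec, "encoder_spec")) model_spec <- encoder_spec(model_spec)
  if (is.null(init_model)) {
    model <- build_model(model_spec, gating_mode, seed = cfg$seed,
                         fixed_gate = fixed_gate)
  } else {
    if (init_model$spec$patch_size != model_spec$patch_size ||
        init_model$gating_mode != gating_mode)
      stop("incompatible init_model: encoder spec or gating mode differ")
    model <- transfer_init(init_model)
  }
  beta <- compute_beta(train_ds$labels)
  lcfg <- loss_config(beta = beta, lambda = cfg$lambda)
  grid <- make_coordinate_grid(full_extent)
  crop_size <- if (is.null(cfg$crop_size)) full_extent else
    as.integer(rep_len(cfg$crop_size, 3L))
  # indicators depend only on the crop origin; cache them
  ind_cache <- new.env(parent = emptyenv())
  indicator_for <- function(crp) {
    key <- paste(crp$origin, collapse = ",")
    hit <- ind_cache[[key]]
    if (is.null(hit)) {
      hit <- extract_position_indicator(crop_grid(grid, crp),
                                        model_spec$layer_geoms)
      ind_cache[[key]] <- hit
    }
    hit
  }
  val_prep <- prepare_eval_set(val_ds, model, cfg, full_extent)
  n_train <- length(train_ds$volumes)
  best <- list(val_loss = Inf, params = NULL, epoch = 0L)
  stall <- 0L
  history <- list()
  set.seed(cfg$seed)
  for (epoch in 0:(cfg$max_epochs - 1L)) {
    lr <- lr_schedule(epoch, cfg)
    ord <- sample.int(n_train)
    train_losses <- numeric(0)
    for (start in seq(1L, n_train, by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
      zero_gradients(model)
      bl <- 0
      for (i in batch) {
        crp <- sample_crop(full_extent, crop_size, mode = "random")
        v <- crop_volume(train_ds$volumes[[i]], crp)
        ind <- if (gating_mode == "position_gate") indicator_for(crp) else NULL
        fw <- model_forward(model, v, indicator = ind)
        y <- train_ds$labels[[i]]
        # the entropy regularizer applies only to learnable gates
        learnable_gate <- gating_mode %in% c("position_gate", "feature_gate")
        bl <- bl + total_loss(fw$y_hat, y,
                              if (learnable_gate) fw$g else NULL, lcfg)
        dz <- classification_loss_dz(fw$y_hat, y, lcfg) / length(batch)
        dg_extra <- if (learnable_gate && lcfg$lambda > 0)
          gate_entropy_loss_dgate(fw$g, lcfg$lambda) / length(batch) else NULL
        model_backward(model, fw, dz, dgate_extra = dg_extra)
      }
      train_losses <- c(train_losses, bl / length(batch))
      adam_step(model, lr)
    }
    val_loss <- mean(vapply(seq_along(val_prep$volumes), function(j) {
      fw <- model_forward(model, val_prep$volumes[[j]],
                          indicator = val_prep$indicator)
      classification_loss(fw$y_hat, val_prep$labels[[j]], lcfg)
    }, numeric(1)))
    history[[length(history) + 1L]] <-
      list(epoch = epoch, lr = lr, train_loss = mean(train_losses),
           val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d lr %.2e train %.4f val %.4f",
                      epoch, lr, mean(train_losses), val_loss))
    if (val_loss < best$val_loss) {
      best <- list(val_loss = val_loss, params = model_parameters(model),
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > cfg$patience) break
    }
  }
  set_model_parameters(model, best$params)
  sc <- eval_scores(model, val_prep)
  metrics <- evaluate_predictions(sc, val_prep$labels)
  structure(list(fold_index = fold_index, model = model,
                 best_val_loss = best$val_loss,
                 epoch_stopped = best$epoch,
                 metrics = metrics,
                 history = do.call(rbind, lapply(history, as.data.frame))),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> fold %d | val loss %.4f @ epoch %d | acc %.3f auroc %.3f\n",
              x$fold_index, x$best_val_loss, x$epoch_stopped,
              x$metrics$acc, x$metrics$auroc))
  invisible(x)
}

# ---- cross-validation ------------------------------------------------------

#' Stratified fold assignment
#'
#' Without `groups`, folds are stratified by label so each fold's class
#' proportion is within one sample of the global one. With `groups`
#' (e.g. the matched-pair identifiers of a phantom cohort), whole groups
#' are assigned to folds, so related samples never straddle a
#' train/validation boundary; for 1:1 matched pairs this is also exactly
#' label-balanced.
#'
#' @param labels 0/1 labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @param groups optional group identifiers (same length as `labels`).
#' @return integer vector of fold indices (1..folds).
#' @export
stratified_folds <- function(labels, folds, seed = 1L, groups = NULL) {
  labels <- as.integer(labels)
  set.seed(seed)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(labels))
    gs <- sample(unique(groups))
    gf <- rep_len(seq_len(folds), length(gs))
    return(gf[match(groups, gs)])
  }
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' k-fold cross-validation
#'
#' For each fold, the held-out fold is the validation/evaluation split and
#' the remaining folds form the training split; early stopping is driven
#' by an inner split carved from the training folds
#' (`inner_val_fraction`, stratified), so the held-out fold never
#' influences model selection.
#'
#' @param ds dataset (list of normalized `volumes` plus `labels`).
#' @param model_spec an [encoder_spec] or patch size.
#' @param gating_mode gating mode.
#' @param cfg a [train_config].
#' @param inner_val_fraction fraction of the training split used for
#'   early stopping.
#' @param groups optional group identifiers kept intact across splits
#'   (see [stratified_folds()]); defaults to `ds$pair_ids` when present.
#' @param verbose print progress.
#' @return list of `fold_result`s with attribute `summary`: mean and sd of
#'   acc/auroc over the held-out folds.
#' @export
cross_validate <- function(ds, model_spec, gating_mode, cfg,
                           inner_val_fraction = 0.2, groups = NULL,
                           verbose = FALSE) {
  check_dataset(ds)
  if (is.null(groups)) groups <- ds$pair_ids
  tab <- table(ds$labels)
  if (length(tab) < 2L || any(tab < cfg$folds))
    stop("need at least `folds` samples per class")
  fold_id <- stratified_folds(ds$labels, cfg$folds, seed = cfg$seed,
                              groups = groups)
  results <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test_idx <- which(fold_id == f)
    tr_idx <- which(fold_id != f)
    inner <- stratified_folds(ds$labels[tr_idx],
                              folds = max(2L, round(1 / inner_val_fraction)),
                              seed = cfg$seed + f,
                              groups = groups[tr_idx])
    val_idx <- tr_idx[inner == 1L]
    fit_idx <- tr_idx[inner != 1L]
    fr <- train_fold(subset_dataset(ds, fit_idx),
                     subset_dataset(ds, val_idx),
                     model_spec, gating_mode,
                     within_seed(cfg, cfg$seed + 1000L * f),
                     fold_index = f, verbose = verbose)
    # report metrics on the genuinely held-out fold
    held <- prepare_eval_set(subset_dataset(ds, test_idx), fr$model, cfg,
                             dim(ds$volumes[[1L]]$data))
    sc <- eval_scores(fr$model, held)
    fr$metrics <- evaluate_predictions(sc, held$labels)
    results[[f]] <- fr
  }
  accs <- vapply(results, function(r) r$metrics$acc, numeric(1))
  aucs <- vapply(results, function(r) r$metrics$auroc, numeric(1))
  attr(results, "summary") <- list(acc_mean = mean(accs), acc_sd = stats::sd(accs),
                                   auroc_mean = mean(aucs), auroc_sd = stats::sd(aucs))
  results
}

within_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed %% .Machine$integer.max)
  cfg
}
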