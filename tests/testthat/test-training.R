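test_that("the learning-rate schedule warms up linearly and anneals as a cosine", {
  cfg <- train_config(max_epochs = 200L, warmup_epochs = 5L,
                      peak_lr = 1e-4)
  # end of warm-up (0-based epoch 4) hits the peak exactly
  expect_identical(lr_schedule(4, cfg), 1e-4)
  expect_equal(lr_schedule(0:3, cfg), 1e-4 * (1:4) / 5, tolerance = 1e-15)
  # final epoch is approximately zero
  expect_lt(lr_schedule(199, cfg), 1e-7)
  # cosine midpoint is half the peak
  mid <- 5 + (200 - 5) / 2
  expect_equal(lr_schedule(mid, cfg), 5e-5, tolerance = 1e-12)
  # continuity at the boundary and non-negativity everywhere
  expect_equal(lr_schedule(5, cfg), 1e-4, tolerance = 1e-9)
  all_lr <- lr_schedule(0:199, cfg)
  expect_true(all(all_lr >= 0))
  expect_lt(max(abs(diff(all_lr))), 2.5e-5)
  expect_error(lr_schedule(200, cfg), "out of range")
  expect_error(lr_schedule(-1, cfg), "out of range")
})

test_that("training is reproducible and early stopping returns the best epoch", {
  ds <- tiny_dataset(tiny_phantom_config(seed = 41, n_per_class = 6L))
  idx <- split_idx(ds$labels, folds = 3L, pairs = ds$pair_ids)
  cfg <- tiny_train_config(max_epochs = 4L, warmup_epochs = 2L)
  f1 <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                   encoder_spec(9), "position_gate", cfg)
  f2 <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                   encoder_spec(9), "position_gate", cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(model_parameters(f1$model), model_parameters(f2$model))
  # best checkpoint is never worse than any epoch observed
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_error(train_fold(list(volumes = ds$volumes[ds$labels == 0],
                               labels = ds$labels[ds$labels == 0]),
                          subset_ds(ds, idx$val),
                          encoder_spec(9), "position_gate", cfg),
               "both classes")
})

test_that("patience zero stops at the first non-improving epoch", {
  ds <- tiny_dataset(tiny_phantom_config(seed = 43, n_per_class = 4L))
  idx <- split_idx(ds$labels, folds = 4L, pairs = ds$pair_ids)
  cfg <- tiny_train_config(max_epochs = 8L, warmup_epochs = 2L,
                           patience = 0L)
  fr <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                   encoder_spec(9), "position_gate", cfg)
  h <- fr$history
  n <- nrow(h)
  if (n < cfg$max_epochs) {
    # stopped: the final epoch did not improve on the best
    expect_gte(h$val_loss[n], min(h$val_loss[-n]))
    expect_identical(fr$epoch_stopped, which.min(h$val_loss) - 1L)
  } else {
    # ran to budget only if improving every epoch
    expect_true(all(diff(h$val_loss) < 0))
  }
})

test_that("a constant fixed gate reproduces gap-mode training", {
  ds <- tiny_dataset(tiny_phantom_config(seed = 47, n_per_class = 4L))
  idx <- split_idx(ds$labels, folds = 4L, pairs = ds$pair_ids)
  cfg <- tiny_train_config(max_epochs = 3L, warmup_epochs = 1L)
  d_out <- output_extent(cfg$crop_size, encoder_spec(9)$layer_geoms)
  fg <- array(0.7, d_out)
  f_gap <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                      encoder_spec(9), "gap", cfg)
  f_fix <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                      encoder_spec(9), "fixed_gate", cfg, fixed_gate = fg)
  expect_equal(f_fix$history$train_loss, f_gap$history$train_loss,
               tolerance = 1e-6)
  expect_equal(f_fix$history$val_loss, f_gap$history$val_loss,
               tolerance = 1e-6)
})

test_that("cross-validation partitions samples once, stratified, and reports all folds", {
  ds <- tiny_dataset(tiny_phantom_config(seed = 53, n_per_class = 10L,
                                         extent = 24L,
                                         lesion_center = c(14, 12, 10),
                                         lesion_radius = 4))
  cfg <- tiny_train_config(max_epochs = 2L, warmup_epochs = 1L,
                           crop_size = 22L, folds = 5L)
  res <- cross_validate(ds, encoder_spec(9), "position_gate", cfg)
  expect_length(res, 5L)
  s <- attr(res, "summary")
  expect_true(all(c("acc_mean", "acc_sd", "auroc_mean", "auroc_sd") %in%
                  names(s)))
  # fold assignment: a partition, stratified within one sample
  f <- stratified_folds(ds$labels, 5L, seed = cfg$seed)
  expect_identical(sort(unique(f)), 1:5)
  expect_identical(length(f), length(ds$labels))
  for (k in 1:5) {
    prop <- mean(ds$labels[f == k])
    expect_lt(abs(prop - mean(ds$labels)) * sum(f == k), 1.0 + 1e-9)
  }
  expect_error(cross_validate(list(volumes = ds$volumes[1:6],
                                   labels = ds$labels[1:6]),
                              encoder_spec(9), "position_gate", cfg),
               "per class")
})

test_that("entropy regularization raises trained-gate entropy relative to lambda zero", {
  ds <- tiny_dataset(tiny_phantom_config(seed = 59))
  idx <- split_idx(ds$labels, pairs = ds$pair_ids)
  gate_H <- function(lambda) {
    cfg <- tiny_train_config(max_epochs = 6L, warmup_epochs = 2L,
                             lambda = lambda)
    fr <- train_fold(subset_ds(ds, idx$train), subset_ds(ds, idx$val),
                     encoder_spec(9), "position_gate", cfg)
    ext <- dim(ds$volumes[[1]]$data)
    crp <- sample_crop(ext, cfg$crop_size, mode = "center")
    ind <- extract_position_indicator(crop_grid(make_coordinate_grid(ext),
                                                crp),
                                      encoder_spec(9)$layer_geoms)
    gate_entropy(gate_forward(fr$model, ind))
  }
  expect_gte(gate_H(0.05), gate_H(0))
})

test_that("transfer from a stronger-contrast task speeds up learning the subtle task", {
  # source: well-separated lesion; target: same lesion at low amplitude
  src <- tiny_dataset(tiny_phantom_config(seed = 61,
                                          lesion_amplitude = 2.5))
  tgt <- tiny_dataset(tiny_phantom_config(seed = 67,
                                          lesion_amplitude = 0.8))
  idx_s <- split_idx(src$labels, pairs = src$pair_ids)
  idx_t <- split_idx(tgt$labels, pairs = tgt$pair_ids)
  cfg_s <- tiny_train_config(max_epochs = 6L, warmup_epochs = 2L)
  f_src <- train_fold(subset_ds(src, idx_s$train), subset_ds(src, idx_s$val),
                      encoder_spec(9), "position_gate", cfg_s)
  warm <- transfer_init(f_src$model)
  # optimizer state is reset by transfer_init
  expect_false(any(grepl("^m_", ls(warm$encoder$stem$conv))))
  cfg_t <- tiny_train_config(max_epochs = 3L, warmup_epochs = 1L, seed = 11L)
  f_scratch <- train_fold(subset_ds(tgt, idx_t$train),
                          subset_ds(tgt, idx_t$val),
                          encoder_spec(9), "position_gate", cfg_t)
  f_warm <- train_fold(subset_ds(tgt, idx_t$train),
                       subset_ds(tgt, idx_t$val),
                       encoder_spec(9), "position_gate", cfg_t,
                       init_model = warm)
  expect_lt(f_warm$best_val_loss, f_scratch$best_val_loss)
  # architecture mismatch is refused
  expect_error(train_fold(subset_ds(tgt, idx_t$train),
                          subset_ds(tgt, idx_t$val),
                          encoder_spec(17), "position_gate", cfg_t,
                          init_model = warm),
               "incompatible")
})
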