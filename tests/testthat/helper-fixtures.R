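# Shared fixtures: tiny phantom configurations and helpers sized so that a
# full training run completes in seconds. The default-scale cohort is only
# generated in the end-to-end acceptance test.

tiny_phantom_config <- function(seed = 101L, ...) {
  args <- list(extent = 32L, n_per_class = 10L,
               lesion_center = c(20, 17, 13), lesion_radius = 5,
               lesion_amplitude = 1.2, n_distractors = 3L,
               distractor_radius = 3, distractor_amplitude = 1.0,
               noise_sd = 0.1, smoothness_sigma = 2.5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

tiny_dataset <- function(cfg = tiny_phantom_config()) {
  cohort <- generate_cohort(cfg)
  list(volumes = lapply(cohort$volumes, normalize_volume),
       labels = cohort$labels, pair_ids = cohort$pair_ids,
       lesion_mask = cohort$lesion_mask, config = cfg)
}

tiny_train_config <- function(...) {
  args <- list(max_epochs = 8L, warmup_epochs = 2L, patience = 8L,
               seed = 7L, crop_size = 28L, batch_size = 4L)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

random_volume <- function(extent = c(20L, 18L, 19L), seed = 1L) {
  set.seed(seed)
  normalize_volume(volume(array(stats::rnorm(prod(extent)), extent)))
}

stem_pool_layers <- function() list(layer_geom(5L, 2L), layer_geom(3L, 2L))

# split a dataset into stratified train/validation index sets; matched
# pairs (when given) stay on one side of the split
split_idx <- function(labels, folds = 5L, seed = 5L, pairs = NULL) {
  f <- stratified_folds(labels, folds, seed = seed, groups = pairs)
  list(train = which(f != 1L), val = which(f == 1L))
}

subset_ds <- function(ds, idx) {
  out <- list(volumes = ds$volumes[idx], labels = ds$labels[idx])
  if (!is.null(ds$pair_ids)) out$pair_ids <- ds$pair_ids[idx]
  out
}
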