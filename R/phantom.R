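# Synthetic 3D phantom cohorts.
#
# Each subject is a template-aligned volume: a smooth per-subject
# background (Gaussian-filtered white noise, standardized to unit sd),
# additive sensor noise, label-irrelevant distractor spheres placed
# uniformly at random in BOTH classes, and - in the positive class only -
# an additive lesion sphere at one fixed template position. The lesion is
# the only inter-subject-consistent class difference, which is exactly the
# structure the position-based gate is designed to exploit.

#' Phantom cohort configuration
#'
#' @param extent volume extent per axis (default 48).
#' @param n_per_class subjects per class (default 50).
#' @param lesion_center 0-based voxel coordinates of the lesion center,
#'   identical for every positive subject.
#' @param lesion_radius lesion sphere radius in voxels.
#' @param lesion_amplitude additive lesion intensity (in background-sd
#'   units).
#' @param n_distractors distractor spheres per subject (both classes).
#' @param distractor_radius distractor sphere radius in voxels.
#' @param distractor_amplitude additive distractor intensity; each
#'   distractor's sign is random.
#' @param noise_sd sd of i.i.d. sensor noise.
#' @param smoothness_sigma Gaussian sigma (voxels) of the background
#'   smoothing.
#' @param seed integer seed; subject i uses derived seed `seed + i`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(extent = c(48L, 48L, 48L),
                           n_per_class = 50L,
                           lesion_center = c(30L, 27L, 19L),
                           lesion_radius = 6,
                           lesion_amplitude = 0.75,
                           n_distractors = 6L,
                           distractor_radius = 4,
                           distractor_amplitude = 1.0,
                           noise_sd = 0.1,
                           smoothness_sigma = 3,
                           seed = 1L) {
  extent <- as.integer(rep_len(extent, 3L))
  lesion_center <- as.numeric(rep_len(lesion_center, 3L))
  if (any(lesion_center - lesion_radius < 0) ||
      any(lesion_center + lesion_radius > extent - 1L))
    stop("lesion sphere must lie fully inside the volume")
  structure(list(extent = extent, n_per_class = as.integer(n_per_class),
                 lesion_center = lesion_center,
                 lesion_radius = lesion_radius,
                 lesion_amplitude = lesion_amplitude,
                 n_distractors = as.integer(n_distractors),
                 distractor_radius = distractor_radius,
                 distractor_amplitude = distractor_amplitude,
                 noise_sd = noise_sd,
                 smoothness_sigma = smoothness_sigma,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# banded row-stochastic Gaussian smoothing matrix for one axis
gauss_smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- ceiling(3 * sigma)
  i <- matrix(seq_len(n), n, n)
  K <- exp(-(i - t(i))^2 / (2 * sigma^2))
  K[abs(i - t(i)) > half] <- 0
  K / rowSums(K)
}

smooth3d <- function(a, sigma) {
  d <- dim(a)
  S1 <- gauss_smooth_matrix(d[1L], sigma)
  S2 <- gauss_smooth_matrix(d[2L], sigma)
  S3 <- gauss_smooth_matrix(d[3L], sigma)
  m <- S1 %*% matrix(a, d[1L])                        # along axis 1
  a <- array(m, d)
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(S2 %*% matrix(a, d[2L]), d[c(2L, 1L, 3L)])
  a <- aperm(a, c(2L, 1L, 3L))
  a <- aperm(a, c(3L, 2L, 1L))
  a <- array(S3 %*% matrix(a, d[3L]), d[c(3L, 2L, 1L)])
  aperm(a, c(3L, 2L, 1L))
}

sphere_mask <- function(extent, center, radius) {
  ax <- lapply(1:3, function(a) (seq_len(extent[a]) - 1) - center[a])
  d2 <- outer(outer(ax[[1L]]^2, ax[[2L]]^2, "+"), ax[[3L]]^2, "+")
  d2 <= radius^2
}

#' Generate a phantom cohort
#'
#' Produces `2 * n_per_class` labeled volumes (negatives first) plus the
#' ground-truth lesion mask on the full grid. Bit-exactly reproducible
#' from `cfg$seed`. The design is matched-pairs: negative subject j and
#' positive subject j share the background, sensor-noise and distractor
#' draws, so the lesion is the *only* systematic class difference and a
#' zero-amplitude lesion makes the classes exactly indistinguishable.
#' Volumes are raw (un-normalized); standardize with [normalize_volume()]
#' before feeding a model.
#'
#' @param cfg a [phantom_config].
#' @return list with `volumes` (list of [volume]s with labels), `labels`,
#'   `pair_ids` (matched-pair identifiers, used for group-aware splits),
#'   and `lesion_mask` (logical array).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  ext <- cfg$extent
  lesion <- sphere_mask(ext, cfg$lesion_center, cfg$lesion_radius)
  n_total <- 2L * cfg$n_per_class
  labels <- rep(c(0L, 1L), each = cfg$n_per_class)
  volumes <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(cfg$seed + (i - 1L) %% cfg$n_per_class + 1L)
    bg <- array(stats::rnorm(prod(ext)), ext)
    bg <- smooth3d(bg, cfg$smoothness_sigma)
    s <- stats::sd(bg)
    if (s > 0) bg <- bg / s                           # unit-sd background
    x <- bg
    if (cfg$noise_sd > 0)
      x <- x + array(stats::rnorm(prod(ext), sd = cfg$noise_sd), ext)
    if (cfg$n_distractors > 0L) {
      for (k in seq_len(cfg$n_distractors)) {
        ctr <- vapply(ext, function(n) stats::runif(1, 0, n - 1), numeric(1))
        amp <- cfg$distractor_amplitude * sample(c(-1, 1), 1L)
        x <- x + amp * sphere_mask(ext, ctr, cfg$distractor_radius)
      }
    }
    if (labels[i] == 1L) x <- x + cfg$lesion_amplitude * lesion
    volumes[[i]] <- volume(x, label = labels[i])
  }
  list(volumes = volumes, labels = labels,
       pair_ids = rep(seq_len(cfg$n_per_class), 2L), lesion_mask = lesion)
}

#' Write a cohort to disk
#'
#' Writes each volume as NIfTI, the ground-truth lesion mask, and a
#' manifest CSV (`path,label,subject_id,split`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$volumes)
  paths <- sprintf("subject_%03d.nii.gz", seq_len(n))
  for (i in seq_len(n))
    write_volume(cohort$volumes[[i]], file.path(dir, paths[i]))
  write_volume(volume(array(as.numeric(cohort$lesion_mask),
                            dim(cohort$lesion_mask))),
               file.path(dir, "lesion_mask.nii.gz"))
  manifest <- data.frame(path = paths, label = cohort$labels,
                         subject_id = sprintf("S%03d", seq_len(n)),
                         split = "all")
  if (!is.null(cohort$pair_ids)) manifest$pair_id <- cohort$pair_ids
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Localization score of a gate map
#'
#' Maps each patch-grid position to its receptive-field footprint in the
#' full volume (crop origin + offset + index * jump, extending
#' (rf - 1)/2 voxels each way) and returns the fraction of total gate mass
#' carried by patches whose footprint overlaps the ground-truth mask.
#'
#' @param g a `gate_map` (w x h x d array).
#' @param mask logical lesion mask on the full grid.
#' @param layers encoder layer geometry (list of [layer_geom]).
#' @param crop_origin 0-based origin of the crop the gate was computed on.
#' @return scalar in \[0, 1\].
#' @export
localization_score <- function(g, mask, layers,
                               crop_origin = c(0L, 0L, 0L)) {
  geom <- compose_geometry(layers)
  d_out <- dim(g)
  ext <- dim(mask)
  half <- (geom$rf - 1) / 2
  centers <- lapply(1:3, function(a)
    crop_origin[a] + geom$offset + geom$jump * (seq_len(d_out[a]) - 1))
  # box-overlap test via the integral volume of the mask
  cs <- apply(apply(apply(mask * 1, c(2, 3), cumsum), c(1, 3), cumsum),
              c(1, 2), cumsum)
  cs <- aperm(cs, c(2, 3, 1))
  pad <- array(0, ext + 1L)
  pad[-1L, -1L, -1L] <- cs
  box_sum <- function(lo, hi) {  # 1-based inclusive bounds, vectors len 3
    pad[hi[1] + 1L, hi[2] + 1L, hi[3] + 1L] -
      pad[lo[1], hi[2] + 1L, hi[3] + 1L] -
      pad[hi[1] + 1L, lo[2], hi[3] + 1L] -
      pad[hi[1] + 1L, hi[2] + 1L, lo[3]] +
      pad[lo[1], lo[2], hi[3] + 1L] +
      pad[lo[1], hi[2] + 1L, lo[3]] +
      pad[hi[1] + 1L, lo[2], lo[3]] -
      pad[lo[1], lo[2], lo[3]]
  }
  overlaps <- array(FALSE, d_out)
  for (k in seq_len(d_out[3])) for (j in seq_len(d_out[2]))
    for (i in seq_len(d_out[1])) {
      ctr <- c(centers[[1]][i], centers[[2]][j], centers[[3]][k])
      lo <- pmax(round(ctr - half) + 1, 1)
      hi <- pmin(round(ctr + half) + 1, ext)
      overlaps[i, j, k] <- box_sum(lo, hi) > 0
    }
  gv <- as.numeric(g)
  sum(gv[as.logical(overlaps)]) / sum(gv)
}
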