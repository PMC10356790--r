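# Export and visualization support: gate and evidence maps live on the
# coarse patch grid; for overlay in template space each grid value is
# placed at its patch-center voxel and trilinearly interpolated between
# centers, with a validity mask flagging voxels outside the patch-center
# bounding box (filled with 0 there).

#' Upsample a patch-grid map to full resolution
#'
#' @param map a `gate_map`, `evidence_map` or plain w x h x d array.
#' @param geom geometry from [compose_geometry()] for the encoder.
#' @param crop a [crop_spec] recording where the model input sat in the
#'   full volume (use origin 0 and the full extent if uncropped).
#' @param target_extent extent of the full-resolution output grid.
#' @return list with `map` (full-resolution array), `valid` (logical
#'   array, TRUE inside the patch-center bounding box) and `geometry`
#'   (rf, jump, offset, crop origin) sufficient to regenerate the overlay.
#' @export
upsample_map <- function(map, geom, crop, target_extent) {
  d_map <- dim(map)
  target_extent <- as.integer(rep_len(target_extent, 3L))
  # per-axis linear interpolation matrices from patch centers to voxels
  mats <- vector("list", 3L)
  valid_ax <- vector("list", 3L)
  for (a in 1:3) {
    centers <- crop$origin[a] + geom$offset + geom$jump * (seq_len(d_map[a]) - 1)
    if (max(centers) > target_extent[a] - 1 + 1e-9)
      stop("inconsistent geometry: patch centers fall outside the target grid")
    vox <- seq_len(target_extent[a]) - 1
    t <- (vox - centers[1L]) / geom$jump
    inside <- t >= 0 & t <= d_map[a] - 1
    A <- matrix(0, target_extent[a], d_map[a])
    lo <- pmin(floor(t), d_map[a] - 2)
    fr <- t - lo
    rows <- which(inside)
    for (r in rows) {
      A[r, lo[r] + 1L] <- 1 - fr[r]
      if (fr[r] > 0) A[r, lo[r] + 2L] <- fr[r]
    }
    mats[[a]] <- A
    valid_ax[[a]] <- inside
  }
  d <- dim(map)
  up <- array(mats[[1L]] %*% matrix(map, d[1L]),
              c(target_extent[1L], d[2L], d[3L]))
  up <- aperm(up, c(2L, 1L, 3L))
  up <- array(mats[[2L]] %*% matrix(up, d[2L]),
              c(target_extent[2L], target_extent[1L], d[3L]))
  up <- aperm(up, c(2L, 1L, 3L))
  up <- aperm(up, c(3L, 2L, 1L))
  up <- array(mats[[3L]] %*% matrix(up, d[3L]),
              c(target_extent[3L], target_extent[2L], target_extent[1L]))
  up <- aperm(up, c(3L, 2L, 1L))
  valid <- outer(outer(valid_ax[[1L]], valid_ax[[2L]], "&"),
                 valid_ax[[3L]], "&")
  up[!valid] <- 0
  list(map = up, valid = valid,
       geometry = list(rf = geom$rf, jump = geom$jump, offset = geom$offset,
                       crop_origin = crop$origin))
}

#' Export gate and evidence maps for one volume
#'
#' Center-crops (if requested), runs both branches, and writes
#' full-resolution gate and evidence overlays as NIfTI next to a JSON
#' prediction record `{z, y_hat, sum_g}`. Evidence is reported
#' pre-normalization (`g * x~`; in gap mode `x~ / (whd)` so that its sum
#' is z); positive evidence supports class 1, negative class 0. A validity
#' mask channel is written alongside each overlay.
#'
#' @param model a trained `bagnet_model`.
#' @param v a [volume] (raw; normalized internally).
#' @param out_prefix path prefix for outputs
#'   (`<prefix>_gate.nii.gz`, `<prefix>_evidence.nii.gz`,
#'   `<prefix>_valid.nii.gz`, `<prefix>_prediction.json`).
#' @param crop_size optional center-crop extent (defaults to the full
#'   volume).
#' @return list with `gate_map`, `evidence_map`, `z`, `y_hat`, `sum_g`
#'   and the written `paths`, invisibly printable.
#' @export
export_evidence <- function(model, v, out_prefix, crop_size = NULL) {
  full_extent <- dim(v$data)
  v <- normalize_volume(v)
  crp <- if (is.null(crop_size)) crop_spec(c(0L, 0L, 0L), full_extent) else
    sample_crop(full_extent, crop_size, mode = "center")
  vc <- crop_volume(v, crp)
  layers <- model$spec$layer_geoms
  ind <- if (model$gating_mode == "position_gate") {
    grid <- make_coordinate_grid(full_extent)
    extract_position_indicator(crop_grid(grid, crp), layers)
  } else NULL
  fw <- model_forward(model, vc, indicator = ind)
  geom <- compose_geometry(layers)
  n <- length(fw$r)
  if (is.null(fw$g)) {
    evidence <- array(fw$r / n, fw$dims)
    gate <- NULL
    sum_g <- NA_real_
  } else {
    evidence <- array(fw$g * fw$r, fw$dims)
    gate <- array(fw$g, fw$dims)
    sum_g <- sum(fw$g)
  }
  ev_up <- upsample_map(evidence, geom, crp, full_extent)
  paths <- c(evidence = paste0(out_prefix, "_evidence.nii.gz"),
             valid = paste0(out_prefix, "_valid.nii.gz"),
             prediction = paste0(out_prefix, "_prediction.json"))
  write_volume(volume(ev_up$map, affine = v$affine), paths[["evidence"]])
  write_volume(volume(ev_up$valid * 1, affine = v$affine), paths[["valid"]])
  if (!is.null(gate)) {
    g_up <- upsample_map(gate, geom, crp, full_extent)
    paths[["gate"]] <- paste0(out_prefix, "_gate.nii.gz")
    write_volume(volume(g_up$map, affine = v$affine), paths[["gate"]])
  }
  rec <- list(z = fw$z, y_hat = fw$y_hat, sum_g = sum_g,
              gating_mode = model$gating_mode,
              patch_size = model$spec$patch_size,
              geometry = ev_up$geometry)
  jsonlite::write_json(rec, paths[["prediction"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(gate_map = gate, evidence_map = evidence,
                 z = fw$z, y_hat = fw$y_hat, sum_g = sum_g, paths = paths))
}
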