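# The two-branch network.
#
# Patch-level prediction branch: a receptive-field-limited encoder (stem
# conv k5 s2 -> instance norm -> ReLU -> max-pool k3 s2 -> four residual
# blocks at 32/64/128/256 channels, stride 1, valid padding) followed by a
# point-wise linear classifier producing one raw response per patch
# position. Position-based gating branch: a point-wise position embedding
# (3 -> 128 -> 256, ReLU after each) and gate network (256 -> 128 -> 16,
# ReLU after the first only), channel-mean then sigmoid, yielding a
# discriminative probability map in [0, 1].

SUPPORTED_PATCH_SIZES <- c(9L, 17L, 25L, 41L, 57L)
# number of 3^3 convolutions (vs 1^3) across the four residual blocks;
# allocated front-loaded, two per block
N_K3_CONVS <- c(`9` = 0L, `17` = 1L, `25` = 2L, `41` = 4L, `57` = 6L)

#' Declare an encoder architecture
#'
#' The encoder family is indexed by the receptive field ("patch size") of
#' its output units: 9 is the minimum, set by the stem convolution
#' (kernel 5, stride 2) plus max pooling (kernel 3, stride 2); larger
#' patch sizes replace 1x1x1 convolutions inside the residual blocks by
#' 3x3x3 ones, each adding 8 voxels of receptive field. The total jump
#' (patch-center spacing) is 4 for every variant.
#'
#' @param patch_size one of 9, 17, 25, 41, 57.
#' @return object of class `encoder_spec` with fields `patch_size`,
#'   `stem_channels`, `block_channels`, `block_kernels` and `layer_geoms`.
#' @export
encoder_spec <- function(patch_size) {
  patch_size <- as.integer(patch_size)
  if (!patch_size %in% SUPPORTED_PATCH_SIZES)
    stop("unsupported patch_size ", patch_size, "; choose one of ",
         paste(SUPPORTED_PATCH_SIZES, collapse = ", "))
  n3 <- N_K3_CONVS[[as.character(patch_size)]]
  kernels <- rep(1L, 8L)
  if (n3 > 0L) kernels[seq_len(n3)] <- 3L
  block_kernels <- split(kernels, rep(1:4, each = 2L))
  layer_geoms <- c(list(layer_geom(5L, 2L), layer_geom(3L, 2L)),
                   lapply(kernels, function(k) layer_geom(k, 1L)))
  structure(list(patch_size = patch_size,
                 stem_channels = 32L,
                 block_channels = c(32L, 64L, 128L, 256L),
                 block_kernels = block_kernels,
                 layer_geoms = layer_geoms),
            class = "encoder_spec")
}

#' Encoder variants shipped with the package
#'
#' @return integer vector of supported patch sizes.
#' @export
patch_size_family <- function() SUPPORTED_PATCH_SIZES

# ---- construction ----------------------------------------------------------

res_block <- function(cin, cout, kernels) {
  list(conv1 = nn_conv3d(cin, cout, kernels[1L]),
       in1 = nn_instnorm(cout),
       conv2 = nn_conv3d(cout, cout, kernels[2L]),
       in2 = nn_instnorm(cout),
       proj = if (cin != cout) nn_pwconv(cin, cout) else NULL)
}

#' Build a model
#'
#' Instantiates encoder, classifier and (depending on the gating mode)
#' the position-embedding and gate networks, He-initialized reproducibly
#' from `seed`. Gating modes: `"gap"` (global average pooling, no gate
#' parameters), `"position_gate"` (gate driven by the position indicator),
#' `"feature_gate"` (same gate topology fed the encoder features), and
#' `"fixed_gate"` (a user-supplied constant gate map, no gate parameters).
#'
#' @param spec an [encoder_spec] (or a patch size).
#' @param gating_mode one of "gap", "position_gate", "feature_gate",
#'   "fixed_gate".
#' @param seed integer seed for He initialization.
#' @param fixed_gate for `fixed_gate` mode: a w x h x d array (or vector)
#'   of gate values in \[0, 1\] matching the response-map extent.
#' @return object of class `bagnet_model`.
#' @export
build_model <- function(spec, gating_mode = c("position_gate", "gap",
                                              "feature_gate", "fixed_gate"),
                        seed = 1L, fixed_gate = NULL) {
  if (!inherits(spec, "encoder_spec")) spec <- encoder_spec(spec)
  gating_mode <- match.arg(gating_mode)
  if (gating_mode == "fixed_gate" && is.null(fixed_gate))
    stop("fixed_gate mode requires a fixed_gate map")
  set.seed(seed)
  ch <- spec$block_channels
  stem_conv <- nn_conv3d(1L, spec$stem_channels, 5L, 2L)
  stem_conv$is_input_layer <- TRUE   # skip input-gradient computation
  encoder <- list(
    stem = list(conv = stem_conv,
                norm = nn_instnorm(spec$stem_channels)),
    pool = nn_maxpool(3L, 2L),
    blocks = list(
      res_block(spec$stem_channels, ch[1L], spec$block_kernels[[1L]]),
      res_block(ch[1L], ch[2L], spec$block_kernels[[2L]]),
      res_block(ch[2L], ch[3L], spec$block_kernels[[3L]]),
      res_block(ch[3L], ch[4L], spec$block_kernels[[4L]])))
  classifier <- nn_pwconv(ch[4L], 1L)
  embed <- NULL; gatenet <- NULL
  if (gating_mode %in% c("position_gate", "feature_gate")) {
    gate_cin <- if (gating_mode == "position_gate") 3L else ch[4L]
    embed <- list(nn_pwconv(gate_cin, 128L), nn_pwconv(128L, 256L))
    gatenet <- list(nn_pwconv(256L, 128L), nn_pwconv(128L, 16L))
  }
  structure(list(spec = spec, gating_mode = gating_mode, seed = seed,
                 encoder = encoder, classifier = classifier,
                 embed = embed, gatenet = gatenet,
                 fixed_gate = fixed_gate),
            class = "bagnet_model")
}

#' @export
print.bagnet_model <- function(x, ...) {
  cat(sprintf("<bagnet_model> patch size %d, gating mode %s\n",
              x$spec$patch_size, x$gating_mode))
  invisible(x)
}

# ---- parameter bookkeeping -------------------------------------------------

# Every trainable parameter belongs to exactly one group:
# phi (encoder), psi (classifier), pi (position embedding), rho (gate net).
model_layers <- function(model) {
  out <- list()
  add <- function(ly, group) {
    if (is.null(ly)) return()
    out[[length(out) + 1L]] <<- list(layer = ly, group = group)
  }
  add(model$encoder$stem$conv, "phi")
  add(model$encoder$stem$norm, "phi")
  add(model$encoder$pool, "phi")
  for (b in model$encoder$blocks) {
    add(b$conv1, "phi"); add(b$in1, "phi")
    add(b$conv2, "phi"); add(b$in2, "phi")
    add(b$proj, "phi")
  }
  add(model$classifier, "psi")
  if (!is.null(model$embed)) for (ly in model$embed) add(ly, "pi")
  if (!is.null(model$gatenet)) for (ly in model$gatenet) add(ly, "rho")
  out
}

#' Collect model parameters
#'
#' @param model a `bagnet_model`.
#' @param groups optional subset of c("phi","psi","pi","rho").
#' @return named list of parameter arrays; names are
#'   `<group>.<layer index>.<slot>`.
#' @export
model_parameters <- function(model, groups = c("phi", "psi", "pi", "rho")) {
  out <- list()
  lys <- model_layers(model)
  for (i in seq_along(lys)) {
    rec <- lys[[i]]
    if (!rec$group %in% groups) next
    for (pn in layer_param_names(rec$layer))
      out[[sprintf("%s.%02d.%s", rec$group, i, pn)]] <- get(pn, envir = rec$layer)
  }
  out
}

#' Gradients matching [model_parameters()]
#' @inheritParams model_parameters
#' @return named list of gradient arrays (zeros where never accumulated).
#' @export
model_gradients <- function(model, groups = c("phi", "psi", "pi", "rho")) {
  out <- list()
  lys <- model_layers(model)
  for (i in seq_along(lys)) {
    rec <- lys[[i]]
    if (!rec$group %in% groups) next
    for (pn in layer_param_names(rec$layer)) {
      g <- get(layer_grad_name(pn), envir = rec$layer)
      if (is.null(g)) g <- get(pn, envir = rec$layer) * 0
      out[[sprintf("%s.%02d.%s", rec$group, i, pn)]] <- g
    }
  }
  out
}

set_model_parameters <- function(model, params) {
  lys <- model_layers(model)
  for (i in seq_along(lys)) {
    rec <- lys[[i]]
    for (pn in layer_param_names(rec$layer)) {
      key <- sprintf("%s.%02d.%s", rec$group, i, pn)
      if (!key %in% names(params)) stop("missing parameter ", key)
      cur <- get(pn, envir = rec$layer)
      val <- params[[key]]
      if (length(val) != length(cur)) stop("shape mismatch for ", key)
      cur[] <- val
      assign(pn, cur, envir = rec$layer)
    }
  }
  invisible(model)
}

zero_gradients <- function(model) {
  for (rec in model_layers(model)) zero_layer_grads(rec$layer)
  invisible(model)
}

# ---- forward / backward ----------------------------------------------------

encoder_forward <- function(model, x) {
  enc <- model$encoder
  h <- layer_forward(enc$stem$conv, x)
  h <- layer_forward(enc$stem$norm, h)
  h <- relu_cached(enc$stem, h)
  h <- layer_forward(enc$pool, h)
  for (b in enc$blocks) h <- res_block_forward(b, h)
  h
}

# ReLU masks and block extents are cached on the layer environments so the
# hand-written backward passes can replay them.
relu_cached <- function(holder, x) {
  mask <- unclass(x) > 0
  holder$conv$relu_mask <- mask
  fmap(unclass(x) * mask, attr(x, "dims"))
}

res_block_forward <- function(b, x) {
  in_dims <- attr(x, "dims")
  h <- layer_forward(b$conv1, x)
  h <- layer_forward(b$in1, h)
  mid_dims <- attr(h, "dims")
  m1 <- unclass(h) > 0
  h <- fmap(unclass(h) * m1, mid_dims)
  h <- layer_forward(b$conv2, h)
  h <- layer_forward(b$in2, h)
  out_dims <- attr(h, "dims")
  # shortcut: center-crop input to the valid-padding output extent,
  # projecting channels point-wise when they change
  sc <- fmap_center_crop(x, out_dims)
  if (!is.null(b$proj)) sc <- layer_forward(b$proj, sc)
  s <- unclass(h) + unclass(sc)
  m2 <- s > 0
  b$conv1$blk_cache <- list(m1 = m1, m2 = m2, in_dims = in_dims,
                            mid_dims = mid_dims, out_dims = out_dims)
  fmap(s * m2, out_dims)
}

res_block_backward <- function(b, g) {
  ca <- b$conv1$blk_cache
  g <- fmap(unclass(g) * ca$m2, ca$out_dims)
  # shortcut path
  gs <- g
  if (!is.null(b$proj)) gs <- layer_backward(b$proj, gs)
  gx_short <- fmap_uncrop(gs, ca$in_dims)
  # main path
  gm <- layer_backward(b$in2, g)
  gm <- layer_backward(b$conv2, gm)
  gm <- fmap(unclass(gm) * ca$m1, ca$mid_dims)
  gm <- layer_backward(b$in1, gm)
  gm <- layer_backward(b$conv1, gm)
  fmap(unclass(gx_short) + unclass(gm), ca$in_dims)
}

encoder_backward <- function(model, g) {
  enc <- model$encoder
  for (b in rev(enc$blocks)) g <- res_block_backward(b, g)
  g <- layer_backward(enc$pool, g)
  g <- unclass(g) * enc$stem$conv$relu_mask
  g <- layer_backward(enc$stem$norm, g)
  g <- layer_backward(enc$stem$conv, g)
  g
}

gate_branch_forward <- function(model, inp) {
  h <- layer_forward(model$embed[[1L]], inp)
  m1 <- h > 0; model$embed[[1L]]$relu_mask <- m1
  h <- fmap(h * m1, attr(h, "dims"))
  h <- layer_forward(model$embed[[2L]], h)
  m2 <- h > 0; model$embed[[2L]]$relu_mask <- m2
  h <- fmap(h * m2, attr(h, "dims"))
  h <- layer_forward(model$gatenet[[1L]], h)
  m3 <- h > 0; model$gatenet[[1L]]$relu_mask <- m3
  h <- fmap(h * m3, attr(h, "dims"))
  h <- layer_forward(model$gatenet[[2L]], h)
  pre <- rowMeans(h)                        # channel mean over the 16 maps
  g <- 1 / (1 + exp(-pre))
  model$gatenet[[2L]]$gate_cache <- list(g = g, nc = ncol(h),
                                         dims = attr(h, "dims"))
  fmap(matrix(g, ncol = 1L), attr(h, "dims"))
}

gate_branch_backward <- function(model, dgate) {
  ca <- model$gatenet[[2L]]$gate_cache
  dpre <- dgate * ca$g * (1 - ca$g)         # through sigmoid
  gh <- matrix(rep(dpre / ca$nc, ca$nc), ncol = ca$nc)  # through channel mean
  gh <- fmap(gh, ca$dims)
  gh <- layer_backward(model$gatenet[[2L]], gh)
  gh <- gh * model$gatenet[[1L]]$relu_mask
  attr(gh, "dims") <- ca$dims
  gh <- layer_backward(model$gatenet[[1L]], gh)
  gh <- gh * model$embed[[2L]]$relu_mask
  attr(gh, "dims") <- ca$dims
  gh <- layer_backward(model$embed[[2L]], gh)
  gh <- gh * model$embed[[1L]]$relu_mask
  attr(gh, "dims") <- ca$dims
  gh <- layer_backward(model$embed[[1L]], gh)
  gh
}

#' Patch-level responses for a volume
#'
#' Runs the encoder and point-wise classifier over a normalized (and
#' typically cropped) volume, returning the raw pre-sigmoid patch response
#' at every patch-grid position. The extraction function is shared across
#' positions (translation-shared weights).
#'
#' @param model a `bagnet_model`.
#' @param v a [volume] (normalized).
#' @return object of class `response_map`: a w x h x d array with the
#'   encoder features attached as attribute `features`.
#' @export
patch_responses <- function(model, v) {
  fw <- model_forward(model, v)
  fw$response_map
}

#' Position-gate forward pass
#'
#' Computes the discriminative probability map from a position indicator
#' alone; output depends only on the coordinates, never on image content.
#'
#' @param model a `bagnet_model` in `position_gate` mode.
#' @param indicator a `position_indicator` (from
#'   [extract_position_indicator()]).
#' @return object of class `gate_map`: w x h x d array of values in
#'   \[0, 1\].
#' @export
gate_forward <- function(model, indicator) {
  if (model$gating_mode != "position_gate")
    stop("gate_forward requires position_gate mode")
  inp <- indicator_matrix(indicator)
  g <- gate_branch_forward(model, fmap(inp, attr(inp, "dims")))
  structure(array(g[, 1L], attr(g, "dims")), class = c("gate_map", "array"))
}

#' Feature-gate forward pass
#'
#' Same gate topology as [gate_forward()] but fed the encoder features,
#' so the output is image-dependent (the feature-based ablation).
#'
#' @param model a `bagnet_model` in `feature_gate` mode.
#' @param features a `[n, f]` feature matrix with a `dims` attribute, as
#'   attached to a `response_map`.
#' @return a `gate_map`.
#' @export
feature_gate_forward <- function(model, features) {
  if (model$gating_mode != "feature_gate")
    stop("feature_gate_forward requires feature_gate mode")
  g <- gate_branch_forward(model, features)
  structure(array(g[, 1L], attr(g, "dims")), class = c("gate_map", "array"))
}

# Full forward pass: returns response map, gate map (mode-dependent),
# image-level response z and posterior y_hat, with all caches retained for
# model_backward().
model_forward <- function(model, v, indicator = NULL) {
  d <- dim(v$data)
  x <- fmap(matrix(as.numeric(v$data), ncol = 1L), d)
  feat <- encoder_forward(model, x)
  resp <- layer_forward(model$classifier, feat)
  d_out <- attr(resp, "dims")
  r <- resp[, 1L]
  g <- switch(model$gating_mode,
    gap = NULL,
    position_gate = {
      if (is.null(indicator)) stop("position_gate mode needs an indicator")
      ind <- indicator_matrix(indicator)
      if (!all(attr(ind, "dims") == d_out))
        stop("indicator extent does not match response-map extent")
      gate_branch_forward(model, ind)[, 1L]
    },
    feature_gate = gate_branch_forward(model, feat)[, 1L],
    fixed_gate = {
      fg <- as.numeric(model$fixed_gate)
      if (length(fg) == 1L) fg <- rep(fg, length(r))
      if (length(fg) != length(r))
        stop("fixed gate extent does not match response-map extent")
      fg
    })
  if (is.null(g)) {
    z <- mean(r)
  } else {
    sg <- sum(g)
    if (sg < 1e-8) stop("degenerate gate: gate mass below tolerance")
    z <- sum(g * r) / sg
  }
  response_map <- structure(array(r, d_out), class = c("response_map", "array"),
                            features = feat)
  gate_map <- if (is.null(g)) NULL else
    structure(array(g, d_out), class = c("gate_map", "array"))
  list(response_map = response_map, gate_map = gate_map,
       z = z, y_hat = 1 / (1 + exp(-z)),
       r = r, g = g, dims = d_out, feat = feat, input_dims = d)
}

# Backward pass from dL/dz plus an optional extra gradient on the gate map
# (the entropy regularizer's). Accumulates parameter gradients in place.
model_backward <- function(model, fw, dz, dgate_extra = NULL) {
  n <- length(fw$r)
  d_out <- fw$dims
  if (is.null(fw$g)) {
    dr <- rep(dz / n, n)
    dg <- NULL
  } else {
    sg <- sum(fw$g)
    dr <- dz * fw$g / sg
    dg <- dz * (fw$r - fw$z) / sg
    if (!is.null(dgate_extra)) dg <- dg + dgate_extra
  }
  dfeat_total <- NULL
  # gate branch (position/feature modes only; fixed gate has no parameters)
  if (model$gating_mode %in% c("position_gate", "feature_gate") &&
      !is.null(dg)) {
    gback <- gate_branch_backward(model, dg)
    if (model$gating_mode == "feature_gate") dfeat_total <- gback
  }
  # classifier + encoder
  dresp <- fmap(matrix(dr, ncol = 1L), d_out)
  dfeat <- layer_backward(model$classifier, dresp)
  if (!is.null(dfeat_total)) dfeat <- dfeat + dfeat_total
  dfeat <- fmap(unclass(dfeat), d_out)
  encoder_backward(model, dfeat)
  invisible(model)
}

# ---- checkpoints -----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a flat named-parameter archive (`<path>`) and a JSON sidecar
#' (`<path>.json`) recording the encoder spec, gating mode and build seed.
#'
#' @param model a `bagnet_model`.
#' @param path output path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model_parameters(model),
               fixed_gate = model$fixed_gate), path)
  meta <- list(patch_size = model$spec$patch_size,
               gating_mode = model$gating_mode,
               seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return a `bagnet_model` with the stored parameters.
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  blob <- readRDS(path)
  model <- build_model(encoder_spec(meta$patch_size), meta$gating_mode,
                       seed = meta$seed, fixed_gate = blob$fixed_gate)
  set_model_parameters(model, blob$params)
  model
}

#' Initialize a model from a source checkpoint (transfer learning)
#'
#' Copies all parameters (encoder, classifier, embedding, gate) from a
#' trained source model into a fresh model for a new task; optimizer state
#' is not carried over. Source and target must share the encoder spec and
#' gating mode.
#'
#' @param source a trained `bagnet_model`.
#' @return a new `bagnet_model` with copied parameters.
#' @export
transfer_init <- function(source) {
  target <- build_model(source$spec, source$gating_mode, seed = source$seed,
                        fixed_gate = source$fixed_gate)
  set_model_parameters(target, model_parameters(source))
  target
}

#' Freeze normalization statistics on a reference volume
#'
#' Runs one forward pass through the encoder on `v`, captures every
#' normalization layer's per-channel mean and scale, and switches those
#' layers to use the captured statistics for subsequent forward passes.
#' With frozen statistics each normalization layer is a fixed per-channel
#' affine map, so the patch-level branch becomes exactly
#' translation-equivariant; this is the mechanism behind the
#' equivariance probe (per-image statistics, the default, drift slightly
#' when image content shifts in or out of the crop). Evaluation-only: do
#' not train while frozen.
#'
#' @param model a `bagnet_model`.
#' @param v reference [volume] whose statistics to capture.
#' @return the model, invisibly (layers are modified in place).
#' @export
freeze_norm_stats <- function(model, v) {
  norms <- Filter(function(r) r$layer$type == "instnorm",
                  model_layers(model))
  for (r in norms) r$layer$capture_stats <- TRUE
  x <- fmap(matrix(as.numeric(v$data), ncol = 1L), dim(v$data))
  encoder_forward(model, x)
  for (r in norms) {
    r$layer$capture_stats <- FALSE
    r$layer$use_frozen <- TRUE
  }
  invisible(model)
}

#' Restore per-image normalization statistics
#'
#' Undoes [freeze_norm_stats()].
#'
#' @param model a `bagnet_model`.
#' @return the model, invisibly.
#' @export
unfreeze_norm_stats <- function(model) {
  for (r in model_layers(model))
    if (r$layer$type == "instnorm") r$layer$use_frozen <- FALSE
  invisible(model)
}

check_compatible <- function(a, b) {
  if (a$spec$patch_size != b$spec$patch_size ||
      a$gating_mode != b$gating_mode)
    stop("incompatible models: encoder spec or gating mode differ")
  invisible(TRUE)
}
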