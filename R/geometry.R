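#' Layer geometry descriptor
#'
#' Describes the spatial arithmetic of one convolution or pooling layer:
#' kernel extent, stride, and symmetric zero padding (all isotropic).
#' Only odd kernels are admitted so that every output unit has a
#' well-defined center voxel.
#'
#' @param kernel integer kernel extent (odd, >= 1).
#' @param stride integer stride (>= 1).
#' @param padding integer symmetric padding per side (>= 0).
#' @return an object of class `layer_geom`.
#' @export
layer_geom <- function(kernel, stride = 1L, padding = 0L) {
  kernel <- as.integer(kernel); stride <- as.integer(stride)
  padding <- as.integer(padding)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be a positive odd integer")
  if (stride < 1L) stop("stride must be >= 1")
  if (padding < 0L) stop("padding must be >= 0")
  structure(list(kernel = kernel, stride = stride, padding = padding),
            class = "layer_geom")
}

#' Compose receptive-field geometry over a layer stack
#'
#' Folds the standard receptive-field recurrence over an ordered list of
#' layers. Starting from `rf = 1`, `jump = 1`, `offset = 0`, each layer
#' with kernel k, stride s, padding p updates
#' `rf' = rf + (k - 1) * jump`, `offset' = offset + ((k - 1)/2 - p) * jump`,
#' `jump' = jump * s`. `rf` is the input extent seen by one output unit,
#' `jump` the input-index spacing between adjacent outputs, and `offset`
#' the input index of the first output's patch center (0-based).
#'
#' @param layers list of [layer_geom] objects, in forward order.
#' @return list with integer-valued `rf`, `jump` and numeric `offset`.
#' @export
compose_geometry <- function(layers) {
  check_layers(layers)
  rf <- 1; jump <- 1; offset <- 0
  for (lg in layers) {
    rf <- rf + (lg$kernel - 1L) * jump
    offset <- offset + ((lg$kernel - 1L) / 2 - lg$padding) * jump
    jump <- jump * lg$stride
  }
  list(rf = rf, jump = jump, offset = offset)
}

check_layers <- function(layers) {
  if (length(layers) == 0L) stop("layer list must be non-empty")
  ok <- vapply(layers, inherits, logical(1), what = "layer_geom")
  if (!all(ok)) stop("all elements must be layer_geom objects")
  invisible(layers)
}

#' Output extent of a layer stack
#'
#' Per axis, folds `floor((n + 2 p - k)/s) + 1` over the layers.
#'
#' @param input_extent integer 3-vector (or scalar, recycled).
#' @param layers list of [layer_geom].
#' @return integer 3-vector of output extents.
#' @export
output_extent <- function(input_extent, layers) {
  check_layers(layers)
  n <- as.integer(rep_len(input_extent, 3L))
  if (any(n < 1L)) stop("input extent must be >= 1")
  for (lg in layers) {
    n <- (n + 2L * lg$padding - lg$kernel) %/% lg$stride + 1L
    if (any(n < 1L))
      stop("input too small: an intermediate extent fell below 1")
  }
  n
}

#' Full-resolution Cartesian coordinate grid
#'
#' Builds the three-channel coordinate space over the full template grid:
#' channel c at 0-based voxel index i along axis c holds `2 i/(n_c - 1) - 1`,
#' so coordinates span `[-1, +1]` across the template. Cropping a grid
#' slices it without renormalizing, which is what makes the gate branch
#' translation-dependent.
#'
#' @param full_extent integer 3-vector, each >= 2.
#' @return object of class `coordinate_grid`: a W x H x D x 3 array.
#' @export
make_coordinate_grid <- function(full_extent) {
  n <- as.integer(rep_len(full_extent, 3L))
  if (any(n < 2L)) stop("degenerate extent: need >= 2 voxels per axis")
  ax <- lapply(n, function(m) 2 * (seq_len(m) - 1) / (m - 1) - 1)
  co <- array(0, c(n, 3L))
  co[, , , 1L] <- ax[[1L]]
  co[, , , 2L] <- rep(ax[[2L]], each = n[1L])
  co[, , , 3L] <- rep(ax[[3L]], each = n[1L] * n[2L])
  structure(co, class = c("coordinate_grid", "array"))
}

#' Crop a coordinate grid
#'
#' Applies the same crop as [crop_volume()] to the coordinate channels,
#' slicing without renormalizing.
#'
#' @param grid a `coordinate_grid`.
#' @param spec a [crop_spec].
#' @return cropped `coordinate_grid`.
#' @export
crop_grid <- function(grid, spec) {
  d <- dim(grid)[1:3]
  validate_crop(spec, d)
  o <- spec$origin; s <- spec$size
  out <- grid[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]),
              o[3] + seq_len(s[3]), , drop = FALSE]
  structure(out, class = c("coordinate_grid", "array"))
}

#' Extract the patch-center position indicator
#'
#' Subsamples a (possibly cropped) coordinate grid at the patch centers
#' implied by a layer stack: output index i (0-based) maps to input
#' position `offset + i * jump` per axis, with linear interpolation when
#' the offset is fractional. The result has the same spatial extent as
#' the encoder output on an input of the grid's extent.
#'
#' @param grid a `coordinate_grid` (full or cropped).
#' @param layers list of [layer_geom] describing the encoder.
#' @return object of class `position_indicator`: a w x h x d x 3 array.
#' @export
extract_position_indicator <- function(grid, layers) {
  geom <- compose_geometry(layers)
  d_out <- output_extent(dim(grid)[1:3], layers)
  sample_grid_at(grid, geom$offset, geom$jump, d_out)
}

# subsample a coordinate grid at positions offset + i*jump (0-based) per
# axis, trilinearly interpolated when fractional
sample_grid_at <- function(grid, offset, jump, d_out) {
  d_in <- dim(grid)[1:3]
  # per-axis sampling weights: linear interpolation at offset + i*jump
  pick <- lapply(1:3, function(a) {
    pos <- offset + jump * (seq_len(d_out[a]) - 1)  # 0-based
    lo <- floor(pos); frac <- pos - lo
    list(lo = as.integer(lo) + 1L,
         hi = pmin(as.integer(lo) + 2L, d_in[a]),
         w = frac)
  })
  out <- array(0, c(d_out, 3L))
  g_lo <- grid[pick[[1]]$lo, pick[[2]]$lo, pick[[3]]$lo, , drop = FALSE]
  if (all(vapply(pick, function(p) all(p$w == 0), logical(1)))) {
    out[] <- g_lo
  } else {
    # trilinear interpolation over the 8 corner combinations
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ix <- if (cx) pick[[1]]$hi else pick[[1]]$lo
      iy <- if (cy) pick[[2]]$hi else pick[[2]]$lo
      iz <- if (cz) pick[[3]]$hi else pick[[3]]$lo
      wx <- if (cx) pick[[1]]$w else 1 - pick[[1]]$w
      wy <- if (cy) pick[[2]]$w else 1 - pick[[2]]$w
      wz <- if (cz) pick[[3]]$w else 1 - pick[[3]]$w
      w3 <- outer(outer(wx, wy), wz)  # w x h x d
      sub <- grid[ix, iy, iz, , drop = FALSE]
      for (ch in 1:3) out[, , , ch] <- out[, , , ch] + w3 * sub[, , , ch]
    }
  }
  structure(out, class = c("position_indicator", "array"))
}

# flatten an indicator to the [n_positions, 3] matrix the gate branch eats
indicator_matrix <- function(ind) {
  d <- dim(ind)
  m <- matrix(as.numeric(ind), prod(d[1:3]), 3L)
  attr(m, "dims") <- d[1:3]
  m
}

#' Gradient-based receptive-field oracle
#'
#' Measures the receptive field and jump of a layer stack empirically,
#' independently of [compose_geometry()]: the stack is instantiated as
#' single-channel convolutions with all-ones kernels (pooling layers are
#' receptive-field-equivalent to such a convolution), a one-hot gradient
#' is backpropagated from one output position, and the nonzero support of
#' the input gradient is measured. The jump is the displacement of that
#' support between two adjacent output positions.
#'
#' @param layers list of [layer_geom].
#' @param probe_extent input extent to probe with (3-vector or scalar);
#'   must yield an output extent >= 2 per axis.
#' @return list with integer 3-vectors `rf` and `jump`.
#' @export
rf_oracle <- function(layers, probe_extent) {
  check_layers(layers)
  n_in <- as.integer(rep_len(probe_extent, 3L))
  if (any(vapply(layers, function(l) l$padding, integer(1)) != 0L))
    stop("oracle assumes zero padding")
  n_out <- output_extent(n_in, layers)
  if (any(n_out < 2L)) stop("probe extent too small for jump measurement")
  convs <- lapply(layers, function(lg) {
    cv <- nn_conv3d(1L, 1L, lg$kernel, lg$stride, init = "zero")
    cv$W[] <- 1; cv$b[] <- 0
    cv
  })
  x <- fmap(matrix(0, prod(n_in), 1L), n_in)
  support <- function(hot) {
    h <- x
    for (cv in convs) h <- conv3d_forward(cv, h)
    d_out <- attr(h, "dims")
    g <- matrix(0, nrow(h), 1L)
    g[flat_index(hot, d_out)] <- 1
    for (cv in rev(convs)) g <- conv3d_backward(cv, g)
    idx <- which(abs(g[, 1L]) > 0)
    arr_index(idx, n_in)
  }
  s1 <- support(c(1L, 1L, 1L))
  s2 <- support(c(2L, 2L, 2L))
  rf <- apply(s1, 2L, function(v) max(v) - min(v) + 1L)
  jump <- apply(s2, 2L, min) - apply(s1, 2L, min)
  list(rf = as.integer(rf), jump = as.integer(jump))
}

# 1-based (i,j,k) -> flat column-major spatial index
flat_index <- function(ijk, dims) {
  (ijk[3L] - 1L) * dims[1L] * dims[2L] + (ijk[2L] - 1L) * dims[1L] + ijk[1L]
}

# flat indices -> matrix of 1-based (i,j,k)
arr_index <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1L]
  j <- (idx0 %/% dims[1L]) %% dims[2L]
  k <- idx0 %/% (dims[1L] * dims[2L])
  cbind(i, j, k) + 1L
}
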