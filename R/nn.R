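# Minimal 3D convolutional network machinery.
#
# Feature maps are stored flattened: a [n_positions, channels] matrix with a
# "dims" attribute holding the spatial extent c(w, h, d); positions run
# column-major (first axis fastest), matching R array layout. Valid (zero)
# padding throughout, so every output position corresponds to a complete
# patch of the input. Layers are environments carrying parameters, gradient
# accumulators and forward caches; backward passes return the gradient with
# respect to the layer input and accumulate parameter gradients in place.

fmap <- function(mat, dims) {
  attr(mat, "dims") <- as.integer(dims)
  mat
}

# column-wise (per-channel) arithmetic without sweep()'s aperm overhead
add_cols <- function(X, v) X + matrix(v, nrow(X), length(v), byrow = TRUE)
mul_cols <- function(X, v) X * matrix(v, nrow(X), length(v), byrow = TRUE)

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

he_init <- function(fan_in, n, rng = stats::rnorm) {
  rng(n) * sqrt(2 / fan_in)
}

# ---- im2col index cache ----------------------------------------------------

.conv_idx_cache <- new.env(parent = emptyenv())

# Index matrix [n_out_positions, k^3] of flat input spatial indices for a
# valid-padding convolution with isotropic kernel k and stride s.
conv_indices <- function(dims_in, k, stride) {
  key <- paste(c(dims_in, k, stride), collapse = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  d_out <- (dims_in - k) %/% stride + 1L
  if (any(d_out < 1L)) stop("input too small for kernel")
  ax <- lapply(1:3, function(a) (seq_len(d_out[a]) - 1L) * stride)  # 0-based corners
  # corner flat index (0-based) of each output position
  corner <- outer(outer(ax[[1L]],
                        ax[[2L]] * dims_in[1L], "+"),
                  ax[[3L]] * dims_in[1L] * dims_in[2L], "+")
  corner <- as.integer(corner)                       # length n_out
  off <- lapply(0:(k - 1L), identity)
  tap <- integer(k^3)
  t <- 1L
  for (dz in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    tap[t] <- dx + dy * dims_in[1L] + dz * dims_in[1L] * dims_in[2L]
    t <- t + 1L
  }
  idx <- outer(corner, tap, "+") + 1L                # 1-based
  res <- list(idx = idx, d_out = d_out)
  .conv_idx_cache[[key]] <- res
  res
}

# ---- conv3d ----------------------------------------------------------------

nn_conv3d <- function(cin, cout, k, stride = 1L, init = "he") {
  n_w <- k^3 * cin * cout
  W <- matrix(if (init == "he") he_init(k^3 * cin, n_w) else 0,
              k^3 * cin, cout)
  new_layer("conv3d", cin = cin, cout = cout, k = as.integer(k),
            stride = as.integer(stride),
            W = W, b = numeric(cout),
            dW = NULL, db = NULL)
}

conv3d_forward <- function(ly, x) {
  dims_in <- attr(x, "dims")
  ci <- conv_indices(dims_in, ly$k, ly$stride)
  res <- cpp_conv_fwd(unclass(x), ci$idx, ly$W, ly$b)
  ly$cache <- list(P = res$P, dims_in = dims_in, idx = ci$idx)
  fmap(res$out, ci$d_out)
}

conv3d_backward <- function(ly, g) {
  ca <- ly$cache
  need_dx <- !isTRUE(ly$is_input_layer)
  res <- cpp_conv_bwd(unclass(g), ca$P, ca$idx, ly$W,
                      prod(ca$dims_in), ly$cin, need_dx)
  ly$dW <- if (is.null(ly$dW)) res$dW else ly$dW + res$dW
  db <- as.numeric(res$db)
  ly$db <- if (is.null(ly$db)) db else ly$db + db
  if (!need_dx) return(NULL)
  fmap(res$dX, ca$dims_in)
}

# ---- point-wise (1x1x1) convolution ---------------------------------------

nn_pwconv <- function(cin, cout, init = "he") {
  W <- matrix(if (init == "he") he_init(cin, cin * cout) else 0, cin, cout)
  new_layer("pwconv", cin = cin, cout = cout, W = W, b = numeric(cout),
            dW = NULL, db = NULL)
}

pwconv_forward <- function(ly, x) {
  out <- add_cols(unclass(x) %*% ly$W, ly$b)
  ly$cache <- list(x = x, dims = attr(x, "dims"))
  fmap(out, attr(x, "dims"))
}

pwconv_backward <- function(ly, g) {
  dW <- crossprod(ly$cache$x, g)
  db <- colSums(g)
  ly$dW <- if (is.null(ly$dW)) dW else ly$dW + dW
  ly$db <- if (is.null(ly$db)) db else ly$db + db
  fmap(g %*% t(ly$W), ly$cache$dims)
}

# ---- max pooling -----------------------------------------------------------

nn_maxpool <- function(k, stride) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride))
}

maxpool_forward <- function(ly, x) {
  dims_in <- attr(x, "dims")
  ci <- conv_indices(dims_in, ly$k, ly$stride)
  res <- cpp_maxpool_fwd(unclass(x), ci$idx)
  ly$cache <- list(tap = res$tap, idx = ci$idx, dims_in = dims_in)
  fmap(res$out, ci$d_out)
}

maxpool_backward <- function(ly, g) {
  ca <- ly$cache
  dX <- cpp_maxpool_bwd(unclass(g), ca$tap, ca$idx, prod(ca$dims_in))
  fmap(dX, ca$dims_in)
}

# ---- instance normalization ------------------------------------------------

nn_instnorm <- function(nc, eps = 1e-5) {
  new_layer("instnorm", nc = nc, eps = eps,
            gamma = rep(1, nc), beta = numeric(nc),
            dgamma = NULL, dbeta = NULL)
}

instnorm_forward <- function(ly, x) {
  if (isTRUE(ly$use_frozen) && !is.null(ly$frozen_mu)) {
    # evaluation with frozen statistics: a fixed per-channel affine map,
    # exactly translation-equivariant (used by the equivariance probe)
    xhat <- mul_cols(add_cols(unclass(x), -ly$frozen_mu), ly$frozen_istd)
    out <- add_cols(mul_cols(xhat, ly$gamma), ly$beta)
    ly$cache <- NULL
    return(fmap(out, attr(x, "dims")))
  }
  res <- cpp_instnorm_fwd(unclass(x), ly$gamma, ly$beta, ly$eps)
  if (isTRUE(ly$capture_stats)) {
    n <- nrow(res$xhat)
    ly$frozen_istd <- as.numeric(res$istd)
    ly$frozen_mu <- colMeans(unclass(x))
  }
  ly$cache <- list(xhat = res$xhat, istd = as.numeric(res$istd),
                   dims = attr(x, "dims"))
  fmap(res$out, attr(x, "dims"))
}

instnorm_backward <- function(ly, g) {
  ca <- ly$cache
  res <- cpp_instnorm_bwd(unclass(g), ca$xhat, ca$istd, ly$gamma)
  dgamma <- as.numeric(res$dgamma); dbeta <- as.numeric(res$dbeta)
  ly$dgamma <- if (is.null(ly$dgamma)) dgamma else ly$dgamma + dgamma
  ly$dbeta <- if (is.null(ly$dbeta)) dbeta else ly$dbeta + dbeta
  fmap(res$dX, ca$dims)
}

# ---- ReLU ------------------------------------------------------------------

nn_relu <- function() new_layer("relu")

relu_forward <- function(ly, x) {
  ly$cache <- x > 0
  out <- x * ly$cache
  fmap(out, attr(x, "dims"))
}

relu_backward <- function(ly, g) {
  out <- g * ly$cache
  attr(out, "dims") <- attr(g, "dims")
  out
}

# ---- generic dispatch ------------------------------------------------------

layer_forward <- function(ly, x) {
  switch(ly$type,
         conv3d = conv3d_forward(ly, x),
         pwconv = pwconv_forward(ly, x),
         maxpool = maxpool_forward(ly, x),
         instnorm = instnorm_forward(ly, x),
         relu = relu_forward(ly, x),
         stop("unknown layer type: ", ly$type))
}

layer_backward <- function(ly, g) {
  switch(ly$type,
         conv3d = conv3d_backward(ly, g),
         pwconv = pwconv_backward(ly, g),
         maxpool = maxpool_backward(ly, g),
         instnorm = instnorm_backward(ly, g),
         relu = relu_backward(ly, g),
         stop("unknown layer type: ", ly$type))
}

# parameter slot names per layer type
layer_param_names <- function(ly) {
  switch(ly$type,
         conv3d = c("W", "b"),
         pwconv = c("W", "b"),
         instnorm = c("gamma", "beta"),
         character(0))
}

layer_grad_name <- function(pn) {
  c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")[[pn]]
}

zero_layer_grads <- function(ly) {
  for (pn in layer_param_names(ly)) assign(layer_grad_name(pn), NULL, envir = ly)
  invisible(ly)
}

# spatial center-crop of a feature map to a smaller extent (equal margins)
fmap_center_crop <- function(x, d_out) {
  d_in <- attr(x, "dims")
  if (all(d_in == d_out)) return(x)
  m <- (d_in - d_out) %/% 2L
  keep <- interior_indices(d_in, m, d_out)
  fmap(x[keep, , drop = FALSE], d_out)
}

# scatter a cropped-gradient back into the full extent (adjoint of crop)
fmap_uncrop <- function(g, d_in) {
  d_out <- attr(g, "dims")
  m <- (d_in - d_out) %/% 2L
  keep <- interior_indices(d_in, m, d_out)
  out <- matrix(0, prod(d_in), ncol(g))
  out[keep, ] <- g
  fmap(out, d_in)
}

interior_indices <- function(d_in, margin, d_out) {
  ii <- margin[1L] + seq_len(d_out[1L])
  jj <- margin[2L] + seq_len(d_out[2L])
  kk <- margin[3L] + seq_len(d_out[3L])
  idx <- outer(outer(ii - 1L, (jj - 1L) * d_in[1L], "+"),
               (kk - 1L) * d_in[1L] * d_in[2L], "+") + 1L
  as.integer(idx)
}
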