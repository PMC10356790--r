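# Image-level aggregation and the training objective.
#
# A response map holds raw patch-level responses x~; a gate map holds
# per-position probabilities g in [0, 1]. Global average pooling takes the
# plain mean of the responses; gated pooling weights them by the gate and
# normalizes by the total gate mass, so the amount of gated region does not
# affect the scale of the image-level response z. The classification loss
# is a class-balanced, label-smoothed binary cross-entropy, and the gate
# entropy regularizer keeps region exploration open early in training.

CLAMP_EPS <- 1e-12

#' Global average pooling of patch responses
#'
#' @param r a `response_map` (or numeric array/vector).
#' @return the scalar image-level response z, the mean of all responses.
#' @export
gap_pool <- function(r) {
  r <- as.numeric(r)
  if (length(r) == 0L) stop("degenerate input: empty response map")
  mean(r)
}

#' Normalized gate-weighted pooling
#'
#' Computes `z = sum(g * r) / sum(g)` together with the patch-level class
#' evidence map `e = g * r`. Invariant to positive rescaling of the gate;
#' reduces exactly to [gap_pool()] for a constant gate.
#'
#' @param r a `response_map`.
#' @param g a `gate_map` of matching extent.
#' @return list with scalar `z` and `evidence` (an `evidence_map` array).
#' @export
gated_pool <- function(r, g) {
  if (length(r) != length(g))
    stop("response and gate maps must have matching extents")
  gv <- as.numeric(g); rv <- as.numeric(r)
  if (any(gv < 0 | gv > 1)) stop("gate values must lie in [0, 1]")
  sg <- sum(gv)
  if (sg < 1e-8) stop("degenerate gate: total gate mass below tolerance")
  e <- gv * rv
  z <- sum(e) / sg
  ev <- if (!is.null(dim(g))) array(e, dim(g)) else e
  list(z = z, evidence = structure(ev, class = c("evidence_map",
                                                 class(ev))))
}

#' Class-balance weight from training labels
#'
#' beta is the fraction of negative-label (`y = 0`) samples in the
#' training split; it weights the positive-class term of the loss.
#'
#' @param labels vector of 0/1 labels.
#' @return scalar beta in (0, 1).
#' @export
compute_beta <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty label list")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute beta")
  sum(labels == 0L) / length(labels)
}

#' Loss configuration
#'
#' @param beta class-balance weight in (0, 1); typically from
#'   [compute_beta()].
#' @param lambda weight of the gate-entropy regularizer (default 0.01).
#' @param smooth_targets smoothed targets for y = 0 and y = 1.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(beta = 0.5, lambda = 0.01,
                        smooth_targets = c(0.1, 0.9)) {
  if (beta <= 0 || beta >= 1) stop("beta must lie in (0, 1)")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(beta = beta, lambda = lambda,
                 smooth_targets = smooth_targets),
            class = "loss_config")
}

smooth_label <- function(y, cfg) ifelse(y == 1, cfg$smooth_targets[2L],
                                        cfg$smooth_targets[1L])

#' Balanced label-smoothed classification loss
#'
#' For a posterior `y_hat` and hard label `y`, maps y to the smoothed
#' target `y_LS` (0.1 or 0.9) and returns
#' `-beta * y_LS * log(y_hat) - (1 - beta) * (1 - y_LS) * log(1 - y_hat)`.
#' Vectorized over samples; the batch loss is the arithmetic mean.
#' Probabilities are clamped at 1e-12 before the logarithms.
#'
#' @param y_hat posterior probabilities.
#' @param y hard labels in \{0, 1\}.
#' @param cfg a [loss_config].
#' @param reduce if TRUE (default) return the mean over samples.
#' @return scalar (or per-sample vector) loss.
#' @export
classification_loss <- function(y_hat, y, cfg, reduce = TRUE) {
  p <- pmin(pmax(y_hat, CLAMP_EPS), 1 - CLAMP_EPS)
  yls <- smooth_label(y, cfg)
  l <- -cfg$beta * yls * log(p) - (1 - cfg$beta) * (1 - yls) * log(1 - p)
  if (reduce) mean(l) else l
}

# dL_cls/dz for y_hat = sigmoid(z); exact where the clamp is inactive
classification_loss_dz <- function(y_hat, y, cfg) {
  yls <- smooth_label(y, cfg)
  -cfg$beta * yls * (1 - y_hat) + (1 - cfg$beta) * (1 - yls) * y_hat
}

#' Mean binary entropy of a gate map
#'
#' `H(G) = -mean(g log g + (1 - g) log(1 - g))` over positions, with
#' entries clamped into `[1e-12, 1 - 1e-12]`. The entropy loss used in the
#' objective is `L_ent = -H(G)`.
#'
#' @param g a `gate_map` (or numeric array).
#' @return scalar entropy in `[0, log 2]`.
#' @export
gate_entropy <- function(g) {
  gv <- pmin(pmax(as.numeric(g), CLAMP_EPS), 1 - CLAMP_EPS)
  -mean(gv * log(gv) + (1 - gv) * log(1 - gv))
}

# d(lambda * L_ent)/dg per position (L_ent = -H)
gate_entropy_loss_dgate <- function(g, lambda) {
  gv <- pmin(pmax(as.numeric(g), CLAMP_EPS), 1 - CLAMP_EPS)
  lambda * (log(gv) - log(1 - gv)) / length(gv)
}

#' Total training objective
#'
#' `L_total = L_cls + lambda * L_ent` where `L_ent = -H(G)`. In
#' position-gate mode the entropy term reaches only the gating-branch
#' parameters, because the gate depends on coordinates alone; this is a
#' structural property of the architecture, not an imposed mask.
#'
#' @param y_hat posterior probability.
#' @param y hard label.
#' @param g gate map (NULL in gap mode, in which case the entropy term is
#'   dropped).
#' @param cfg a [loss_config].
#' @return scalar loss.
#' @export
total_loss <- function(y_hat, y, g, cfg) {
  l <- classification_loss(y_hat, y, cfg)
  if (!is.null(g) && cfg$lambda > 0) l <- l - cfg$lambda * gate_entropy(g)
  l
}

#' Classification metrics
#'
#' Accuracy at the fixed threshold 0.5 on the posterior, and AUROC via the
#' rank (Mann-Whitney) statistic with ties averaged.
#'
#' @param scores posterior probabilities (or any monotone scores for
#'   AUROC).
#' @param labels 0/1 labels.
#' @return list with `acc` and `auroc`.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  acc <- mean((scores >= 0.5) == (labels == 1L))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  rk <- rank(scores, ties.method = "average")
  auroc <- (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(acc = acc, auroc = auroc)
}
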