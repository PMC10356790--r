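test_that("global average pooling is the plain mean", {
  expect_identical(gap_pool(array(3.5, c(2, 2, 2))), 3.5)
  expect_identical(gap_pool(c(1, -1, 1, -1)), 0)
  expect_identical(gap_pool(array(1:8, c(2, 2, 2))), 4.5)
  expect_error(gap_pool(numeric(0)), "empty")
})

test_that("gated pooling reduces to GAP for constant gates and is scale-invariant", {
  set.seed(10)
  for (rep in 1:50) {
    d <- c(3L, 4L, 2L)
    r <- array(stats::rnorm(prod(d)), d)
    # constant gate: exact reduction to the mean
    gp <- gated_pool(r, array(0.37, d))
    expect_equal(gp$z, gap_pool(r), tolerance = 1e-12)
    # positive rescaling leaves z unchanged (clamped into [0,1])
    g <- array(stats::runif(prod(d), 0.1, 0.9), d)
    z1 <- gated_pool(r, g)$z
    z2 <- gated_pool(r, g * 0.5)$z
    expect_equal(z1, z2, tolerance = 1e-10)
  }
  # one-hot gate selects a single response
  r <- array(seq_len(8), c(2, 2, 2))
  g <- array(0, c(2, 2, 2)); g[2, 1, 2] <- 1
  expect_equal(gated_pool(r, g)$z, r[2, 1, 2], ignore_attr = TRUE)
  # evidence map is the elementwise product
  gg <- array(stats::runif(8), c(2, 2, 2))
  expect_equal(unclass(gated_pool(r, gg)$evidence), r * gg,
               ignore_attr = TRUE)
  expect_error(gated_pool(r, array(0, c(2, 2, 2))), "degenerate")
  expect_error(gated_pool(r, array(0.5, c(3, 3, 3))), "matching")
})

test_that("the balanced label-smoothed loss matches a scalar-arithmetic oracle", {
  # independent oracle: literal term-by-term evaluation
  oracle <- function(beta, yls, p) -beta * yls * log(p) -
    (1 - beta) * (1 - yls) * log(1 - p)
  for (beta in c(0.25, 0.5, 433 / 792)) {
    cfg <- loss_config(beta = beta)
    for (p in c(0.05, 0.3, 0.5, 0.9, 0.99)) {
      expect_equal(classification_loss(p, 1, cfg), oracle(beta, 0.9, p),
                   tolerance = 1e-12)
      expect_equal(classification_loss(p, 0, cfg), oracle(beta, 0.1, p),
                   tolerance = 1e-12)
    }
  }
  # the worked value at beta = 0.5, y_LS = 0.9, p = 0.9
  cfg <- loss_config(beta = 0.5)
  expect_equal(classification_loss(0.9, 1, cfg),
               0.5 * (-0.9 * log(0.9) - 0.1 * log(0.1)), tolerance = 1e-12)
  # log penalty grows monotonically as a wrong prediction hardens
  ps <- c(0.9, 0.99, 0.999, 1 - 1e-9)
  ls <- vapply(ps, classification_loss, numeric(1), y = 0, cfg = cfg)
  expect_true(all(diff(ls) > 0))
  # batch reduction is the mean
  expect_equal(classification_loss(c(0.2, 0.8), c(0, 1), cfg),
               mean(classification_loss(c(0.2, 0.8), c(0, 1), cfg,
                                        reduce = FALSE)))
  # degenerate-parameter equivalence: beta 0.5 + hard targets = BCE / 2
  hard <- loss_config(beta = 0.5, smooth_targets = c(0, 1))
  for (p in c(0.1, 0.6, 0.95)) {
    expect_equal(classification_loss(p, 1, hard), -0.5 * log(p),
                 tolerance = 1e-12)
    expect_equal(classification_loss(p, 0, hard), -0.5 * log(1 - p),
                 tolerance = 1e-12)
  }
})

test_that("loss is symmetric around 0.5 when targets are symmetric", {
  cfg <- loss_config(beta = 0.5, smooth_targets = c(0.5, 0.5))
  for (d in c(0.1, 0.25, 0.4))
    expect_equal(classification_loss(0.5 + d, 1, cfg),
                 classification_loss(0.5 - d, 1, cfg), tolerance = 1e-12)
})

test_that("gate entropy attains its known extremes and bounds", {
  expect_equal(gate_entropy(array(0.5, c(3, 3, 3))), log(2),
               tolerance = 1e-12)
  expect_lt(gate_entropy(array(c(0, 1), c(2, 2, 2))), 1e-10)
  set.seed(20)
  for (i in 1:1000) {
    h <- gate_entropy(stats::runif(sample(2:30, 1)))
    expect_true(h >= 0 && h <= log(2) + 1e-12)
  }
})

test_that("total loss composes the classification and entropy terms", {
  cfg0 <- loss_config(beta = 0.4, lambda = 0)
  cfg <- loss_config(beta = 0.4, lambda = 0.01)
  g <- array(0.5, c(2, 2, 2))
  expect_identical(total_loss(0.7, 1, g, cfg0),
                   classification_loss(0.7, 1, cfg0))
  expect_equal(total_loss(0.7, 1, g, cfg),
               classification_loss(0.7, 1, cfg) - 0.01 * log(2),
               tolerance = 1e-12)
})

test_that("the entropy term has exactly zero gradient on encoder and classifier in position-gate mode", {
  # finite-difference probe: perturbing any phi/psi parameter cannot change
  # L_ent because the gate sees only coordinates
  spec <- encoder_spec(9)
  model <- build_model(spec, "position_gate", seed = 14)
  ext <- c(24L, 24L, 24L)
  v <- random_volume(ext, seed = 3)
  ind <- extract_position_indicator(make_coordinate_grid(ext),
                                    spec$layer_geoms)
  l_ent <- function() {
    fw <- bagnet3d:::model_forward(model, v, indicator = ind)
    -gate_entropy(fw$g)
  }
  base <- l_ent()
  lys <- bagnet3d:::model_layers(model)
  set.seed(8)
  for (rec in lys[vapply(lys, function(r) r$group %in% c("phi", "psi"),
                         logical(1))][c(1, 5, 9, 12)]) {
    pn <- bagnet3d:::layer_param_names(rec$layer)[1L]
    p <- get(pn, envir = rec$layer)
    idx <- sample(length(p), 1)
    p[idx] <- p[idx] + 0.1
    assign(pn, p, envir = rec$layer)
    expect_identical(l_ent(), base)
    p[idx] <- p[idx] - 0.1
    assign(pn, p, envir = rec$layer)
  }
  # and the analytic gradients routed by the backward pass agree: with only
  # the entropy gradient injected, phi/psi accumulate exactly zero
  fw <- bagnet3d:::model_forward(model, v, indicator = ind)
  bagnet3d:::zero_gradients(model)
  bagnet3d:::model_backward(model, fw, dz = 0,
                            dgate_extra = bagnet3d:::gate_entropy_loss_dgate(fw$g, 0.01))
  gr <- model_gradients(model, c("phi", "psi"))
  expect_true(all(vapply(gr, function(g) all(g == 0), logical(1))))
  gr_gate <- model_gradients(model, c("pi", "rho"))
  expect_gt(max(vapply(gr_gate, function(g) max(abs(g)), numeric(1))), 0)
})

test_that("beta is the negative-class fraction of the training split", {
  expect_identical(compute_beta(c(0, 0, 1, 1)), 0.5)
  expect_identical(compute_beta(c(0, 0, 0, 1)), 0.75)
  # cohort-scale arithmetic: 433 negatives of 792 total
  expect_equal(compute_beta(rep(c(0, 1), c(433, 359))), 433 / 792,
               tolerance = 1e-12)
  expect_error(compute_beta(c(1, 1, 1)), "both classes")
})

test_that("metrics: accuracy thresholds at 0.5 and AUROC is the rank statistic", {
  m <- evaluate_predictions(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_identical(m$acc, 1)
  expect_identical(m$auroc, 1)
  # label-independent scores concentrate near 0.5 (permutation behavior)
  set.seed(5)
  s <- stats::runif(2000); l <- rep(c(0, 1), 1000)
  m2 <- evaluate_predictions(s, l)
  expect_lt(abs(m2$auroc - 0.5), 0.05)
  # ties are averaged
  m3 <- evaluate_predictions(c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 1))
  expect_identical(m3$auroc, 0.5)
  expect_error(evaluate_predictions(c(0.2, 0.8), c(1, 1)), "undefined")
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    n <- 60
    l <- rbinom(n, 1, 0.45)
    if (length(unique(l)) < 2) next
    s <- stats::rnorm(n, mean = l)
    ours <- evaluate_predictions(s, l)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
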