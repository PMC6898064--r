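tiny_config <- function(...) {
  args <- list(enc_channels = c(3, 4, 4), embed_dim = 8, code_dim = 16,
               dec_channels = 4, head_dim = 6, batch_size = 8, seed = 5)
  do.call(cae_config, utils::modifyList(args, list(...)))
}

tiny_dataset <- function(n = 10, seed = 21) {
  generate_dataset(n, seed = seed, coapt_grid = c(32, 32))
}

test_that("bc-weighted loss reproduces hand-computed cases", {
  expect_identical(bc_weighted_loss(c(1, 2), c(1, 2)), 0)
  # fixed-node error suppressed: weights (0, 1)
  expect_identical(bc_weighted_loss(c(1, 2), c(0, 2)), 0)
  # weights (0.5, 1): (0.5*1 + 1*4) / 2
  expect_equal(bc_weighted_loss(c(0, 0), c(1, 2)), 2.25)
  # all-zero target falls back to plain MSE
  expect_equal(bc_weighted_loss(c(1, 1), c(0, 0)), 1)
  expect_error(bc_weighted_loss(c(NaN, 1), c(0, 1)), "NaN")
  expect_error(bc_weighted_loss(c(1, 2, 3), c(1, 2)), "shape")
})

test_that("bc-weighted loss gradient matches finite differences", {
  set.seed(14)
  u_true <- array(rnorm(24), c(2, 3, 4))
  u_true[1, 1, ] <- 0
  u_pred <- u_true + array(rnorm(24, sd = 0.3), c(2, 3, 4))
  g <- bc_weighted_loss(u_pred, u_true, gradient = TRUE)
  h <- 1e-6
  for (i in sample(24, 10)) {
    up <- u_pred; up[i] <- up[i] + h
    um <- u_pred; um[i] <- um[i] - h
    fd <- (bc_weighted_loss(up, u_true) - bc_weighted_loss(um, u_true)) / (2 * h)
    expect_lt(abs(fd - g$gradient[i]) / max(abs(fd), abs(g$gradient[i]), 1e-10),
              1e-5)
  }
  # perturbing the prediction only at fixed (zero-target) entries leaves the
  # loss unchanged: their weight is exactly zero
  up <- u_pred; up[1, 1, ] <- up[1, 1, ] + 100
  expect_identical(bc_weighted_loss(up, u_true),
                   bc_weighted_loss(u_pred, u_true))
})

test_that("total loss is additive in its two terms", {
  set.seed(15)
  ut <- array(rnorm(3 * 4 * 4 * 3, sd = 0.1), c(3, 4, 4, 3))
  up <- ut + array(rnorm(length(ut), sd = 0.05), dim(ut))
  target <- list(displacement = ut, coaptation = 1.4)
  pred <- list(displacement = up, coaptation = 1.1)
  expect_identical(total_loss(target, target), 0)
  lu <- total_loss(pred, list(displacement = ut, coaptation = 1.1),
                   lambda_c = 1)
  expect_equal(total_loss(pred, target, lambda_c = 0), lu)
  la <- ((1.1 - 1.4) / 0.5)^2
  expect_equal(total_loss(pred, target, lambda_c = 1, coapt_sd = 0.5),
               lu + la)
})

test_that("encode_input builds the standardised feature bundle", {
  ds <- tiny_dataset()
  norm <- valvecae:::.fit_norm(ds, 1:10)
  enc <- encode_input(ds$inputs$reference, ds$inputs$pressure,
                      ds$inputs$material, norm)
  expect_identical(dim(enc$features), c(10L, 14L))
  # pressure block: one standardised value repeated 10 times
  pblock <- enc$features[, 5:14]
  expect_true(all(abs(pblock - pblock[, 1]) == 0))
  # affine round trip recovers the raw features
  mat_rec <- sweep(sweep(enc$features[, 1:4], 2, norm$mat_sd, "*"), 2,
                   -norm$mat_mean, "-")
  expect_lt(max(abs(mat_rec - ds$inputs$material)), 1e-10)
  # textures pass through unchanged
  expect_identical(enc$textures, ds$inputs$reference)
  # single-sample form
  smp <- dataset_sample(ds, 4)
  e1 <- encode_input(smp$textures, smp$pressure, smp$material, norm)
  expect_identical(dim(e1$textures), c(1L, 3L, 8L, 8L, 3L))
  expect_equal(e1$features[1, ], enc$features[4, ])
})

test_that("forward pass satisfies its output contracts", {
  cfg <- tiny_config()
  model <- build_cae(cfg)
  model$norm <- valvecae:::.fit_norm(tiny_dataset(), 1:10)
  set.seed(33)
  N <- 200L
  tex <- array(rnorm(N * 3 * 8 * 8 * 3), c(N, 3, 8, 8, 3))
  p <- runif(N, 60, 100)
  mat <- cbind(runif(N, 100, 900), runif(N, 100, 2000),
               runif(N, 0.5, 3), runif(N, 0.01, 0.1))
  pr <- predict(model, tex, p, mat)
  expect_true(all(pr$coaptation >= 0))
  expect_identical(dim(pr$displacement), c(N, 3L, 8L, 8L, 3L))
  expect_identical(dim(pr$code), c(N, 16L))
  pr2 <- predict(model, tex, p, mat)
  expect_identical(pr$displacement, pr2$displacement)
  expect_identical(pr$coaptation, pr2$coaptation)
  # identical inputs map to matching codes (batched vs single forward)
  expect_equal(pr$code[1, ], extract_code(
    model, tex[1, , , , , drop = TRUE], p[1], mat[1, ])[1, ],
    tolerance = 1e-12)
})

test_that("analytic network gradients match finite differences", {
  cfg <- cae_config(grid = c(6, 6), enc_channels = c(2, 3, 3), embed_dim = 5,
                    code_dim = 7, dec_channels = 3, head_dim = 4, seed = 11)
  model <- build_cae(cfg)
  set.seed(3)
  B <- 3
  tex <- array(rnorm(B * 3 * 6 * 6 * 3), c(B, 3, 6, 6, 3))
  feats <- matrix(rnorm(B * 14), B, 14)
  u_true <- array(rnorm(B * 3 * 6 * 6 * 3, sd = 0.1), c(B, 3, 6, 6, 3))
  u_true[, , 1, , ] <- 0
  a_true <- runif(B, 0.5, 1.5)
  lossfn <- function(params) {
    fw <- valvecae:::.cae_fwd(params, cfg, tex, feats, keep = TRUE)
    valvecae:::.batch_loss(fw$u_pred, u_true, fw$a_pred, fw$cache$a_raw,
                           a_true, 1, 0.5, 1e-12)
  }
  bl <- lossfn(model$params)
  fw <- valvecae:::.cae_fwd(model$params, cfg, tex, feats, keep = TRUE)
  grads <- valvecae:::.cae_bwd(model$params, cfg, fw$cache, bl$dU, bl$da)
  set_leaf <- function(tree, pth, i, v) {
    if (length(pth) == 1) { tree[[pth[1]]][i] <- v; return(tree) }
    tree[[pth[1]]] <- set_leaf(tree[[pth[1]]], pth[-1], i, v)
    tree
  }
  paths <- list(c("enc", "conv1", "W"), c("enc", "emb", "W"), c("fus", "W"),
                c("dec_fc", "W"), c("tconv2", "W"), c("head2", "W"))
  h <- 1e-5
  for (pth in paths) {
    P <- model$params; G <- grads
    for (k in pth) { P <- P[[k]]; G <- G[[k]] }
    for (i in sample(length(P), 3)) {
      lp <- lossfn(set_leaf(model$params, pth, i, P[i] + h))$loss
      lm <- lossfn(set_leaf(model$params, pth, i, P[i] - h))$loss
      fd <- (lp - lm) / (2 * h)
      expect_lt(abs(fd - G[i]) / max(abs(fd), abs(G[i]), 1e-8), 1e-4)
    }
  }
})

test_that("translation augmentation shifts inputs and preserves targets", {
  ds <- tiny_dataset()
  smp <- dataset_sample(ds, 1)
  same <- augment_translate(smp, shift = c(0, 0, 0))
  expect_identical(same, smp)
  shifted <- augment_translate(smp, shift = c(0.2, -0.1, 0.4))
  for (c_ in 1:3)
    expect_equal(shifted$textures[, , , c_] - smp$textures[, , , c_],
                 array(c(0.2, -0.1, 0.4)[c_], c(3, 8, 8)))
  expect_identical(shifted$displacement, smp$displacement)
  expect_identical(shifted$coaptation, smp$coaptation)
  a1 <- augment_translate(smp, seed = 99)
  a2 <- augment_translate(smp, seed = 99)
  expect_identical(a1, a2)
})

test_that("zero-epoch training returns the seeded initialisation", {
  ds <- tiny_dataset()
  sp <- list(train = 1:8, validation = 9:10)
  m0 <- train_cae(ds, sp, tiny_config(epochs = 0))
  expect_identical(m0$params, build_cae(tiny_config(epochs = 0))$params)
  expect_false(m0$trained)
})

test_that("one small Adam step on a fixed batch decreases its loss", {
  cfg <- tiny_config(lr = 1e-4)
  ds <- tiny_dataset()
  model <- build_cae(cfg)
  norm <- valvecae:::.fit_norm(ds, 1:10)
  enc <- encode_input(ds$inputs$reference, ds$inputs$pressure,
                      ds$inputs$material, norm)
  idx <- 1:4
  tex <- enc$textures[idx, , , , , drop = FALSE]
  feats <- enc$features[idx, , drop = FALSE]
  ut <- ds$targets$displacement[idx, , , , , drop = FALSE]
  at <- ds$targets$coaptation[idx]
  loss_of <- function(params) {
    fw <- valvecae:::.cae_fwd(params, cfg, tex, feats, keep = TRUE)
    list(fw = fw,
         bl = valvecae:::.batch_loss(fw$u_pred, ut, fw$a_pred,
                                     fw$cache$a_raw, at, 1,
                                     norm$coapt_sd, 1e-12))
  }
  r0 <- loss_of(model$params)
  grads <- valvecae:::.cae_bwd(model$params, cfg, r0$fw$cache,
                               r0$bl$dU, r0$bl$da)
  opt <- valvecae:::.adam_init(model$params)
  st <- valvecae:::.adam_step(opt, model$params, grads, 1e-4)
  expect_lt(loss_of(st$params)$bl$loss, r0$bl$loss)
})

test_that("the network can overfit a 10-sample corpus", {
  ds <- tiny_dataset()
  sp <- list(train = 1:10, validation = 1:10)
  cfg <- tiny_config(epochs = 500, lr = 3e-3, batch_size = 10,
                     augment = FALSE, lr_schedule = "constant")
  model <- train_cae(ds, sp, cfg)
  hist <- model$history
  expect_lt(min(hist$train_loss) / hist$train_loss[1], 0.01)
  # after training, valves differing only in belly get distinct codes
  v1 <- build_valve(valve_params(belly = 0.2))
  v2 <- build_valve(valve_params(belly = 0.8))
  tex_of <- function(v) {
    tex <- array(NA_real_, c(3, 8, 8, 3))
    for (k in 1:3) tex[k, , , ] <- v$leaflets[[k]]$control
    tex
  }
  c1 <- extract_code(model, tex_of(v1), 80, c(500, 1000, 1.5, 0.05))
  c2 <- extract_code(model, tex_of(v2), 80, c(500, 1000, 1.5, 0.05))
  expect_gt(sqrt(sum((c1 - c2)^2)), 0)
})

test_that("training reports divergence instead of returning NaN weights", {
  ds <- tiny_dataset()
  sp <- list(train = 1:8, validation = 9:10)
  cfg <- tiny_config(epochs = 3, lr = 1e160, lr_schedule = "constant",
                     augment = FALSE)
  expect_error(train_cae(ds, sp, cfg), "diverged")
})
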