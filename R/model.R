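#' Configuration of the valve convolutional autoencoder
#'
#' The network takes the three leaflet control-grid textures, the material
#' vector, and the pressure vector, and predicts the three displacement
#' grids (linear output) plus the coaptation area (ReLU output, hence
#' non-negative). Each leaflet texture passes through a stack of 3x3
#' convolutions applied directly to the control grid, followed by a dense
#' embedding; the three embeddings are fused with the standardised material
#' features and the pressure value repeated 10 times into the code layer,
#' from which a mirrored decoder (dense expansion + stride-1 transposed
#' convolutions) emits the displacement grids and a small dense head emits
#' the coaptation area.
#'
#' @param grid Control grid `c(m, n)`.
#' @param enc_channels Channels of the three encoder convolution blocks.
#' @param embed_dim Per-leaflet embedding size.
#' @param code_dim Code (fusion) layer size.
#' @param dec_channels Channels of the decoder convolution blocks.
#' @param head_dim Hidden width of the coaptation head.
#' @param share_encoder Share encoder weights across the three leaflets
#'   (default `TRUE`; exploits the valve's 3-fold symmetry).
#' @param lambda_c Weight of the (standardised) coaptation loss term.
#' @param tau Fallback threshold of the boundary-condition weighting: targets
#'   whose maximum absolute displacement is below `tau` use unweighted MSE.
#' @param lr Adam learning rate.
#' @param lr_schedule `"cosine"` (decay to `lr/20` over the run) or
#'   `"constant"`.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param augment Apply random-translation augmentation during training.
#' @param augment_prob Per-sample probability of translation.
#' @param augment_shift Half-width (cm) of the uniform per-axis translation.
#' @param pressure_repeat Length of the repeated-pressure vector; fixed at 10.
#' @param seed Seed for initialisation, shuffling, and augmentation.
#' @return Object of class `cae_config`.
#' @export
cae_config <- function(grid = c(8, 8), enc_channels = c(8, 16, 32),
                       embed_dim = 64, code_dim = 128, dec_channels = 32,
                       head_dim = 32, share_encoder = TRUE,
                       lambda_c = 1, tau = 1e-12,
                       lr = 1.5e-3, lr_schedule = c("cosine", "constant"),
                       batch_size = 16, epochs = 50,
                       augment = TRUE, augment_prob = 0.5,
                       augment_shift = 0.5,
                       pressure_repeat = 10, seed = 1) {
  if (pressure_repeat != 10)
    stop("the repeated-pressure vector has fixed length 10")
  if (length(enc_channels) != 3) stop("enc_channels must have length 3")
  if (lambda_c < 0) stop("lambda_c must be >= 0")
  structure(list(grid = grid, enc_channels = enc_channels,
                 embed_dim = embed_dim, code_dim = code_dim,
                 dec_channels = dec_channels, head_dim = head_dim,
                 share_encoder = share_encoder, lambda_c = lambda_c,
                 tau = tau, lr = lr,
                 lr_schedule = match.arg(lr_schedule),
                 batch_size = batch_size, epochs = epochs,
                 augment = augment, augment_prob = augment_prob,
                 augment_shift = augment_shift,
                 pressure_repeat = 10L, n_features = 14L, seed = seed),
            class = "cae_config")
}

.init_encoder <- function(cfg) {
  m <- cfg$grid[1]; n <- cfg$grid[2]; ch <- cfg$enc_channels
  list(conv1 = .init_conv(3, ch[1]),
       conv2 = .init_conv(ch[1], ch[2]),
       conv3 = .init_conv(ch[2], ch[3]),
       emb = .init_dense(m * n * ch[3], cfg$embed_dim))
}

#' Initialise an untrained autoencoder
#'
#' @param config A [cae_config()].
#' @return Object of class `valve_cae` (untrained; normalisation statistics
#'   are attached by [train_cae()]).
#' @export
build_cae <- function(config) {
  m <- config$grid[1]; n <- config$grid[2]
  params <- withr::with_seed(config$seed, {
    p <- list()
    p$enc <- if (config$share_encoder) .init_encoder(config)
             else list(.init_encoder(config), .init_encoder(config),
                       .init_encoder(config))
    p$fus <- .init_dense(3 * config$embed_dim + config$n_features,
                         config$code_dim)
    p$dec_fc <- .init_dense(config$code_dim, m * n * config$dec_channels)
    p$tconv1 <- .init_conv(config$dec_channels, config$dec_channels)
    p$tconv2 <- .init_conv(config$dec_channels, 9, gain = 1)
    p$head1 <- .init_dense(config$code_dim, config$head_dim)
    p$head2 <- .init_dense(config$head_dim, 1, gain = 1)
    # the head works on the standardised area scale (targets are O(1) sd);
    # a positive bias starts the ReLU output in its active region
    p$head2$b <- 1.5
    p
  })
  structure(list(params = params, config = config, norm = NULL,
                 history = NULL, trained = FALSE),
            class = "valve_cae")
}

#' @export
print.valve_cae <- function(x, ...) {
  np <- sum(unlist(.tree_map1(length, x$params)))
  cat(sprintf("<valve_cae> grid %d x %d, code %d, %s, %d parameters\n",
              x$config$grid[1], x$config$grid[2], x$config$code_dim,
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

# normalisation statistics from the training split
.fit_norm <- function(dataset, idx) {
  mat <- dataset$inputs$material[idx, , drop = FALSE]
  p <- dataset$inputs$pressure[idx]
  a <- dataset$targets$coaptation[idx]
  sd_or_1 <- function(x) { s <- stats::sd(x); if (!is.finite(s) || s == 0) 1 else s }
  list(mat_mean = colMeans(mat), mat_sd = apply(mat, 2, sd_or_1),
       p_mean = mean(p), p_sd = sd_or_1(p),
       coapt_mean = mean(a), coapt_sd = sd_or_1(a),
       u_sd = sd_or_1(as.numeric(dataset$targets$displacement[idx, , , , ])))
}

#' Assemble standardised model inputs
#'
#' Builds the model input bundle from raw quantities: the leaflet textures
#' are passed through unchanged, the four material features are standardised
#' with the training statistics, and the scalar pressure is standardised and
#' repeated 10 times.
#'
#' @param textures Array `3 x m x n x 3` (one sample) or `N x 3 x m x n x 3`.
#' @param pressure Pressure(s) in mmHg.
#' @param material Material vector `(c0, c1, c2, thickness)` or `N x 4`
#'   matrix.
#' @param norm Normalisation statistics (from a trained [valve_cae()] model,
#'   element `norm`).
#' @return List with `textures` (`N x 3 x m x n x 3`) and `features`
#'   (`N x 14`: standardised material then repeated standardised pressure).
#' @export
encode_input <- function(textures, pressure, material, norm) {
  if (length(dim(textures)) == 4) {
    textures <- array(textures, c(1, dim(textures)))
  }
  N <- dim(textures)[1]
  if (is.null(dim(material))) material <- matrix(material, N, 4, byrow = TRUE)
  mat_std <- sweep(sweep(material, 2, norm$mat_mean), 2, norm$mat_sd, "/")
  p_std <- (pressure - norm$p_mean) / norm$p_sd
  feats <- cbind(mat_std, matrix(p_std, N, 10))
  list(textures = textures, features = unname(feats))
}

# ---- forward / backward -------------------------------------------------

.enc_fwd <- function(ep, x) {
  c1 <- .conv_fwd(x, ep$conv1$W, ep$conv1$b); h1 <- .relu(c1$y)
  c2 <- .conv_fwd(h1, ep$conv2$W, ep$conv2$b); h2 <- .relu(c2$y)
  c3 <- .conv_fwd(h2, ep$conv3$W, ep$conv3$b); h3 <- .relu(c3$y)
  dmh <- dim(h3)
  flat <- h3; dim(flat) <- c(dmh[1], prod(dmh[2:4]))
  epre <- .dense_fwd(flat, ep$emb$W, ep$emb$b)
  e <- .relu(epre)
  list(e = e, c1 = c1, c2 = c2, c3 = c3, h1 = h1, h2 = h2, h3 = h3,
       flat = flat, epre = epre)
}

.enc_bwd <- function(ep, cache, de) {
  de <- de * (cache$epre > 0)
  bemb <- .dense_bwd(de, cache$flat, ep$emb$W)
  dh3 <- bemb$dx; dim(dh3) <- dim(cache$h3)
  dh3 <- dh3 * (cache$c3$y > 0)
  b3 <- .conv_bwd(dh3, cache$c3, ep$conv3$W)
  dh2 <- b3$dx * (cache$c2$y > 0)
  b2 <- .conv_bwd(dh2, cache$c2, ep$conv2$W)
  dh1 <- b2$dx * (cache$c1$y > 0)
  b1 <- .conv_bwd(dh1, cache$c1, ep$conv1$W)
  list(grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    conv2 = list(W = b2$dW, b = b2$db),
                    conv3 = list(W = b3$dW, b = b3$db),
                    emb = list(W = bemb$dW, b = bemb$db)))
}

.cae_fwd <- function(params, cfg, tex, feats, keep = FALSE) {
  dmt <- dim(tex)
  B <- dmt[1]; m <- dmt[3]; n <- dmt[4]
  cache <- list(B = B)
  if (cfg$share_encoder) {
    xl <- tex; dim(xl) <- c(B * 3, m, n, 3)
    ec <- .enc_fwd(params$enc, xl)
    e <- ec$e                          # (3B, E), row = b + B*(l-1)
    dim(e) <- c(B, 3, cfg$embed_dim)
    dim(e) <- c(B, 3 * cfg$embed_dim)
    if (keep) cache$enc <- ec
  } else {
    ecs <- vector("list", 3); embs <- vector("list", 3)
    for (l in 1:3) {
      xl <- tex[, l, , , , drop = TRUE]
      if (B == 1) xl <- array(xl, c(1, m, n, 3))
      ecs[[l]] <- .enc_fwd(params$enc[[l]], xl)
      embs[[l]] <- ecs[[l]]$e
    }
    e <- do.call(cbind, embs)
    if (keep) cache$enc <- ecs
  }
  z <- cbind(e, feats)
  cpre <- .dense_fwd(z, params$fus$W, params$fus$b)
  code <- .relu(cpre)
  dpre <- .dense_fwd(code, params$dec_fc$W, params$dec_fc$b)
  d0 <- .relu(dpre)
  d0a <- d0; dim(d0a) <- c(B, m, n, cfg$dec_channels)
  t1 <- .conv_fwd(d0a, params$tconv1$W, params$tconv1$b)
  t1h <- .relu(t1$y)
  t2 <- .conv_fwd(t1h, params$tconv2$W, params$tconv2$b)
  u9 <- t2$y                            # (B, m, n, 9), channel = l + 3*(comp-1)
  dim(u9) <- c(B, m, n, 3, 3)
  u_pred <- aperm(u9, c(1, 4, 2, 3, 5)) # (B, leaflet, m, n, comp)
  hpre <- .dense_fwd(code, params$head1$W, params$head1$b)
  h <- .relu(hpre)
  a_raw <- .dense_fwd(h, params$head2$W, params$head2$b)
  a_pred <- pmax(a_raw, 0)
  out <- list(u_pred = u_pred, a_pred = as.numeric(a_pred), code = code)
  if (keep) {
    cache$z <- z; cache$cpre <- cpre; cache$code <- code
    cache$dpre <- dpre; cache$d0 <- d0; cache$t1 <- t1; cache$t1h <- t1h
    cache$t2 <- t2; cache$hpre <- hpre; cache$h <- h; cache$a_raw <- a_raw
    out$cache <- cache
  }
  out
}

.cae_bwd <- function(params, cfg, cache, du_pred, da_pred) {
  B <- cache$B; m <- cfg$grid[1]; n <- cfg$grid[2]
  g <- list()
  # coaptation head
  da_raw <- matrix(da_pred * (cache$a_raw > 0), B, 1)
  bh2 <- .dense_bwd(da_raw, cache$h, params$head2$W)
  dh <- bh2$dx * (cache$hpre > 0)
  bh1 <- .dense_bwd(dh, cache$code, params$head1$W)
  g$head2 <- list(W = bh2$dW, b = bh2$db)
  g$head1 <- list(W = bh1$dW, b = bh1$db)
  # decoder
  du9 <- aperm(du_pred, c(1, 3, 4, 2, 5))     # (B, m, n, l, comp)
  dim(du9) <- c(B, m, n, 9)
  bt2 <- .conv_bwd(du9, cache$t2, params$tconv2$W)
  dt1 <- bt2$dx * (cache$t1$y > 0)
  bt1 <- .conv_bwd(dt1, cache$t1, params$tconv1$W)
  dd0 <- bt1$dx
  dim(dd0) <- c(B, m * n * cfg$dec_channels)
  dd0 <- dd0 * (cache$dpre > 0)
  bdf <- .dense_bwd(dd0, cache$code, params$dec_fc$W)
  g$tconv2 <- list(W = bt2$dW, b = bt2$db)
  g$tconv1 <- list(W = bt1$dW, b = bt1$db)
  g$dec_fc <- list(W = bdf$dW, b = bdf$db)
  # fusion
  dcode <- bdf$dx + bh1$dx
  dcode <- dcode * (cache$cpre > 0)
  bf <- .dense_bwd(dcode, cache$z, params$fus$W)
  g$fus <- list(W = bf$dW, b = bf$db)
  de <- bf$dx[, seq_len(3 * cfg$embed_dim), drop = FALSE]
  # encoders
  if (cfg$share_encoder) {
    dim(de) <- c(B, 3, cfg$embed_dim)
    dim(de) <- c(B * 3, cfg$embed_dim)
    g$enc <- .enc_bwd(params$enc, cache$enc, de)$grads
  } else {
    g$enc <- vector("list", 3)
    for (l in 1:3) {
      del <- de[, ((l - 1) * cfg$embed_dim + 1):(l * cfg$embed_dim),
                drop = FALSE]
      g$enc[[l]] <- .enc_bwd(params$enc[[l]], cache$enc[[l]], del)$grads
    }
  }
  g[names(params)]
}

# ---- losses -------------------------------------------------------------

#' Boundary-condition-weighted loss
#'
#' Mean squared displacement error with each node weighted by
#' `w = |u_true| / max(|u_true|)`, the true displacement magnitude relative
#' to the largest one in the tensor. Nodes whose true displacement is zero
#' -- the fixed attachment-edge points -- receive weight exactly 0, so the
#' network is never penalised for failing to hit zero there, which in turn
#' protects the moving nodes during backpropagation. For arrays whose last
#' dimension has extent 3 that dimension is taken as the Cartesian component
#' axis and all three components of a node share its magnitude weight; plain
#' vectors are treated as scalar nodal values (`|.|` is the absolute value).
#' If `max(|u_true|) < tau` the weighting degenerates and plain MSE is used.
#'
#' @param u_pred,u_true Numeric arrays of identical shape.
#' @param tau Degenerate-target fallback threshold (default 1e-12).
#' @param gradient If `TRUE`, also return the analytic gradient with respect
#'   to `u_pred`.
#' @return Scalar loss, or `list(value, gradient)` when `gradient = TRUE`.
#' @export
bc_weighted_loss <- function(u_pred, u_true, tau = 1e-12, gradient = FALSE) {
  if (!identical(dim(u_pred), dim(u_true)) ||
      length(u_pred) != length(u_true))
    stop("shape mismatch between u_pred and u_true")
  if (anyNA(u_pred) || anyNA(u_true)) stop("NaN/NA displacement input")
  dm <- dim(u_true)
  vector_nodes <- !is.null(dm) && length(dm) >= 2 && dm[length(dm)] == 3
  mag <- if (vector_nodes) {
    nodes <- matrix(u_true, ncol = 3)
    mg <- sqrt(rowSums(nodes * nodes))
    array(rep(mg, 3), dm)
  } else abs(u_true)
  mx <- max(mag)
  w <- if (mx < tau) {
    if (is.null(dm)) rep(1, length(u_true)) else array(1, dm)
  } else mag / mx
  d <- u_pred - u_true
  val <- mean(w * d * d)
  if (!gradient) return(val)
  list(value = val, gradient = 2 * w * d / length(d))
}


#' Combined training loss for one sample
#'
#' Sum over the three leaflets of the boundary-condition-weighted
#' displacement loss plus `lambda_c` times the squared error of the
#' coaptation area on the standardised scale.
#'
#' @param prediction,target Lists with `displacement` (array `3 x m x n x 3`
#'   or list of three `m x n x 3` arrays) and `coaptation` (scalar, cm^2).
#' @param lambda_c Coaptation term weight (>= 0).
#' @param coapt_sd Standardisation scale of the coaptation area (cm^2).
#' @param tau Passed to [bc_weighted_loss()].
#' @return Scalar loss.
#' @export
total_loss <- function(prediction, target, lambda_c = 1, coapt_sd = 1,
                       tau = 1e-12) {
  if (lambda_c < 0) stop("lambda_c must be >= 0")
  as_list3 <- function(u) {
    if (is.list(u)) return(u)
    lapply(1:3, function(l) array(u[l, , , ], dim(u)[2:4]))
  }
  up <- as_list3(prediction$displacement)
  ut <- as_list3(target$displacement)
  lu <- sum(vapply(1:3, function(l)
    bc_weighted_loss(up[[l]], ut[[l]], tau = tau), 0))
  lu + lambda_c * ((prediction$coaptation - target$coaptation) / coapt_sd)^2
}

# batched loss + gradient used by the training loop; u arrays (B,3,m,n,3)
.batch_loss <- function(u_pred, u_true, a_pred, a_raw, a_true,
                        lambda_c, coapt_sd, tau, u_scale = 1) {
  dmu <- dim(u_pred)
  B <- dmu[1]; K <- prod(dmu[3:5])
  up <- u_pred; dim(up) <- c(B * 3, K)
  ut <- u_true; dim(ut) <- c(B * 3, K)
  # per-node magnitude weights shared across the three Cartesian components
  # (columns come in three blocks of m*n: x, y, z)
  mn <- K / 3
  mag <- sqrt(ut[, 1:mn, drop = FALSE]^2 +
                ut[, mn + 1:mn, drop = FALSE]^2 +
                ut[, 2 * mn + 1:mn, drop = FALSE]^2)
  mx <- apply(mag, 1, max)
  degen <- mx < tau
  mx[degen] <- 1
  w <- cbind(mag, mag, mag) / mx
  w[degen, ] <- 1
  d <- up - ut
  # displacement term on the standardised scale so that, with lambda_c = 1,
  # the two loss terms are comparably conditioned
  rowloss <- rowSums(w * d * d) / (K * u_scale^2)
  L_u <- sum(rowloss) / B
  dU <- (2 / (K * B * u_scale^2)) * (w * d)
  dim(dU) <- dmu
  r <- (a_pred - a_true) / coapt_sd
  L_a <- lambda_c * mean(r * r)
  da <- lambda_c * 2 * r / (coapt_sd * B)
  list(loss = L_u + L_a, loss_u = L_u, loss_a = L_a, dU = dU, da = da)
}

#' Translation augmentation of a training record
#'
#' Shifts all reference control-point textures of the sample by one random
#' translation vector; displacement and coaptation targets are translation
#' invariant and remain bit-identical.
#'
#' @param sample A [dataset_sample()] record (or any list with a `textures`
#'   element of shape `3 x m x n x 3`).
#' @param shift Length-3 translation (cm), or `NULL` to draw one.
#' @param range Uniform half-width (cm) of each drawn component.
#' @param seed Optional seed making the draw reproducible.
#' @return The sample with shifted textures.
#' @export
augment_translate <- function(sample, shift = NULL, range = 0.5, seed = NULL) {
  if (is.null(shift)) {
    shift <- if (is.null(seed)) stats::runif(3, -range, range)
             else withr::with_seed(seed, stats::runif(3, -range, range))
  }
  for (c_ in 1:3) sample$textures[, , , c_] <- sample$textures[, , , c_] + shift[c_]
  sample
}

# ---- training -----------------------------------------------------------

.lr_at <- function(cfg, epoch) {
  if (cfg$lr_schedule == "constant" || cfg$epochs <= 1) return(cfg$lr)
  lr_min <- cfg$lr / 20
  lr_min + 0.5 * (cfg$lr - lr_min) *
    (1 + cos(pi * (epoch - 1) / (cfg$epochs - 1)))
}

#' Train the autoencoder
#'
#' Minibatch Adam on the boundary-condition-weighted displacement loss plus
#' the standardised coaptation term, with optional random-translation
#' augmentation, per-epoch validation, and checkpoint selection at the
#' minimum validation loss. Fully deterministic given the config seed.
#'
#' @param dataset A [generate_dataset()] object.
#' @param split List with integer index vectors `train` and `validation`
#'   (see [split_dataset()]).
#' @param config A [cae_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `valve_cae` with elements `history` (per-epoch
#'   data.frame of train/validation losses) and `norm` (training-split
#'   standardisation statistics).
#' @export
train_cae <- function(dataset, split, config = cae_config(),
                      verbose = FALSE) {
  model <- build_cae(config)
  norm <- .fit_norm(dataset, split$train)
  model$norm <- norm
  if (config$epochs == 0) return(model)
  enc <- encode_input(dataset$inputs$reference, dataset$inputs$pressure,
                      dataset$inputs$material, norm)
  tex_all <- enc$textures
  feats_all <- enc$features
  u_all <- dataset$targets$displacement
  # the head learns the coaptation area on the standardised scale
  a_all <- dataset$targets$coaptation / norm$coapt_sd
  tr <- split$train; va <- split$validation
  if (length(tr) < 1 || length(va) < 1)
    stop("train and validation splits must be non-empty")
  params <- model$params
  opt <- .adam_init(params)
  best_val <- Inf; best_params <- params; best_epoch <- 0
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric())

  eval_loss <- function(params, idx, chunk = 256) {
    tot <- 0
    for (s in split(idx, ceiling(seq_along(idx) / chunk))) {
      fw <- .cae_fwd(params, config,
                     tex_all[s, , , , , drop = FALSE],
                     feats_all[s, , drop = FALSE], keep = FALSE)
      bl <- .batch_loss(fw$u_pred, u_all[s, , , , , drop = FALSE],
                        fw$a_pred, NULL, a_all[s],
                        config$lambda_c, 1, config$tau, norm$u_sd)
      tot <- tot + bl$loss * length(s)
    }
    tot / length(idx)
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- .lr_at(config, epoch)
    ord <- withr::with_seed(config$seed * 1000L + epoch, sample(tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      tex <- tex_all[idx, , , , , drop = FALSE]
      if (config$augment) {
        aug <- withr::with_seed(
          config$seed * 100000L + epoch * 1000L + bi,
          list(sel = stats::runif(B) < config$augment_prob,
               sh = matrix(stats::runif(3 * B, -config$augment_shift,
                                        config$augment_shift), B, 3)))
        aug$sh[!aug$sel, ] <- 0
        for (c_ in 1:3) tex[, , , , c_] <- tex[, , , , c_] + aug$sh[, c_]
      }
      fw <- .cae_fwd(params, config, tex, feats_all[idx, , drop = FALSE],
                     keep = TRUE)
      bl <- .batch_loss(fw$u_pred, u_all[idx, , , , , drop = FALSE],
                        fw$a_pred, fw$cache$a_raw, a_all[idx],
                        config$lambda_c, 1, config$tau, norm$u_sd)
      if (!is.finite(bl$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch ", bi, "; reduce the learning rate")
      grads <- .cae_bwd(params, config, fw$cache, bl$dU, bl$da)
      st <- .adam_step(opt, params, grads, lr)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + bl$loss * B
    }
    ep_loss <- ep_loss / length(tr)
    val_loss <- eval_loss(params, va)
    if (!is.finite(val_loss))
      stop("training diverged (non-finite validation loss) at epoch ", epoch,
           "; reduce the learning rate")
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.5f  val %.5f",
                      epoch, lr, ep_loss, val_loss))
  }
  model$params <- best_params
  model$history <- hist
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Predict closure deformations and coaptation area
#'
#' @param object A `valve_cae` model.
#' @param textures Reference textures, `3 x m x n x 3` or `N x 3 x m x n x 3`.
#' @param pressure Pressure(s), mmHg.
#' @param material Material vector or `N x 4` matrix.
#' @param apply_fixed_mask Impose the known essential boundary condition on
#'   the output: the attachment-edge control points (grid edges `i = 0`,
#'   `i = m-1`, `j = 0`) are held by the stent and have zero displacement by
#'   definition, so their predicted displacements are zeroed (default
#'   `TRUE`). The loss never trains these outputs (their weight is exactly
#'   zero), so this replaces untrained values with the exact ones.
#' @param chunk Internal batch size.
#' @param ... Unused.
#' @return List with `displacement` (`N x 3 x m x n x 3`, cm), `coaptation`
#'   (length `N`, cm^2, non-negative), and `code` (`N x code_dim` fusion-layer
#'   activations).
#' @export
predict.valve_cae <- function(object, textures, pressure, material,
                              apply_fixed_mask = TRUE, chunk = 256, ...) {
  if (is.null(object$norm))
    stop("model has no normalisation statistics; train it first")
  enc <- encode_input(textures, pressure, material, object$norm)
  N <- dim(enc$textures)[1]
  m <- object$config$grid[1]; n <- object$config$grid[2]
  u <- array(NA_real_, c(N, 3, m, n, 3))
  a <- numeric(N)
  code <- matrix(NA_real_, N, object$config$code_dim)
  for (s in split(seq_len(N), ceiling(seq_len(N) / chunk))) {
    fw <- .cae_fwd(object$params, object$config,
                   enc$textures[s, , , , , drop = FALSE],
                   enc$features[s, , drop = FALSE], keep = FALSE)
    u[s, , , , ] <- fw$u_pred
    a[s] <- fw$a_pred * object$norm$coapt_sd   # back to cm^2
    code[s, ] <- fw$code
  }
  if (apply_fixed_mask) {
    u[, , 1, , ] <- 0
    u[, , m, , ] <- 0
    u[, , , 1, ] <- 0
  }
  list(displacement = u, coaptation = a, code = code)
}

#' Predict on stored dataset samples
#'
#' @param model A trained `valve_cae`.
#' @param dataset A `valve_dataset`.
#' @param idx Sample indices (default all).
#' @return As [predict.valve_cae()].
#' @export
predict_dataset <- function(model, dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(dataset$inputs$pressure)
  predict(model, dataset$inputs$reference[idx, , , , , drop = FALSE],
          dataset$inputs$pressure[idx],
          dataset$inputs$material[idx, , drop = FALSE])
}

#' Extract code-layer activations
#'
#' Returns the fusion-layer (code) activations, the learned low-dimensional
#' representation of geometry, material, and load from which the decoder
#' reconstructs the deformation.
#'
#' @inheritParams predict.valve_cae
#' @param model A `valve_cae`.
#' @return `N x code_dim` matrix.
#' @export
extract_code <- function(model, textures, pressure, material) {
  predict(model, textures, pressure, material)$code
}
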