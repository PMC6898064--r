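# Minimal neural-network engine: 3x3 same-padding convolutions (stride 1),
# dense layers, ReLU, and Adam, with hand-derived backpropagation.  All
# heavy lifting is BLAS matrix multiplication via an im2col layout.  Arrays
# carry the batch in dimension 1; reshapes rely on R's column-major order
# and are exactly reversed in the backward pass.

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# forward convolution; returns output and the im2col matrix for backprop
.conv_fwd <- function(x, W, b) {
  dm <- dim(x)
  N <- dm[1]; H <- dm[2]; Wd <- dm[3]; Cin <- dm[4]
  xp <- array(0, c(N, H + 2, Wd + 2, Cin))
  xp[, 2:(H + 1), 2:(Wd + 1), ] <- x
  cols <- matrix(0, N * H * Wd, 9 * Cin)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    sl <- xp[, (1 + di):(H + di), (1 + dj):(Wd + dj), , drop = FALSE]
    dim(sl) <- c(N * H * Wd, Cin)
    cols[, (k * Cin + 1):((k + 1) * Cin)] <- sl
    k <- k + 1
  }
  y <- cols %*% W
  y <- y + matrix(b, nrow(y), length(b), byrow = TRUE)
  dim(y) <- c(N, H, Wd, length(b))
  list(y = y, cols = cols, xdim = dm)
}

.conv_bwd <- function(dy, fwd, W) {
  xdim <- fwd$xdim
  N <- xdim[1]; H <- xdim[2]; Wd <- xdim[3]; Cin <- xdim[4]
  cout <- ncol(W)
  dim(dy) <- c(N * H * Wd, cout)
  dW <- crossprod(fwd$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(W)
  dxp <- array(0, c(N, H + 2, Wd + 2, Cin))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    blk <- dcols[, (k * Cin + 1):((k + 1) * Cin), drop = FALSE]
    dim(blk) <- c(N, H, Wd, Cin)
    dxp[, (1 + di):(H + di), (1 + dj):(Wd + dj), ] <-
      dxp[, (1 + di):(H + di), (1 + dj):(Wd + dj), ] + blk
    k <- k + 1
  }
  dx <- dxp[, 2:(H + 1), 2:(Wd + 1), , drop = FALSE]
  dim(dx) <- xdim
  list(dx = dx, dW = dW, db = db)
}

.dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y + matrix(b, nrow(y), length(b), byrow = TRUE)
}

.dense_bwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# He-normal initialised conv / dense parameter pairs
.init_conv <- function(cin, cout, gain = sqrt(2)) {
  fan <- 9 * cin
  list(W = matrix(stats::rnorm(fan * cout, sd = gain / sqrt(fan)), fan, cout),
       b = rep(0, cout))
}

.init_dense <- function(din, dout, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(din * dout, sd = gain / sqrt(din)), din, dout),
       b = rep(0, dout))
}

# recursive map over identically shaped parameter trees
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) .tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

.tree_map1 <- function(f, a) {
  if (is.list(a)) return(lapply(a, .tree_map1, f = f))
  f(a)
}

# in-place style Adam step over parameter / gradient / state trees
.adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt$m <- .tree_map2(function(m, g) b1 * m + (1 - b1) * g, opt$m, grads)
  opt$v <- .tree_map2(function(v, g) b2 * v + (1 - b2) * g * g, opt$v, grads)
  mhat_fac <- 1 / (1 - b1^opt$t)
  vhat_fac <- 1 / (1 - b2^opt$t)
  upd <- .tree_map2(function(m, v)
    lr * (m * mhat_fac) / (sqrt(v * vhat_fac) + eps), opt$m, opt$v)
  params <- .tree_map2(`-`, params, upd)
  list(opt = opt, params = params)
}

.adam_init <- function(params) {
  zero <- .tree_map1(function(x) x * 0, params)
  list(m = zero, v = .tree_map1(function(x) x * 0, params), t = 0)
}
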