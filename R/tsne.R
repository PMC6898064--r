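# Exact (O(n^2)) t-distributed stochastic neighbour embedding, used to
# visualise the code layer.  Standard formulation: Gaussian input affinities
# with per-point bandwidths found by bisection on the perplexity, Student-t
# low-dimensional kernel, gradient descent with momentum, gain adaptation,
# and early exaggeration.

.tsne_p <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X * X)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- Inf
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    # shift by the nearest-neighbour distance: leaves the conditional
    # distribution unchanged but keeps exp() away from total underflow;
    # the self term is excluded explicitly
    di <- D2[i, ]
    di <- di - min(di[is.finite(di)])
    di[i] <- 0
    for (it in 1:50) {
      w <- exp(-di * beta)
      w[i] <- 0
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, ] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2D t-SNE embedding
#'
#' Exact t-SNE of a set of vectors, seeded and deterministic. Intended for
#' embedding code-layer activations; any labels are used for colouring only,
#' never as input.
#'
#' @param X Numeric matrix (rows = observations).
#' @param perplexity Effective neighbourhood size (default 30); requires
#'   `3 * perplexity < nrow(X) - 1`.
#' @param n_iter Gradient-descent iterations (default 500).
#' @param seed Seed of the random initialisation (default 0).
#' @return `nrow(X) x 2` matrix.
#' @export
fit_tsne <- function(X, perplexity = 30, n_iter = 500, seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (3 * perplexity >= n - 1)
    stop("perplexity too large for ", n, " points")
  P <- .tsne_p(X, perplexity)
  Y <- withr::with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)      # update (momentum) buffer
  gains <- matrix(1, n, 2)
  exag <- 4
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exag else P
    sq <- rowSums(Y * Y)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8), 0.01)
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
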