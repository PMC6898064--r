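# Independent oracles and shared fixtures.  The oracles deliberately use
# naive formulations (plain recursion, double loops, dense triangulation)
# written separately from the package's vectorised evaluators.

# plain recursive Cox-de Boor basis function N_{i,p}(u); the last nonempty
# span is treated as closed so that the basis sums to one at u = max(knots)
cdb_basis <- function(knots, degree, u, i) {
  kmax <- knots[length(knots)]
  if (degree == 0) {
    if (knots[i] <= u && u < knots[i + 1]) return(1)
    if (u == kmax && knots[i] < knots[i + 1] && knots[i + 1] == kmax) return(1)
    return(0)
  }
  out <- 0
  d1 <- knots[i + degree] - knots[i]
  if (d1 > 0) out <- out + (u - knots[i]) / d1 * cdb_basis(knots, degree - 1, u, i)
  d2 <- knots[i + degree + 1] - knots[i + 1]
  if (d2 > 0) out <- out + (knots[i + degree + 1] - u) / d2 *
      cdb_basis(knots, degree - 1, u, i + 1)
  out
}

# rational surface point by explicit double loop over the control grid
oracle_surface_point <- function(surface, u, v) {
  m <- dim(surface$control)[1]; n <- dim(surface$control)[2]
  num <- c(0, 0, 0); den <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    r <- cdb_basis(surface$knots_u, surface$degree[1], u, i) *
      cdb_basis(surface$knots_v, surface$degree[2], v, j) *
      surface$weights[i, j]
    num <- num + r * surface$control[i, j, ]
    den <- den + r
  }
  num / den
}

# random smooth rational patch on a randomised open-uniform knot layout
random_surface <- function(m = 6, n = 5, degree = c(3, 2), rational = TRUE) {
  ctrl <- array(0, c(m, n, 3))
  for (i in seq_len(m)) for (j in seq_len(n))
    ctrl[i, j, ] <- c(i / m, j / n, 0.3 * sin(i) * cos(j)) + rnorm(3, sd = 0.05)
  w <- if (rational) matrix(runif(m * n, 0.5, 2), m, n) else matrix(1, m, n)
  nurbs_surface(ctrl, weights = w, degree = degree)
}

# unit flat patch spanning [0, L] x [0, W] with uniformly spaced control grid
flat_patch <- function(m = 4, n = 4, L = 1, W = 1) {
  ctrl <- array(0, c(m, n, 3))
  for (i in seq_len(m)) for (j in seq_len(n))
    ctrl[i, j, 1:2] <- c(L * (i - 1) / (m - 1), W * (j - 1) / (n - 1))
  nurbs_surface(ctrl, degree = c(min(3, m - 1), min(3, n - 1)))
}

# exact NURBS quarter cylinder, radius r, height h (area = pi/2 * r * h)
quarter_cylinder <- function(r = 1, h = 2) {
  ctrl <- array(0, c(3, 2, 3))
  ctrl[, 1, 1] <- r * c(1, 1, 0); ctrl[, 1, 2] <- r * c(0, 1, 1)
  ctrl[, 2, 1] <- r * c(1, 1, 0); ctrl[, 2, 2] <- r * c(0, 1, 1)
  ctrl[, 2, 3] <- h
  nurbs_surface(ctrl, weights = matrix(c(1, sqrt(2) / 2, 1), 3, 2),
                degree = c(2, 1))
}

# surface area by dense triangulation of an (nu+1) x (nv+1) sample grid
triangulation_area <- function(surface, nu = 700, nv = 700) {
  us <- seq(0, 1, length.out = nu + 1)
  vs <- seq(0, 1, length.out = nv + 1)
  P <- array(NA_real_, c(nu + 1, nv + 1, 3))
  for (chunk in split(seq_len(nv + 1), ceiling(seq_len(nv + 1) / 30))) {
    uu <- rep(us, times = length(chunk))
    vv <- rep(vs[chunk], each = nu + 1)
    pts <- evaluate_surface(surface, uu, vv)
    P[, chunk, ] <- array(pts, c(nu + 1, length(chunk), 3))
  }
  i <- 1:nu; j <- 1:nv
  tri_area <- function(a, b, cc) {
    u <- b - a; v <- cc - a
    cx <- u[, , 2] * v[, , 3] - u[, , 3] * v[, , 2]
    cy <- u[, , 3] * v[, , 1] - u[, , 1] * v[, , 3]
    cz <- u[, , 1] * v[, , 2] - u[, , 2] * v[, , 1]
    0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
  }
  A <- P[i, j, , drop = FALSE]; B <- P[i + 1, j, , drop = FALSE]
  C <- P[i, j + 1, , drop = FALSE]; D <- P[i + 1, j + 1, , drop = FALSE]
  tri_area(A, B, C) + tri_area(B, D, C)
}

# brute-force symmetric Hausdorff distance by explicit double loop
oracle_hausdorff <- function(a, b) {
  directed <- function(x, y) {
    worst <- 0
    for (i in seq_len(nrow(x))) {
      best <- Inf
      for (j in seq_len(nrow(y)))
        best <- min(best, sum((x[i, ] - y[j, ])^2))
      worst <- max(worst, best)
    }
    sqrt(worst)
  }
  max(directed(a, b), directed(b, a))
}

rotation_matrix <- function(axis = c(0, 0, 1), angle = pi / 5) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
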