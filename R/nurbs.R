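#' Open (clamped) uniform knot vector
#'
#' Builds the open knot vector on \[0, 1\] used for all generated leaflet
#' patches: the first and last knots are repeated `degree + 1` times and the
#' interior knots are uniformly spaced, so the surface interpolates the four
#' corner control points.
#'
#' @param n_ctrl Number of control points along the direction (> `degree`).
#' @param degree Polynomial degree (>= 1).
#' @return Numeric vector of length `n_ctrl + degree + 1`.
#' @export
open_knot_vector <- function(n_ctrl, degree) {
  if (degree < 1) stop("degree must be >= 1")
  if (n_ctrl <= degree) stop("need more control points than the degree")
  n_int <- n_ctrl - degree - 1
  interior <- if (n_int > 0) seq_len(n_int) / (n_int + 1) else numeric(0)
  c(rep(0, degree + 1), interior, rep(1, degree + 1))
}

.check_knots <- function(knots, degree, n_ctrl = NULL) {
  if (is.unsorted(knots)) stop("knot vector must be non-decreasing")
  k <- length(knots)
  nc <- k - degree - 1
  if (!is.null(n_ctrl) && nc != n_ctrl)
    stop("knot vector length must equal n_ctrl + degree + 1")
  if (any(knots[seq_len(degree + 1)] != knots[1]) ||
      any(knots[(k - degree):k] != knots[k]))
    stop("knot vector must be open (clamped): end knots repeated degree+1 times")
  invisible(nc)
}

# Cox-de Boor basis values (and optionally first/second derivatives) for all
# n_ctrl functions at the parameter values `u`.  Vectorised over `u`; the
# recursion runs over the (few) basis columns.  0/0 convention: terms with a
# zero knot span are dropped.
.bspline_basis <- function(knots, degree, u, n_deriv = 0) {
  nk <- length(knots)
  n_ctrl <- nk - degree - 1
  kmin <- knots[1]; kmax <- knots[nk]
  if (any(u < kmin) || any(u > kmax))
    stop("parameter outside knot range [", kmin, ", ", kmax, "]")
  nu <- length(u)
  span <- findInterval(u, knots)           # last index i with knots[i] <= u
  last_span <- max(which(knots < kmax))    # clamp u == kmax into final span
  span[u >= kmax] <- last_span

  levels <- vector("list", degree + 1)
  N <- matrix(0, nu, nk - 1)
  N[cbind(seq_len(nu), span)] <- 1
  levels[[1]] <- N
  if (degree >= 1) {
    for (d in seq_len(degree)) {
      Np <- levels[[d]]
      ncol_d <- nk - 1 - d
      Nd <- matrix(0, nu, ncol_d)
      for (i in seq_len(ncol_d)) {
        den1 <- knots[i + d] - knots[i]
        den2 <- knots[i + d + 1] - knots[i + 1]
        if (den1 > 0) Nd[, i] <- Nd[, i] + (u - knots[i]) / den1 * Np[, i]
        if (den2 > 0) Nd[, i] <- Nd[, i] + (knots[i + d + 1] - u) / den2 * Np[, i + 1]
      }
      levels[[d + 1]] <- Nd
    }
  }
  out <- list(values = levels[[degree + 1]])

  # derivative of a degree-p basis from the degree-(p-1) level
  deriv_from <- function(lower, p) {
    ncol_d <- ncol(lower) - 1
    D <- matrix(0, nu, ncol_d)
    for (i in seq_len(ncol_d)) {
      den1 <- knots[i + p] - knots[i]
      den2 <- knots[i + p + 1] - knots[i + 1]
      if (den1 > 0) D[, i] <- D[, i] + p / den1 * lower[, i]
      if (den2 > 0) D[, i] <- D[, i] - p / den2 * lower[, i + 1]
    }
    D
  }
  if (n_deriv >= 1) out$d1 <- deriv_from(levels[[degree]], degree)
  if (n_deriv >= 2) {
    if (degree < 2) stop("second derivatives require degree >= 2")
    d1_lower <- deriv_from(levels[[degree - 1]], degree - 1)
    # differentiate the first-derivative expansion once more
    ncol_d <- n_ctrl
    D2 <- matrix(0, nu, ncol_d)
    for (i in seq_len(ncol_d)) {
      den1 <- knots[i + degree] - knots[i]
      den2 <- knots[i + degree + 1] - knots[i + 1]
      if (den1 > 0) D2[, i] <- D2[, i] + degree / den1 * d1_lower[, i]
      if (den2 > 0) D2[, i] <- D2[, i] - degree / den2 * d1_lower[, i + 1]
    }
    out$d2 <- D2
  }
  out
}

#' B-spline basis functions at given parameters
#'
#' Evaluates all basis functions of the given open knot vector at the
#' parameters `u`. Values are non-negative, at most `degree + 1` are nonzero
#' at any parameter, and each row sums to one (partition of unity).
#'
#' @param knots Open (clamped) non-decreasing knot vector.
#' @param degree Polynomial degree (>= 1).
#' @param u Numeric vector of parameters within the knot range.
#' @return Matrix of dimension `length(u) x n_ctrl`.
#' @export
basis_functions <- function(knots, degree, u) {
  .check_knots(knots, degree)
  .bspline_basis(knots, degree, u)$values
}

#' Tensor-product NURBS surface
#'
#' The geometry carrier for valve leaflets: an `m x n` grid of 3D control
#' points (cm), per-point positive weights, open knot vectors, and degrees
#' `(p, q)`. Grid axis 1 (`i`) runs circumferentially, axis 2 (`j`) from the
#' attachment edge to the free edge; this orientation is fixed because the
#' convolution layers operate on it. With all weights equal to one the patch
#' is an ordinary B-spline surface; rational weights are supported (exact
#' conics such as circular arcs).
#'
#' @param control_points Numeric array `m x n x 3` (cm).
#' @param weights `m x n` matrix of positive weights; default all 1.
#' @param degree Length-2 integer vector `(p, q)`; default cubic `(3, 3)`.
#' @param knots_u,knots_v Open knot vectors; default open uniform on \[0, 1\].
#' @return Object of class `nurbs_surface`.
#' @export
nurbs_surface <- function(control_points, weights = NULL, degree = c(3, 3),
                          knots_u = NULL, knots_v = NULL) {
  dm <- dim(control_points)
  if (length(dm) != 3 || dm[3] != 3)
    stop("control_points must be an m x n x 3 array")
  m <- dm[1]; n <- dm[2]
  degree <- as.integer(degree)
  if (m <= degree[1] || n <= degree[2])
    stop("grid too small for the requested degrees")
  if (is.null(weights)) weights <- matrix(1, m, n)
  if (!all(dim(weights) == c(m, n))) stop("weights must be m x n")
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(knots_u)) knots_u <- open_knot_vector(m, degree[1])
  if (is.null(knots_v)) knots_v <- open_knot_vector(n, degree[2])
  .check_knots(knots_u, degree[1], m)
  .check_knots(knots_v, degree[2], n)
  structure(list(control = control_points, weights = weights,
                 degree = degree, knots_u = knots_u, knots_v = knots_v),
            class = "nurbs_surface")
}

#' @export
print.nurbs_surface <- function(x, ...) {
  dm <- dim(x$control)
  cat(sprintf("<nurbs_surface> %d x %d control grid, degrees (%d, %d)\n",
              dm[1], dm[2], x$degree[1], x$degree[2]))
  invisible(x)
}

# Rational basis matrices at paired parameter vectors (u[a], v[a]).
# Returns R (npts x m*n, column-major over the control grid: i fastest) and,
# per `deriv`, Ru/Rv and Ruu/Ruv/Rvv.  The surface and any field sharing its
# parametrisation are then linear maps of their control grids: S = R %*% P.
.rational_basis <- function(surface, u, v, deriv = 1) {
  m <- dim(surface$control)[1]; n <- dim(surface$control)[2]
  bu <- .bspline_basis(surface$knots_u, surface$degree[1], u, n_deriv = deriv)
  bv <- .bspline_basis(surface$knots_v, surface$degree[2], v, n_deriv = deriv)
  iu <- rep(seq_len(m), n)
  iv <- rep(seq_len(n), each = m)
  wrow <- as.vector(surface$weights)      # (i, j), i fastest
  npts <- length(u)
  wmat <- matrix(wrow, npts, m * n, byrow = TRUE)
  tens <- function(U, V) (U[, iu, drop = FALSE] * V[, iv, drop = FALSE]) * wmat
  T0 <- tens(bu$values, bv$values)
  W <- rowSums(T0)
  R <- T0 / W
  out <- list(R = R, W = W)
  if (deriv >= 1) {
    Tu <- tens(bu$d1, bv$values); Wu <- rowSums(Tu)
    Tv <- tens(bu$values, bv$d1); Wv <- rowSums(Tv)
    out$Ru <- (Tu - R * Wu) / W
    out$Rv <- (Tv - R * Wv) / W
    out$Wu <- Wu; out$Wv <- Wv
    if (deriv >= 2) {
      Tuu <- tens(bu$d2, bv$values); Wuu <- rowSums(Tuu)
      Tvv <- tens(bu$values, bv$d2); Wvv <- rowSums(Tvv)
      Tuv <- tens(bu$d1, bv$d1);     Wuv <- rowSums(Tuv)
      out$Ruu <- (Tuu - 2 * out$Ru * Wu - R * Wuu) / W
      out$Rvv <- (Tvv - 2 * out$Rv * Wv - R * Wvv) / W
      out$Ruv <- (Tuv - out$Ru * Wv - out$Rv * Wu - R * Wuv) / W
    }
  }
  out
}

# control grid as an (m*n) x 3 matrix, rows column-major (i fastest)
.ctrl_mat <- function(x) {
  dm <- dim(x)
  matrix(x, dm[1] * dm[2], 3)
}

#' Evaluate a NURBS surface
#'
#' Rational tensor-product evaluation at paired parameters: the weighted sum
#' of control points normalised by the weighted sum of basis products.
#'
#' @param surface A [nurbs_surface()].
#' @param xi,eta Numeric vectors (recycled to common length) in the knot range.
#' @return `length(xi) x 3` matrix of surface points (cm).
#' @export
evaluate_surface <- function(surface, xi, eta) {
  k <- max(length(xi), length(eta))
  xi <- rep_len(xi, k); eta <- rep_len(eta, k)
  rb <- .rational_basis(surface, xi, eta, deriv = 0)
  rb$R %*% .ctrl_mat(surface$control)
}

#' Partial derivatives of a NURBS surface
#'
#' First (and optionally second) partial derivatives with respect to the
#' parameters, by the rational quotient rule.
#'
#' @inheritParams evaluate_surface
#' @param order 1 or 2; must not exceed `min(degree)`.
#' @return List with `S`, `Su`, `Sv` (and `Suu`, `Suv`, `Svv` for order 2),
#'   each a `length(xi) x 3` matrix.
#' @export
surface_derivatives <- function(surface, xi, eta, order = 1) {
  if (!order %in% 1:2) stop("order must be 1 or 2")
  if (order > min(surface$degree))
    stop("derivative order exceeds the surface degree")
  k <- max(length(xi), length(eta))
  xi <- rep_len(xi, k); eta <- rep_len(eta, k)
  rb <- .rational_basis(surface, xi, eta, deriv = order)
  P <- .ctrl_mat(surface$control)
  out <- list(S = rb$R %*% P, Su = rb$Ru %*% P, Sv = rb$Rv %*% P)
  if (order == 2) {
    out$Suu <- rb$Ruu %*% P
    out$Suv <- rb$Ruv %*% P
    out$Svv <- rb$Rvv %*% P
  }
  out
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(x) sqrt(rowSums(x * x))

#' Surface area by Gauss-Legendre quadrature
#'
#' Integrates the area element |dS/dxi x dS/deta| with Gauss-Legendre
#' quadrature applied per nonempty knot span in each direction.
#'
#' @param surface A [nurbs_surface()].
#' @param quad_order Gauss points per span per direction (>= 1, default 4).
#' @return Area in cm^2. A degenerate (zero-area) surface returns 0 with a
#'   warning.
#' @export
surface_area <- function(surface, quad_order = 4) {
  if (quad_order < 1) stop("quad_order must be >= 1")
  gl_dir <- function(knots) {
    brk <- unique(knots)
    xs <- c(); ws <- c()
    for (s in seq_len(length(brk) - 1)) {
      g <- pracma::gaussLegendre(quad_order, brk[s], brk[s + 1])
      xs <- c(xs, g$x); ws <- c(ws, g$w)
    }
    list(x = xs, w = ws)
  }
  gu <- gl_dir(surface$knots_u)
  gv <- gl_dir(surface$knots_v)
  uu <- rep(gu$x, times = length(gv$x))
  vv <- rep(gv$x, each = length(gu$x))
  ww <- rep(gu$w, times = length(gv$w)) * rep(gv$w, each = length(gu$w))
  d <- surface_derivatives(surface, uu, vv, order = 1)
  area <- sum(ww * .rownorm(.cross3(d$Su, d$Sv)))
  if (area < .Machine$double.eps^0.5) {
    warning("surface is degenerate (zero area)")
    return(0)
  }
  area
}

#' Control-grid texture representation
#'
#' Restructures the `m x n` control grid into a three-channel `m x n x 3`
#' array (one channel per Cartesian coordinate), the image-like input of the
#' convolutional encoder. Channel order is (x, y, z); axis 1 is the
#' circumferential parameter, axis 2 runs attachment edge to free edge. The
#' mapping is lossless: `from_texture(to_texture(s), s)` returns `s`.
#'
#' @param surface A [nurbs_surface()].
#' @param provenance Optional identifier of the source surface.
#' @return `m x n x 3` numeric array with attribute `provenance`.
#' @export
to_texture <- function(surface, provenance = NULL) {
  tex <- surface$control
  attr(tex, "provenance") <- provenance
  tex
}

#' @rdname to_texture
#' @param tensor An `m x n x 3` texture array.
#' @param template A [nurbs_surface()] supplying weights, knots, and degrees.
#' @export
from_texture <- function(tensor, template) {
  if (!all(dim(tensor) == dim(template$control)))
    stop("texture shape does not match the template control grid")
  out <- template
  tex <- array(as.numeric(tensor), dim(template$control))
  out$control <- tex
  out
}

#' Read / write the JSON geometry schema
#'
#' Serialises a surface as
#' `{degrees, knots_u, knots_v, weights, control_points, units}`; weights and
#' control points are stored row-major (outer index `i`, the circumferential
#' axis), each control point as `[x, y, z]` in cm.
#'
#' @param surface A [nurbs_surface()].
#' @param path File path.
#' @return `write_geometry_json` returns `path` invisibly; `read_geometry_json`
#'   returns a [nurbs_surface()].
#' @export
write_geometry_json <- function(surface, path) {
  m <- dim(surface$control)[1]; n <- dim(surface$control)[2]
  cp <- lapply(seq_len(m), function(i)
    lapply(seq_len(n), function(j) unname(surface$control[i, j, ])))
  obj <- list(degrees = surface$degree,
              knots_u = surface$knots_u, knots_v = surface$knots_v,
              weights = lapply(seq_len(m), function(i) unname(surface$weights[i, ])),
              control_points = cp, units = "cm")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- obj$control_points
  if (is.list(cp)) {  # ragged fallback: list over i of n x 3 matrices
    cp <- simplify2array(cp)          # n x 3 x m
    cp <- aperm(cp, c(3, 1, 2))
  }
  ctrl <- array(as.numeric(cp), dim = dim(cp))
  w <- obj$weights
  if (is.list(w)) w <- do.call(rbind, w)
  nurbs_surface(ctrl, weights = matrix(as.numeric(w), dim(ctrl)[1]),
                degree = as.integer(obj$degrees),
                knots_u = as.numeric(obj$knots_u),
                knots_v = as.numeric(obj$knots_v))
}

#' Export surfaces as legacy ASCII VTK PolyData
#'
#' Samples each surface on a parameter grid and writes quad cells, for visual
#' inspection of reference or deformed valves in ParaView-class viewers.
#'
#' @param surfaces A [nurbs_surface()] or list of them.
#' @param path Output file path (`.vtk`).
#' @param grid Sampling resolution `c(nu, nv)`.
#' @param scalars Optional list of per-surface sample-point scalar vectors
#'   (length `nu * nv` each), written as point data named `value`.
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(surfaces, path, grid = c(30, 30), scalars = NULL) {
  if (inherits(surfaces, "nurbs_surface")) surfaces <- list(surfaces)
  nu <- grid[1]; nv <- grid[2]
  us <- seq(0, 1, length.out = nu); vs <- seq(0, 1, length.out = nv)
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  pts <- lapply(surfaces, evaluate_surface, xi = uu, eta = vv)
  npts_s <- nu * nv
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "valvecae surface export",
               "ASCII", "DATASET POLYDATA"), con)
  allpts <- do.call(rbind, pts)
  writeLines(sprintf("POINTS %d double", nrow(allpts)), con)
  writeLines(apply(allpts, 1, function(r) paste(format(r, digits = 12), collapse = " ")), con)
  quads <- list()
  for (s in seq_along(surfaces)) {
    off <- (s - 1) * npts_s
    for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) {
      a <- off + (j - 1) * nu + i - 1
      quads[[length(quads) + 1]] <- c(4, a, a + 1, a + nu + 1, a + nu)
    }
  }
  qm <- do.call(rbind, quads)
  writeLines(sprintf("POLYGONS %d %d", nrow(qm), length(qm)), con)
  writeLines(apply(qm, 1, paste, collapse = " "), con)
  if (!is.null(scalars)) {
    vals <- unlist(scalars)
    writeLines(sprintf("POINT_DATA %d", nrow(allpts)), con)
    writeLines(c("SCALARS value double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(vals, digits = 12), con)
  }
  invisible(path)
}
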