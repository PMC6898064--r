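#' Valve design parameters
#'
#' The five parameters of the parametric tri-leaflet valve family: diameter
#' `D` (cm), dimensionless belly curve parameter `b` and free-edge curve
#' parameter `f` (both in \[0, 1\]), free-edge height `h` (cm), and commissure
#' height `Hc` (cm). The belly parameter controls how far the mid-leaflet
#' bulges toward the valve axis, the free-edge parameter sags the free edge,
#' and `h` sets its height relative to the commissures. Defaults are anchored
#' to the 2.3 cm average aortic valve diameter.
#'
#' @param diameter Valve diameter D in cm (> 0).
#' @param belly Belly curve parameter in \[0, 1\].
#' @param free_edge Free-edge curve parameter in \[0, 1\].
#' @param free_edge_height Free-edge height h in cm, 0 < h <= Hc.
#' @param commissure_height Commissure height Hc in cm.
#' @return Object of class `valve_params`.
#' @export
valve_params <- function(diameter = 2.3, belly = 0.5, free_edge = 0.5,
                         free_edge_height = 0.9, commissure_height = 1.2) {
  if (diameter <= 0) stop("diameter must be positive")
  if (belly < 0 || belly > 1) stop("belly must lie in [0, 1]")
  if (free_edge < 0 || free_edge > 1) stop("free_edge must lie in [0, 1]")
  if (free_edge_height <= 0 || free_edge_height > commissure_height)
    stop("free_edge_height must satisfy 0 < h <= commissure_height")
  structure(list(diameter = diameter, belly = belly, free_edge = free_edge,
                 free_edge_height = free_edge_height,
                 commissure_height = commissure_height),
            class = "valve_params")
}

#' Build one leaflet of the parametric valve
#'
#' Constructs the reference (undeformed) NURBS patch of leaflet 0, occupying
#' the angular sector \[-60, 60\] degrees about the valve (z) axis. Control
#' point (i, j), with `i = 0..m-1` circumferential and `j = 0..n-1` running
#' from the attachment edge to the free edge, sits at angle
#' `phi_i = -pi/3 + (2*pi/3) * i/(m-1)`, radius
#' `r_ij = R * (1 - b * sin(pi*i/(m-1)) * j/(n-1))` with `R = D/2`, and a
#' height blending linearly in `j` from the attachment curve
#' `z_att(i) = Hc * (1 - sin(pi*i/(m-1)) * (1 - h/Hc))` to the free-edge
#' curve `z_free(i) = h * (1 - f * (1 - |2i/(m-1) - 1|) * 0.2)`.
#' The construction is mirror-symmetric in `i <-> m-1-i` and each parameter
#' has a monotone, localised geometric effect.
#'
#' @param params A [valve_params()].
#' @param grid Control grid size `c(m, n)`, each >= 4.
#' @param degree Surface degrees `(p, q)`, default cubic.
#' @return A [nurbs_surface()] with unit weights and open uniform knots.
#' @export
build_leaflet <- function(params, grid = c(8, 8), degree = c(3, 3)) {
  m <- grid[1]; n <- grid[2]
  if (m < 4 || n < 4) stop("grid must be at least 4 x 4")
  if (m <= degree[1] || n <= degree[2])
    stop("grid too small for the requested degrees")
  R <- params$diameter / 2
  b <- params$belly; f <- params$free_edge
  h <- params$free_edge_height; Hc <- params$commissure_height
  si <- (seq_len(m) - 1) / (m - 1)        # i/(m-1)
  sj <- (seq_len(n) - 1) / (n - 1)        # j/(n-1)
  phi <- -pi / 3 + 2 * pi / 3 * si
  belly_i <- sin(pi * si)
  z_att <- Hc * (1 - belly_i * (1 - h / Hc))
  z_free <- h * (1 - f * (1 - abs(2 * si - 1)) * 0.2)
  ctrl <- array(0, c(m, n, 3))
  for (j in seq_len(n)) {
    r_ij <- R * (1 - b * belly_i * sj[j])
    ctrl[, j, 1] <- r_ij * cos(phi)
    ctrl[, j, 2] <- r_ij * sin(phi)
    ctrl[, j, 3] <- z_att * (1 - sj[j]) + z_free * sj[j]
  }
  nurbs_surface(ctrl, degree = degree)
}

# rotation of an m x n x 3 control array about the z axis
.rotate_ctrl <- function(ctrl, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  out <- ctrl
  out[, , 1] <- c_ * ctrl[, , 1] - s_ * ctrl[, , 2]
  out[, , 2] <- s_ * ctrl[, , 1] + c_ * ctrl[, , 2]
  out
}

#' Build a tri-leaflet valve geometry
#'
#' Assembles three leaflets, leaflet `k` being leaflet 0 rotated by
#' `2*pi*k/3` about the valve axis, together with the fixed-boundary mask:
#' `TRUE` exactly on the attachment-edge control points (grid edges `i = 0`,
#' `i = m-1`, and `j = 0`), which the stent/suture line holds in place.
#'
#' @inheritParams build_leaflet
#' @return Object of class `valve_geometry` with elements `leaflets` (list of
#'   three [nurbs_surface()]), `params`, and `fixed_mask` (`m x n` logical).
#' @export
build_valve <- function(params, grid = c(8, 8), degree = c(3, 3)) {
  leaf0 <- build_leaflet(params, grid, degree)
  leaflets <- vector("list", 3)
  leaflets[[1]] <- leaf0
  for (k in 1:2) {
    lk <- leaf0
    lk$control <- .rotate_ctrl(leaf0$control, 2 * pi * k / 3)
    leaflets[[k + 1]] <- lk
  }
  m <- grid[1]; n <- grid[2]
  fixed <- matrix(FALSE, m, n)
  fixed[1, ] <- TRUE; fixed[m, ] <- TRUE; fixed[, 1] <- TRUE
  structure(list(leaflets = leaflets, params = params, fixed_mask = fixed),
            class = "valve_geometry")
}

#' @export
print.valve_geometry <- function(x, ...) {
  dm <- dim(x$leaflets[[1]]$control)
  cat(sprintf(
    "<valve_geometry> 3 leaflets, %d x %d control grids, D = %.3g cm\n",
    dm[1], dm[2], x$params$diameter))
  invisible(x)
}

#' Default design-space sampling ranges
#'
#' Belly and free-edge parameters span their full \[0, 1\] range; the
#' free-edge height spans 0.6-1.2 cm under the default 1.2 cm commissure
#' height; diameter and commissure height are held at their defaults.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_design_ranges <- function() {
  list(belly = c(0, 1), free_edge = c(0, 1), free_edge_height = c(0.6, 1.2))
}

#' Sample the valve design space
#'
#' Draws reproducible Latin-hypercube (or plain uniform) samples of the
#' design parameters within the given ranges. Parameters without a range are
#' held at the [valve_params()] defaults.
#'
#' @param ranges Named list of `c(lo, hi)` ranges over any of `diameter`,
#'   `belly`, `free_edge`, `free_edge_height`, `commissure_height`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the call is deterministic given it.
#' @param method `"lhs"` (default) or `"uniform"`.
#' @return List of `n` [valve_params()] objects.
#' @export
sample_design_space <- function(ranges = default_design_ranges(), n, seed,
                                method = c("lhs", "uniform")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  for (r in ranges)
    if (length(r) != 2 || r[2] < r[1]) stop("each range must be c(lo, hi) with hi >= lo")
  d <- length(ranges)
  u01 <- withr::with_seed(seed, {
    if (method == "lhs") lhs::randomLHS(n, max(d, 1))
    else matrix(stats::runif(n * max(d, 1)), n, max(d, 1))
  })
  defaults <- valve_params()
  lapply(seq_len(n), function(s) {
    vals <- unclass(defaults)
    for (k in seq_along(ranges)) {
      nm <- names(ranges)[k]
      vals[[nm]] <- ranges[[k]][1] + diff(ranges[[k]]) * u01[s, k]
    }
    do.call(valve_params, vals)
  })
}
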