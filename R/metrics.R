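# Shape-comparison metrics between predicted and simulated deformed valves,
# coaptation statistics, and Green-Lagrange strain fields.

# deformed control points of both configurations as matched point matrices
.deformed_points <- function(x) {
  if (inherits(x, "deformed_valve")) {
    return(do.call(rbind, lapply(seq_len(3), function(k)
      .ctrl_mat(x$valve$leaflets[[k]]$control + x$u[[k]]))))
  }
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected a deformed_valve or an N x 3 point matrix")
}

#' Mean Euclidean distance between deformed configurations
#'
#' Mean over all control points of all leaflets of the pointwise Euclidean
#' distance between the predicted and true deformed positions (cm).
#'
#' @param pred,true `deformed_valve` objects or matched `N x 3` point
#'   matrices.
#' @return Distance in cm.
#' @export
mean_euclidean <- function(pred, true) {
  a <- .deformed_points(pred); b <- .deformed_points(true)
  if (!all(dim(a) == dim(b))) stop("point sets must have matching shapes")
  mean(.rownorm(a - b))
}

# symmetric Hausdorff distance between two point matrices, chunked so the
# cross-distance matrix never exceeds ~1e7 entries
.hausdorff_points <- function(a, b, chunk = 2000L) {
  b2 <- rowSums(b * b)
  directed <- function(x, y, y2) {
    worst <- 0
    for (s in split(seq_len(nrow(x)), ceiling(seq_len(nrow(x)) / chunk))) {
      xs <- x[s, , drop = FALSE]
      d2 <- outer(rowSums(xs * xs), y2, "+") - 2 * xs %*% t(y)
      worst <- max(worst, max(apply(d2, 1, min)))
    }
    sqrt(max(worst, 0))
  }
  a2 <- rowSums(a * a)
  max(directed(a, b, b2), directed(b, a, a2))
}

#' Symmetric Hausdorff distance between deformed valves
#'
#' Samples each deformed leaflet surface on a dense parameter grid (control
#' points do not lie on the surface) and returns the symmetric Hausdorff
#' distance between the pooled sample sets.
#'
#' @param pred,true `deformed_valve` objects, or `N x 3` point matrices (used
#'   as-is).
#' @param grid Per-leaflet sampling grid, default `c(50, 50)`.
#' @return Distance in cm.
#' @export
hausdorff_distance <- function(pred, true, grid = c(50, 50)) {
  if (any(grid < 1)) stop("sampling grid must be non-empty")
  sample_pts <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(deformed_surfaces(x), function(s) {
      gb <- .grid_basis(s, grid, midpoint = FALSE)
      gb$R %*% .ctrl_mat(s$control)
    }))
  }
  .hausdorff_points(sample_pts(pred), sample_pts(true))
}

#' Procrustes distance (rigid alignment residual)
#'
#' Root-mean-square deviation between the two matched control-point sets
#' after optimal translation and rotation (Kabsch alignment; no scaling), in
#' cm. Identical shapes in different rigid poses give 0.
#'
#' @param pred,true `deformed_valve` objects or matched `N x 3` matrices
#'   (>= 3 points).
#' @return RMSD in cm.
#' @export
procrustes_distance <- function(pred, true) {
  a <- .deformed_points(pred); b <- .deformed_points(true)
  if (!all(dim(a) == dim(b))) stop("point sets must have matching shapes")
  if (nrow(a) < 3) stop("Procrustes alignment needs at least 3 points")
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  sv <- svd(crossprod(ac, bc))
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- ac %*% t(rot) - bc
  sqrt(mean(rowSums(resid * resid)))
}

#' Coaptation-area error statistics
#'
#' @param predicted,true Equal-length numeric vectors (cm^2), n >= 2.
#' @return List with `rmse` (cm^2) and Pearson correlation `r` (`NA` with a
#'   warning if either vector has zero variance).
#' @export
coaptation_stats <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 2)
    stop("need two equal-length vectors with n >= 2")
  rmse <- sqrt(mean((predicted - true)^2))
  r <- if (stats::sd(predicted) == 0 || stats::sd(true) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else stats::cor(predicted, true)
  list(rmse = rmse, r = r)
}

#' Maximum in-plane principal Green-Lagrange strain field
#'
#' At each sample of a parameter grid, the covariant tangents of the
#' reference and deformed surfaces give the first fundamental forms
#' `A = [a_i . a_j]` and `Abar`; the in-plane Green-Lagrange strain is
#' `E = (Abar - A) / 2` and the maximum principal strain is the larger
#' eigenvalue of the generalized problem `E v = lambda A v`. A uniform
#' in-plane stretch by factor `s` gives `(s^2 - 1) / 2` everywhere; a rigid
#' motion gives 0. Points with a degenerate reference metric are returned as
#' `NA` and flagged.
#'
#' @param reference,deformed [nurbs_surface()] objects sharing a
#'   parametrisation.
#' @param grid Sampling grid `c(nu, nv)`, default `c(30, 30)`.
#' @return List with `strain` (`nu x nv` matrix), `u`, `v` (grid vectors),
#'   and `n_degenerate`.
#' @export
max_principal_strain <- function(reference, deformed, grid = c(30, 30)) {
  nu <- grid[1]; nv <- grid[2]
  us <- seq(0, 1, length.out = nu); vs <- seq(0, 1, length.out = nv)
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  dr <- surface_derivatives(reference, uu, vv, order = 1)
  dd <- surface_derivatives(deformed, uu, vv, order = 1)
  A11 <- rowSums(dr$Su * dr$Su); A12 <- rowSums(dr$Su * dr$Sv)
  A22 <- rowSums(dr$Sv * dr$Sv)
  B11 <- rowSums(dd$Su * dd$Su); B12 <- rowSums(dd$Su * dd$Sv)
  B22 <- rowSums(dd$Sv * dd$Sv)
  E11 <- (B11 - A11) / 2; E12 <- (B12 - A12) / 2; E22 <- (B22 - A22) / 2
  detA <- A11 * A22 - A12 * A12
  degen <- detA < .Machine$double.eps
  # larger root of det(E - lambda A) = 0:
  # detA lambda^2 - (E11 A22 + E22 A11 - 2 E12 A12) lambda + detE = 0
  bq <- E11 * A22 + E22 * A11 - 2 * E12 * A12
  detE <- E11 * E22 - E12 * E12
  disc <- pmax(bq * bq - 4 * detA * detE, 0)
  lam <- (bq + sqrt(disc)) / (2 * detA)
  lam[degen] <- NA_real_
  if (any(degen)) warning(sum(degen), " sample points have a degenerate metric")
  list(strain = matrix(lam, nu, nv), u = us, v = vs,
       n_degenerate = sum(degen))
}
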