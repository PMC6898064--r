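#' Leaflet material properties
#'
#' Isotropic model-scale material description of the chemically treated
#' tissue: three positive stiffness coefficients and the leaflet thickness.
#' The effective stiffness entering the load response is
#' `k_eff = c0 + c1 * c2`; `c1` is the coefficient swept in material
#' sensitivity studies.
#'
#' @param c0,c1,c2 Positive material coefficients (model-scale stiffness
#'   units).
#' @param thickness Leaflet thickness in cm (> 0).
#' @return Object of class `material_properties`.
#' @export
material_properties <- function(c0 = 500, c1 = 1000, c2 = 1.5,
                                thickness = 0.05) {
  if (any(c(c0, c1, c2, thickness) <= 0))
    stop("material coefficients and thickness must be positive")
  structure(list(c0 = c0, c1 = c1, c2 = c2, thickness = thickness),
            class = "material_properties")
}

#' Default material sampling ranges
#'
#' Chosen so the dimensionless load and the resulting displacement scale are
#' comparable to physiological valve closure on a 2.3 cm valve (peak
#' displacements of roughly 0.6-0.9 cm over the 70-90 mmHg diastolic range).
#'
#' @return Named list of `c(lo, hi)` ranges for `c0`, `c1`, `c2`, `thickness`.
#' @export
default_material_ranges <- function() {
  list(c0 = c(300, 700), c1 = c(500, 1500), c2 = c(1, 2),
       thickness = c(0.035, 0.065))
}

# cache of rational basis matrices on shared parameter grids; keyed by the
# full analytic signature (knots, degrees, weights, grid)
.vc_cache <- new.env(parent = emptyenv())

.grid_basis <- function(surface, ngrid, midpoint = TRUE) {
  nu <- ngrid[1]; nv <- ngrid[2]
  key <- paste(c("gb", dim(surface$control)[1:2], surface$degree, nu, nv,
                 midpoint,
                 format(surface$knots_u, digits = 17),
                 format(surface$knots_v, digits = 17),
                 format(as.vector(surface$weights), digits = 17)),
               collapse = "|")
  hit <- .vc_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (midpoint) {
    us <- (seq_len(nu) - 0.5) / nu
    vs <- (seq_len(nv) - 0.5) / nv
  } else {
    us <- seq(0, 1, length.out = nu)
    vs <- seq(0, 1, length.out = nv)
  }
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  rb <- .rational_basis(surface, uu, vv, deriv = 1)
  out <- list(R = rb$R, Ru = rb$Ru, Rv = rb$Rv, u = uu, v = vv)
  .vc_cache[[key]] <- out
  out
}

# smooth low-order random field on the (m, n) grid, zero on all edges,
# normalised to max |eta| = 1; deterministic given the seed
.noise_field <- function(m, n, seed) {
  si <- (seq_len(m) - 1) / (m - 1)
  sj <- (seq_len(n) - 1) / (n - 1)
  co <- withr::with_seed(seed, stats::rnorm(4))
  eta <- matrix(0, m, n)
  k <- 1
  for (a in 1:2) for (b in 1:2) {
    eta <- eta + co[k] * outer(sin(a * pi * si), sin(b * pi * sj))
    k <- k + 1
  }
  mx <- max(abs(eta))
  if (mx > 0) eta <- eta / mx
  eta
}

#' Simulate quasi-static valve closure
#'
#' Fast surrogate for the full shell-contact closure simulation. Each control
#' point moves radially toward the valve axis by
#' `dr = g * S * rho * r`, where `g(i, j) = sin(pi*i/(m-1)) * j/(n-1)` is a
#' displacement envelope vanishing identically on the attachment edges,
#' `S = L / (L + lambda0)` is a saturating response to the dimensionless load
#' `L = p * R / (k_eff * t)` with `k_eff = c0 + c1*c2` and `R = D/2`, and
#' `rho < 1` prevents axis crossing. Angular and axial coordinates are
#' unchanged, so leaflets never leave their 120-degree sector and cannot
#' interpenetrate. An optional smooth multiplicative perturbation
#' (`1 + noise_amp * eta`, `eta` a seeded low-order field shared by the three
#' leaflets) emulates run-to-run variability of the training corpus; with
#' `noise_seed = NULL` the response is the deterministic physics. The
#' coaptation area of the deformed configuration is computed with
#' [coaptation_area()].
#'
#' @param valve A [build_valve()] geometry.
#' @param material A [material_properties()].
#' @param pressure Transvalvular pressure in mmHg (> 0 required; physiological
#'   range 70-90).
#' @param noise_amp Perturbation amplitude (default 0.02); used only when
#'   `noise_seed` is given.
#' @param noise_seed Integer seed of the perturbation field, or `NULL` for
#'   the noiseless response.
#' @param lambda0 Load saturation constant (default 1; absorbs the pressure
#'   unit conversion).
#' @param rho Maximum closure fraction (< 1, default 0.95).
#' @param coapt_eps Contact proximity threshold in cm for the coaptation
#'   area (default 0.05).
#' @param coapt_u_min Motion threshold in cm excluding undisplaced points
#'   (default 0.01).
#' @param coapt_grid Coaptation sampling grid (default `c(64, 64)`).
#' @return Object of class `deformed_valve`: displacement grids `u` (list of
#'   three `m x n x 3` arrays, cm), `coaptation_area` (cm^2), and the inputs.
#' @export
simulate_closure <- function(valve, material, pressure,
                             noise_amp = 0.02, noise_seed = NULL,
                             lambda0 = 1, rho = 0.95,
                             coapt_eps = 0.05, coapt_u_min = 0.01,
                             coapt_grid = c(64, 64)) {
  if (pressure <= 0) stop("pressure must be positive")
  if (material$thickness <= 0) stop("thickness must be positive")
  dm <- dim(valve$leaflets[[1]]$control)
  m <- dm[1]; n <- dm[2]
  R <- valve$params$diameter / 2
  k_eff <- material$c0 + material$c1 * material$c2
  load <- pressure * R / (k_eff * material$thickness)
  S <- load / (load + lambda0)

  si <- (seq_len(m) - 1) / (m - 1)
  sj <- (seq_len(n) - 1) / (n - 1)
  g <- outer(sin(pi * si), sj)
  g[1, ] <- 0; g[m, ] <- 0; g[, 1] <- 0   # bitwise-zero fixed boundary

  fac <- g * S * rho
  if (!is.null(noise_seed) && noise_amp > 0) {
    eta <- .noise_field(m, n, noise_seed)
    fac <- fac * (1 + noise_amp * eta)
  }

  displacements <- lapply(valve$leaflets, function(lf) {
    u <- array(0, c(m, n, 3))
    u[, , 1] <- -fac * lf$control[, , 1]
    u[, , 2] <- -fac * lf$control[, , 2]
    u
  })
  out <- structure(list(u = displacements, coaptation_area = NA_real_,
                        valve = valve, material = material,
                        pressure = pressure, noise_amp = noise_amp,
                        noise_seed = noise_seed),
                   class = "deformed_valve")
  out$coaptation_area <- coaptation_area(out, eps = coapt_eps,
                                         u_min = coapt_u_min,
                                         grid = coapt_grid)
  out
}

#' @export
print.deformed_valve <- function(x, ...) {
  umax <- max(vapply(x$u, function(a) max(.rownorm(.ctrl_mat(a))), 0))
  cat(sprintf(
    "<deformed_valve> p = %.1f mmHg, max |u| = %.4f cm, coaptation = %.4f cm^2\n",
    x$pressure, umax, x$coaptation_area))
  invisible(x)
}

#' Deformed leaflet surfaces
#'
#' Reconstructs the three deformed NURBS surfaces (reference control points
#' plus displacements; weights and knots unchanged).
#'
#' @param deformed A `deformed_valve`.
#' @return List of three [nurbs_surface()] objects.
#' @export
deformed_surfaces <- function(deformed) {
  lapply(seq_len(3), function(k) {
    lf <- deformed$valve$leaflets[[k]]
    lf$control <- lf$control + deformed$u[[k]]
    lf
  })
}

#' Coaptation area of a deformed valve
#'
#' Measures the leaflet area pressed into contact at closure. The leaflet
#' reference surface is sampled on a midpoint grid; a sample contributes its
#' reference (material) area element when (i) its deformed position lies
#' within `eps` of either of the leaflet's two sector-boundary half-planes
#' (distance of a point at deformed radius r' and angle phi to the plane at
#' angle phi_b is `r' * |sin(phi - phi_b)|`) and (ii) its displacement
#' magnitude exceeds `u_min`, which excludes undisplaced attachment and
#' commissure points. Contributions are summed one-sidedly over the three
#' leaflets (no division by two). Using the material area element reflects
#' the near-inextensibility of leaflet tissue and makes the area response
#' monotone in the load.
#'
#' @param deformed A `deformed_valve`.
#' @param eps Contact proximity threshold in cm (> 0, default 0.05).
#' @param u_min Motion threshold in cm (default 0.01).
#' @param grid Midpoint sampling grid `c(nu, nv)` per leaflet (default
#'   `c(64, 64)`).
#' @return Coaptation area in cm^2 (>= 0).
#' @export
coaptation_area <- function(deformed, eps = 0.05, u_min = 0.01,
                            grid = c(64, 64)) {
  if (eps <= 0) stop("eps must be positive")
  total <- 0
  for (k in seq_len(3)) {
    lf <- deformed$valve$leaflets[[k]]
    gb <- .grid_basis(lf, grid, midpoint = TRUE)
    P <- .ctrl_mat(lf$control)
    U <- .ctrl_mat(deformed$u[[k]])
    pref <- gb$R %*% P
    su <- gb$Ru %*% P; sv <- gb$Rv %*% P
    dA <- .rownorm(.cross3(su, sv)) / (grid[1] * grid[2])
    ud <- gb$R %*% U
    umag <- .rownorm(ud)
    x <- pref + ud
    phi <- atan2(x[, 2], x[, 1])
    rp <- sqrt(x[, 1]^2 + x[, 2]^2)
    # sector centre from the leaflet's own reference geometry, so the
    # measure is invariant under leaflet relabelling and whole-valve rotation
    centre <- atan2(mean(lf$control[, , 2]), mean(lf$control[, , 1]))
    d1 <- rp * abs(sin(phi - (centre - pi / 3)))
    d2 <- rp * abs(sin(phi - (centre + pi / 3)))
    qual <- (pmin(d1, d2) <= eps) & (umag >= u_min)
    total <- total + sum(dA[qual])
  }
  total
}

#' Generate a synthetic closure dataset
#'
#' Emulates a corpus of valve-closure simulations at desk scale: design
#' parameters, material coefficients, and pressure are drawn by Latin
#' hypercube over their ranges, each valve is closed with
#' [simulate_closure()] (with a per-sample perturbation seed), and the
#' reference control-grid textures, displacement targets, and coaptation
#' areas are collected. Fully reproducible from `seed`. Design parameters are
#' stored as metadata only and are never part of the model inputs.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer master seed.
#' @param grid Control grid `c(m, n)` (default `c(8, 8)`).
#' @param degree Surface degrees (default cubic).
#' @param design_ranges See [default_design_ranges()].
#' @param material_ranges See [default_material_ranges()].
#' @param pressure_range Pressure range in mmHg (default `c(70, 90)`).
#' @param noise_amp Per-sample perturbation amplitude (default 0.02).
#' @param coapt_grid Coaptation sampling grid (default `c(64, 64)`).
#' @param path Optional file path; the dataset is serialised there with
#'   [saveRDS()].
#' @return Object of class `valve_dataset` with elements `inputs` (reference
#'   textures `n x 3 x m x n x 3`, pressure, material `n x 4`), `targets`
#'   (displacement `n x 3 x m x n x 3`, coaptation), and `meta`
#'   (design parameters, template surface, schema version, units, seeds).
#' @export
generate_dataset <- function(n, seed, grid = c(8, 8), degree = c(3, 3),
                             design_ranges = default_design_ranges(),
                             material_ranges = default_material_ranges(),
                             pressure_range = c(70, 90),
                             noise_amp = 0.02, coapt_grid = c(64, 64),
                             path = NULL) {
  if (n < 1) stop("n must be >= 1")
  dnames <- names(design_ranges)
  mnames <- c("c0", "c1", "c2", "thickness")
  ndim <- length(design_ranges) + 4 + 1
  drawn <- withr::with_seed(seed, {
    list(u = lhs::randomLHS(n, ndim),
         nseeds = sample.int(.Machine$integer.max - 1, n))
  })
  scale_col <- function(col, rng) rng[1] + diff(rng) * col
  m <- grid[1]; ng <- grid[2]
  X <- array(NA_real_, c(n, 3, m, ng, 3))
  Uarr <- array(NA_real_, c(n, 3, m, ng, 3))
  pres <- numeric(n)
  mat <- matrix(NA_real_, n, 4, dimnames = list(NULL, mnames))
  coapt <- numeric(n)
  dp <- matrix(NA_real_, n, 5, dimnames = list(NULL, c(
    "diameter", "belly", "free_edge", "free_edge_height", "commissure_height")))
  template <- NULL
  for (s in seq_len(n)) {
    vals <- unclass(valve_params())
    for (k in seq_along(design_ranges))
      vals[[dnames[k]]] <- scale_col(drawn$u[s, k], design_ranges[[k]])
    params <- do.call(valve_params, vals)
    off <- length(design_ranges)
    mvals <- vapply(seq_len(4), function(k)
      scale_col(drawn$u[s, off + k], material_ranges[[mnames[k]]]), 0)
    material <- material_properties(mvals[1], mvals[2], mvals[3], mvals[4])
    p <- scale_col(drawn$u[s, ndim], pressure_range)
    valve <- build_valve(params, grid, degree)
    if (is.null(template)) template <- valve$leaflets[[1]]
    dv <- simulate_closure(valve, material, p, noise_amp = noise_amp,
                           noise_seed = drawn$nseeds[s],
                           coapt_grid = coapt_grid)
    for (k in 1:3) {
      X[s, k, , , ] <- valve$leaflets[[k]]$control
      Uarr[s, k, , , ] <- dv$u[[k]]
    }
    pres[s] <- p
    mat[s, ] <- mvals
    coapt[s] <- dv$coaptation_area
    dp[s, ] <- unlist(params)
  }
  ds <- structure(list(
    inputs = list(reference = X, pressure = pres, material = mat),
    targets = list(displacement = Uarr, coaptation = coapt),
    meta = list(design_params = dp, grid = grid, degree = degree,
                template = template, fixed_mask = build_valve(
                  valve_params(), grid, degree)$fixed_mask,
                schema_version = "1.0",
                units = list(length = "cm", pressure = "mmHg",
                             area = "cm^2"),
                seed = seed, noise_amp = noise_amp,
                noise_seeds = drawn$nseeds, coapt_grid = coapt_grid,
                design_ranges = design_ranges,
                material_ranges = material_ranges,
                pressure_range = pressure_range)),
    class = "valve_dataset")
  if (!is.null(path)) saveRDS(ds, path)
  ds
}

#' @export
print.valve_dataset <- function(x, ...) {
  cat(sprintf(
    "<valve_dataset> %d samples, grid %d x %d, p in [%.0f, %.0f] mmHg\n",
    length(x$inputs$pressure), x$meta$grid[1], x$meta$grid[2],
    x$meta$pressure_range[1], x$meta$pressure_range[2]))
  invisible(x)
}

#' Extract one training record
#'
#' @param dataset A `valve_dataset`.
#' @param i Sample index.
#' @return List with `textures` (`3 x m x n x 3`), `pressure`, `material`,
#'   `displacement` (`3 x m x n x 3`), `coaptation`, `design_params`.
#' @export
dataset_sample <- function(dataset, i) {
  list(textures = dataset$inputs$reference[i, , , , , drop = TRUE],
       pressure = dataset$inputs$pressure[i],
       material = dataset$inputs$material[i, ],
       displacement = dataset$targets$displacement[i, , , , , drop = TRUE],
       coaptation = dataset$targets$coaptation[i],
       design_params = dataset$meta$design_params[i, ])
}
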