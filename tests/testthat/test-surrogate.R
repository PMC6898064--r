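default_valve <- function() build_valve(valve_params())

test_that("unloaded valve does not move and has zero coaptation", {
  v <- default_valve()
  dv <- simulate_closure(v, material_properties(), pressure = 1e-9)
  expect_lt(max(abs(unlist(dv$u))), 1e-9)
  expect_identical(dv$coaptation_area, 0)
  expect_error(simulate_closure(v, material_properties(), -5), "pressure")
})

test_that("attachment-edge displacement is bitwise zero for any input", {
  set.seed(4)
  for (rep in 1:5) {
    p <- valve_params(belly = runif(1), free_edge = runif(1))
    v <- build_valve(p)
    dv <- simulate_closure(v, material_properties(runif(1, 300, 700),
                                                  runif(1, 500, 1500),
                                                  runif(1, 1, 2),
                                                  runif(1, 0.035, 0.065)),
                           runif(1, 70, 90), noise_seed = rep)
    for (k in 1:3) {
      u <- dv$u[[k]]
      expect_identical(u[1, , ], array(0, c(8, 3)))
      expect_identical(u[8, , ], array(0, c(8, 3)))
      expect_identical(u[, 1, ], array(0, c(8, 3)))
    }
  }
})

test_that("interior displacement follows the saturating load formula", {
  # one control point with envelope g = 1, reference radius 1 cm, S = 0.5:
  # radial closure dr = g * S * rho * r = 0.475 cm for rho = 0.95
  v <- build_valve(valve_params(diameter = 2, belly = 0), grid = c(9, 9))
  mat <- material_properties(c0 = 500, c1 = 1000, c2 = 1.5, thickness = 0.05)
  k_eff <- 500 + 1000 * 1.5
  p <- k_eff * 0.05 / 1    # load = p*R/(k_eff*t) = 1 -> S = 0.5
  dv <- simulate_closure(v, mat, p)
  # midcolumn (i = 5) free edge (j = 9): g = sin(pi/2) * 1 = 1, r = 1
  u <- dv$u[[1]][5, 9, ]
  expect_equal(sqrt(sum(u^2)), 0.475, tolerance = 1e-12)
  # displacement points radially inward
  x <- v$leaflets[[1]]$control[5, 9, ]
  expect_lt(sum(u[1:2] * x[1:2]), 0)
  expect_identical(u[3], 0)
})

test_that("closure is equivariant under 120-degree rotation", {
  v <- build_valve(valve_params(belly = 0.6))
  v_rot <- v
  v_rot$leaflets <- v$leaflets[c(2, 3, 1)]   # rotate + relabel
  a <- simulate_closure(v, material_properties(), 80, noise_seed = 10)
  b <- simulate_closure(v_rot, material_properties(), 80, noise_seed = 10)
  for (k in 1:3)
    expect_lt(max(abs(a$u[[k %% 3 + 1]] - b$u[[k]])), 1e-12)
  expect_equal(a$coaptation_area, b$coaptation_area, tolerance = 1e-12)
})

test_that("no deformed sample point leaves its leaflet's angular sector", {
  set.seed(8)
  for (rep in 1:3) {
    v <- build_valve(valve_params(belly = runif(1)))
    dv <- simulate_closure(v, material_properties(thickness = 0.035), 90,
                           noise_seed = rep)
    for (k in 1:3) {
      surf <- deformed_surfaces(dv)[[k]]
      pts <- evaluate_surface(surf, rep(seq(0, 1, length.out = 25), 25),
                              rep(seq(0, 1, length.out = 25), each = 25))
      centre <- 2 * pi * (k - 1) / 3
      dphi <- atan2(pts[, 2], pts[, 1]) - centre
      dphi <- atan2(sin(dphi), cos(dphi))   # wrap to (-pi, pi]
      r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
      expect_true(all(abs(dphi[r > 1e-9]) <= pi / 3 + 1e-9))
    }
  }
})

test_that("coaptation area responds monotonically to load factors", {
  v <- default_valve()
  mat <- material_properties()
  a_p <- vapply(seq(70, 90, length.out = 20), function(p)
    simulate_closure(v, mat, p)$coaptation_area, 0)
  expect_true(all(diff(a_p) >= 0))
  a_c1 <- vapply(seq(500, 1500, length.out = 20), function(c1)
    simulate_closure(v, material_properties(c1 = c1), 80)$coaptation_area, 0)
  expect_true(all(diff(a_c1) <= 0))
  a_t <- vapply(seq(0.035, 0.065, length.out = 20), function(t)
    simulate_closure(v, material_properties(thickness = t), 80)$coaptation_area, 0)
  expect_true(all(diff(a_t) <= 0))
})

test_that("coaptation area vanishes in the eps -> 0 limit", {
  v <- default_valve()
  dv <- simulate_closure(v, material_properties(), 80)
  a <- vapply(c(0.05, 0.02, 0.005, 1e-4), function(e)
    coaptation_area(dv, eps = e), 0)
  expect_true(all(diff(a) <= 0))
  expect_identical(a[4], 0)
  expect_error(coaptation_area(dv, eps = 0), "eps")
})

test_that("coaptation quadrature matches a dense-sampling oracle", {
  # hand-built configuration: the free-edge half of leaflet 1 is pressed
  # exactly onto its lower sector-boundary plane, giving a broad, well
  # resolved contact region
  v <- build_valve(valve_params())
  m <- 8; n <- 8
  u1 <- array(0, c(m, n, 3))
  ctrl1 <- v$leaflets[[1]]$control
  for (i in 1:m) for (j in 1:n) {
    if (j > n / 2) {
      r <- sqrt(sum(ctrl1[i, j, 1:2]^2))
      u1[i, j, 1:2] <- r * c(cos(-pi / 3), sin(-pi / 3)) - ctrl1[i, j, 1:2]
    }
  }
  dv <- structure(list(u = list(u1, array(0, c(m, n, 3)),
                                array(0, c(m, n, 3))),
                       valve = v),
                  class = "deformed_valve")
  a_prod <- coaptation_area(dv, grid = c(160, 160))
  # independent dense evaluation: 500 x 500 midpoints, reference area
  # elements from finite differences of the reference surface
  a_dense <- 0
  ng <- 500
  us <- (seq_len(ng) - 0.5) / ng
  for (k in 1:3) {
    lf <- dv$valve$leaflets[[k]]
    centre <- atan2(mean(lf$control[, , 2]), mean(lf$control[, , 1]))
    dsurf <- deformed_surfaces(dv)[[k]]
    usurf <- lf; usurf$control <- dv$u[[k]]
    for (chunk in split(seq_len(ng), ceiling(seq_len(ng) / 50))) {
      uu <- rep(us, times = length(chunk))
      vv <- rep(us[chunk], each = ng)
      dref <- surface_derivatives(lf, uu, vv)
      dA <- sqrt(rowSums((cbind(
        dref$Su[, 2] * dref$Sv[, 3] - dref$Su[, 3] * dref$Sv[, 2],
        dref$Su[, 3] * dref$Sv[, 1] - dref$Su[, 1] * dref$Sv[, 3],
        dref$Su[, 1] * dref$Sv[, 2] - dref$Su[, 2] * dref$Sv[, 1]))^2)) / ng^2
      ud <- evaluate_surface(usurf, uu, vv)
      xd <- evaluate_surface(dsurf, uu, vv)
      umag <- sqrt(rowSums(ud^2))
      phi <- atan2(xd[, 2], xd[, 1])
      rp <- sqrt(xd[, 1]^2 + xd[, 2]^2)
      d <- pmin(rp * abs(sin(phi - (centre - pi / 3))),
                rp * abs(sin(phi - (centre + pi / 3))))
      a_dense <- a_dense + sum(dA[d <= 0.05 & umag >= 0.01])
    }
  }
  expect_lt(abs(a_prod - a_dense) / a_dense, 0.02)
})

test_that("dataset generation is reproducible and physically bounded", {
  d1 <- generate_dataset(20, seed = 31, coapt_grid = c(32, 32))
  d2 <- generate_dataset(20, seed = 31, coapt_grid = c(32, 32))
  expect_identical(d1$inputs, d2$inputs)
  expect_identical(d1$targets, d2$targets)
  expect_true(all(d1$inputs$pressure >= 70 & d1$inputs$pressure <= 90))
  # max displacement bounded by the closure cap rho * r < R
  umag <- sqrt(d1$targets$displacement[, , , , 1]^2 +
                 d1$targets$displacement[, , , , 2]^2 +
                 d1$targets$displacement[, , , , 3]^2)
  expect_true(all(apply(umag, 1, max) < 2.3 / 2))
  expect_true(all(d1$targets$coaptation >= 0))
  # round trip through the serialised form
  path <- withr::local_tempfile(fileext = ".rds")
  d3 <- generate_dataset(5, seed = 2, coapt_grid = c(32, 32), path = path)
  expect_identical(readRDS(path)$targets, d3$targets)
  smp <- dataset_sample(d3, 3)
  expect_identical(dim(smp$textures), c(3L, 8L, 8L, 3L))
  expect_identical(smp$pressure, d3$inputs$pressure[3])
})
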