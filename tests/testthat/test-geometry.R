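geom <- stenosis_geometry(R0 = 1, lam = 0.4, L0 = 1)

test_that("radius profile matches the cosine bump and is continuous", {
  expect_equal(radius_profile(0, geom), 0.6)            # throat: R0 - lam
  expect_equal(radius_profile(1 / 8, geom), 0.8)        # half-depth station
  # junction continuity: both branches meet at R0 to machine precision
  x_j <- 1 / 4
  inside_limit <- 1 - (0.4 / 2) * (1 + cos(4 * pi * (x_j - 1e-12)))
  expect_equal(inside_limit, radius_profile(x_j, geom), tolerance = 1e-9)
  expect_identical(radius_profile(x_j, geom), 1)
  expect_identical(radius_profile(-x_j, geom), 1)
  expect_identical(radius_profile(5, geom), 1)
  # global minimum sits at the throat
  xs <- seq(-0.5, 0.5, length.out = 2001)
  rs <- radius_profile(xs, geom)
  expect_equal(min(rs), 0.6)
  expect_equal(xs[which.min(rs)], 0)
})

test_that("geometry validation rejects impossible stenoses", {
  expect_error(stenosis_geometry(R0 = 1, lam = 1.2, L0 = 1), "lam")
  expect_error(stenosis_geometry(R0 = 1, lam = 0, L0 = 1), "lam")
  expect_error(stenosis_geometry(R0 = -1, lam = 0.2, L0 = 1), "positive")
})

scales <- dimensional_scales(u0 = 0.04, nu_f = 1e-5, mu_f = 1.05e-2,
                             Tw = 315, Tinf = 310)

test_that("similarity coordinate maps wall and unit stations correctly", {
  R <- radius_profile(0.3, geom)
  expect_equal(similarity_coordinate(R, 0.3, geom, scales), 0)
  ell <- sqrt(scales$nu_f * geom$L0 / scales$u0)   # boundary-layer scale
  r1 <- sqrt(R^2 + 2 * R * ell)
  expect_equal(similarity_coordinate(r1, 0.3, geom, scales), 1,
               tolerance = 1e-12)
  expect_error(similarity_coordinate(R - 1e-3, 0.3, geom, scales), "wall")
  # direct hand evaluation: R = 1, r = 1.5, u0/(nu_f L0) = 4
  sc4 <- dimensional_scales(u0 = 4e-5, nu_f = 1e-5, mu_f = 1e-2,
                            Tw = 315, Tinf = 310)
  g1 <- stenosis_geometry(R0 = 1, lam = 0.1, L0 = 1)
  expect_equal(similarity_coordinate(1.5, 0.4, g1, sc4), 1.25,
               tolerance = 1e-12)
})

test_that("reconstructed fields honor wall and far-field boundary values", {
  sol <- crane_solution()
  x <- 0.35                                  # straight segment: R = R0
  R <- radius_profile(x, geom)
  far <- sqrt(R^2 + 2 * R * 40 * sqrt(scales$nu_f * geom$L0 / scales$u0))
  df <- reconstruct_fields(sol, geom, scales, x_grid = x,
                           r_grid = c(R, (R + far) / 2, far))
  expect_equal(df$u[1], scales$u0 * x / geom$L0, tolerance = 1e-10)
  expect_equal(df$v[1], 0, tolerance = 1e-10)
  expect_equal(df$T[1], scales$Tw)
  n <- nrow(df)
  expect_lt(abs(df$u[n]), 1e-8 * scales$u0)
  expect_equal(df$T[n], scales$Tinf, tolerance = 1e-6)
})

test_that("reconstructed fields satisfy continuity at fixed radius", {
  # finite-difference residual of (1/r) [d(ru)/dx + d(rv)/dr] over a patch in
  # the straight segment, checked against the axial-flux scale
  sol <- crane_solution()
  x_grid <- seq(0.3, 0.34, length.out = 50)
  R <- 1
  ell <- sqrt(scales$nu_f * geom$L0 / scales$u0)
  r_grid <- sqrt(R^2 + 2 * R * seq(0.02, 3, length.out = 50) * ell)
  df <- reconstruct_fields(sol, geom, scales, x_grid, r_grid)
  u <- matrix(df$u, nrow = length(r_grid))   # r varies fastest within x
  v <- matrix(df$v, nrow = length(r_grid))
  r <- r_grid
  dx <- diff(x_grid)[1]
  ru_x <- (r * u[, 3:50] - r * u[, 1:48]) / (2 * dx)     # d(ru)/dx
  rv <- r * v
  drv <- apply(rv, 2, function(col) {
    c(NA, (col[3:50] - col[1:48]) / (r[3:50] - r[1:48]), NA)
  })
  resid <- ru_x[2:49, ] + drv[2:49, 2:49]
  scale_ref <- max(abs(ru_x), na.rm = TRUE)
  expect_lt(max(abs(resid), na.rm = TRUE) / scale_ref, 1e-3)
})
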