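test_that("momentum right-hand side matches hand-evaluated wall states", {
  # classical limit at the wall: F''' = F'^2 - F F'' gives 1 at (0, 1, -1)
  p <- params()
  expect_equal(momentum_rhs(0, c(0, 1, -1), p), c(1, -1, 1))
  # Darcy drag adds beta * F'
  p_beta <- params(beta = 0.5)
  expect_equal(momentum_rhs(0, c(0, 1, -1), p_beta)[3], 1.5)
  # full Sisko/curvature numerator and denominator at the wall
  p_sisko <- params(S = 1, gamma = 0.1, n = 2)
  expect_equal(momentum_rhs(0, c(0, 1, -1), p_sisko)[3], 1.3 / 3,
               tolerance = 1e-14)
})

test_that("energy right-hand side matches hand-evaluated states", {
  # Ec = 0, gamma = 0: theta'' = -Pr * F * theta'
  p <- params(Pr = 2)
  expect_equal(energy_rhs(0, c(1, 0, -1, 1, -0.5), p), c(-0.5, 1))
  # constant theta solves the source-free interior equation
  expect_equal(energy_rhs(0.7, c(0.5, 0.4, -0.3, 1, 0), params(Pr = 5))[2], 0)
  # curvature plus dissipation at the wall
  p_ec <- params(gamma = 0.1, Ec = 0.1, Pr = 1)
  expect_equal(energy_rhs(0, c(0, 1, -1, 1, -1), p_ec)[2], 0.1,
               tolerance = 1e-14)
})

test_that("with S = 0 the momentum equation is independent of the power-law index", {
  set.seed(42)
  for (i in 1:20) {
    st <- c(runif(1, 0, 2), runif(1, 0, 1), -runif(1, 0, 2))
    eta <- runif(1, 0, 5)
    p1 <- params(gamma = 0.2, beta = 0.3, n = 0.7, phi = 0.05)
    p2 <- params(gamma = 0.2, beta = 0.3, n = 2.6, phi = 0.05)
    expect_equal(momentum_rhs(eta, st, p1), momentum_rhs(eta, st, p2),
                 tolerance = 1e-15)
  }
})

test_that("momentum RHS is continuous across the shear clamp for n >= 1", {
  p <- params(S = 0.4, gamma = 0.1, n = 1.5)
  at_zero <- momentum_rhs(1, c(0.5, 0.2, 0), p)[3]
  gaps <- vapply(10^(-(6:10)), function(eps)
    abs(momentum_rhs(1, c(0.5, 0.2, -eps), p)[3] - at_zero), numeric(1))
  expect_true(all(diff(gaps) < 0))   # gap shrinks as z3 -> 0-
  expect_lt(gaps[length(gaps)], 1e-5)
})

test_that("unit factors and vanishing groups recover the classical system", {
  set.seed(7)
  p <- params(Pr = 3)
  for (i in 1:20) {
    z <- c(runif(1, 0, 2), runif(1, -0.2, 1), -runif(1, 0, 2),
           runif(1, 0, 1), -runif(1, 0, 1))
    expect_equal(momentum_rhs(1.3, z, p)[3], z[2]^2 - z[1] * z[3],
                 tolerance = 1e-14)
    expect_equal(energy_rhs(1.3, z, p)[2], -3 * z[1] * z[5],
                 tolerance = 1e-14)
  }
})

test_that("shear clamp keeps extreme Sisko states finite", {
  # positive (reversed) shear is clamped inside the fractional powers, so
  # even extreme consistency ratios produce finite, real right-hand sides
  p <- params(S = 1e12, n = 0.5)
  expect_no_error(momentum_rhs(0, c(0, 1, 1e-2), p))
  expect_true(is.finite(momentum_rhs(0, c(0, 1, 1e-2), p)[3]))
  expect_true(is.finite(momentum_rhs(0, c(0, 1, -1), p)[3]))
})

test_that("dimensionless groups follow their defining scales", {
  g <- stenosis_geometry(R0 = 2e-3, lam = 5e-4, L0 = 0.04)
  sc <- dimensional_scales(u0 = 0.05, nu_f = 3.2e-6, mu_f = 3.36e-3,
                           Tw = 315, Tinf = 310, K = 1e-8,
                           alpha_sisko = 0, n = 2)
  p <- dimensionless_groups(sc, x = 0.005, geometry = g,
                            composition = nanofluid(phi = 0))
  expect_equal(p$S, 0)                         # Newtonian limit alpha = 0
  expect_equal(p$beta, sc$mu_f * g$L0 / (1050 * sc$u0 * sc$K))
  expect_equal(p$Pr, sc$mu_f * 3617 / 0.52)
  expect_equal(p$Ec, sc$u0^2 * 0.005^2 / (3617 * 5 * g$L0^2))
  # permeability -> infinity removes the Darcy group
  sc_free <- dimensional_scales(u0 = 0.05, nu_f = 3.2e-6, mu_f = 3.36e-3,
                                Tw = 315, Tinf = 310, K = Inf)
  expect_equal(dimensionless_groups(sc_free, x = 0.005, geometry = g)$beta, 0)
  # gamma = 1 when the radius equals the boundary-layer length scale
  R_unit <- sqrt(sc$nu_f * g$L0 / sc$u0)
  expect_equal(dimensionless_groups(sc, x = 0.005, R = R_unit, L0 = g$L0)$gamma,
               1, tolerance = 1e-14)
  expect_error(dimensionless_groups(sc, x = -1, geometry = g), "positive")
})

test_that("parameter validation rejects out-of-domain groups", {
  expect_error(params(S = -0.1), "nonnegative")
  expect_error(params(n = 0), "positive")
  expect_error(params(Pr = -1), "positive")
})
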