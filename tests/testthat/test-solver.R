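test_that("classical stretching-sheet closed form is recovered", {
  sol <- crane_solution()
  expect_equal(sol$fpp_wall, -1, tolerance = 1e-6)
  on_grid <- sol$eta <= 15
  expect_lt(max(abs(sol$F[on_grid] - (1 - exp(-sol$eta[on_grid])))), 1e-6)
  expect_lt(max(abs(sol$Fp[on_grid] - exp(-sol$eta[on_grid]))), 1e-6)
})

test_that("wall temperature gradient matches the quadrature closed form", {
  # for gamma = S = Ec = 0, phi = 0, Pr = 1 the temperature equation
  # integrates in closed form along F = 1 - exp(-eta):
  # -theta'(0) = 1 / integral_0^inf exp(-(s - 1 + exp(-s))) ds = 1/(e - 1)
  sol <- crane_solution()
  expect_equal(sol$thetap_wall, -1 / (exp(1) - 1), tolerance = 1e-7)
})

test_that("superposition and direct shooting agree on the energy solve", {
  p <- params(S = 0.2, gamma = 0.1, beta = 0.2, Pr = 5, Ec = 0.2, phi = 0.05)
  s <- solver_settings()
  mom <- solve_momentum(p, s)
  sup <- solve_energy(p, mom, s, method = "superposition")
  sht <- solve_energy(p, mom, s, method = "shooting")
  expect_equal(sup$thetap_wall, sht$thetap_wall, tolerance = 1e-7)
  expect_lt(max(abs(sup$theta - sht$theta)), 1e-6)
})

test_that("source-free temperature profile is monotone and bounded", {
  sol <- crane_solution()
  expect_equal(sol$theta[1], 1)
  expect_lt(abs(sol$theta[length(sol$theta)]), 1e-6)
  expect_true(all(diff(sol$theta) <= 1e-10))
  expect_true(all(sol$theta <= 1 + 1e-12 & sol$theta >= -1e-8))
})

test_that("conduction-dominated limit flattens the wall gradient", {
  s <- solver_settings()
  mom <- solve_momentum(params(), s)
  slow <- solve_energy(params(Pr = 0.05), mom, s)
  fast <- solve_energy(params(Pr = 1), mom, s)
  expect_lt(abs(slow$thetap_wall), abs(fast$thetap_wall))
})

test_that("domain doubling converges the wall derivatives", {
  sol <- curved_solution()
  h <- sol$diagnostics$doubling_history
  expect_gte(nrow(h), 2)
  k <- nrow(h)
  expect_lt(abs(h[k, "fpp_wall"] - h[k - 1, "fpp_wall"]), 1e-7)
  expect_lt(abs(h[k, "thetap_wall"] - h[k - 1, "thetap_wall"]), 1e-7)
  expect_false(sol$diagnostics$eta_max_cap_hit)
})

test_that("converged solutions satisfy the boundary conditions and shape invariants", {
  for (sol in list(crane_solution(), curved_solution())) {
    n <- length(sol$eta)
    expect_equal(sol$F[1], 0)
    expect_equal(sol$Fp[1], 1)
    expect_equal(sol$theta[1], 1)
    expect_lte(abs(sol$Fp[n]), 1e-8)
    expect_lte(abs(sol$theta[n]), 1e-6)
    expect_true(all(diff(sol$Fp) <= 1e-6))     # monotone nonincreasing
    expect_true(all(sol$Fpp <= 1e-8))          # no shear reversal
  }
})

test_that("momentum solve reports diagnostics and honors hints", {
  p <- params(gamma = 0.1)
  s <- solver_settings()
  m1 <- solve_momentum(p, s)
  expect_lt(m1$diagnostics$momentum_residual, 1e-5)
  m2 <- solve_momentum(p, s, fpp0_hint = m1$fpp_wall)
  expect_equal(m1$fpp_wall, m2$fpp_wall, tolerance = 1e-9)
})

test_that("solution CSV export round-trips the grid", {
  sol <- crane_solution()
  path <- withr::local_tempfile(fileext = ".csv")
  write_solution_csv(sol, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("eta", "F", "Fp", "Fpp", "theta", "theta_p"))
  expect_equal(df$F, sol$F, tolerance = 1e-12)
})
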