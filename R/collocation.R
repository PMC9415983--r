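# Independent global collocation solver used to cross-validate the shooting
# scheme: Chebyshev spectral differentiation + damped Newton for the
# momentum equation, direct linear solve for the temperature equation.

# Chebyshev differentiation matrix on the Gauss-Lobatto nodes x_j = cos(j*pi/N)
.cheb <- function(N) {
  if (N == 0) return(list(D = matrix(0, 1, 1), x = 1))
  x <- cos(pi * (0:N) / N)
  c_w <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- outer(c_w, 1 / c_w) / (dX + diag(N + 1))
  D <- D - diag(rowSums(D))
  list(D = D, x = x)
}

#' Solve the similarity BVP by Chebyshev collocation
#'
#' Global spectral collocation on the truncated domain `[0, eta_max]`:
#' the momentum equation is discretized on Chebyshev-Gauss-Lobatto nodes and
#' solved by damped Newton with an analytic Jacobian, seeded from the
#' classical stretching-sheet closed form `F = (1 - exp(-a eta))/a`; the
#' temperature equation, linear in `theta` for fixed `F`, is then solved
#' directly as one linear system. This path shares no code with the shooting
#' solver and serves as its independent cross-check.
#'
#' @param p a [sisko_params()] object.
#' @param eta_max far-field truncation.
#' @param n_nodes number of collocation nodes.
#' @param tol Newton residual tolerance (max norm).
#' @param max_iter maximum Newton iterations.
#' @return List with `fpp_wall`, `thetap_wall`, node vectors `eta`, `F`,
#'   `Fp`, `Fpp`, `theta`, `theta_p`, and `newton_iterations`.
#' @export
solve_collocation <- function(p, eta_max = 15, n_nodes = 121, tol = 1e-10,
                              max_iter = 60) {
  N <- n_nodes - 1
  ch <- .cheb(N)
  eta <- eta_max * (1 - ch$x) / 2          # eta[1] = 0 (wall), eta[N+1] = L
  D  <- -(2 / eta_max) * ch$D
  D2 <- D %*% D
  D3 <- D2 %*% D

  f <- p$phi_factors
  g <- p$gamma
  c1 <- 1 + 2 * eta * g
  cs <- c1^((p$n - 1) / 2)

  residual <- function(F) {
    F1 <- drop(D %*% F); F2 <- drop(D2 %*% F); F3 <- drop(D3 %*% F)
    shear <- pmax(-F2, .shear_eps)
    r <- c1 * F3 + 2 * g * F2 +
      f$phi1 * p$S * cs * (p$n * c1 * shear^(p$n - 1) * F3 - g * shear^p$n) -
      p$beta * F1 - f$phi1 * f$phi2 * (F1^2 - F * F2)
    r[1] <- F[1]                 # F(0) = 0
    r[2] <- F1[1] - 1            # F'(0) = 1
    r[N + 1] <- F1[N + 1]        # F'(L) = 0
    list(r = r, F1 = F1, F2 = F2, F3 = F3, shear = shear)
  }

  jacobian <- function(F, parts) {
    F1 <- parts$F1; F2 <- parts$F2; F3 <- parts$F3; shear <- parts$shear
    clamped <- (-F2) < .shear_eps
    a3 <- c1 + f$phi1 * p$S * p$n * cs * c1 * shear^(p$n - 1)
    dshear <- ifelse(clamped, 0, -1)   # d(shear)/d(F2)
    a2 <- 2 * g +
      f$phi1 * p$S * cs *
        (p$n * c1 * (p$n - 1) * shear^(p$n - 2) * dshear * F3 -
           g * p$n * shear^(p$n - 1) * dshear) +
      f$phi1 * f$phi2 * F
    a1 <- -p$beta - 2 * f$phi1 * f$phi2 * F1
    a0 <- f$phi1 * f$phi2 * F2
    J <- a3 * D3 + a2 * D2 + a1 * D + diag(a0)
    J[1, ] <- 0; J[1, 1] <- 1
    J[2, ] <- D[1, ]
    J[N + 1, ] <- D[N + 1, ]
    J
  }

  a <- sqrt(max(f$phi1 * f$phi2, 0.5))
  F <- (1 - exp(-a * eta)) / a
  parts <- residual(F)
  rnorm0 <- max(abs(parts$r))
  iter <- 0
  while (rnorm0 > tol && iter < max_iter) {
    J <- jacobian(F, parts)
    step <- solve(J, -parts$r)
    lambda <- 1
    repeat {
      F_new <- F + lambda * step
      parts_new <- residual(F_new)
      rn <- max(abs(parts_new$r))
      if (is.finite(rn) && (rn < rnorm0 || lambda < 1 / 64)) break
      lambda <- lambda / 2
    }
    F <- F_new; parts <- parts_new; rnorm0 <- rn
    iter <- iter + 1
  }
  if (rnorm0 > 1e-6)
    stop("collocation Newton failed to converge: residual ", format(rnorm0))

  F1 <- parts$F1; F2 <- parts$F2
  shear <- parts$shear

  # temperature: c1 theta'' + (2 g + phi3 Pr F / phi4) theta' = -(Pr Ec/phi4) Phi
  phi1_fac <- if (p$dissipation_phi1 == "divide_by_phi1") 1 / f$phi1 else f$phi1
  e <- if (p$dissipation_exponent == "physical_n_plus_1") p$n + 1 else p$n
  diss <- c1 * phi1_fac * F2^2 + p$S * c1^((p$n + 1) / 2) * shear^e
  A <- c1 * D2 + (2 * g + f$phi3 * p$Pr * F / f$phi4) * D
  b <- -(p$Pr * p$Ec / f$phi4) * diss
  A[1, ] <- 0; A[1, 1] <- 1; b[1] <- 1          # theta(0) = 1
  A[N + 1, ] <- 0; A[N + 1, N + 1] <- 1; b[N + 1] <- 0  # theta(L) = 0
  theta <- drop(solve(A, b))
  theta_p <- drop(D %*% theta)

  list(fpp_wall = F2[1], thetap_wall = theta_p[1],
       eta = eta, F = F, Fp = F1, Fpp = F2,
       theta = theta, theta_p = theta_p,
       newton_iterations = iter)
}

#' Cross-validate shooting against collocation
#'
#' Solves the same boundary value problem on the same truncated domain with
#' the shooting scheme and with the independent Chebyshev collocation solver,
#' and reports the absolute differences of the wall derivatives.
#'
#' @inheritParams solve_collocation
#' @param s [solver_settings()] for the shooting side; its `eta_max` is the
#'   shared truncation.
#' @param n_nodes collocation nodes.
#' @return List with `delta_fpp`, `delta_thetap`, and the two solutions
#'   (`shooting`, `collocation`). Collocation failure is reported in the
#'   `collocation_error` field rather than raised.
#' @export
cross_validate <- function(p, s = solver_settings(), n_nodes = 121) {
  mom <- solve_momentum(p, s)
  shoot <- solve_energy(p, mom, s)
  coll <- tryCatch(
    solve_collocation(p, eta_max = s$eta_max, n_nodes = n_nodes),
    error = function(e) e)
  if (inherits(coll, "error"))
    return(list(delta_fpp = NA_real_, delta_thetap = NA_real_,
                shooting = shoot, collocation = NULL,
                collocation_error = conditionMessage(coll)))
  list(delta_fpp = abs(shoot$fpp_wall - coll$fpp_wall),
       delta_thetap = abs(shoot$thetap_wall - coll$thetap_wall),
       shooting = shoot, collocation = coll,
       collocation_error = NULL)
}
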