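# Similarity-reduced model: dimensionless groups and first-order ODE
# right-hand sides for the momentum and energy equations.

# shear clamp for fractional powers of (-F''); F'' <= 0 on physical solutions
.shear_eps <- 1e-12
.denom_min <- 1e-10

#' Dimensionless model parameters
#'
#' Collects the dimensionless groups of the similarity-reduced Sisko
#' nanofluid system together with the nanoparticle property factors and the
#' model-variant flags.
#'
#' The groups are:
#' \describe{
#'   \item{S}{Sisko material parameter — ratio of the power-law consistency
#'     to the Newtonian viscosity on the wall shear-rate scale. `S = 0` is
#'     the Newtonian limit.}
#'   \item{gamma}{curvature parameter — boundary-layer length scale over the
#'     local vessel radius; `gamma = 0` is the flat (planar) limit.}
#'   \item{beta}{porosity (Darcy drag) parameter `mu_f L0 / (rho_f u0 K)`.}
#'   \item{n}{power-law index of the Sisko shear-rate term (`> 0`).}
#'   \item{Pr}{base-fluid Prandtl number `mu_f Cp_f / k_f`; nanoparticle
#'     effects enter only through `phi3` and `phi4`, never through Pr.}
#'   \item{Ec}{Eckert number — kinetic energy over wall-to-ambient enthalpy
#'     difference; scales viscous-dissipation heating.}
#' }
#'
#' Defaults are the package's documented held-fixed set used for trend
#' studies (`n = 2, Pr = 21, Ec = 0.1, S = 0.1, beta = 0.1, gamma = 0.1,
#' phi = 0.01` with blood/gold properties).
#'
#' Variant flags select between readings of ambiguously grouped terms; see
#' the methods vignette. Defaults: dissipation exponent `n + 1`
#' (`"physical_n_plus_1"`), dissipation carries `1/phi1`
#' (`"divide_by_phi1"`), and the skin-friction `1/phi1` multiplies only the
#' Newtonian term (`"phi1_on_first_term_only"`).
#'
#' @param S,gamma,beta,n,Pr,Ec dimensionless groups (see Details).
#' @param composition a [nanofluid()]; its [phi_factors()] are stored.
#' @param phi_factors optionally, precomputed [phi_factors()] (overrides
#'   `composition`).
#' @param dissipation_exponent `"physical_n_plus_1"` or `"as_printed_n"`.
#' @param dissipation_phi1 `"divide_by_phi1"` or `"multiply_by_phi1"`.
#' @param cf_grouping `"phi1_on_first_term_only"` or `"phi1_on_both_terms"`.
#' @return Object of class `"sisko_params"`.
#' @examples
#' p <- sisko_params(S = 0, gamma = 0.1, beta = 0,
#'                   composition = nanofluid(phi = 0))
#' @export
sisko_params <- function(S = 0.1, gamma = 0.1, beta = 0.1, n = 2,
                         Pr = 21, Ec = 0.1,
                         composition = nanofluid(phi = 0.01),
                         phi_factors = NULL,
                         dissipation_exponent = c("physical_n_plus_1",
                                                  "as_printed_n"),
                         dissipation_phi1 = c("divide_by_phi1",
                                              "multiply_by_phi1"),
                         cf_grouping = c("phi1_on_first_term_only",
                                         "phi1_on_both_terms")) {
  if (is.null(phi_factors)) phi_factors <- phi_factors(composition)
  if (!inherits(phi_factors, "phi_factors"))
    stop("`phi_factors` must be a phi_factors() object")
  if (S < 0 || gamma < 0 || beta < 0 || Ec < 0)
    stop("S, gamma, beta and Ec must be nonnegative")
  if (n <= 0) stop("power-law index `n` must be positive")
  if (Pr <= 0) stop("Prandtl number `Pr` must be positive")
  structure(list(
    S = S, gamma = gamma, beta = beta, n = n, Pr = Pr, Ec = Ec,
    phi_factors = phi_factors,
    dissipation_exponent = match.arg(dissipation_exponent),
    dissipation_phi1 = match.arg(dissipation_phi1),
    cf_grouping = match.arg(cf_grouping)
  ), class = "sisko_params")
}

#' @export
print.sisko_params <- function(x, ...) {
  cat(sprintf(
    "<sisko_params> S = %g, gamma = %g, beta = %g, n = %g, Pr = %g, Ec = %g, phi = %g\n",
    x$S, x$gamma, x$beta, x$n, x$Pr, x$Ec, x$phi_factors$phi))
  cat(sprintf("  variants: %s, %s, %s\n", x$dissipation_exponent,
              x$dissipation_phi1, x$cf_grouping))
  invisible(x)
}

#' Dimensionless groups from dimensional scales
#'
#' Builds a [sisko_params()] object from raw physical inputs at one axial
#' station `x` (local-similarity convention: the `x`-dependent groups `S` and
#' `Ec` are frozen at that station).
#'
#' The groups are
#' `S = (alpha/mu_f) * (u0 x / L0 * sqrt(u0/(nu_f L0)))^(n-1)`,
#' `gamma = sqrt(nu_f L0 / u0) / R`,
#' `beta = mu_f L0 / (rho_f u0 K)`,
#' `Pr = mu_f Cp_f / k_f` (base fluid), and
#' `Ec = u0^2 x^2 / (Cp_f (Tw - Tinf) L0^2)`.
#'
#' @param scales a [dimensional_scales()] object (velocity/viscosity/thermal
#'   scales, permeability `K`, and the Sisko constants `alpha_sisko`, `n`).
#' @param x axial station (m), measured from the stenosis throat; must be
#'   positive (S and Ec are locally defined).
#' @param R local vessel radius (m). Alternatively pass `geometry` and the
#'   radius is taken as [radius_profile()] at `x`.
#' @param geometry optional [stenosis_geometry()] used when `R` is missing.
#' @param L0 stenosis segment length scale (m); taken from `geometry` when
#'   supplied.
#' @param composition a [nanofluid()]; supplies the property factors and the
#'   base-fluid `Cp_f`, `rho_f`, `k_f`.
#' @param ... variant flags passed on to [sisko_params()].
#' @return A [sisko_params()] object.
#' @export
dimensionless_groups <- function(scales, x, R = NULL, geometry = NULL,
                                 L0 = NULL, composition = nanofluid(phi = 0),
                                 ...) {
  if (!inherits(scales, "dimensional_scales"))
    stop("`scales` must be a dimensional_scales() object")
  if (is.null(L0)) {
    if (is.null(geometry)) stop("supply `L0` or `geometry`")
    L0 <- geometry$L0
  }
  if (is.null(R)) {
    if (is.null(geometry)) stop("supply `R` or `geometry`")
    R <- radius_profile(x, geometry)
  }
  if (x <= 0) stop("station `x` must be positive (S and Ec are local groups)")
  if (R <= 0 || L0 <= 0) stop("R and L0 must be positive")
  bf <- composition$base
  with(scales, {
    S <- (alpha_sisko / mu_f) * (u0 * x / L0 * sqrt(u0 / (nu_f * L0)))^(n - 1)
    gamma <- sqrt(nu_f * L0 / u0) / R
    beta <- mu_f * L0 / (bf$density * u0 * K)
    Pr <- mu_f * bf$specific_heat / bf$conductivity
    Ec <- u0^2 * x^2 / (bf$specific_heat * (Tw - Tinf) * L0^2)
    sisko_params(S = S, gamma = gamma, beta = beta, n = n, Pr = Pr, Ec = Ec,
                 composition = composition, ...)
  })
}

#' Momentum right-hand side
#'
#' First-order form of the similarity-reduced momentum equation. The state is
#' `(z1, z2, z3) = (F, F', F'')` and the derivative of `z3` is
#'
#' \deqn{z_3' = \frac{\varphi_1 S (1+2\eta\gamma)^{(n-1)/2}\gamma(-z_3)^n
#'   - 2\gamma z_3 + \beta z_2 + \varphi_1\varphi_2 (z_2^2 - z_1 z_3)}
#'   {(1+2\eta\gamma)\left[1 + \varphi_1 S n (1+2\eta\gamma)^{(n-1)/2}
#'   (-z_3)^{n-1}\right]}}
#'
#' `(-z3)` is clamped to at least `1e-12` inside the fractional powers, which
#' keeps the right-hand side real during shooting iterations that transiently
#' produce positive shear; converged solutions are checked for `F'' <= 0`.
#'
#' @param eta similarity coordinate (requires `1 + 2*eta*gamma > 0`).
#' @param state numeric vector `(z1, z2, z3)` (longer vectors allowed; only
#'   the first three entries are read).
#' @param p a [sisko_params()] object.
#' @return Numeric vector `c(dz1, dz2, dz3)`.
#' @export
momentum_rhs <- function(eta, state, p) {
  z1 <- state[[1]]; z2 <- state[[2]]; z3 <- state[[3]]
  g <- p$gamma
  c1 <- 1 + 2 * eta * g
  if (c1 <= 0) stop("momentum_rhs requires 1 + 2*eta*gamma > 0")
  f <- p$phi_factors
  shear <- max(-z3, .shear_eps)
  cs <- c1^((p$n - 1) / 2)
  denom_bracket <- 1 + f$phi1 * p$S * p$n * cs * shear^(p$n - 1)
  if (denom_bracket < .denom_min)
    stop("degenerate momentum equation: Sisko denominator bracket below ",
         .denom_min, " (strongly shear-thinning regime)")
  num <- f$phi1 * p$S * cs * g * shear^p$n - 2 * g * z3 + p$beta * z2 +
    f$phi1 * f$phi2 * (z2^2 - z1 * z3)
  c(z2, z3, num / (c1 * denom_bracket))
}

#' Energy right-hand side
#'
#' First-order form of the similarity-reduced energy equation. The state is
#' `(z1, z2, z3, z4, z5) = (F, F', F'', theta, theta')` and
#'
#' \deqn{z_5' = \frac{1}{1+2\eta\gamma}\left[-2\gamma z_5 - \frac{1}{\varphi_4}
#'   \left(\varphi_3 \mathrm{Pr}\, z_1 z_5 + \mathrm{Pr}\,\mathrm{Ec}\,\Phi
#'   \right)\right]}
#'
#' with viscous dissipation
#' `Phi = (1+2*eta*gamma) * c1 * z3^2 + S * (1+2*eta*gamma)^((n+1)/2) * (-z3)^e`,
#' where `c1` is `1/phi1` or `phi1` and `e` is `n+1` or `n` according to the
#' variant flags in `p` (defaults `1/phi1` and `n+1`).
#'
#' @inheritParams momentum_rhs
#' @param state numeric vector `(z1, z2, z3, z4, z5)`.
#' @return Numeric vector `c(dz4, dz5)`.
#' @export
energy_rhs <- function(eta, state, p) {
  z1 <- state[[1]]; z3 <- state[[3]]; z5 <- state[[5]]
  g <- p$gamma
  c1 <- 1 + 2 * eta * g
  if (c1 <= 0) stop("energy_rhs requires 1 + 2*eta*gamma > 0")
  f <- p$phi_factors
  shear <- max(-z3, .shear_eps)
  phi1_fac <- if (p$dissipation_phi1 == "divide_by_phi1") 1 / f$phi1 else f$phi1
  e <- if (p$dissipation_exponent == "physical_n_plus_1") p$n + 1 else p$n
  diss <- c1 * phi1_fac * z3^2 + p$S * c1^((p$n + 1) / 2) * shear^e
  dz5 <- (-2 * g * z5 -
            (f$phi3 * p$Pr * z1 * z5 + p$Pr * p$Ec * diss) / f$phi4) / c1
  c(z5, dz5)
}

# combined 5-state RHS in deSolve calling convention; `forced` toggles the
# Ec dissipation forcing (FALSE gives the homogeneous theta equation used by
# the superposition energy solver)
.ode_rhs <- function(eta, state, p, with_energy = TRUE, forced = TRUE) {
  dm <- momentum_rhs(eta, state, p)
  if (!with_energy) return(list(dm))
  pe <- p
  if (!forced) pe$Ec <- 0
  de <- energy_rhs(eta, state, pe)
  list(c(dm, de))
}
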