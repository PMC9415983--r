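# Wall engineering quantities: Reynolds-scaled skin-friction and Nusselt
# groups evaluated from a converged similarity solution.

#' Reynolds-scaled skin-friction coefficient
#'
#' Computes `Re_x^{1/2} Cf` from the wall shear of a converged solution. The
#' dimensional wall stress carries the nanofluid viscosity only on its
#' Newtonian part, so the default grouping is
#' `cf_rex = F''(0)/phi1 - S * (-F''(0))^n`
#' (`"phi1_on_first_term_only"`); the alternative reading
#' `(1/phi1) * (F''(0) - S * (-F''(0))^n)` is selected by setting
#' `cf_grouping = "phi1_on_both_terms"` in the parameters. The two coincide
#' whenever `phi = 0` or `S = 0`.
#'
#' @param sol a converged `"similarity_solution"` (only `fpp_wall` is used).
#' @param p a [sisko_params()] object; defaults to the parameters stored in
#'   `sol`.
#' @return `Re_x^{1/2} Cf` (dimensionless, negative for decaying wall flow).
#' @export
skin_friction <- function(sol, p = sol$params) {
  fpp0 <- sol$fpp_wall
  if (!is.finite(fpp0)) stop("solution has no converged wall shear")
  if (fpp0 > 0)
    stop("F''(0) > 0: the (-F'')^n wall-stress term is undefined for ",
         "reversed shear")
  phi1 <- p$phi_factors$phi1
  if (p$cf_grouping == "phi1_on_first_term_only")
    fpp0 / phi1 - p$S * (-fpp0)^p$n
  else
    (fpp0 - p$S * (-fpp0)^p$n) / phi1
}

#' Reynolds-scaled Nusselt number
#'
#' `Re_x^{-1/2} Nu = -(k_nf/k_f) * theta'(0) = -phi4 * theta'(0)`.
#'
#' @inheritParams skin_friction
#' @return `Re_x^{-1/2} Nu` (dimensionless).
#' @export
nusselt <- function(sol, p = sol$params) {
  tp0 <- sol$thetap_wall
  if (!is.finite(tp0)) stop("solution has no converged wall temperature gradient")
  -p$phi_factors$phi4 * tp0
}

#' Wall quantities of a converged solution
#'
#' Bundles the Reynolds-scaled skin-friction and Nusselt groups together
#' with the unscaled dimensionless wall shear and heat-flux groups.
#'
#' @inheritParams skin_friction
#' @return Named list: `cf_rex`, `nu_rex`, `tau_w_dimless` (the bracket of
#'   the skin-friction group), `q_w_dimless` (`-phi4 * theta'(0)`).
#' @export
wall_quantities <- function(sol, p = sol$params) {
  cf <- skin_friction(sol, p)
  list(cf_rex = cf,
       nu_rex = if (is.finite(sol$thetap_wall)) nusselt(sol, p) else NA_real_,
       tau_w_dimless = cf,
       q_w_dimless = if (is.finite(sol$thetap_wall))
         -p$phi_factors$phi4 * sol$thetap_wall else NA_real_)
}
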