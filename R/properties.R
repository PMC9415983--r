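#' Constituent material properties
#'
#' Bundle the thermophysical properties of one constituent of a nanofluid:
#' either the base fluid (blood, here) or the suspended nanoparticle material.
#'
#' @param density mass density rho (kg/m^3)
#' @param specific_heat specific heat capacity Cp (J/kg/K)
#' @param conductivity thermal conductivity k (W/m/K)
#'
#' @return An object of class `"nf_material"`: a named list with the three
#'   fields above.
#' @examples
#' material(density = 1050, specific_heat = 3617, conductivity = 0.52)
#' @export
material <- function(density, specific_heat, conductivity) {
  vals <- c(density = density, specific_heat = specific_heat,
            conductivity = conductivity)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all material properties must be finite and strictly positive")
  structure(list(density = density, specific_heat = specific_heat,
                 conductivity = conductivity),
            class = "nf_material")
}

# experimental property values for blood (base fluid) and gold nanoparticles
.material_presets <- list(
  blood = list(density = 1050,  specific_heat = 3617, conductivity = 0.52),
  gold  = list(density = 19300, specific_heat = 129,  conductivity = 318)
)

#' Built-in material presets
#'
#' Returns the packaged property values for `"blood"` (the base fluid) or
#' `"gold"` (Au nanoparticles), the constituents of the gold/blood nanofluid
#' the model targets.
#'
#' @param name `"blood"` or `"gold"`.
#' @return An [material()] object.
#' @examples
#' material_preset("gold")$density   # 19300 kg/m^3
#' @export
material_preset <- function(name = c("blood", "gold")) {
  name <- match.arg(name)
  do.call(material, .material_presets[[name]])
}

#' Nanofluid composition
#'
#' A base fluid loaded with solid nanoparticles at volume fraction `phi`.
#' The effective-property correlations used downstream (Brinkman viscosity,
#' mixture density/heat capacity, Maxwell conductivity) are dilute-suspension
#' models; loadings at or above 0.3 are accepted but flagged with a warning
#' because the correlations lose validity there. `phi >= 1` is an error.
#'
#' @param phi nanoparticle volume fraction, in `[0, 1)`.
#' @param base,particle [material()] objects; default blood and gold presets.
#' @return An object of class `"nanofluid"`.
#' @examples
#' nanofluid(phi = 0.05)
#' @export
nanofluid <- function(phi = 0, base = material_preset("blood"),
                      particle = material_preset("gold")) {
  if (!inherits(base, "nf_material") || !inherits(particle, "nf_material"))
    stop("`base` and `particle` must be material() objects")
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi))
    stop("`phi` must be a single finite number")
  if (phi < 0 || phi >= 1)
    stop("volume fraction `phi` must lie in [0, 1)")
  if (phi >= 0.3)
    warning("phi = ", phi, " is outside the customary validity range of the ",
            "dilute-suspension (Brinkman/Maxwell) correlations (phi < 0.3)")
  structure(list(base = base, particle = particle, phi = phi),
            class = "nanofluid")
}

#' Nanofluid property-ratio factors
#'
#' The four dimensionless factors through which the nanoparticle loading
#' enters the similarity-reduced equations:
#' \describe{
#'   \item{phi1}{`(1 - phi)^2.5` — reciprocal Brinkman viscosity ratio, so
#'     `mu_nf / mu_f = 1 / phi1`.}
#'   \item{phi2}{`1 - phi + phi * rho_s / rho_f` — density ratio.}
#'   \item{phi3}{`1 - phi + phi * (rho Cp)_s / (rho Cp)_f` — heat-capacity
#'     ratio.}
#'   \item{phi4}{Maxwell conductivity ratio
#'     `(k_s + 2 k_f - 2 phi (k_f - k_s)) / (k_s + 2 k_f + 2 phi (k_f - k_s))`.}
#' }
#' At `phi = 0` all four equal 1 exactly.
#'
#' @param comp a [nanofluid()] composition.
#' @return An object of class `"phi_factors"`: list with `phi1`..`phi4` and
#'   the `phi` they were computed from.
#' @examples
#' phi_factors(nanofluid(phi = 0.05))
#' @export
phi_factors <- function(comp) {
  if (!inherits(comp, "nanofluid")) stop("`comp` must be a nanofluid() object")
  phi <- comp$phi
  bf <- comp$base
  np <- comp$particle
  rho_cp_f <- bf$density * bf$specific_heat
  rho_cp_s <- np$density * np$specific_heat
  kf <- bf$conductivity
  ks <- np$conductivity
  structure(list(
    phi1 = (1 - phi)^2.5,
    phi2 = 1 - phi + phi * np$density / bf$density,
    phi3 = 1 - phi + phi * rho_cp_s / rho_cp_f,
    phi4 = (ks + 2 * kf - 2 * phi * (kf - ks)) /
           (ks + 2 * kf + 2 * phi * (kf - ks)),
    phi  = phi
  ), class = "phi_factors")
}

#' Effective nanofluid-to-base property ratios
#'
#' Convenience view of [phi_factors()] on the property scale a practitioner
#' quotes: `mu_nf/mu_f` (Brinkman), `rho_nf/rho_f`,
#' `(rho Cp)_nf/(rho Cp)_f`, and `k_nf/k_f` (Maxwell).
#'
#' @inheritParams phi_factors
#' @return Named list with elements `mu_ratio`, `rho_ratio`, `rho_cp_ratio`,
#'   `k_ratio`.
#' @examples
#' effective_property_ratios(nanofluid(phi = 0.1))
#' @export
effective_property_ratios <- function(comp) {
  f <- phi_factors(comp)
  list(mu_ratio = 1 / f$phi1,
       rho_ratio = f$phi2,
       rho_cp_ratio = f$phi3,
       k_ratio = f$phi4)
}

#' @export
print.nf_material <- function(x, ...) {
  cat(sprintf("<material> rho = %g kg/m^3, Cp = %g J/kg/K, k = %g W/m/K\n",
              x$density, x$specific_heat, x$conductivity))
  invisible(x)
}

#' @export
print.nanofluid <- function(x, ...) {
  cat(sprintf("<nanofluid> phi = %g\n", x$phi))
  cat("  base:     "); print(x$base)
  cat("  particle: "); print(x$particle)
  invisible(x)
}

#' @export
print.phi_factors <- function(x, ...) {
  cat(sprintf(
    "<phi_factors> phi = %g: phi1 = %.6f, phi2 = %.6f, phi3 = %.6f, phi4 = %.6f\n",
    x$phi, x$phi1, x$phi2, x$phi3, x$phi4))
  invisible(x)
}
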