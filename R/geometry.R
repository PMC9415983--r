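# Stenosis geometry and reconstruction of dimensional velocity/temperature
# fields from a similarity solution.

#' Cosine stenosis geometry
#'
#' An axisymmetric artery of unobstructed radius `R0` narrowed by a cosine
#' bump of maximum height `lam` over the axial window `|x| < L0/4`; the
#' throat (maximum constriction, radius `R0 - lam`) sits at `x = 0`.
#'
#' @param R0 unobstructed vessel radius (m).
#' @param lam maximum stenosis height (m), `0 < lam < R0`.
#' @param L0 stenosis segment length scale (m).
#' @return Object of class `"stenosis_geometry"`.
#' @export
stenosis_geometry <- function(R0, lam, L0) {
  if (!(R0 > 0 && L0 > 0)) stop("R0 and L0 must be positive")
  if (!(lam > 0 && lam < R0)) stop("stenosis height must satisfy 0 < lam < R0")
  structure(list(R0 = R0, lam = lam, L0 = L0), class = "stenosis_geometry")
}

#' Dimensional scales for field reconstruction
#'
#' Physical scales needed to map the dimensionless similarity solution back
#' to velocities (m/s) and temperatures (K), and to form the dimensionless
#' groups from raw inputs. The base-fluid dynamic viscosity `mu_f` must be
#' supplied here (it is not part of the packaged material properties, which
#' carry only density, heat capacity and conductivity).
#'
#' @param u0 wall stretching velocity scale (m/s).
#' @param nu_f base-fluid kinematic viscosity (m^2/s).
#' @param mu_f base-fluid dynamic viscosity (Pa s).
#' @param Tw,Tinf wall and ambient temperature (K), `Tw != Tinf`.
#' @param K permeability of the porous medium (m^2).
#' @param alpha_sisko Sisko power-law consistency (Pa s^n).
#' @param n power-law index.
#' @return Object of class `"dimensional_scales"`.
#' @export
dimensional_scales <- function(u0, nu_f, mu_f, Tw, Tinf, K = Inf,
                               alpha_sisko = 0, n = 1) {
  if (!(u0 > 0 && nu_f > 0 && mu_f > 0)) stop("u0, nu_f, mu_f must be positive")
  if (Tw == Tinf) stop("Tw must differ from Tinf")
  if (!(K > 0)) stop("permeability K must be positive")
  if (alpha_sisko < 0) stop("alpha_sisko must be nonnegative")
  if (n <= 0) stop("power-law index n must be positive")
  structure(list(u0 = u0, nu_f = nu_f, mu_f = mu_f, Tw = Tw, Tinf = Tinf,
                 K = K, alpha_sisko = alpha_sisko, n = n),
            class = "dimensional_scales")
}

#' Stenosed radius profile
#'
#' `R(x) = R0 - (lam/2) * (1 + cos(4 pi x / L0))` inside `|x| < L0/4` and
#' `R0` outside; continuous at the junctions, with minimum `R0 - lam` at the
#' throat `x = 0`.
#'
#' @param x axial position(s) (m), measured from the throat; vectorized.
#' @param g a [stenosis_geometry()].
#' @return Radius (m), same length as `x`.
#' @export
radius_profile <- function(x, g) {
  if (!inherits(g, "stenosis_geometry")) stop("`g` must be a stenosis_geometry()")
  inside <- abs(x) < g$L0 / 4
  r <- rep(g$R0, length(x))
  r[inside] <- g$R0 - (g$lam / 2) * (1 + cos(4 * pi * x[inside] / g$L0))
  r
}

#' Similarity coordinate of a physical point
#'
#' `eta = (r^2 - R^2) / (2 R) * sqrt(u0 / (nu_f L0))` with `R = R(x)` frozen
#' at the local station (local-similarity convention).
#'
#' @param r radial position(s) (m), `r >= R(x)`.
#' @param x axial position (m).
#' @param g a [stenosis_geometry()].
#' @param scales a [dimensional_scales()].
#' @return Similarity coordinate eta (dimensionless).
#' @export
similarity_coordinate <- function(r, x, g, scales) {
  R <- radius_profile(x, g)
  if (any(r < R - 1e-12)) stop("r < R(x): point lies inside the vessel wall")
  (r^2 - R^2) / (2 * R) * sqrt(scales$u0 / (scales$nu_f * g$L0))
}

#' Reconstruct dimensional fields from a similarity solution
#'
#' Maps the similarity solution onto a physical `(x, r)` grid:
#' `u = (u0 x / L0) * F'(eta)`, `v = -(R/r) * sqrt(u0 nu_f / L0) * F(eta)`,
#' `T = Tinf + (Tw - Tinf) * theta(eta)`, with `eta` from
#' [similarity_coordinate()]. Points beyond the solved grid use the
#' far-field asymptote (`F' = 0`, `theta = 0`, `F = F(eta_max)`). The
#' similarity solution assumes a locally constant radius; evaluating it with
#' `R = R(x)` is a local-similarity visualization of the stenosed vessel.
#'
#' @param sol a converged `"similarity_solution"`.
#' @param g a [stenosis_geometry()].
#' @param scales a [dimensional_scales()].
#' @param x_grid,r_grid numeric vectors of axial/radial stations (m); `r_grid`
#'   values below the local wall radius are dropped for that station.
#' @return A data frame in tidy layout with columns
#'   `x, r, eta, u, v, T` (SI units).
#' @export
reconstruct_fields <- function(sol, g, scales, x_grid, r_grid) {
  if (!inherits(sol, "similarity_solution")) stop("`sol` must be a similarity_solution")
  # cubic-spline interpolants on the solved grid; beyond eta_max the frozen
  # far-field asymptote (F' = 0, theta = 0, F = F(eta_max)) is held, which is
  # what clamping eta to the grid end achieves on the regularized solution
  L <- sol$eta_max_used
  Ff  <- local({ f <- stats::splinefun(sol$eta, sol$F);  function(e) f(pmin(e, L)) })
  Fpf <- local({ f <- stats::splinefun(sol$eta, sol$Fp); function(e) f(pmin(e, L)) })
  thf <- local({ f <- stats::splinefun(sol$eta, sol$theta); function(e) f(pmin(e, L)) })
  vel_scale <- sqrt(scales$u0 * scales$nu_f / g$L0)
  out <- lapply(x_grid, function(x) {
    R <- radius_profile(x, g)
    r <- r_grid[r_grid >= R]
    if (!length(r)) return(NULL)
    eta <- similarity_coordinate(r, x, g, scales)
    data.frame(
      x = x, r = r, eta = eta,
      u = scales$u0 * x / g$L0 * Fpf(eta),
      v = -(R / r) * vel_scale * Ff(eta),
      T = scales$Tinf + (scales$Tw - scales$Tinf) * thf(eta))
  })
  do.call(rbind, out)
}
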