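# Parameter-sweep engine, comparison-table reproduction, and profile export.

# scalar parameter fields a sweep axis may address
.sweepable <- c("S", "gamma", "beta", "n", "Pr", "Ec", "phi")

#' Parameter sweep specification
#'
#' A base parameter set plus named axes; [run_sweep()] solves the Cartesian
#' product. Axis names must be scalar model parameters (`"S"`, `"gamma"`,
#' `"beta"`, `"n"`, `"Pr"`, `"Ec"`) or `"phi"` (nanoparticle volume fraction,
#' re-deriving the property factors with blood/gold constituents unless
#' `base`/`particle` are supplied).
#'
#' @param base a [sisko_params()] object giving the held-fixed values.
#' @param axes named list of numeric value vectors, one per swept parameter.
#' @param base_material,particle_material [material()]s used when `phi` is
#'   swept.
#' @return Object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(base = sisko_params(), axes = list(),
                       base_material = material_preset("blood"),
                       particle_material = material_preset("gold")) {
  if (!inherits(base, "sisko_params")) stop("`base` must be sisko_params()")
  if (length(axes)) {
    if (is.null(names(axes)) || any(!nzchar(names(axes))))
      stop("all sweep axes must be named")
    bad <- setdiff(names(axes), .sweepable)
    if (length(bad))
      stop("unknown sweep axis: ", paste(bad, collapse = ", "),
           " (valid: ", paste(.sweepable, collapse = ", "), ")")
    if (any(!vapply(axes, length, 1L)))
      stop("sweep axes must have non-empty value lists")
  }
  structure(list(base = base, axes = axes,
                 base_material = base_material,
                 particle_material = particle_material),
            class = "sweep_spec")
}

# build (and re-validate) the parameter object for one sweep record
.params_at <- function(spec, values) {
  b <- spec$base
  fields <- list(S = b$S, gamma = b$gamma, beta = b$beta, n = b$n,
                 Pr = b$Pr, Ec = b$Ec, phi_factors = b$phi_factors,
                 dissipation_exponent = b$dissipation_exponent,
                 dissipation_phi1 = b$dissipation_phi1,
                 cf_grouping = b$cf_grouping)
  for (nm in names(values)) {
    if (nm == "phi") {
      fields$phi_factors <- phi_factors(
        nanofluid(phi = values[[nm]], base = spec$base_material,
                  particle = spec$particle_material))
    } else {
      fields[[nm]] <- values[[nm]]
    }
  }
  do.call(sisko_params, fields)
}

#' Run a parameter sweep
#'
#' Solves the boundary value problem at every point of the Cartesian product
#' of the sweep axes (axes iterated in sorted-name lexicographic order,
#' making the record order deterministic). Failed solves are kept as flagged
#' rows (`converged = FALSE`, `error` message) rather than dropped, so the
#' grid shape survives for downstream tabulation.
#'
#' @param spec a [sweep_spec()].
#' @param settings a [solver_settings()].
#' @param keep_solutions also return the solution objects (list column
#'   dropped; returned as attribute `"solutions"`).
#' @return Data frame with one row per combination: the full parameter set,
#'   `fpp_wall`, `thetap_wall`, `cf_rex`, `nu_rex`, `eta_max_used`,
#'   `converged`, `error`.
#' @export
run_sweep <- function(spec, settings = solver_settings(),
                      keep_solutions = FALSE) {
  if (!inherits(spec, "sweep_spec")) stop("`spec` must be a sweep_spec()")
  axes <- spec$axes
  if (length(axes)) axes <- axes[order(names(axes))]
  grid <- if (length(axes)) {
    expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)[, names(axes), drop = FALSE]
  } else {
    data.frame(row.names = 1)
  }
  n_rec <- max(1L, nrow(grid))
  sols <- vector("list", n_rec)
  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    vals <- if (ncol(grid)) as.list(grid[i, , drop = FALSE]) else list()
    res <- tryCatch({
      p <- .params_at(spec, vals)
      list(p = p, sol = solve_similarity(p, settings))
    }, error = function(e) e)
    ok <- !inherits(res, "error")
    if (ok) sols[[i]] <- res$sol
    base_vals <- list(S = spec$base$S, gamma = spec$base$gamma,
                      beta = spec$base$beta, n = spec$base$n,
                      Pr = spec$base$Pr, Ec = spec$base$Ec,
                      phi = spec$base$phi_factors$phi)
    for (nm in names(vals)) base_vals[[nm]] <- vals[[nm]]
    rows[[i]] <- data.frame(
      S = base_vals$S, gamma = base_vals$gamma, beta = base_vals$beta,
      n = base_vals$n, Pr = base_vals$Pr, Ec = base_vals$Ec,
      phi = base_vals$phi,
      fpp_wall = if (ok) res$sol$fpp_wall else NA_real_,
      thetap_wall = if (ok) res$sol$thetap_wall else NA_real_,
      cf_rex = if (ok) skin_friction(res$sol, res$p) else NA_real_,
      nu_rex = if (ok) nusselt(res$sol, res$p) else NA_real_,
      eta_max_used = if (ok) res$sol$eta_max_used else NA_real_,
      converged = ok,
      error = if (ok) "" else conditionMessage(res))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(!out$converged)) stop("all sweep records failed to solve")
  if (keep_solutions) attr(out, "solutions") <- sols
  out
}

# published comparison values: curvature/volume-fraction sweep of the
# Reynolds-scaled skin friction at S = 0, beta = 0 (Newtonian, non-porous),
# present-study column and the earlier-study column it was compared against
.comparison_reference <- data.frame(
  gamma = c(0.10, 0.12, 0.14, 0.10, 0.10, 0.10),
  phi   = c(0.00, 0.00, 0.00, 0.00, 0.05, 0.10),
  cf_rex_published = c(-0.93947, -0.9295648, -0.9180573,
                       -0.93947, -1.323752, -1.714007),
  cf_rex_reference = c(-0.939968, -0.924794, -0.911311,
                       -0.939968, -1.329552, -1.715985)
)

#' Reproduce the published skin-friction comparison table
#'
#' Re-solves the Newtonian, non-porous momentum problem (`S = 0`, `beta = 0`)
#' at the six published (curvature, volume fraction) settings and tabulates
#' the computed `Re_x^{1/2} Cf` next to the published values (both the
#' original study's column and the earlier reference study it compared
#' against), with absolute differences.
#'
#' @param settings a [solver_settings()].
#' @return Data frame with columns `gamma`, `phi`, `cf_rex_computed`,
#'   `cf_rex_published`, `cf_rex_reference`, `abs_diff_published`.
#' @export
reproduce_comparison_table <- function(settings = solver_settings()) {
  ref <- .comparison_reference
  cf <- vapply(seq_len(nrow(ref)), function(i) {
    p <- sisko_params(S = 0, gamma = ref$gamma[i], beta = 0,
                      composition = nanofluid(phi = ref$phi[i]))
    sol <- solve_similarity_momentum_only(p, settings)
    skin_friction(sol, p)
  }, numeric(1))
  data.frame(gamma = ref$gamma, phi = ref$phi,
             cf_rex_computed = cf,
             cf_rex_published = ref$cf_rex_published,
             cf_rex_reference = ref$cf_rex_reference,
             abs_diff_published = abs(cf - ref$cf_rex_published))
}

#' Momentum-only solve with domain doubling
#'
#' Convenience wrapper used for skin-friction studies: runs the momentum
#' shooting solve with the same automatic far-field enlargement as
#' [solve_similarity()], skipping the temperature equation.
#'
#' @inheritParams solve_similarity
#' @return A partial `"similarity_solution"` (theta block `NA`).
#' @export
solve_similarity_momentum_only <- function(p, s = solver_settings()) {
  L <- s$eta_max
  prev <- NULL
  repeat {
    sol <- solve_momentum(p, s, eta_max = L,
                          fpp0_hint = if (is.null(prev)) NULL else prev$fpp_wall)
    if (!is.null(prev) && abs(sol$fpp_wall - prev$fpp_wall) < s$wall_tol)
      return(sol)
    L_next <- L * s$eta_max_growth
    if (L_next > s$eta_max_cap) {
      warning("eta_max cap reached before wall shear converged")
      return(sol)
    }
    prev <- sol
    L <- L_next
  }
}

#' Export profile curves for a figure-style sweep
#'
#' Writes one CSV with the similarity coordinate in the first column and one
#' column per solution for the requested profile (`"Fp"` for the velocity
#' shape `F'` or `"theta"` for temperature), resampled onto a common grid.
#'
#' @param sols list of `"similarity_solution"` objects.
#' @param path output CSV path.
#' @param what `"Fp"` or `"theta"`.
#' @param labels column labels; defaults to `profile_1..k`.
#' @param eta_grid common output grid; defaults to the grid of the first
#'   solution truncated to the shortest solved domain.
#' @return The written data frame, invisibly.
#' @export
export_profiles <- function(sols, path, what = c("Fp", "theta"),
                            labels = NULL, eta_grid = NULL) {
  what <- match.arg(what)
  if (inherits(sols, "similarity_solution")) sols <- list(sols)
  if (!length(sols)) stop("`sols` must contain at least one solution")
  if (is.null(labels)) labels <- paste0("profile_", seq_along(sols))
  if (is.null(eta_grid)) {
    L <- min(vapply(sols, function(s) s$eta_max_used, numeric(1)))
    eta_grid <- seq(0, L, length.out = length(sols[[1]]$eta))
  }
  cols <- lapply(sols, function(s) {
    yright <- if (what == "Fp") 0 else 0
    stats::approxfun(s$eta, s[[what]], yleft = s[[what]][1],
                     yright = yright)(eta_grid)
  })
  df <- data.frame(eta = eta_grid, stats::setNames(cols, labels),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
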