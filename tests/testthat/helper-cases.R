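# shared fixtures: parameter constructors and lazily cached reference solves

params <- function(S = 0, gamma = 0, beta = 0, n = 2, Pr = 1, Ec = 0,
                   phi = 0, ...) {
  sisko_params(S = S, gamma = gamma, beta = beta, n = n, Pr = Pr, Ec = Ec,
               composition = nanofluid(phi = phi), ...)
}

# held-fixed default set used for all directional (trend) checks
trend_params <- function(phi = 0.01, ...) {
  sisko_params(composition = nanofluid(phi = phi), ...)
}

.cache <- new.env(parent = emptyenv())

# classical stretching-sheet case (gamma = S = beta = Ec = 0, phi = 0, Pr = 1):
# F has the closed form 1 - exp(-eta)
crane_solution <- function() {
  if (is.null(.cache$crane))
    .cache$crane <- solve_similarity(params())
  .cache$crane
}

# curved-vessel Newtonian case used by structural-invariant checks
curved_solution <- function() {
  if (is.null(.cache$curved))
    .cache$curved <- solve_similarity(params(gamma = 0.1, Pr = 21, Ec = 0.1))
  .cache$curved
}
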