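---
title: "Modeling Sisko nanofluid flow and heat transfer in a porous stenosed artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Sisko nanofluid flow and heat transfer in a porous stenosed artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siskoflow)
```

## The physical problem

`siskoflow` simulates the steady, incompressible boundary layer that forms
when blood laden with gold nanoparticles is driven along the wall of an
axisymmetric artery narrowed by a cosine-shaped stenosis. Three physical
ingredients set this problem apart from a textbook boundary layer:

* **Non-Newtonian rheology.** Blood is modeled as a Sisko fluid, whose wall
  shear stress combines a Newtonian part and a power-law part,
  $\tau = \mu\,\dot\gamma + \alpha\,\dot\gamma^{\,n}$. The power-law index
  $n$ distinguishes shear-thinning ($n<1$) from shear-thickening ($n>1$)
  behavior.
* **Nanoparticle loading.** A volume fraction $\phi$ of gold particles
  modifies the effective transport properties of the suspension through
  standard dilute-suspension correlations: Brinkman viscosity
  $\mu_{nf} = \mu_f (1-\phi)^{-2.5}$, volume-weighted mixture density and
  heat capacity, and the Maxwell conductivity formula.
* **Porous wall region and curvature.** A Darcy drag term
  $-(\mu_{nf}/K)u$ represents the porous medium, and the cylindrical
  geometry introduces a curvature group that has no analogue on a flat
  stretching sheet.

## Similarity reduction

With the stretching-wall velocity scale $u_0 x/L_0$ and the transverse
similarity coordinate
$\eta = \frac{r^2-R^2}{2R}\sqrt{u_0/(\nu_f L_0)}$,
the momentum and energy balances collapse to two ODEs for the dimensionless
stream function $F(\eta)$ and temperature $\theta(\eta)$:

$$
(1+2\eta\gamma)F''' + 2\gamma F''
+ \varphi_1 S (1+2\eta\gamma)^{\frac{n-1}{2}}
\left[ n (1+2\eta\gamma) (-F'')^{n-1} F''' - \gamma (-F'')^{n} \right]
- \beta F' - \varphi_1\varphi_2\left(F'^2 - F F''\right) = 0
$$

$$
\varphi_4\left[(1+2\eta\gamma)\theta'' + 2\gamma\theta'\right]
+ \varphi_3 \mathrm{Pr}\, F\theta'
+ \mathrm{Pr}\,\mathrm{Ec}\left[ \frac{(1+2\eta\gamma)}{\varphi_1} F''^2
+ S (1+2\eta\gamma)^{\frac{n+1}{2}} (-F'')^{n+1} \right] = 0
$$

with boundary conditions $F(0)=0$, $F'(0)=1$, $\theta(0)=1$ and
$F',\theta \to 0$ as $\eta\to\infty$. The groups are the Sisko material
parameter $S$, curvature $\gamma = \sqrt{\nu_f L_0/u_0}/R$, Darcy porosity
$\beta = \mu_f L_0/(\rho_f u_0 K)$, the base-fluid Prandtl number
$\mathrm{Pr}$ and the Eckert number $\mathrm{Ec}$; the $\varphi_i$ are the
nanoparticle property factors from `phi_factors()`. Momentum decouples from
temperature, so the system is solved in sequence.

The wall deliverables are the Reynolds-scaled skin friction
$\mathrm{Re}_x^{1/2} C_f = F''(0)/\varphi_1 - S(-F''(0))^n$ and Nusselt
number $\mathrm{Re}_x^{-1/2} Nu = -\varphi_4\,\theta'(0)$.

## Interpretation choices behind the variant flags

Three places in this model family are rendered ambiguously across the
literature, so the package implements both readings behind explicit flags
and documents its defaults:

* **Dissipation exponent** (`dissipation_exponent`). The dimensional
  dissipation source is $\alpha(-\partial u/\partial r)^{n+1}$, which under
  the similarity map produces $(-F'')^{n+1}$ together with the prefactor
  $(1+2\eta\gamma)^{(n+1)/2}$; some renderings print the exponent as $n$.
  Default: `physical_n_plus_1`, for dimensional consistency.
* **Viscosity factor in the dissipation term** (`dissipation_phi1`). The
  Newtonian dissipation carries $\mu_{nf} = \mu_f/\varphi_1$, so the default
  divides by $\varphi_1$; the multiplied form is selectable.
* **Skin-friction grouping** (`cf_grouping`). In the dimensional wall
  stress only the Newtonian part carries $\mu_{nf}$, so the default applies
  $1/\varphi_1$ to the first term only. The two readings coincide whenever
  $S=0$ or $\phi=0$.

A related decision concerns the Prandtl number: one rendering attaches
$(\rho C_p)_{nf}$ to $\mathrm{Pr}$ even though the heat-capacity factor
$\varphi_3$ already multiplies the convection term. `siskoflow` treats
$\mathrm{Pr}$ as the base-fluid Prandtl number $\mu_f C_{p,f}/k_f$ so the
loading enters exactly once, through $\varphi_3$ and $\varphi_4$.

## Numerical method

**Shooting.** The momentum BVP is solved by shooting on the wall shear
$F''(0)$: the IVP is integrated with `deSolve` (lsodar,
rtol $10^{-10}$/atol $10^{-12}$) and the residual $F'(\eta_{\max})$ is
driven to zero by bracketing over $F''(0)\in[-30,-10^{-3}]$ followed by
Brent's method (tolerance $10^{-12}$). Trajectories that leave
$F' \in [-10^{-6}, 3]$ are terminated early; the sign of $F'$ at
termination steers the bisection. The tight lower sentinel matters: under
curvature the far field decays only algebraically, and overshooting
trajectories dip below zero and rebound, which would otherwise fold the
residual back to positive values and hide the root.

**Far-field truncation.** Solutions on a truncated domain are re-solved on
domains enlarged by `eta_max_growth` (default 2) until both wall
derivatives move by less than `wall_tol` ($10^{-7}$). Because the velocity
tail decays like $(1+2\eta\gamma)^{-k}$ rather than exponentially when
$\gamma>0$, the default cap on $\eta_{\max}$ is 480: measured convergence
at $\gamma=0.14$ requires $\eta_{\max}\approx 240$ for the $10^{-7}$
stability target, and caps near 120 are insufficient. Beyond the point
where $|F'|$ attains its minimum the profile is replaced by its far-field
asymptote ($F'=F''=0$, $F$ frozen); the wall quantities are unaffected.

**Energy by superposition.** For fixed $F$ the temperature equation is
linear in $\theta$, so instead of a second shooting loop the package
integrates one forced IVP with $(\theta,\theta')(0)=(1,0)$ and one
homogeneous (dissipation-free) IVP with $(0,1)$, and combines them so that
$\theta(\eta_{\max})=0$ holds exactly. The temperature integration is
coupled to an exact re-integration of the momentum states up to the freeze
point and continues with the frozen asymptote beyond it, so no profile
interpolation error enters. A direct-shooting fallback
(`method = "shooting"`) exists and is tested to agree.

**Independent cross-check.** `solve_collocation()` discretizes the same BVP
by Chebyshev spectral collocation (121 Gauss–Lobatto nodes by default) with
a damped Newton iteration and an analytic Jacobian, seeded from the
classical closed form — sharing no code path with the shooting solver. The
temperature equation is solved there as a single linear system.
`cross_validate()` reports the wall-derivative differences; across the
documented parameter ranges ($\phi\in[0,0.1]$, $S\in[0,0.5]$,
$n\in[1,2.5]$, $\gamma\in[0,0.3]$, $\beta\in[0,0.5]$, $\mathrm{Pr}\in[1,10]$,
$\mathrm{Ec}\in[0,0.3]$) the two solvers agree to about $10^{-10}$.

**Degenerate shear.** The fractional powers $(-F'')^{n-1}$, $(-F'')^n$ are
only physical for decaying wall flow, $F''\le 0$. During iteration the
shear argument is clamped to $\max(-F'', 10^{-12})$, and converged
solutions are checked post hoc for $F''\le 10^{-8}$ everywhere, with a
model-validity warning otherwise. The clamp keeps the right-hand side real
for fractional $n$ and is continuous in the limit $F''\to 0^-$ for
$n \ge 1$.

## Analytic anchors

Two closed forms pin the solver down independently of any published
numbers. At $\gamma=S=\beta=\phi=0$ the momentum problem is the classical
stretching-sheet flow with $F = 1-e^{-\eta}$ and $F''(0)=-1$; the solver
reproduces the profile to below $10^{-10}$. Along that flow, with
$\mathrm{Pr}=1$ and $\mathrm{Ec}=0$, the temperature equation
$\theta'' + F\theta' = 0$ integrates by quadrature to
$-\theta'(0) = 1/(e-1) \approx 0.5819767$, which the energy solver matches
to $10^{-10}$.

## Defaults for parameter studies

Published parameter studies of this configuration typically omit the
held-fixed values of the companion parameters. The package fixes one
documented default set for all directional (trend) work — $n=2$,
$\mathrm{Pr}=21$ (whole blood), $\mathrm{Ec}=0.1$, $S=0.1$, $\beta=0.1$,
$\gamma=0.1$, $\phi=0.01$ — chosen once as physiologically plausible
magnitudes, and uses it only for orderings, never for exact-value claims.

At these defaults the model responds as follows: the skin-friction group
becomes more negative as $\phi$, $S$ or $\beta$ grows (heavier and more
viscous suspension, stronger shear-thickening stress, stronger Darcy drag)
and also as $\gamma$ grows; the Nusselt group falls with $\mathrm{Ec}$
(dissipation heats the near-wall fluid), falls mildly with $\phi$, and
rises mildly with $\gamma$.

## Relation to published comparison values

`reproduce_comparison_table()` re-solves the Newtonian, non-porous momentum
problem ($S=0$, $\beta=0$) at six published (curvature, loading) settings
and tabulates the computed $\mathrm{Re}_x^{1/2}C_f$ next to the published
values. The two disagree beyond their own printed spread: this
implementation, in agreement with the classical stretching-cylinder
literature and with its own independent collocation solver, finds that
$|F''(0)|$ *increases* with curvature (e.g. $-1.03657$ at $\gamma=0.1$),
whereas the published comparison column *decreases* from $-1$ with growing
curvature (e.g. $-0.93947$). No admissible reading of the similarity
equations above — including the variant flags, an inside-the-vessel
curvature form, and regroupings of the $\varphi_i$ factors — reproduces
the published column. The function therefore reports the absolute
differences rather than asserting agreement, and the package treats the
two analytic anchors plus the dual-solver agreement as its correctness
evidence. The same caveat applies to the published direction of the
Nusselt response to loading and curvature, which the model equations do
not support at any defaults we examined.

## Geometry and field reconstruction

The vessel radius follows
$R(x) = R_0 - \tfrac{\lambda}{2}\left(1+\cos(4\pi x/L_0)\right)$ inside
$|x|<L_0/4$ and $R_0$ outside — continuous at the junctions with its
minimum $R_0-\lambda$ at the throat. `reconstruct_fields()` maps a
similarity solution onto a physical $(x, r)$ grid via
$u = (u_0 x/L_0)F'(\eta)$, $v = -(R/r)\sqrt{u_0\nu_f/L_0}\,F(\eta)$,
$T = T_\infty + (T_w - T_\infty)\theta(\eta)$. The similarity solution
assumes a locally constant radius, so evaluating it with $R = R(x)$ is a
local-similarity visualization; the reconstructed fields satisfy the
continuity equation exactly at fixed $R$ (the package tests verify the
finite-difference residual stays below $10^{-3}$ of the axial-flux scale),
but not across strong axial radius variation. $x$ is measured from the
throat, all lengths in SI units, and the base-fluid dynamic viscosity
$\mu_f$ must be supplied in `dimensional_scales()` since the material
presets carry only density, heat capacity and conductivity.

## Problem sizes and runtimes

The default output mesh has 2001 points; shooting residuals use two-point
integrations, so cost is dominated by the domain-doubling ladder
(15 → 30 → … → 480 at most). A full coupled solve takes a couple of
seconds; the five-case comparison table takes about five seconds; the
20-point cross-validation sample runs in well under a minute.

## Known limitations

* Steady, laminar, local-similarity flow only: no pulsatility, no full
  axisymmetric Navier–Stokes in the stenosed geometry, no pressure-drop
  prediction across the stenosis.
* The dilute-suspension property correlations degrade above
  $\phi \approx 0.3$ (the constructors warn there) and ignore particle
  shape, size distribution, and temperature dependence.
* Single-particle-species nanofluids only; no hybrid suspensions.
* The shear-clamp treatment of $(-F'')^{n}$ is designed for decaying wall
  flow; strongly shear-thinning regimes that genuinely reverse shear are
  outside the model's validity and are flagged, not solved.
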