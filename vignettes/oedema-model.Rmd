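---
title: "Modelling myocardial oedema: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling myocardial oedema: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroedema)
```

This vignette documents the model implemented by `poroedema`, the
assumptions behind it, and the numerical decisions that were genuinely
open when the package was written — together with why they were settled
the way they were.

## The physical picture

Interstitial oedema is the accumulation of fluid in the space between
cells. During an infection, leukocyte-driven inflammation raises the
permeability of the capillary endothelium; plasma then filters out of the
capillaries faster than the lymphatic system drains it, and the tissue
swells. The package couples three submodels on a one-dimensional strip of
myocardium:

1. **Finite-strain poroelasticity.** The tissue is a saturated porous
   solid. The skeleton is isotropic neo-Hookean (no fibre architecture,
   no active contraction — oedema forms over days to weeks, far slower
   than the cardiac cycle, so the muscle is treated as passive). Biot
   coupling with modulus $\alpha$ transmits pore pressure to total
   stress. Incompressibility of both constituents yields the saturation
   constraint $J - \phi_f = 1 - \phi_0$: volume change is pore-volume
   change.
2. **Interstitial fluid balance.** Darcy flow through the skeleton plus a
   distributed exchange source $\ell(p, c_p)$: a Starling filtration term
   whose conductivity $C_f$ grows and whose reflection coefficient
   $\sigma$ decays with pathogen concentration, minus a Hill-saturating
   lymphatic drainage term that activates as interstitial pressure rises
   above its resting value.
3. **Immune kinetics.** A pathogen reproduces at net rate $\gamma_p$ and
   is destroyed by phagocytosis at rate $\lambda_{lp} c_l$; leukocytes
   are recruited from the bloodstream at rate $\lambda_{pl} c_p c_l$
   (recruitment needs both a stimulus and cells already present to
   amplify the signal; the model deliberately has no leukocyte decay, so
   inflammation does not resolve completely). Both species diffuse in the
   pore fluid, and leukocytes chemotax up the pathogen gradient with
   mobility $\chi c_l$.

All transport is assembled in the material (reference) frame; in 1D the
pull-back is exact algebra ($F^{-t} = F^{-1}$, $J F^{-1} = 1$), so no ALE
machinery is needed and a quasi-static momentum balance
$-(P_\mathrm{eff} - \alpha p)_X = 0$ closes the system.

## Units and parameters

The internal unit system is {cm, day, mmHg, cell/cm³}. Days match the
reaction and diffusion rates and the 150-day simulation horizon; mmHg
matches every pressure in the exchange term. Per-second rates are
converted with 1 day = 86400 s and elastic moduli printed in
kg/(cm·s²) with 1 mmHg = 1.33322 kg/(cm·s²) (the reference Young's
modulus becomes 45.0 mmHg). Two conventions worth spelling out:

* `mu_f` is treated as a **dimensionless scaling** of the absolute
  permeability, so `kappa0/mu_f` is the Darcy mobility in
  cm²/(day·mmHg) (2.16e-2 for the reference values). The fluid-pressure
  field is dominated by the exchange source, not by Darcy transport, so
  the simulated dynamics are insensitive to this convention; it is fixed
  for dimensional consistency of the flux term.
* `p0`, the resting interstitial pressure, is 0 mmHg, and `v_max` = 200
  is a dimensionless multiplier of the resting lymph flow `q0`. The Hill
  fraction is clamped to zero below `p0`: lymphatic drainage never falls
  below its resting value, and for odd Hill exponents the unclamped
  expression would have a pole at $p - p_0 = -k_m$.

With the reference values the rest state is *nearly* balanced:
$\ell(0, 0) = C_{f0}(p_c - \sigma_0(\pi_c - \pi_i)) - q_0 \approx$
`r format(baseline_balance(reference_parameters("local-1d")), digits = 3)`
/day, about 0.1 % of `q0`. This small imbalance bounds the drift of an
uninfected simulation (see the rest-state oracle below).

### The porosity weighting of the reaction terms

One modelling decision deserves emphasis because it controls the
timescale of the whole simulation. The species balances carry the fluid
fraction in their storage term, $\partial_t(\phi_f c)$. The reaction
sources can then be specified either per unit *fluid* volume (so the
source entering the balance is $\phi_f r(c)$, and $\phi_f$ cancels in the
homogeneous limit) or per unit *total* volume (the source is $r(c)$, and
homogeneous kinetics become $\dot c = r(c)/\phi_f$). The package adopts
the **per-total-volume** convention. With the reference rate constants
the per-fluid-volume reading produces a local infection that is not
controlled until day ~75 and a diffuse infection that never peaks within
150 days, while the per-total-volume reading yields the intended
separation of phenotypes — local control within two to three weeks,
diffuse spread over two to three months — which is the behaviour the
rate constants were evidently calibrated to produce. The pure functions
`pathogen_reaction()` and `leukocyte_reaction()` expose the pointwise
kinetic laws (the former including its $\phi_f$ factor as conventionally
written); the solver's sources are the per-total-volume ones, and the
kinetics oracle `kinetics_reference()` integrates exactly the
homogeneous reduction of what the solver discretises,
$\dot c_p = (\gamma_p - \lambda_{lp} c_l) c_p / \phi$ and
$\dot c_l = \lambda_{pl} c_p c_l / \phi$.

## Discretisation

* **Space.** Continuous piecewise-linear elements for all five fields on
  a uniform mesh (default 400 elements on 8 cm, h = 0.02 cm, resolving
  the 0.4 cm infected region with 20 elements). Equal-order pairs are
  inf-sup problematic in higher dimensions, but at these permeabilities
  the 1D equal-order discretisation is stable, and it is validated
  against the consolidation oracle below.
* **Quadrature and lumping.** Flux terms use midpoint (one-point)
  element quadrature; storage, reaction and exchange terms use lumped
  nodal quadrature. Lumping is what makes the backward-Euler transport
  update an M-matrix: with a consistent mass matrix the first steps of
  diffusion across the discontinuous initial infection front undershoot
  zero by ~1e-5, which is physically meaningless and would defeat any
  strict nonnegativity accounting. With lumping, concentrations stay
  nonnegative up to solver round-off; anything in $(-10^{-12}, 0)$ after
  a converged step is clamped to zero and anything more negative raises
  an error instead of being masked.
* **Saturation constraint.** Collocated at nodes, with the nodal $J$
  taken as the mean of the two adjacent (element-constant) values.
* **Time.** Backward Euler with dt = 0.1 day by default. The peak times
  of the reference scenarios change by well under 1 % when dt and h are
  halved. On a Newton failure the step is retried at dt/2, recursively
  up to four levels — a robustness guard for the stiff interval around
  the pathogen peak, where the exchange term's pressure derivative is of
  order $10^2$–$10^3$ per day per mmHg.
* **Newton.** Monolithic Newton–Raphson with absolute residual tolerance
  $10^{-6}$ and a **colored finite-difference Jacobian**: nodes are
  3-colored so that one perturbed residual evaluation per color and per
  field recovers an entire block of Jacobian columns — 15 extra residual
  evaluations, assembled into a sparse matrix with a precomputed
  pattern. An analytic Jacobian was considered and rejected: the colored
  FD Jacobian is exact to first order for *every* term including the
  clamped Hill nonlinearity, costs the same asymptotically in 1D, and
  cannot silently drift out of sync with the residual as terms are
  modified. Away from the peak most steps converge in 1–2 iterations.
* **Boundary conditions.** $u(0)=0$ is imposed strongly (row
  replacement); the traction-free end and all zero-flux conditions are
  natural. At $x = 0$ the fields $p, c_p, c_l$ also get natural zero-flux
  conditions — only the right end is stated explicitly in the reference
  setup, and zero flux at the fixed end is the unique choice that leaves
  the uninfected rest state an exact solution. Dirichlet pressure at
  either end is available as a scenario option (used by the
  consolidation benchmark).

## Verification oracles

Three independent references validate the solver
(`verify_solver()` runs all of them):

* **Terzaghi consolidation.** With exchange and reactions off,
  $\alpha = 1$, and a step load giving strains of order $10^{-3}$, the
  solver is in the classical linear consolidation regime. The
  pressure-based degree of consolidation is compared with the Fourier
  series at $T_v \in \{0.1, 0.5, 1\}$ (tolerance 2 %). The mapping is
  $c_v = (\kappa_0/\mu_f)\,\phi_0\,(\lambda_s + 2\mu_s)$ — the fluid
  fraction appears because the Darcy flux carries $\phi_f$. This check
  exercises the mechanics/fluid coupling and both kinds of pressure
  boundary condition.
* **Homogeneous kinetics.** With uniform initial data, zero
  diffusivities and chemotaxis, and mechanics frozen, every node follows
  the two-species kinetics ODE. The solver (Richardson-extrapolated in
  dt to remove the first-order backward-Euler error) is compared with an
  adaptive integration at relative tolerance $10^{-10}$. Errors are
  scaled by each species' trajectory maximum: after the infection
  resolves, the pathogen decays exponentially towards zero, where a
  pointwise relative error is ill-conditioned.
* **Rest state.** With no pathogen anywhere, all fields must stay within
  0.1 % (in natural per-field scales) of rest for 150 days; the drift is
  bounded by the small residual imbalance $\ell(0,0)$ noted above.

## The scenario generator and what it does not capture

`build_scenario()` constructs the study conditions: 8 cm strip,
infection seeded at 0.001 cell/cm³ on [3.8, 4.2] cm, leukocytes at
0.003 cell/cm³, fluid phase 0.2, and the local/diffuse parameter
columns. These are idealised conditions — a 1D bar with a symmetric
infected patch, homogeneous material properties, a sharp initial front.
Passing tests on them demonstrates the coupled solver reproduces the
intended phenomenology (confined vs travelling infection, filtration-
driven swelling, lymphatic negative feedback), not that the model is
calibrated to patient data: real myocardium is three-dimensional,
fibrous, actively contracting and heterogeneous, and none of those enter
here.

The one-at-a-time sensitivity driver (`oat_sensitivity()`) scales one
parameter at a time by 0.5/1/2, re-deriving the Lamé constants when the
scaled parameter is Young's modulus, and the directional findings are
asserted as orderings (peak height increases with $\gamma_p$, etc.),
never as exact values.

## Problem sizes used by the test-suite

The structural and property tests run at 100 elements and dt = 0.25 day
(a resolution at which the infected region spans 5 elements and the
150-day run takes a few seconds); the reference-dynamics checks run at
the full 400 elements and dt = 0.1 day, the same configuration the
acceptance script uses. Convergence of the peak times under refinement
(halving both dt and h) was verified to better than 1 %.

## Known limitations

* One spatial dimension only; the travelling-wave character of diffuse
  inflammation in a real ventricle (a front that propagates, collides
  with itself and annihilates) has no 1D analogue beyond front spread.
* No leukocyte decay: inflammation never fully resolves, so leukocyte
  concentration saturates rather than returning to baseline.
* Oncotic pressures are constants; protein transport is not modelled.
* The quasi-static momentum balance means total stress is identically
  zero along the strip: inertia, viscoelasticity and external loading
  (beyond the optional end traction) are out of scope.
* Equal-order linear elements are justified here by the 1D setting and
  the consolidation benchmark; they are not a recipe for 2D/3D mixed
  problems.
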