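---
title: "Alchemical free-energy estimators on analytically tractable systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical free-energy estimators on analytically tractable systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemr)
```

## Scope and model

`alchemr` implements the six estimators commonly compared for
two-dimensional alchemical problems — BAR, TI, extended TI (X-TI),
enveloping distribution sampling (EDS), the hybrid EDS-TI, and 2D-TI —
together with their error estimators, cycle-closure metrics, the
automated EDS parameter search, and convergence/prolongation
algorithms.  The motivating scenario is a residue mutation coupled to
the appearance or removal of a restrained active-site water molecule: a
four-state network (side chain G or A × water present H or dummy D)
with six pairwise perturbations, five audit cycles, and a steric clash
in the fully coupled corner.

All Hamiltonians are configurational.  Momenta contribute equal and
opposite kinetic terms to every free-energy difference considered here,
so they are never represented; sampling is Metropolis Monte Carlo
rather than molecular dynamics, which delivers exact Boltzmann
ensembles without thermostat artifacts.  Units are kJ mol⁻¹, nm, and K
throughout, with k_B = 0.00831446 kJ mol⁻¹ K⁻¹ and a default
temperature of 298 K.

## The coupling model

Perturbed atoms interpolate their own interaction parameters: the
charge linearly, and the Lennard-Jones coefficients through their
square roots, `sqrt(C12)(c) = (1-c) sqrt(C12_A) + c sqrt(C12_B)` (and
likewise C6), so that geometric pair combination commutes with the
interpolation.  Each atom couples to one axis (λ or κ), which makes
simultaneous two-species changes expressible without a global mixing
rule.

Pair interactions use a Beutler-style soft core.  The Lennard-Jones
denominator is `r^6 + alpha_LJ * Lambda^2 * C126` with
`C126 = C12/C6` of the interpolated pair, and the electrostatic
denominator is `sqrt(r^2 + alpha_CRF * Lambda^2)`.  Two conventions
deserve explanation:

- **Softening magnitude.** `Lambda^2` is the *sum of the squared
  decoupling extents* of the pair's perturbed partners, where an atom's
  decoupling extent interpolates an indicator that is 1 at a fully
  noninteracting (dummy) end state and 0 at an interacting one.  The
  softening therefore vanishes at every physical end state, and for a
  pair with a single perturbed partner it reduces exactly to the
  familiar one-axis `alpha * delta^2` form.  The alternative — a
  *product* of the partners' extents — fails in precisely the situation
  this package exists to study: a particle growing in against a fully
  coupled partner would receive no softening at all, and the r⁻¹²
  singularity the soft core is meant to remove reappears mid-path
  (Metropolis chains freeze against the bare repulsive wall).  The sum
  form is the natural two-axis extension of the `(1-λ)²`/`λ²` softening
  of linear-path formulations.
- **C126 at dummy endpoints.** `C12/C6` is 0/0 at a dummy end state.
  It is evaluated through per-atom σ-ratio limits
  (`sqrt(C12)/sqrt(C6)`, replaced by the ratio of derivatives at an
  end where both vanish), which keeps the soft-core denominator and —
  more importantly — the analytic ∂H/∂λ at λ = 0 continuous with its
  interior limit, the quantity TI actually integrates.

Soft-core defaults are `alpha_LJ = 0.5`, `alpha_CRF = 0.5 nm²` (the
usual values for perturbing a water molecule); the steep side-chain
growth runs use `alpha = 1.0`, the standard choice for flattening the
⟨∂H/∂λ⟩ curvature of an appearing group at the cost of more λ-points.

## Toy systems and their oracles

**Quadratic (Gaussian) family.** `quad_system()` takes an arbitrary
positive-definite stiffness `A(λ, κ)` and linear term `b(λ, κ)`;
`analytic_free_energy()` returns
`G = (k_BT/2) log det A − b' A⁻¹ b / 2` up to a state-independent
constant.  Derivative terms use entry-wise central differences of the
user's matrix functions (exact for the bilinear couplings used in the
tests).  This family exercises every estimator with an exact oracle.

**Four-state clash toy.** A mobile 1D (optionally 2D) "water" particle
is pulled to a site by a harmonic restraint (force constant
500 kJ mol⁻¹ nm⁻², target 0 — a deliberately strained on-site pull)
while a "grower" particle appears at that site on the λ axis and the
water's own interactions couple on κ.  Default Lennard-Jones
coefficients (C12 = 7.5 × 10⁻⁵, C6 = 0.075, pair contact distance
σ ≈ 0.32 nm, well depth ≈ 19 kJ/mol, a strong-hydrogen-bond scale)
are chosen so that at full coupling the minimum-energy water–site
distance (≈ 0.34 nm) far exceeds the restraint target while the water
essentially never penetrates the contact distance — the steric clash.
A weak confining background (25 kJ mol⁻¹ nm⁻²) guarantees bounded
corners even for decoupled states.  `quadrature_free_energy()`
integrates the Boltzmann factor deterministically (nested adaptive
quadrature, ≤ 3 dimensions) and is the gold reference for this system.

Two variants serve different purposes:

- the symmetric default (no fixed neighbor) keeps every coupling state
  ergodically sampleable by Metropolis moves, so *all* estimators can
  be validated against quadrature;
- the *confined* variant adds a fixed, unperturbed neighbor particle
  0.45 nm from the site — a one-particle model of binding-site
  crowding.  Its one-sided attraction splits the fully coupled corner
  into disjoint basins separated by effectively impassable barriers.
  This is the "full-strength" clash on which the EDS parameter search
  exhibits its characteristic failure (below); it is *not* used for
  oracle agreement because no estimator can sample it honestly at
  desk scale, which is the very point.

What the toys emulate: end-state strain, steep and curved TI profiles,
envelope-sampling barriers, cycle structure.  What they do not: solvent
fluctuations (end-state energy gaps here are smooth functions of one
coordinate rather than noisy many-body sums), conformational entropy,
and molecular-dynamics integrator artifacts.  Passing tests therefore
validate estimator arithmetic and statistics, not force-field realism.

## Sampling

`metropolis_sample()` runs single-particle random-walk Metropolis with
a step size tuned toward 30–50 % acceptance during burn-in (default
10 % of the run) and frozen afterwards, so detailed balance holds
exactly during production.  Every recorded frame (default stride 10)
carries the energy, both coupling derivatives, the end-state energies
and their gap ΔV_BA, energies re-evaluated at arbitrary neighbor
states (BAR input), and ∂H/∂λ plus H at a dense probe grid (X-TI
input) — the "store everything on the fly" practice that makes
re-analysis cheap.  Identical seeds give bit-identical series; the
caller's RNG stream is left untouched.

## Estimator notes and numerical choices

- **BAR** solves the self-consistency on the strictly monotone
  residual by bracketing plus Brent's method (residual < 10⁻¹⁰), with
  the standard `k_BT log(n₁/n₀)` correction for unequal sample sizes
  (it vanishes for the equal-length runs used here).  Interval errors
  come from contiguous-block re-solving (10 blocks).
- **TI** integrates trapezoidally via half-interval weights
  `Δλ_i = (λ_{i+1} − λ_{i−1})/2`; the weighted per-point errors add in
  quadrature.  Profiles that do not span [0, 1] are refused rather
  than extrapolated.
- **X-TI** predicts the dense profile from each simulated window by
  exponential reweighting and combines overlapping windows by
  inverse-variance weighting of their seeded bootstrap errors
  (100 resamples).  Two safeguards matter in practice: at a probe
  exactly equal to a simulated λ the plain ensemble average is used
  unchanged (bit-for-bit reduction to TI), and a window only enters
  the combination at probes where its reweighting retains at least 5 %
  of its frames as effective samples (absolute floor 10) — far outside
  its overlap region a window's bootstrap variance stays deceptively
  small while the estimate is dominated by a biased tail.  The
  integrated X-TI error is taken from per-bootstrap combined profiles,
  because neighboring dense-grid probes are almost perfectly
  correlated and naive error propagation would understate it several
  fold.
- **EDS** energies use max-subtracted log-sum-exp everywhere; every
  reweighted quantity reports its Kish effective sample size and
  attaches a warning below 10 effective frames.  The two-state
  convention applies the single offset E to the second state.
- **2D-TI** fills the landscape row-major from G(0,0) = 0, computing
  at each node up to three estimates (diagonal, λ-step, κ-step) that
  are combined by Boltzmann averaging over the m available estimates
  (1/m replaces 1/3 at edges).  The steps integrate the mean
  derivatives *trapezoidally* between the two nodes involved.  A
  one-sided (forward-difference) reading of the step equations carries
  an O(Δλ) bias that visibly breaks path independence against 1D TI on
  a 10 × 10 grid; the trapezoidal form is exact for separable linear
  profiles and makes the landscape's edge paths coincide with ordinary
  TI.  Corner-difference errors are propagated along edge paths, a
  deliberately conservative choice.

## The EDS parameter search

The offset E levels the two end states; the smoothness s lowers the
envelope barrier; they are strongly coupled.  The implemented scheme
(constants all exposed in `eds_search_control()`) runs three phases:
an offset phase (E moves by 0.4 k_BT per unit of scaled imbalance
toward the undersampled state), a smoothness phase (s × 0.9 when
transitions are scarce, × 1.1 when abundant, capped at 2, with a
halved E correction kept active), and a refine phase (alternating ±2 %
corrections; at a balanced ratio with adequate transitions nothing
changes — the scheme's fixed point).  A phase advances after its
criterion holds for 10 consecutive rounds; the offset phase
additionally times out after 20 rounds because at the deliberately low
starting smoothness (s = 0.002) the offset has almost no leverage on
the sampling ratio, and without a timeout E runs away while s never
moves.  Convergence is judged mainly on s: relative drift < 5 % over
the trailing 50 rounds, with a balanced trailing ratio and a nonzero
transition count (a search with zero recent transitions is never
reported converged).  If s reaches the underflow bound 10⁻⁴ the search
stops and reports the failure mode: the reference state no longer
samples configurations relevant to both end states.

On an overlap-friendly pair of harmonic wells the search converges
comfortably within 200 rounds of 1500 MC steps; on the confined clash
variant it shows the characteristic pathology — persistent one-sided
sampling with a collapsing s — and flags itself as failed.

## Error estimation and convergence tools

Block averaging uses the pairwise (Flyvbjerg–Petersen) transformation
with the maximum standard error over levels retaining ≥ 8 blocks — a
deterministic, conservative plateau proxy that correctly inflates
errors for autocorrelated series.  The bootstrap (default 100
resamples) is seeded and used where blocking is impractical (X-TI).

Cycle closures are signed sums around audited cycles (edges traversed
against their stored direction flip sign); Σ sums absolute closures
and Ω = (1/N_cycles) Σ |closure|/N_legs.  Both are invariant under
edge reversal, and both vanish identically on any network derived
from a potential on the nodes.

The retrospective prolongation algorithm splits an overall ½ k_BT
budget evenly over the N contributions (λ-points for TI/X-TI,
intervals for BAR; the slightly stricter linear rather than
squared-error split), then repeatedly prolongs the single largest
violator of the accuracy criterion, and afterwards of the precision
criterion, reporting both flanking λ-points for a BAR interval; ties
break toward the lowest λ so plans are deterministic.  The predictive
variant greedily assigns a fixed budget to the contribution with the
largest current effective error `σ_i Δλ_i` under a `1/sqrt(n)` decay
model.

## Problem sizes

The validation suite runs at deliberately modest sizes chosen to keep
statistical and systematic errors honestly separated: 11–33 windows of
3–11 × 10⁴ MC steps for path estimators, 10⁵–10⁶ steps for EDS
production runs, 200 search rounds of 1500 steps, 7 × 7 and 10 × 10
landscape grids, and 101-point dense X-TI profiles.  The hard
side-chain-growth edge uses λ-points clustered in the high-curvature
region of its TI profile (spacing 0.0125 across the peak), the
standard preparatory practice for appearing particles; the same
uniform 10-point grid that works for smooth profiles mis-integrates
this one by design, which is exactly the effect the X-TI comparison
demonstrates.

## Known limitations

- Toy Hamiltonians have at most a few degrees of freedom; there is no
  periodic box, cutoff, pairlist, reaction-field permittivity, or
  force-field topology.
- Electrostatics are plain (softened) Coulomb; no reaction-field
  correction is applied, and all bundled toys are neutral by default.
- The 2D landscape reports statistical errors along edge paths only.
- The EDS search constants are behavior-calibrated for the bundled
  toys; real systems will need the exposed control parameters
  revisited.
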