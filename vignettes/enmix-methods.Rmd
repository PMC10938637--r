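---
title: "Conformational free energies from lambda-perturbed elastic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational free energies from lambda-perturbed elastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Coarse-grained (Martini-style) protein models keep their secondary and
tertiary structure through an *elastic network*: harmonic distance
restraints ("rubber bands") between backbone bead pairs closer than a
cutoff. Because the restraints are single-minimum, a protein prepared in
conformation A can never spontaneously visit conformation B, no matter
how long the simulation. `enmix` implements the alchemical workaround:
build a state-specific network for each conformation, merge the two into
a single dual topology whose restraint parameters depend on a coupling
parameter $\lambda$, and measure the free energy change of sliding
$\lambda$ from 0 (state A) to 1 (state B).

## The model

Every perturbed term is harmonic. For a bead pair $(i,j)$ with endpoint
parameters $(b_0^A, k^A)$ and $(b_0^B, k^B)$, the energy at coupling
$\lambda$ is

$$V_{ij}(\lambda) = \tfrac12\, k(\lambda)\,\bigl(d_{ij} - b_0(\lambda)\bigr)^2,
\qquad
k(\lambda) = (1-\lambda)k^A + \lambda k^B,\quad
b_0(\lambda) = (1-\lambda)b_0^A + \lambda b_0^B .$$

This is the convention a molecular dynamics engine applies to
dual-parameter bond lines (`i j funct b0_A k_A b0_B k_B`), so files
written by `write_perturbed_topology()` mean the same thing to the engine
and to `restraint_energy()`. An alternative energy-linear mode
($V = (1-\lambda)V_A + \lambda V_B$) is available behind
`mode = "energy"` for sensitivity checks only. Note that with the
parameter-interpolated convention the fixed-configuration energy is a
*cubic* polynomial in $\lambda$ (linear $k$ times a quadratic
displacement), which the test suite verifies by an exact four-point fit.

Merging follows set algebra on atom-index pairs, regardless of which
topology section a term sat in (a pair may be a regular bond in one state
and a rubber band in the other):

* identical in both states — copied once, unperturbed;
* present in both with different parameters — perturbed with both
  endpoint sets;
* present in one state only — the missing endpoint gets $k = 0$ and
  (by choice) the *existing* state's $b_0$ as an inert but physically
  plausible minimum.

Everything non-harmonic (regular angles, constraints, all passthrough
directives) must be identical between the states and is carried over
untouched; a difference there is an error, because the method perturbs
restraints only. Restricted bending angles (function type 10), which the
engine cannot $\lambda$-perturb, are converted to ordinary
cosine-harmonic angles (type 2) with unchanged parameters by
`convert_restricted_angles()`.

Given per-window work samples
$w_F = U(\lambda_{i+1}) - U(\lambda_i)$ on the $\lambda_i$ ensemble and
$w_R = U(\lambda_i) - U(\lambda_{i+1})$ on the $\lambda_{i+1}$ ensemble,
the interval free energy solves the Bennett acceptance-ratio equation

$$\sum_F \frac{1}{1 + e^{\,\ln(n_F/n_R) + \beta(w_F - \Delta G)}}
 = \sum_R \frac{1}{1 + e^{\,\ln(n_R/n_F) + \beta(w_R + \Delta G)}},$$

found by a bracketing root search (the residual is monotone in
$\Delta G$). Interval estimates are summed along the path; thermodynamic
integration (trapezoidal quadrature of the mean
$\partial H/\partial\lambda$) is provided as the independent second
route. Relative free energies between condition sets follow
$\Delta\Delta G_{AB}(XY) = \Delta G_{AB}(Y) - \Delta G_{AB}(X)$, and
`cycle_absolute()` closes the four-legged thermodynamic cycle
$\Delta G_{AB}(Y) = \Delta G_{AB}(X) - \Delta G_A(XY) + \Delta G_B(XY)$.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| elastic-network force constant | 500 | kJ/mol/nm$^2$ | common production value for Martini elastic networks |
| network cutoff | 0.9 | nm | standard contact cutoff for backbone bead pairs |
| minimum sequence separation | 2 | residues | first neighbours are covered by regular backbone bonds, not the network; the exact value used by coarse-graining tools varies, so it is a documented knob |
| temperature | 310 | K | physiological reference; $k_BT \approx 2.5775$ kJ/mol with $k_B = 0.00831446$ kJ/mol/K |
| $\lambda$ schedule | 29 points | — | 0.05 spacing through the middle, densified ends where restraints switch on/off; a uniform 21-point grid is the quick alternative |
| error blocks | 5 | — | block averaging with five contiguous blocks, the engine-default convention |
| `k_scale` | 1 | — | scalar on all rubber-band force constants (0.5 or 2 for stiffness sensitivity scans) |

Distance ties exactly at the cutoff are *included*; pairs are emitted
sorted by `(i, j)` so network files diff reproducibly. Atomic charges
must agree between the states unless `allow_charge_diff = TRUE` is
passed: a protonation change belongs to the condition leg of the cycle,
not to the conformational path.

On the 29-point schedule: the printed end-point values (0.0167, 0.983)
round thirds of 0.05 at different precisions, so the list is symmetric
about $\tfrac12$ only to about $10^{-3}$; `lambda_schedule_dense29()`
returns the printed values verbatim rather than an idealized symmetric
grid.

## What the synthetic generator emulates — and what it does not

`make_fixture_structures()` builds two bead chains with identical
composition (one backbone bead per residue plus a seeded number of
side-chain beads) and different geometries — a compact helix-like coil
versus an extended or random-walk chain — standing in for an
experimentally determined conformer pair. `toy_oscillators()` and
`toy_system_from_topology()` turn perturbed topologies into samplable
toy systems, and `sample_window()` runs Metropolis Monte Carlo
(single-bead Gaussian proposals, acceptance $\min(1, e^{-\beta\Delta U})$)
rather than molecular dynamics: detailed balance is a simpler correctness
contract than an integrator, and only equilibrium ensembles matter for
the estimators. The proposal width is auto-tuned toward a 30–60%
acceptance rate during burn-in and frozen before production.

The toy world contains no nonbonded interactions, solvent, membranes, or
kinetics. A green pipeline test therefore establishes that the
*machinery* — network construction, mixing, file formats, sampling,
estimation, error bars — is correct against analytic references; it says
nothing about force-field accuracy or about the sampling hardness of
real microsecond-scale transitions.

Analytic anchors used by the tests:

* independent 1-D tethered oscillators:
  $\Delta G = \tfrac{k_BT}{2}\sum_i \ln(k_i^B/k_i^A)$, with $b_0$ shifts
  contributing nothing (the closed form is 1-D only; 3-D distance
  restraints carry Jacobian terms and are validated by BAR–TI and
  forward–reverse consistency instead);
* Crooks-consistent Gaussian work pairs
  ($w_F \sim \mathcal N(\mu,\sigma^2)$,
  $w_R \sim \mathcal N(-\mu + \beta\sigma^2, \sigma^2)$) with implied
  truth $\Delta G = \mu - \beta\sigma^2/2$.

## Numerical choices

* **BAR root search** brackets by doubling until the residual changes
  sign within $\pm(\max|w| + 50\,k_BT)$; the residual's monotonicity
  makes the root unique. Distributions with no statistical overlap
  produce a numerically flat residual plateau, so the solver additionally
  rejects solutions whose mean Fermi weights fall below $10^{-10}$ and
  advises adding $\lambda$ points.
* **Errors.** The default error is the block-averaging standard error:
  each window's series is split into 5 contiguous blocks, re-estimated
  per block, and the sample standard deviation of block estimates divided
  by $\sqrt{n_{\text{blocks}}}$ (the wording "average variance over
  blocks" is ambiguous; this reading is implemented and frozen). Interval
  errors sum *linearly* along the path and across conditions — the
  conservative engine-reporting convention — with quadrature combination
  behind a flag. The per-window block error is individually noisy for
  few blocks; the path-summed error is the stable, reported quantity. A
  Fermi-weight asymptotic standard error (`err_asymptotic`,
  `bar_asymptotic_err()`) is exposed as an iid cross-check.
* **Convergence flag** compares the last two fractional re-estimates
  against twice the path-summed *asymptotic* error: the block error
  inflates under slow drift and would mask exactly the non-stationarity
  the check is meant to expose.
* **Autocorrelation** is the normalized autocovariance; the integrated
  time truncates at the first nonpositive value (no windowing schemes).
* **Superposition** uses the singular-value solution with the
  determinant sign forced positive, so reflections are never applied.
* **Exchange identity.** With the sign conventions above (each direction's
  work computed in its own ensemble), exchanging the forward and reverse
  sets negates the BAR estimate exactly — no renegation of the samples is
  involved; this is the forward/reverse hysteresis check.
* **One-sided windows** (empty reverse set) fall back to exponential
  averaging with a warning flag on the result; this is a rescue path,
  not a recommendation.

## Known limitations

* The topology dialect covers the subset the method touches (atoms,
  harmonic bonds, rubber bands, angles types 2/10, constraints);
  everything else round-trips verbatim but is not modelled. Preprocessor
  semantics (`#ifdef`, `#include`) are out of scope.
* Pair matching during mixing is by atom index; inputs renumbered
  differently (e.g. after trimming loops) must be reconciled by the
  caller first.
* The sampler is for validation-scale systems; it makes no attempt at
  the performance or ensembles of a real MD engine, and dihedrals,
  nonbonded perturbation, and soft-core transformations are deliberately
  absent.
* `analytic_dG()` refuses coupled or 3-D systems rather than returning a
  subtly wrong closed form.

No empirical claim in this document goes beyond what the test suite and
`scripts/acceptance.R` recompute at run time.
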