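---
title: "Fitting pair potentials to radial and energy distribution functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting pair potentials to radial and energy distribution functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dffit)
```

## The problem

A pairwise-additive force field is determined, up to a constant, by the
equilibrium pair distribution function it generates (Henderson's
uniqueness theorem). Structure-based parametrization exploits this:
choose the parameters of a candidate potential so that its distribution
function (DF) matches a target DF obtained from a reference calculation.
Classically the radial distribution function g(r) is matched (as in
iterative Boltzmann inversion), but similar g(r) can arise from different
potentials, making the inversion ill-conditioned. `dffit` additionally
implements matching of the *energy distribution function* (EDF) — the
histogram of pairwise interaction energies u(r_ij) between a reference
molecule and its in-range partners — which responds much more directly to
each potential parameter and has a naturally bounded support.

This vignette documents the model, the estimators, the objective, the
optimizer, and the design decisions behind them.

## The molecular model

A rigid 3-site water-like molecule carries five parameters: the
Lennard-Jones diameter σ (nm) and well depth ε (kJ/mol) on the oxygen
site, the oxygen charge q (e, negative), the O–H bond length d (nm) and
the H–O–H angle a (degrees). Hydrogens carry charge −q/2 each and no van
der Waals terms, so the molecule is always neutral. A monatomic LJ fluid
is the q = 0, single-site special case. TIP3P
(0.315061, 0.636386, −0.834, 0.09572, 104.52) and SPC/E
(0.316557, 0.650629, −0.8476, 0.1, 109.47) ship as presets.

Internal units are nm, kJ/mol, e, degrees and Kelvin, with Coulomb
constant 138.935458 kJ mol⁻¹ nm e⁻². The energy-bin definition table is
specified in kcal/mol and converted once, exactly (1 cal = 4.184 J), at
scheme construction. One deliberate relaxation of the parameter
invariants: the angle is allowed to reach 180° exactly, so the collinear
degenerate geometry (zero dipole) is representable.

In optimizer space the parameters appear as the search vector
(σ, ε, q, d, a/500); the angle is scaled by 500 so that all coordinates
have magnitude of order 0.1–1 and a single isotropic initial step (0.01)
is meaningful. With the molecular geometry held fixed, the vector reduces
to (σ, ε, q); for a bare LJ fluid, (σ, ε).

## The sampler and what it stands in for

Target DFs in a production setting come from a molecular-dynamics engine.
The package's internal sampler is a Metropolis Monte Carlo engine for
periodic cubic boxes: single-molecule translations (plus rigid rotations
for water-like species) accepted with probability min(1, exp(−ΔU/k_BT)).
For the optimization loop this is sufficient — only equilibrium
configurations enter the DFs — and it keeps the whole pipeline
reproducible at desk scale. Consequences of that substitution, stated
openly:

* **Truncation scheme.** Both LJ and Coulomb terms are truncated and
  shifted to zero at a cutoff (default 1.0 nm, capped at L/2). A
  production MD engine would use PME electrostatics and a switched vdW
  cutoff; truncated-shifted Coulomb distorts the dielectric environment
  of a dense polar fluid. Candidate and target always use the *same*
  scheme, so the matching problem remains exactly posed, but absolute
  water properties (pressure, dielectric constant) deviate from
  literature MD values.
* **Molecule pairs are "in range"** when their first-site (oxygen)
  minimum-image distance is below the cutoff; the EDF counts exactly
  those pairs. The pair energy in the EDF uses the same truncated-shifted
  scheme as the sampler, keeping the two consistent.
* **Nominal time.** The budget-doubling rule speaks in picoseconds for
  MD-adapter compatibility; the internal sampler maps 1 ps ≡ 10 sweeps
  (one sweep = N single-molecule move attempts). The default initial
  budget, 250 ps ≡ 2500 sweeps, and the cap, 100 ns, carry over
  unchanged.
* **Move sizes** auto-tune toward ~40 % acceptance during equilibration
  and are frozen for production, so production sampling is unbiased.
  Proposals are symmetric (uniform displacement cube, uniform rotation
  angle about a uniform axis), satisfying detailed balance; a χ² test of
  the two-particle radial visit distribution against
  r² exp(−u/k_BT) is part of the test suite.
* **System sizes.** Default validation systems use 64–216 molecules
  rather than 1000: the DF domain is then limited by min(1.5 nm, L/2).
  All estimators are N-agnostic.

Energy bookkeeping is incremental (ΔU per accepted move) with a full
O(N²) recomputation every 1000 sweeps; the maximum relative drift is
recorded in the trajectory metadata and asserted ≤ 1e−8 in the tests.

## Distribution-function estimators

Both estimators count **both orderings** of each molecule pair, matching
the per-reference-molecule definition (each molecule sees each partner).

* **RDF**: value in bin [r_lo, r_hi) =
  count / (N_frames · N · 4π r_mid² Δr · ρ₀), with ρ₀ = N/V and r_mid the
  bin midpoint. Using the midpoint instead of the exact shell volume is a
  second-order difference in Δr and cancels between candidate and target.
  The scheme domain must not exceed L/2 (minimum-image validity).
* **EDF**: value in bin [e_lo, e_hi) = count / (N_frames · N · Δe) — a
  density per kJ/mol per molecule whose integral is the mean number of
  in-range partners. Pair energies outside the scheme's fixed span
  (−30.02 to 30.22 kcal/mol) are dropped, not clamped; the dropped
  fraction is recorded. Values are densities (not raw counts) so the
  Δx_i weighting of the fitness is meaningful across the non-uniform
  energy bins.

Per-bin uncertainties come from block averaging: the trajectory is split
into 10 consecutive equal blocks, the DF is computed per block, and the
population standard deviation (divisor n_blocks) across blocks is the
per-bin σ.

**Bin schemes.** Radial schemes are uniform over [0, 1.5 nm] with the
eleven studied widths (1–500) × 10⁻⁵ nm. Energy schemes follow a
five-region table in kcal/mol — outer regions (−30.02, −0.22) and
(0.22, 30.22) always at 0.04; inner regions at 0.002·I_i, 0.0002·J_j and
0.002·K_k with I = (1, 2, 4, 10, 20), J = (1, 2, 4, 8, 20, 40, 100, 200),
K = (1, 2, 4, 10, 20) — giving 200 definitions indexed by
ID = 40(i−1) + 5(j−1) + k. Definition 40 (i = 1, j = 8, k = 5), which
merges the near-zero region into a single 0.04 kcal/mol bin, is the
default: a single wide zero bin has a tiny relative block SD, which
*increases* its weight in the fitness and improves the distinguishability
of nearby parameter sets.

## The objective and its edge cases

`fitnessEq1` implements

fitness = Σ_i (ρ_i^cand − ρ_i^target)² / (σ_i^cand σ_i^target) · Δx_i,

summed over the shared scheme (a scheme mismatch is an error, never a
silent rebinning). The product form multiplies the RDF- and EDF-based
values. Properties relied on elsewhere: non-negativity, zero iff the DFs
coincide, symmetry, strict monotonicity in any single-bin deviation, and
linearity in a uniform Δx scaling — all tested.

**Zero-uncertainty bins** are the one genuinely open numerical corner. A
bin with σ^cand σ^target = 0 contributes zero when the squared difference
is also zero (both DFs agree the bin is deterministic — typically empty),
and raises an error otherwise: silent regularization would hide
undersampling. For practical desk-scale runs a configurable floor
`sigmaFloor` (default off) clamps the SDs from below; the recovery
experiments use 1e−4, which is below the density contributed by a single
pair count in an outer-region bin at the default budget, so the floor
only touches bins that are effectively empty.

**Threshold.** Three replicate target runs give three pairwise fitnesses;
their maximum is the convergence threshold — the fitness level at which a
candidate is statistically indistinguishable from a replicate of the
target itself. `thresholdValue` applies the max rule; with the product
objective the two single-kind thresholds are multiplied.

## The optimizer

CMA-ES with the combined rank-one + rank-μ update and cumulative
step-size adaptation, implemented in the package with the canonical
default parameters (weights, learning rates, damping as in the standard
tutorial formulation). Only fitness rankings enter the update; the tests
assert iterate-for-iterate invariance under exp-transformation of the
objective, and a 5-D sphere benchmark (λ = 60, step 0.01 from (1, …, 1))
reaching 1e−10 within 200 generations. A degenerate covariance (condition
number above 1e14) restarts the matrix with an inflated step — logged,
never fatal.

The outer loop per generation: propose λ = 12 × n_params individuals;
sample each at the current budget with a per-individual RNG stream
derived from (master seed, generation, index); evaluate the fitness;
stop if the generation best is at or below the threshold; otherwise apply
the budget rule and the CMA-ES update. Two wordings in the source
procedure required a decision:

* **Convergence** is interpreted as *best fitness ≤ threshold* (the
  alternative reading, "decreased by more than the threshold", is
  inconsistent with the threshold's replicate semantics).
* **The doubling rule** is implemented literally: double when
  best_t > best_{t−1} AND scale · avg_t > avg_{t−2}, with scale 2 for
  single-kind and 4 for product fitness, budgets capped at 100 ns
  equivalent. Read literally the rule fires easily in early generations
  (average fitness starts high); since each generation's fitnesses are
  kept as evaluated at their own budget (no re-evaluation of history),
  this is benign — the budget is monotone and capped, which the tests
  assert.

Individuals whose parameters are unphysical (negative σ, |a| out of
range, failed sampling) receive a penalty of 10 × the largest finite
fitness seen, keeping λ constant as the CMA-ES update assumes.

## The recovery experiment

`ljRecoveryExperiment` is the package's end-to-end validation: an LJ
fluid with σ = 0.34 nm, ε = 1 kJ/mol, N = 100 at reduced density 0.6 and
reduced temperature 1.5 (a dense supercritical state with pronounced
structure but no phase coexistence), cutoff 0.9 nm, EDF definition 40,
three replicate targets at 250 ps nominal budget each, and an optimization
started at +5 % in both parameters. The generating parameters are ground
truth, so the recovered relative errors measure the entire pipeline.
Across seeded repeats the recovered σ and ε land well inside 2 %; the
acceptance suite requires 4 of 5 fixed seeds inside that band. Problem
sizes (N = 100, 2500 production sweeps per evaluation, 10 blocks,
≤ 20 generations) are chosen so one repeat completes in minutes on a
single core while the threshold is still tight enough to force sub-percent
recovery.

One condition differs deliberately from the full-scale procedure: the
per-individual budget cap is 500 ps — one doubling above the target
budget — rather than the 100-ns cap of an MD campaign. Because the
targets here are themselves sampled at 250 ps, the expected fitness of a
truth-level candidate behaves like σ_c/σ_t + σ_t/σ_c per bin: it is
*minimized at matched sampling* and grows again as the candidate budget
outruns the targets' (the candidate's shrinking uncertainties deflate the
denominator faster than the residual shrinks). Larger caps therefore
raise the fitness floor while multiplying wall time; in the MD setting
this does not arise because the targets are sampled two orders of
magnitude longer than any candidate. The doubling rule itself is active
and exercised within the cap.

What passing this experiment does **not** show: recovery of a 5-parameter
polar molecule at MD fidelity (PME electrostatics, 1000-molecule boxes,
100-ns trajectories), condensed-phase property prediction, or
transferability of fitted parameters — those require the original MD
setting that this package deliberately replaces at desk scale.

## Known limitations

* Truncated-shifted electrostatics bias absolute water-model properties;
  the EDF/RDF *matching* problem is unaffected, but fitted water
  parameters should not be compared numerically against PME-based
  literature values.
* The EDF convention counts both orderings of each pair; a different
  global factor would rescale fitness values but cancel in threshold
  comparisons.
* `sigmaFloor` trades the fail-loudly contract for practicality on
  sparse bins; it is off by default and its value is reported wherever
  used.
* The sampler is canonical (NVT) only; no constant-pressure ensemble,
  no dynamics, no transport properties.
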