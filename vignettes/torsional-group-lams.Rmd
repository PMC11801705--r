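---
title: "Torsional-group-partitioned local approximate models of intramolecular energy"
author: "lampart authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional-group-partitioned local approximate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lampart)
```

## The problem

Crystal structure prediction (CSP) enumerates the crystal packings a
molecule can adopt and ranks them by lattice energy. For a flexible
molecule the lattice energy contains an intramolecular part: the energy
penalty $\Delta U^{\mathrm{intra}}(\theta)$ of the conformation with
flexible torsions $\theta$, relative to the isolated-molecule (in vacuo)
minimum $U^{\mathrm{vac}}$. Evaluating it exactly requires a constrained
quantum-mechanical (QM) minimization — fix $\theta$, relax everything
else — which is far too expensive to call inside a global search that
performs hundreds of thousands of lattice-energy minimizations.

The standard remedy is a database of **local approximate models (LAMs)**:
constrained minimizations are performed once, at a set of reference
torsion values, and each solution is stored together with its derivative
blocks. Around reference point $\theta^{\mathrm{ref}}$, with
$d = \theta - \theta^{\mathrm{ref}}$ wrapped per-torsion into
$(-180^\circ, 180^\circ]$:

* energy, second order:
  $\Delta U^{\mathrm{intra}} \approx (U^{\mathrm{ref}} - U^{\mathrm{vac}})
  + b^{\mathsf T} d + \tfrac12 d^{\mathsf T} H d$;
* dependent degrees of freedom (bond lengths, bond angles, non-flexible
  torsions) and atomic point charges, first order:
  $\beta \approx \beta^{\mathrm{ref}} + K d$,
  $q \approx q^{\mathrm{ref}} + A d$,

where $b$ and $H$ are the gradient and Hessian of the *reduced*
(dependent-DoF-relaxed) energy at the solution, and $K$, $A$ the property
Jacobians. The energy model is second order because the energy enters the
lattice-energy objective directly; the dependent DoFs and charges enter
through geometry and electrostatics and a first-order model suffices.
(When the source formulation leaves the symbol assignment of the
derivative matrices ambiguous, this package takes the energy block to be
the Hessian and the property blocks to be single Jacobians, consistent
with a second-order energy / first-order property expansion; the class
documentation of `reference_record` states this explicitly.)

On a uniform grid the number of reference points grows exponentially with
the number of flexible torsions $l$. **Torsional-group partitioning**
breaks that growth: the torsions are split into $N_G$ disjoint groups
$\theta_g$ that are assumed to contribute *additively* to the deviations
from the in vacuo values. Each group gets its own reference set, fitted
with all other groups pinned at their in vacuo torsions, and a query is
answered by

$$U = U^{\mathrm{vac}} + \sum_g \Delta U_g(\theta_g), \qquad
\beta = \beta^{\mathrm{vac}} + \sum_g \Delta\beta_g(\theta_g), \qquad
q = q^{\mathrm{vac}} + \sum_g \Delta q_g(\theta_g),$$

with each $\Delta_g$ evaluated at the group's nearest reference point.
The oracle-call bill drops from $\prod_t N_t + 1$ to
$\sum_g N_{g,\mathrm{ref}} + 1$. The approximation is good whenever the
groups are geometrically separated (for example on opposite sides of an
aromatic ring) so that their couplings are weak.

## What the package provides

`lampart` implements the full workflow against any oracle satisfying the
`conformational_model` contract — `minimize_at(model, theta)` returning
energy, dependent DoFs, charges and derivative blocks:

1. `molecule_spec()` declares the torsions, their group partition and the
   dependent-DoF/charge schemas.
2. `build_partitioned_database()` / `build_full_database()` perform the
   in vacuo search (`minimize_vacuo()`) and the reference fits
   (`fit_reference()`) on uniform grids in either dialect
   (`grid_wraparound()`, `grid_bounded()`, `grid_points()`), logging
   every oracle call in a `call_ledger`.
3. `lam_evaluate()` answers queries by nearest-reference Taylor
   evaluation and the additivity rule; conformations scoring below the
   current in vacuo minimum are flagged, and `rebase_vacuo()` re-anchors
   the database (confirming the lower minimum, replacing the in vacuo
   record and refitting every reference).
4. `adaptive_refine()` densifies a group's reference set where the LAM is
   inaccurate *and* the region matters.
5. `sample_uniform()`, `filter_relevant()` and `assess_accuracy()`
   implement the accuracy-assessment protocol.
6. `save_lam_database()` / `load_lam_database()` archive the result;
   `inst/cli/lampart.R` wires everything into shell subcommands.

## The synthetic conformational model

Real oracles are QM engines; for development, testing and method studies
the package ships a fully synthetic stand-in (`make_synthetic_model()`)
with the same mathematical structure:

* per-torsion potentials, either cosine series
  $\sum_k a_k\,(1 - \cos(n_k(\theta - \phi_k)))$ or quadratic bowls
  $\tfrac12 c\, w(\theta - \theta_0)^2$ in the wrapped deviation;
* pairwise couplings $a \cos(\theta_i - \theta_j + \phi)$, applied at
  full strength within a group and scaled by a single knob
  $\varepsilon$ (`cross_coupling_epsilon`) between groups;
* dependent DoFs bound harmonically to torsion-dependent equilibria
  (sinusoidal or affine maps), so at the constrained minimum they equal
  those equilibria exactly and the reduced energy is available in closed
  form, with analytic gradients, Hessians and Jacobians;
* charges from an analogous map constrained so the derivative of the
  total charge with respect to every torsion vanishes identically.

At $\varepsilon = 0$ the reduced energy is *exactly* a sum of per-group
functions, so group additivity is exact and every residual error is
attributable to the Taylor truncation; the test suite uses this to verify
that partitioning itself introduces no error (the partitioned energy
error decomposes identically into per-group single-LAM errors). Quadratic
bowls with affine property maps go further: there the Taylor models are
exact everywhere, giving a machine-precision end-to-end oracle
(`fixture_quadratic()`). Turning $\varepsilon$ up lets one study how the
additivity approximation degrades — mean surrogate error grows
monotonically with $\varepsilon$, and splitting a genuinely coupled pair
of torsions into separate groups degrades accuracy in the same way.

What the synthetic model does **not** emulate: real QM surfaces have
anharmonicities tied to specific chemistry, dependent-DoF relaxations
that can be discontinuous at conformational transitions, charge
redistributions from genuine electron flow, and multiple conformers of
the dependent coordinates at fixed $\theta$. Passing tests on the
synthetic model therefore validate the *machinery* — grids, accounting,
Taylor evaluation, additivity, refinement — not the physical accuracy of
LAMs on any particular compound, which must be judged with
`assess_accuracy()` against a real oracle.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| grid increment / offset | degrees | 60 / 30 (wraparound fixtures) | reference spacing; 60° balances cost against Taylor error for typical barriers |
| `delta_star` ($\Delta^*$) | kJ/mol | 5 | adaptive refinement: LAM error above this adds a reference |
| `delta_star_star` ($\Delta^{**}$) | kJ/mol | 20 | crystallographic-relevance ceiling; conformations above it are ignored by refinement and assessment |
| `cutoff` in `filter_relevant()` | kJ/mol | 20 | same ceiling in the assessment protocol |
| `fd_step` in `oracle_model()` | degrees | 1 | central-difference step for derivative-free oracles; small against 60–120° grid spacings |
| `cross_coupling_epsilon` | – | fixture-specific | strength of inter-group coupling in the synthetic model |

$\Delta^*$ is interpreted as the surrogate-error tolerance and
$\Delta^{**}$ as the relevance cutoff; the refinement loop probes seeded
low-discrepancy (Halton) candidates over the group's domain, skips
irrelevant ones, and stops when a full sweep adds no reference or the
candidate budget is exhausted (the database is then flagged
non-converged rather than silently accepted).

## Numerical choices

* **Angles** are degrees everywhere, on $[0, 360)$; derivative units are
  per degree. Deviations wrap into $(-180^\circ, 180^\circ]$, which keeps
  every expansion local and makes evaluation invariant to $360^\circ$
  shifts of any input torsion.
* **Nearest reference** means smallest Euclidean norm of the wrapped
  per-torsion deviations; exact ties go to the lowest record index, so
  evaluation is deterministic.
* **Energy zero**: models report absolute energies; every reported
  $\Delta U^{\mathrm{intra}}$ is taken against the database's in vacuo
  energy. Parity $R^2$ (squared Pearson correlation of LAM vs oracle
  $\Delta U$) is invariant to a common offset.
* **Single nearest point** only: smoothed/weighted multi-point LAM
  averaging is a deliberate non-goal of this package.
* The **in vacuo record is not added as a reference point** of any group;
  the worked two-torsion example counts 12 references plus the separate
  in vacuo minimization.
* **Accounting**: the ledger records every oracle call by purpose. The
  conventional totals (sum/product plus one) count the in vacuo
  minimization once — regardless of how many local-search starts it used
  — plus the stored references; adaptive candidates that were probed but
  rejected are logged separately as `adaptive_probe` so the ledger
  remains an honest record of oracle work.
* **Archives** are single-file RDS containers with an explicit format
  version; round-trips are bit-exact, and loading re-validates the
  structural invariants, checks an optional expected molecule schema, and
  flags databases whose references lie below the stored in vacuo energy
  (stale, pre-rebase state).
* **Degenerate inputs** fail loudly: empty grids, non-partitioning group
  lists, duplicate reference points (within wrap tolerance), dimension
  mismatches and non-finite oracle energies are all errors, not warnings.

## A worked example

```{r example}
fx <- fixture_fig1()          # two torsions, one per group
db <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                 starts = fx$starts)
ledger_total(db$ledger)       # 12 reference fits + 1 in vacuo = 13
lam_evaluate(db, c(104, 235)) # picks the references at 90 and 210 degrees
```

Scaling the same machinery up, the three-torsion fixture with 60-degree
wraparound grids needs 43 partitioned calls against 217 non-partitioned
(an 80% reduction); the narrow-range bounded grids of the
paracetamol-like fixture give 29 against 76 (62%); the restricted
eight-torsion fixture gives 25 against 129. For adaptive databases whose
per-group record counts are known, `projected_call_counts()` reports the
totals and the full-equivalent size (the product of per-group counts)
without any oracle work.

## Problem sizes used by the tests

The test-suite and acceptance-script study conditions are the fixtures'
defaults: 60-degree (or coarser, for refinement demonstrations) grids,
2000-point uniform samples for the assessment protocol with the 20 kJ/mol
relevance cutoff, 100–200-point samples for the property checks, and
1-degree validation scans for one-dimensional groups. These sizes were
chosen as the smallest at which each property is unambiguous; all run in
seconds on one CPU.

## Known limitations

* The additivity assumption is structural: nothing in the package
  detects a *bad partition* automatically — `assess_accuracy()` with a
  deliberately split group is the diagnostic.
* The quadratic-bowl potential is smooth everywhere except at the
  antipode of its centre (an artifact of wrapping); fixtures place
  centres and grids so the seam is never crossed.
* The adaptive loop refines against the point oracle only; it inherits
  the single-nearest-point evaluation, so its converged error bound is
  $\Delta^*$ in the relevant region, not globally.
* `minimize_vacuo()` is a multi-start local search; a poor start set on a
  rugged surface can anchor the database at a non-global minimum. The
  below-vacuo flag plus `rebase_vacuo()` is the recovery path, exactly as
  in production use.
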