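# lampart

Torsional-group-partitioned **L**ocal **A**pproximate **M**odels of
intramolecular energy, for crystal structure prediction (CSP) workflows.

## The problem

CSP global searches perform enormous numbers of lattice-energy
minimizations, and for a flexible molecule each one needs the
intramolecular energy penalty ΔU<sup>intra</sup>(θ) of a conformation
with flexible torsions θ, plus the relaxed molecular geometry and the
conformation-dependent atomic charges. Computing these exactly means a
constrained quantum-mechanical (QM) minimization per query — intractable
inside a search. The practical substitute is a database of **local
approximate models (LAMs)**: constrained minimizations performed once at
reference torsion values, each stored with its derivative blocks and
evaluated as a Taylor expansion around the nearest reference,

ΔU<sup>intra</sup> ≈ (U<sup>ref</sup> − U<sup>vac</sup>) + bᵀd + ½ dᵀH d,  β ≈ β<sup>ref</sup> + K d,  q ≈ q<sup>ref</sup> + A d,

with d the wrapped deviation from the reference point, b/H the reduced
energy gradient/Hessian, and K/A the Jacobians of the dependent degrees
of freedom and charges.

A uniform reference grid grows exponentially with the number of flexible
torsions. This package implements the **torsional-group partitioning**
scheme that removes the exponential: torsions are split into groups
assumed to contribute *additively* to the deviations from the in vacuo
conformation. Each group gets its own (uniform or adaptively refined)
reference set, fitted with the other groups held at their in vacuo
values, and a query combines per-group contributions:

U = U<sup>vac</sup> + Σ<sub>g</sub> ΔU<sub>g</sub>(θ<sub>g</sub>),  and likewise for β and q.

The QM bill drops from ∏ N<sub>t</sub> + 1 calls to
Σ<sub>g</sub> N<sub>g,ref</sub> + 1.

The package is aimed at developers and users of CSP pipelines who want
the LAM machinery — grids in both field dialects, oracle-call
accounting, nearest-reference evaluation with the additivity rule,
in vacuo rebasing, adaptive refinement, accuracy assessment, archiving —
exercised and testable without a QM engine: a built-in synthetic
conformational model with closed-form constrained minima and analytic
derivatives stands in for the QM oracle, and any real engine can be
plugged in through the same `conformational_model` contract
(`oracle_model()` adds wrap-aware finite-difference derivatives for
oracles that lack them).

## Worked example

Two flexible torsions, trivially split into two one-torsion groups, six
reference points per group on a 60° wraparound grid (first point at 30°):

```r
library(lampart)
fx <- fixture_fig1()
db <- build_partitioned_database(fx$model, fx$molecule, fx$grids,
                                 starts = fx$starts)
ledger_total(db$ledger)
#> [1] 13
lam_evaluate(db, c(104, 235))
#> LAM evaluation
#>   delta_U: 22.064 kJ/mol
#>   per-group contributions:
#>  group_id ref_index   delta_U
#>         1         2 14.027816
#>         2         4  8.036184
```

Thirteen oracle calls built the database (12 reference fits plus one
in vacuo minimization), and the query at θ = (104°, 235°) was answered
from the references at 90° (record 2 of group 1) and 210° (record 4 of
group 2); `delta_U` is the group-additive intramolecular energy above the
in vacuo minimum in kJ/mol.

The same accounting at three torsions (groups {1} and {2, 3}, 60° grids)
gives 43 partitioned vs 217 non-partitioned calls — an 80% reduction:

```sh
$ Rscript inst/cli/lampart.R count --fixture paraben
per-group reference points: 6, 36
partitioned oracle calls:  43
non-partitioned calls:     217
reduction:                 80.2%
```

The CLI (`inst/cli/lampart.R`) also exposes `fixture`, `vacuo`, `build`,
`adapt`, `evaluate` (single θ or a TSV batch), and `assess`
(the sampling → 20 kJ/mol relevance filter → LAM-vs-oracle comparison
protocol, reporting per-category average absolute deviations, the
maximum energy error and the parity R²). Every run writes a JSON
manifest with its inputs and seeds.

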