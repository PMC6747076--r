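---
title: "Multi-endpoint 3D-QSAR with a fuzzy comprehensive evaluation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-endpoint 3D-QSAR with a fuzzy comprehensive evaluation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzcomfa)
```

## The problem

Classical QSAR models one endpoint at a time.  For drug families such as the
fluoroquinolone antibiotics, however, the safety profile is intrinsically
multi-endpoint: the same scaffold interacts with the GABA receptor
(convulsive toxicity), cyclooxygenase (gastrointestinal toxicity) and the
hERG potassium channel (cardiotoxicity).  `fuzzcomfa` implements a workflow
that collapses several per-endpoint scores into one response — a
*comprehensive evaluation index* (CEI) — and then models that response
against CoMFA-style molecular interaction fields, so that a single 3D-QSAR
model captures the joint adverse-reaction profile and can steer
derivative design toward reducing all endpoints at once.

## Fuzzy comprehensive evaluation

Given a compounds-by-endpoints score matrix \(c_{ij}\) (compound \(j\),
endpoint \(i\); docking scores in the motivating application), each endpoint
is converted to a membership value with the large-scale (min–max) membership
function

\[ r_{ij} = \frac{c_{ij} - \min_j c_{ij}}{\max_j c_{ij} - \min_j c_{ij}}, \]

the extrema taken over compounds **within one endpoint**.  This is the only
reading of the membership definition that reproduces the published index
column, and it makes \(r\) dimensionless, affinely invariant per endpoint,
and anchored so that the worst compound on an endpoint scores 1 and the best
scores 0 (for a larger-is-worse endpoint; an orientation flag mirrors the
mapping).  A degenerate endpoint (all compounds equal) has no information and
errors by default rather than contributing a silent constant.

The weighted-average aggregation model then gives the index

\[ \mathrm{CEI}_j = \sum_i a_i\, r_{ij}, \qquad \sum_i a_i = 1,\ a_i \ge 0 .\]

The weights are configuration, not estimated: in the bundled study they are
(0.50, 0.40, 0.10) for the convulsive/gastrointestinal/cardiac endpoints,
reflecting relative clinical incidence.  With weights on the simplex the CEI
is a convex combination, hence bounded in \([0,1]\), monotone in every
endpoint, and equal to 1 exactly for a compound that is worst on every
endpoint.  Only this weighted-average operator is implemented; max–min and
other fuzzy compositions are out of scope.

Display values are rounded to 3 decimals, half away from zero
(`round_half_up()`), matching how such tables are printed; all internal
arithmetic is full precision.

## Interaction fields

Molecules must arrive aligned (rigid least-squares superposition onto a
template framework is provided via `superpose_on_framework()`, a Kabsch
fit over user-labeled framework atoms; conformer generation, force-field
minimization and charge assignment are out of scope — coordinates and
partial charges are inputs).  On a shared rectangular lattice
(`make_grid()`, default 2.0 Å spacing and 4.0 Å margin, both configurable)
two probe fields are evaluated per molecule:

* **steric**: Lennard-Jones 6–12 energy
  \(\sum_a \varepsilon_a [(R_a/r)^{12} - 2 (R_a/r)^6]\) with
  \(R_a = r^{vdw}_{atom} + r^{vdw}_{probe}\) and
  \(\varepsilon_a = \sqrt{\varepsilon_{atom}\varepsilon_{probe}}\);
* **electrostatic**: Coulomb energy with a distance-dependent dielectric
  \(\epsilon(r) = r\), i.e. \(\sum_a 332.0636\, q_a q_{probe}/r^2\) kcal/mol.

The probe is the classical CoMFA default — an sp³ carbon of radius 1.70 Å,
well depth 0.107 kcal/mol, charge +1.  Energies are truncated at
\(\pm 30\) kcal/mol; the 30 kcal/mol steric threshold is exactly the
125.4 kJ/mol figure quoted in SYBYL-style settings (4.184 kJ/kcal applied at
I/O only — the internal unit is kcal/mol throughout).  Electrostatic values
at lattice points buried inside a molecule (steric value at the cutoff) are
physically meaningless for a charged probe; they are flagged and imputed by
the column mean over the non-buried molecules (the conventional "mean"
treatment; a drop column filter would be the alternative).  Per-element
Lennard-Jones parameters for H, C, N, O, F, S, Cl and Br ship with the
package; other elements error loudly instead of receiving defaults.

`assemble_descriptor_table()` flattens the two fields into one row per
molecule, drops columns whose standard deviation is below `min_sigma`
(default 2.0 kcal/mol, the usual minimum-sigma filter), and applies
CoMFA-standard block scaling: each field block is divided by its pooled
column standard deviation so neither field dominates by units alone.  The
transform (imputation means, retained columns, scale factors) is stored so
unseen molecules are projected into the identical descriptor space by
`descriptor_rows()`.

## PLS and its validation statistics

`fit_pls()` is a NIPALS PLS1 on column-centered data, deterministic for a
fixed row order, with no column autoscaling (the block scaling above is the
intended weighting).  The validation suite mirrors the conventional CoMFA
report:

* `loo_crossvalidate()` — leave-one-out \(q^2 = 1 - PRESS/SS_{tot}\), with
  \(SS_{tot}\) about the training-fold means (each fold's own mean of the
  retained responses; the whole-set-mean convention is available by flag and
  typically differs in the third decimal), and \(SEP = \sqrt{PRESS/(N-n-1)}\);
* `select_components()` — arg-max \(q^2\) by default, ties toward fewer
  components; a parsimony policy takes the smallest count within a tolerance
  of the maximum.  The component cap defaults to 10; models using more than
  \(N/3\) components should be treated as overfitting-prone;
* `fit_statistics()` — \(r^2\), \(SEE = \sqrt{SS_{res}/(N-n-1)}\) and the
  \(F\) statistic, all with the \(N-n-1\) degrees-of-freedom convention;
* `external_q2()` — \(Q^2_{ext} = 1 - \sum (y_i-\hat y_i)^2 / \sum (y_i-\bar
  y_{tr})^2\) with the training-set response mean in the denominator, plus
  \(r^2_{pred}\), the squared observed-predicted correlation.  The squares in
  both sums are part of the standard definition (the only form bounded by 1)
  and are used here even where source material typesets the expression
  without them;
* `progressive_scrambling()` — the response is partially permuted over a
  ladder of perturbation strengths (10 levels from untouched to fully
  permuted, ≥ 10 draws per level, fully seeded); the summary statistics are
  the slope of \(q^2\) against \(r^2_{yy'}\) (near 1 for a stable model) and
  `cSDEP`, the cross-validated SDEP interpolated at the reference correlation
  \(r^2_{yy'} = 0.85\) (a common choice; configurable);
* `field_contributions()` — per-field share of
  \(\sum |\beta_j| \cdot sd_j\), normalized to 100%.

`make_split()` reproduces the ~3:1 training/test protocol (default 22/8 for
a 29-compound series) and honors the practice of carrying the template
molecule in both roles: it is guaranteed a training slot and duplicated into
the evaluation list, which slightly flatters external statistics and is
therefore documented rather than silent.

## Contour maps

`stdev_coeff_grid()` maps each retained column's standard deviation times
its PLS coefficient back to its lattice point (filtered columns contribute
zero).  `contour_levels()` takes the 80% quantile of the positive values as
the favored level and the 20% quantile of the negative values as the
disfavored level — the "80/20 by contribution" convention, applied per field
(steric and electrostatic maps are contoured independently; a joint
treatment would couple the two fields' scales for no clear benefit).
Quantiles interpolate linearly between order statistics.  Grids export as
OpenDX text files readable by PyMOL/VMD/Chimera; values are laid out with
the z index fastest, the OpenDX ordering used consistently for descriptor
columns as well.

## Derivative enumeration and screening

`enumerate_derivatives()` decorates a template carrying two labeled
substitution sites: every single substitution at position 1 (six
hydrocarbon-type groups: methyl, hydrogen, ethyl, vinyl, ethynyl, carbonyl),
every single at position 5 (hydroxyl, carboxyl, thiol, fluorine, chlorine,
bromine), and all pairwise doubles — \(|P_1| + |P_5| + |P_1||P_5|\)
structures, 48 for the default sets.  Fragments are attached with idealized
bond lengths along the direction of the replaced atom; no conformer search
is attempted, and the carbonyl/ethynyl attachment geometries are best-effort
idealizations.  Predicted CEIs come either from the live field→PLS chain
(`predict_derivative_cei()` with a fitted model) or from a supplied
prediction column (fixture mode), which keeps all downstream arithmetic
exactly testable when the upstream model is not reconstructible.

`pop_screen()` applies the three persistent-organic-pollutant criteria in
sequence: genotoxicity change \(\ge 0\) (inclusive — a derivative exactly
matching the template passes, which the bundled table requires), then
photodegradability change strictly \(> 0\), then bioconcentration change
strictly \(< 0\).  The boundary semantics are forced by the bundled table's
stage cardinalities (28 → 24 → 3): the zero-change derivative is counted in
stage 1, while the unchanged-photodegradability derivatives are excluded in
stage 2.  Survivor sets are nested by construction and invariant to row
order.

## Validation and risk arithmetic

`single_factor_compare()` checks the weighted share of a derivative's CEI
change against a single-endpoint model's prediction.  The relative error
between the two conventions uses the **weighted CEI change** as the
denominator; recomputing the bundled comparison table shows this is the
convention its printed error values follow (the single-change denominator is
available by flag and gives systematically different numbers, e.g. 3.33%
instead of 3.23% for the first derivative's convulsive comparison).  One
printed cardiotoxicity error in that table (15.07%) is not reproducible from
its own printed inputs under either convention; the package reports the
recomputed value and the discrepancy is documented rather than patched.

The exposure module is the standard intake algebra: ADD = C·IR·EF·ED/(BW·AT);
HI = ADD/RfD, acceptable strictly below 1; RI = ADD·SF under the linear
non-threshold model, negligible below 10⁻⁶ and acceptable in [10⁻⁶, 10⁻⁴).
All thresholds are strict/closed exactly as unit-tested at the boundaries.
Thermochemistry bookkeeping (ΔG = ΣG(products) − ΣG(reactants);
ΔE = E(TS) − ΣE(reactants); spontaneous iff ΔG < 0; paths ranked by
ascending ΔE) takes energies verbatim in the units declared by the input
file — the bundled path table labels ~40-magnitude barriers "a.u.", which is
chemically implausible for hartrees and is carried through uncorrected as an
open question about the source data.

## The synthetic congeneric series

The bundled 29-compound docking table fixes the evaluation side of the
package, but the study's 3D structures, grid region and modelling internals
are unpublished, so its model statistics (e.g. a reported \(q^2\) of 0.560
with \(r^2\) of 0.999) cannot be reproduced from published material.  The
modelling engine is therefore validated on a synthetic congeneric series
with a *known* structure–activity law: a rigid four-atom polar scaffold
carries one variable substituent atom whose van der Waals radius (1.2–2.0 Å)
and partial charge (−0.5 to +0.5 e) are drawn uniformly, and

\[ \text{activity} = e_s u_{size} + e_c u_{charge} + \mathcal N(0, \sigma), \]

with unit effect sizes and \(\sigma = 0.1\) by default (about 6% noise
variance, a mild error level for a designed series), \(n = 29\) molecules
matching the real series' size.  The steric probe field is monotone in the
substituent radius and the electrostatic field is linear in its charge, so
a correct field→PLS pipeline must recover the law: at the defaults the
pipeline reaches leave-one-out \(q^2 \approx 0.97\) and \(r^2 \approx 0.98\),
comfortably clearing the conventional model-quality gates
(\(q^2 > 0.5\), \(r^2 > 0.9\)) that the acceptance tests assert.

What the generator deliberately does **not** emulate: conformational
flexibility, correlated substituent properties, alignment noise, charge
redistribution through the scaffold, and multi-substituent interactions.
Passing tests on this series therefore demonstrate that the numerical
pipeline is correct and that the descriptors carry the intended information;
they do not certify predictive performance on real congeneric series.

## Numerical choices and problem sizes

* Field cutoff exactly 30.0 kcal/mol; coincident probe/atom positions get
  the cutoff value rather than an infinity.
* Minimum-sigma filter 2.0 kcal/mol by default; the synthetic-series tests
  use 0.5 because the single-substituent design varies fewer lattice points
  than a real series would.
* Component selection ties break toward fewer components; the LOO
  \(SS_{tot}\) uses fold means.
* Display rounding is half-away-from-zero everywhere (3 decimals for
  indices, 2 for percent changes).  Consensus by-product tables in the
  bundled data contain a handful of exact .0005 midpoints that the source
  rounded inconsistently (binary-float display artifacts) and whose printed
  relative changes were computed from the already-rounded consensus; tests
  compare at half-a-unit-in-the-last-printed-digit to absorb exactly this.
* Test problem sizes: the synthetic series runs at 29 molecules on a
  2.0 Å grid (~280 lattice points, ~270 retained descriptors), where the
  full pipeline plus leave-one-out validation completes in seconds;
  scrambling tests use 16-row instances with 5 ladder levels.

## Limitations

* Docking scores, partial charges and 3D coordinates are inputs; nothing in
  the package computes them.
* The weighted-average aggregation is the only fuzzy operator; weights are
  user responsibility and the package cannot detect unreasonable ones.
* Fragment attachment uses idealized geometry — derived structures are
  suitable for field calculation on a rigid-alignment assumption, not for
  energy evaluation.
* Literature regression models for external endpoints (genotoxicity,
  photodegradability, bioconcentration) are pluggable inputs
  (`apply_linear_qsar()`); their coefficients are not bundled because they
  are not published in usable form.
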