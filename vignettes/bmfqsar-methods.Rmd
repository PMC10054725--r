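---
title: "Modelling the dietary biomagnification factor in fish with bmfqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dietary biomagnification factor in fish with bmfqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmfqsar)
```

## The endpoint

The biomagnification factor (BMF) of a chemical is the steady-state ratio of
its concentration in a predator to that in the predator's diet.  Because
hydrophobic chemicals partition into lipids, laboratory BMFs are normalized
by lipid content before they can be compared across experiments.  The
endpoint modelled here is the doubly lipid-normalized factor on the log
scale,

$$\mathrm{BMF_L} = \mathrm{BMF}\cdot \frac{L_{diet}}{L_{fish}},
\qquad y = \log_{10}\mathrm{BMF_L},$$

implemented by `lipid_normalize()`.  The alternative standardization to a
reference fish lipid content of 5% (`bmf_five_percent()`) keeps wet-weight
units and is provided for completeness.  A chemical is classified as a
biomagnifier when BMF exceeds 1, i.e. strictly positive Log BMF$_L$
(`classify_biomagnifier()`; the boundary value 0 is classified negative).

## Structures and curation

Chemicals enter as SMILES strings.  `parse_smiles()` builds a
hydrogen-suppressed molecular graph with attached-hydrogen counts; aromatic
systems are perceived both from lowercase notation (kekulized internally by
a backtracking matching so conventional bond orders are always available)
and from alternating-bond input (a Hückel electron count over enumerated
rings of size 5–6).  Stereo descriptors are discarded on input: all
descriptors used here are two-dimensional and stereoisomer-specific records
are outside the modelled domain.

`curate()` applies the standardizations used before descriptor calculation:

* **salt stripping** — the covalently connected component with the most
  heavy atoms is kept; ties are broken by molecular weight and then by the
  lexicographically smallest canonical SMILES;
* **nitro standardization** — neutral `N(=O)=O` groups are rewritten in the
  single charge-separated form `[N+](=O)[O-]`;
* **aromaticity re-perception**.

Curation is idempotent, and `canonicalize()` delegates canonical SMILES
generation to OpenBabel (through ChemmineOB), so identical molecules written
in different atom orders or Kekulé forms map to identical keys.  CAS
registry numbers are checked (format plus weighted-digit checksum) but
validation is advisory: the loader warns and keeps the record, since the
curated data table is the authority.  `load_dataset()` also reports, as
offline consistency checks, duplicated CAS numbers attached to different
structures and identical structures filed under different CAS numbers; no
online identifier resolution is attempted.  Replicate measurements sharing a
canonical structure are averaged arithmetically by `merge_replicates()`,
and the merged record keeps the best contributing quality category — a
choice the underlying data description leaves open; taking the best label
reflects that at least one high-grade measurement supports the merged value.

## The descriptor engine

Seventeen two-dimensional descriptors — the ones appearing in the frozen
models and the fold-frequency analyses — are computed directly from the
molecular graph (`compute_matrix()`, `descriptor_names()`).  Conventions
that the descriptor literature leaves to the implementation are centralized
and recorded in the `provenance` attribute of every matrix:

* **Property tables** (`atom_properties()`): CIAAW 2021 atomic masses and
  NIST first ionization energies (eV).
* **Autocorrelations** (`autocorrelation()`): Broto–Moreau (ATS/AATS),
  Moran (MATS) and Geary (GATS) forms over the hydrogen-suppressed graph.
  Degenerate cases — no atom pair at the requested lag, or zero property
  variance — return 0 with a warning so matrix assembly never stalls.
* **BCUT** (`bcut_lowest()`): Burden matrix with masses on the diagonal,
  off-diagonals 0.1 × bond order (0.15 aromatic, +0.01 for terminal bonds),
  0.001 elsewhere; the descriptor is the smallest eigenvalue.
* **Topological charge** (`topological_charge_index()`): the Galvez
  formulation $GGI_k = \sum_{i<j,\,d_{ij}=k}|M_{ij}-M_{ji}|$ with
  $M = A\,Q$, $Q_{ij}=1/d_{ij}^2$.
* **Path counts** (`path_count_ratio()`): exhaustive simple-path
  enumeration capped at length 10 (per the descriptor definition) under a
  configurable expansion budget; molecules exceeding the budget fail that
  cell explicitly rather than silently.
* **Detour matrix** (`detour_matrix()`, `ve3_detour()`): exact longest
  simple paths by depth-first search with a budget; acyclic molecules use
  the tree shortcut (detour = distance).  The exponential worst case is
  accepted because modelled chemicals are small.
* **E-states**: heavy-atom E-states follow the classic Kier–Hall
  formulation and are cross-checked against an independent implementation
  in the test suite.  For hydrogen E-states (`max_h_estate_other()`) the
  literature formula is not uniquely fixed; this package documents its own
  convention — the perturbation sum of heavy-atom intrinsic states at
  inverse-square topological distance from the hydrogen — applied to the
  aaCH/dCH2/dsCH atom types.  The convention preserves symmetry equivalence
  and qualitative ordering but its absolute scale differs from other
  descriptor software; see *Descriptor-convention parity* below.
* **MLFER_S** (`mlfer_s()`): a fragment-contribution estimate of Abraham's
  dipolarity/polarizability.  The scheme's structure (intercept + counts ×
  coefficients, `mlfer_s_table()`) follows published fragment methods, but
  the shipped coefficient table is a synthetic calibration versioned as
  `bmfqsar-synthetic-1`: the upstream regression coefficients are not
  redistributable here, so the values are the package's own, chosen to
  behave like published group contributions.
* **PubChem bits** 38/257/503/738 follow the NCBI fingerprint
  specification; bit 738 (an aromatic ring bearing an aliphatic carbon and
  a chlorine meta to each other) is taken from the specification's
  complex-SMARTS series and is documented as a swappable convention.

`prereduce()` mirrors the usual pre-reduction: near-constant columns
(≥ 95% identical values) are dropped, then of any pair with |Pearson r| >
0.98 the later column in name order is dropped — the tie-break is this
package's rule, since which member of a correlated pair survives is
otherwise arbitrary.

### Descriptor-convention parity

The frozen equations were estimated with a particular descriptor software;
re-implemented descriptors can differ in convention (most visibly the
hydrogen E-state scale, and the synthetic MLFER_S calibration).  Predictions
of the frozen equations are therefore exactly reproducible *given the
original descriptor values*, while predictions computed end-to-end from
structures carry these convention offsets.  Every matrix records its
conventions in `provenance` so an offset can be traced to a named choice.

## The models

`builtin_model()` returns the four frozen MLR equations with every
coefficient and standard error stored at printed precision — no re-derived
digits are substituted, and the coefficients round-trip through JSON
bit-exactly (`model_card()`).  `eq1`/`eq3` are split models (n = 115 and
194); `eq2`/`eq4` are their recalibrations on the pooled training and
prediction sets (n = 152 and 258), the step reproduced by `recalibrate()`.

New models are fitted with `qsar_mlr()` (formula or matrix interface), a
QR-based OLS that exposes coefficients and standard errors, residuals, the
hat diagonal and $s=\sqrt{RSS/(n-p')}$, and fails loudly on rank-deficient
designs, naming the collinear columns.

## Splitting and validation

`split_by_response()` sorts records by increasing response and sends every
record at a sorted position divisible by the stride to the prediction set,
keeping the global minimum and maximum in training.  The default stride is
4: the source text describes a one-in-three selection, but only one-in-four
reproduces both published training/prediction counts (115/37 of 152 and
194/64 of 258); the stride is an argument, and the discrepancy is treated
as a documented textual inconsistency rather than silently resolved.

Validation statistics follow their standard definitions: `basic_stats()`
(R², RMSE, MAE), `q2_loo()` (leave-one-out Q² via the hat identity
$e_i/(1-h_i)$, checked against brute-force refits to 10⁻¹⁰), `q2_lmo()`
(leave-many-out; the source names the statistic without parameters, so the
defaults — 30% left out, 1000 seeded iterations — follow common QSAR-suite
practice and are configurable), `q2_f3()`, and `ccc()` (Lin's concordance,
population moments).  `kfold_cv()` assigns folds venetian-blind style over
response-sorted records (deterministic; a seeded random option exists),
runs a fresh GA selection per fold, and tallies descriptor selection
frequencies across folds.

## Applicability domain

`williams()` combines leverages ($h_q = x_q^T(X^TX)^{-1}x_q$, intercept
included) with standardized residuals into the Williams-plot table.  The
cutoffs are $h^* = 3p'/n$ for structural outliers and 2.5 standard
deviations for response outliers, both strict inequalities, so boundary
points are in-domain.  A 3-standard-deviation tier is reported as
`strong_outlier` but does not drive categorization.  External points are
standardized with the training $s$, so they plot on the same axes.
`screen_external()` turns this into the three-way verdict used to assess
lower-quality data against a trusted model: `outside_AD_unreliable`
(leverage above $h^*$ — the model cannot judge such data),
`inconsistent_in_AD`, and `consistent_in_AD` (the records eligible for
pooling into a larger training set).

## Variable selection

`all_subset_search()` enumerates all subsets up to a size under a budget
guard; `ga_vss()` is a seeded generational GA over fixed-size subsets
(tournament selection of size 3, uniform crossover over the parents' gene
union, per-child gene-swap mutation, elitism).  Fitness defaults to
Q²$_{LOO}$ of the OLS fit, the statistic the modelling workflow reports
most prominently; R² and Q²$_{LMO}$ are selectable.  The GA hyperparameters
(population 100, generations 500, mutation 0.2, elitism 2) are defaults of
this package — the original software's settings are not published — and
every run is reproducible from its seed.  `detect_recurrent_outliers()`
flags chemicals that are response outliers or high-leverage in a majority
of the top-ranked models; outlier removal is a discrete pass followed by a
refit, not an iterated loop, mirroring how recurrent outliers were handled
in the source workflow.

## Synthetic fixtures

`generate_library()` builds a deterministic library from four template
families: PCB-like chlorinated biphenyls (0–8 Cl), chlorinated/methylated
benzenes, fused PAHs, and heteroatom-bearing aliphatics and monoaromatics.
The mix covers the descriptor surface (chlorine fingerprints, fused-ring
C3SP2, heteroatom fragment counts, unsaturation) while staying small enough
that every descriptor, including the exhaustive path searches, evaluates in
milliseconds.  `generate_response()` draws a linear response
$y = \beta_0 + X_{true}\beta + \varepsilon$ with coefficients scaled to
each column's spread; the default noise (0.4 log units) and response
location place synthetic statistics in the magnitudes familiar from
measured Log BMF$_L$ data.  `synthetic_pool()` provides wider Gaussian
descriptor pools (mild AR(1) correlation, ρ = 0.3) for selection studies
beyond the package's own descriptor count.

The fixtures exercise the statistical machinery end-to-end — split, GA,
validation, AD, screening — but they do not imitate biomagnification
biology: passing synthetic recovery tests demonstrates that the estimator
and selection machinery are correct, not that the frozen models generalize
to new chemical classes.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 150–200 synthetic chemicals
with pools of 30–50 descriptors and GA runs of 25–150 generations, sizes at
which the full pipeline completes in seconds while leaving the recovery
problems non-trivial (the largest search space is $\binom{50}{7} \approx
10^8$ subsets).  Matrix algebra uses QR decompositions throughout; the
leave-one-out identity avoids refits; eigenproblems use symmetric solvers.
Degenerate inputs (single atoms for detour descriptors, zero-variance
properties, exact-fit points with $h_i = 1$) raise explicit errors or
logged conventions rather than propagating NaN.

## Known limitations

* Absolute parity of structure-derived predictions with the original
  descriptor software is limited by the documented convention choices
  (hydrogen E-state scale, synthetic MLFER_S table, PubChem bit 738
  fragment), not by the regression machinery.
* Ring perception enumerates simple cycles up to size 8; exotic macrocyclic
  aromatics are outside the supported domain.
* The SMILES reader covers the organic subset, bracket atoms, charges and
  ring closures, and discards stereochemistry by design; it is not a full
  OpenSMILES validator.
* No distance-to-centroid or density AD variants, no octanol–water
  partitioning estimates, and no consensus averaging of the frozen models
  are provided.
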