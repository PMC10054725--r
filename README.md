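# bmfqsar

QSAR modelling of the **dietary biomagnification factor in fish** for
ecotoxicologists and regulatory risk assessors.  The biomagnification factor
(BMF) is the steady-state ratio of a chemical's concentration in a predator
to that in its diet; normalized by the lipid content of both fish and diet
it becomes BMF_L, and a chemical with BMF > 1 (Log BMF_L > 0) is considered
capable of biomagnifying.  `bmfqsar` implements the full in-silico workflow
for this endpoint:

* **Structure handling** — SMILES parsing with aromaticity perception,
  curation (salt stripping, nitro standardization), OpenBabel canonical
  SMILES, CAS checksum validation, replicate averaging and the lipid
  normalizations that define the endpoint.
* **A 2D descriptor engine** computed directly from the molecular graph:
  Broto–Moreau/Moran/Geary autocorrelations, Burden-matrix BCUT, Galvez
  topological charge indices, carbon types, PubChem fingerprint bits,
  carbon–heteroatom bond counts, bond-order path ratios, E-state and
  hydrogen E-state indices, detour-matrix eigenvector descriptors and a
  fragment-based dipolarity/polarizability estimate.
* **Frozen multiple-linear-regression predictors** of Log BMF_L
  (`builtin_model("eq1")` … `"eq4"`) with their published coefficients and
  standard errors stored at printed precision, e.g.

      Log BMF_L = −1.04 − 0.42·SubFPC295 + 1.38·PubchemFP503 − 0.06·R_TpiPCTPC
                  + 0.57·MLFER_S + 0.73·GGI5 − 1.05·maxHother − 5.0e−3·VE3_Dt

* **Model building and validation** — response-ordered train/prediction
  splitting, OLS fitting (`qsar_mlr()`), Q²(LOO/LMO), Q²-F3, Lin's
  concordance, five-fold cross-validation with per-fold genetic-algorithm
  variable selection (`ga_vss()`, `all_subset_search()`), recurrent-outlier
  detection and recalibration.
* **Applicability domain** — leverage/standardized-residual Williams plots
  with the h* = 3p′/n cutoff, and a three-way consistency screen for
  lower-quality data against a trusted model.
* **Deterministic synthetic fixtures** (chlorinated biphenyls, PAHs,
  chlorobenzenes, heteroatom aliphatics plus planted linear responses) so
  the entire pipeline is testable without any external data.

## Worked example

```r
library(bmfqsar)

g <- curate(parse_smiles("Clc1ccc(cc1)-c1ccc(Cl)cc1"))   # 4,4'-dichlorobiphenyl
g
#> <mol_graph> 14 heavy atoms, 15 bonds, 1 component
#>   formula-ish: C12 Cl2

m <- builtin_model("eq4")
X <- compute_matrix(list(g), m$terms$name)
round(as.matrix(X), 3)
#>                          SubFPC295 PubchemFP503 R_TpiPCTPC MLFER_S  GGI5 maxHother VE3_Dt
#> Clc1ccc(cc1)c1ccc(cc1)Cl         0            1      8.967   1.313 0.361     4.431  1.647

predict(m, X)
#> [1] -3.846715
```

The descriptor row reads: no carbon–heteroatom bonds, the chloro-aromatic
fingerprint present, a path-count ratio of ~9 for the conjugated biphenyl
skeleton, a moderate polarizability estimate, and aromatic-CH hydrogen
E-states as the `maxHother` term.  The prediction is the exact linear form
of the frozen equation over these values.  Note that descriptors
re-implemented from their literature definitions can differ in convention
from the software the equations were originally estimated with (the
hydrogen E-state scale in particular); each descriptor matrix carries a
`provenance` attribute naming the conventions so such offsets are
traceable — see the methods vignette.

A complete synthetic study — library generation, descriptor matrix,
pre-reduction, split, GA selection, validation and applicability domain —
runs in a few seconds:

```r
pool <- synthetic_pool(200, 50, seed = 1)
resp <- generate_response(pool, synthetic_spec(n_molecules = 200, n_true = 7,
                                               noise_sd = 0.4, seed = 1))
sp   <- split_by_response(resp$y, stride = 4)   # 151 train / 49 test
popn <- ga_vss(pool, resp$y, ga_config(model_size = 7, seed = 1))
fit  <- fit_ols(pool[sp$train, best_subset(popn)], resp$y[sp$train])
summary(fit)
plot(fit)    # Williams plot with the h* line
```

## Command line

A thin CLI wraps the same functions:

```sh
bmfqsar curate   --input chems.csv --output curated.csv --exclusions log.csv
bmfqsar describe --input chems.csv --output descriptors.csv
bmfqsar predict  --input chems.csv --model eq4 --output predictions.csv
bmfqsar fixtures --n 100 --seed 1 --prefix fixtures/run1
```

Input tables need columns `CAS`, `SMILES`, `quality` (high/medium/low) and
`LogBMFL`.

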