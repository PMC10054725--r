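Package: bmfqsar
Title: QSAR Models for the Dietary Biomagnification Factor in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the lipid-normalized dietary biomagnification
    factor (Log BMF_L) of organic chemicals in fish from molecular structure.
    Provides a SMILES reader and curation pipeline (salt stripping, aromaticity
    perception, nitro standardization, canonicalization through OpenBabel), a
    two-dimensional molecular descriptor engine covering autocorrelation
    (Broto-Moreau, Moran, Geary), BCUT, topological charge, E-state, path-count
    and fingerprint descriptors, frozen multiple-linear-regression predictors
    with their published coefficients, response-ordered train/test splitting,
    internal and external validation statistics (Q2 leave-one-out,
    leave-many-out, Q2-F3, concordance correlation), leverage-based
    applicability-domain assessment (Williams plot), genetic-algorithm variable
    subset selection, and deterministic synthetic fixtures for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
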