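test_that("autocorrelation flavors match the brute-force pair enumeration", {
  tab <- atom_properties()
  cases <- expand.grid(nm = c("hexane", "chloroethane", "styrene", "pcb_2cl",
                              "anisole", "dmso"),
                       lag = c(1L, 2L, 5L),
                       prop = c("mass", "ionization"),
                       flavor = c("ATS", "AATS", "MATS", "GATS"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    g <- mol[[cases$nm[k]]]
    w <- tab[[cases$prop[k]]][match(g$atoms$element, tab$element)]
    got <- suppressWarnings(
      autocorrelation(g, cases$lag[k], cases$prop[k], cases$flavor[k]))
    degenerate <- cases$flavor[k] %in% c("MATS", "GATS") && var(w) == 0
    expected <- if (degenerate) 0 else
      oracle_autocorr(g, cases$lag[k], w, cases$flavor[k])
    expect_equal(got, expected, tolerance = 1e-12,
                 info = paste(cases[k, ], collapse = " "))
  }
})

test_that("autocorrelation degenerate conventions return 0 with a warning", {
  # uniform property: zero variance
  expect_warning(v <- autocorrelation(mol$hexane, 1L, "mass", "GATS"),
                 "variance")
  expect_equal(v, 0)
  # single pair at lag 5 on the hexane chain: AATS = w^2
  w <- atom_properties()$mass[atom_properties()$element == "C"]
  expect_equal(autocorrelation(mol$hexane, 5L, "mass", "AATS"), w^2)
  # no pair beyond the diameter
  expect_warning(v2 <- autocorrelation(mol$ethane, 5L, "mass", "AATS"),
                 "no atom pair")
  expect_equal(v2, 0)
})

test_that("MATS/GATS are affine-invariant in the property, ATS/AATS are not", {
  g <- mol$chloroethane
  D <- distance_matrix(g)
  tab <- atom_properties()
  w <- tab$mass[match(g$atoms$element, tab$element)]
  w2 <- 3.7 * w + 11
  for (fl in c("MATS", "GATS"))
    expect_equal(oracle_autocorr(g, 1L, w, fl), oracle_autocorr(g, 1L, w2, fl),
                 tolerance = 1e-12)
  expect_false(isTRUE(all.equal(oracle_autocorr(g, 1L, w, "AATS"),
                                oracle_autocorr(g, 1L, w2, "AATS"))))
})

test_that("Burden-matrix lowest eigenvalue matches closed forms and a dense solver", {
  m_c <- atom_properties()$mass[atom_properties()$element == "C"]
  expect_equal(bcut_lowest(parse_smiles("[CH4]")), m_c)
  # ethane: 2x2 with off-diagonal 0.1 + 0.01 (terminal single bond)
  expect_equal(bcut_lowest(mol$ethane), m_c - 0.11)
  # benzene: dense eigensolver on the explicit 6x6 Burden matrix
  B <- matrix(0.001, 6, 6)
  for (k in 1:6) { i <- k; j <- k %% 6 + 1; B[i, j] <- B[j, i] <- 0.15 }
  diag(B) <- m_c
  expect_equal(bcut_lowest(mol$benzene),
               min(eigen(B, symmetric = TRUE)$values))
})

test_that("C3SP2 counts double-bonded carbons with three carbon neighbours", {
  expect_equal(carbon_type_c3sp2(mol$benzene), 0L)
  expect_equal(carbon_type_c3sp2(mol$naphthalene), 2L)
  expect_gt(carbon_type_c3sp2(mol$pyrene), 5L)  # PAH signature
  # exhaustive enumeration on naphthalene
  g <- mol$naphthalene
  nb <- lapply(seq_len(nrow(g$atoms)), function(a)
    c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a]))
  manual <- sum(vapply(seq_len(nrow(g$atoms)), function(a) {
    kb <- g$bonds$i == a | g$bonds$j == a
    g$atoms$element[a] == "C" &&
      any(g$bonds$order[kb] == 2 | g$bonds$aromatic[kb]) &&
      sum(g$atoms$element[nb[[a]]] == "C") == 3L
  }, logical(1)))
  expect_equal(carbon_type_c3sp2(g), manual)
})

test_that("topological charge index matches the dense matrix formula", {
  expect_equal(topological_charge_index(mol$ethane, 5L), 0)
  for (nm in c("hexane", "chlorobenzene", "pcb_2cl")) {
    g <- mol[[nm]]
    A <- matrix(0, nrow(g$atoms), nrow(g$atoms))
    A[cbind(g$bonds$i, g$bonds$j)] <- 1; A <- A + t(A)
    D <- distance_matrix(g)
    Q <- ifelse(D > 0, 1 / D^2, 0)
    M <- A %*% Q
    for (ordk in c(2L, 5L)) {
      manual <- 0
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
        if (i < j && D[i, j] == ordk) manual <- manual + abs(M[i, j] - M[j, i])
      expect_equal(topological_charge_index(g, ordk), manual,
                   info = paste(nm, ordk))
    }
  }
  # GGI_k is 0 whenever no pair sits at distance k
  expect_equal(topological_charge_index(mol$benzene, 7L), 0)
})

test_that("PubChem bits follow their fragment definitions", {
  expect_equal(pubchem_bit(mol$benzene, 257), 0L)
  expect_equal(pubchem_bit(mol$biphenyl, 257), 1L)
  expect_equal(pubchem_bit(mol$naphthalene, 257), 1L)

  expect_equal(pubchem_bit(mol$chlorobenzene, 503), 1L)
  hexaCl <- curate(parse_smiles("Clc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl"))
  expect_equal(pubchem_bit(hexaCl, 503), 0L)   # no aromatic CH neighbour

  expect_equal(pubchem_bit(curate(parse_smiles("ClCCl")), 38), 1L)
  expect_equal(pubchem_bit(curate(parse_smiles("CCl")), 38), 0L)

  expect_equal(pubchem_bit(mol$toluene_mCl, 738), 1L)
  para <- curate(parse_smiles("Cc1ccc(Cl)cc1"))
  expect_equal(pubchem_bit(para, 738), 0L)
})

test_that("SubFPC295 counts carbon-heteroatom bonds of any order", {
  expect_equal(subfpc_295(mol$hexane), 0L)
  expect_equal(subfpc_295(mol$ether), 2L)
  expect_equal(subfpc_295(mol$dmso), 2L)   # S=O not counted
  expect_equal(subfpc_295(mol$anisole), 2L)
})

test_that("path-count ratio equals the exhaustive path enumeration", {
  expect_equal(path_count_ratio(mol$hexane), 1)
  expect_equal(path_count_ratio(parse_smiles("C=C")), 4 / 3)
  for (nm in c("benzene", "styrene", "naphthalene")) {
    g <- mol[[nm]]
    pe <- oracle_paths(g, 10L)
    n <- nrow(g$atoms)
    expect_equal(path_count_ratio(g), (n + pe$wsum) / (n + pe$count),
                 info = nm)
  }
})

test_that("detour matrix dominates the distance matrix and matches exhaustive search", {
  for (nm in c("hexane", "styrene"))  # acyclic or benzylic
    expect_equal(detour_matrix(mol[[nm]]) >= distance_matrix(mol[[nm]]),
                 matrix(TRUE, nrow(mol[[nm]]$atoms), nrow(mol[[nm]]$atoms)))
  expect_identical(detour_matrix(mol$hexane), distance_matrix(mol$hexane))
  ch <- mol$cyclohexane
  Dt <- detour_matrix(ch)
  expect_equal(Dt[1, 2], 5)            # adjacent atoms, the long way round
  expect_equal(Dt, oracle_detour(ch))
  expect_equal(detour_matrix(mol$naphthalene), oracle_detour(mol$naphthalene))
})

test_that("VE3_Dt matches the closed 2x2 form and the dense eigensolver", {
  expect_equal(ve3_detour(mol$ethane), log(0.2 * sqrt(2)), tolerance = 1e-12)
  g <- mol$cyclohexane
  Dt <- oracle_detour(g)
  e <- eigen(Dt, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  expect_equal(ve3_detour(g), log(0.1 * 6 * sum(abs(v))))
  expect_error(ve3_detour(parse_smiles("[CH4]")), "single atom")
})

test_that("nBondsS3 counts non-aromatic single heavy-atom bonds", {
  expect_equal(nbonds_s3(mol$benzene), 0L)
  expect_equal(nbonds_s3(mol$hexane), 5L)
  expect_equal(nbonds_s3(mol$biphenyl), 1L)
})

test_that("heavy-atom E-state indices agree with RDKit", {
  smis <- c("CCO", "CCCl", "CC(C)=O", "c1ccccc1O")
  script <- paste(
    "from rdkit import Chem",
    "from rdkit.Chem.EState import EStateIndices",
    sprintf("smis = %s",
            paste0("['", paste(smis, collapse = "','"), "']")),
    "for s in smis:",
    "    m = Chem.MolFromSmiles(s)",
    "    print(','.join('%.9f' % x for x in EStateIndices(m)))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_length(out, length(smis))
  for (k in seq_along(smis)) {
    ref <- as.numeric(strsplit(out[k], ",")[[1]])
    expect_equal(estate_indices(parse_smiles(smis[k])), ref,
                 tolerance = 1e-8, info = smis[k])
  }
})

test_that("maxHother covers aaCH/dCH2/dsCH hydrogens with the empty-set convention", {
  expect_equal(max_h_estate_other(mol$cyclohexane), 0)
  # benzene: six equivalent aromatic hydrogens
  g <- mol$benzene
  vals <- vapply(1:6, function(a) bmfqsar:::hydrogen_estate(g, a), numeric(1))
  expect_equal(max(vals), min(vals))
  expect_equal(max_h_estate_other(g), vals[1])
  # styrene: maximum over explicit per-hydrogen evaluation of all three types
  g <- mol$styrene
  cand <- which(vapply(seq_len(nrow(g$atoms)), function(a)
    bmfqsar:::is_aaCH(g, a) || bmfqsar:::is_dCH2(g, a) ||
      bmfqsar:::is_dsCH(g, a), logical(1)))
  expect_gt(length(cand), 2L)
  expect_equal(max_h_estate_other(g),
               max(vapply(cand, function(a) bmfqsar:::hydrogen_estate(g, a),
                          numeric(1))))
})

test_that("MLFER_S is the shipped fragment table evaluated on the structure", {
  tab <- mlfer_s_table()
  expect_equal(mlfer_s(mol$hexane), attr(tab, "intercept"))  # no fragments
  # benzene: six aromatic carbons only
  expect_equal(mlfer_s(mol$benzene),
               attr(tab, "intercept") +
                 6 * tab$coefficient[tab$fragment == "C_aromatic"])
  # adding one Cl raises S by exactly the Cl coefficient
  expect_equal(mlfer_s(mol$chlorobenzene) - mlfer_s(mol$benzene),
               tab$coefficient[tab$fragment == "Cl"])
})

test_that("descriptors are invariant under atom reordering", {
  set.seed(11)
  targets <- c("AATS5i", "MATS1i", "GATS5m", "BCUTw-1l", "C3SP2", "GGI5",
               "SubFPC295", "R_TpiPCTPC", "MLFER_S", "maxHother", "VE3_Dt",
               "nBondsS3", "PubchemFP257", "PubchemFP503", "PubchemFP738")
  for (nm in c("pcb_2cl", "styrene", "toluene_mCl")) {
    g <- mol[[nm]]
    ref <- vapply(targets, function(d)
      suppressWarnings(bmfqsar:::compute_descriptor(g, d)), numeric(1))
    for (r in 1:3) {
      gp <- permute_graph(g, sample(nrow(g$atoms)))
      got <- vapply(targets, function(d)
        suppressWarnings(bmfqsar:::compute_descriptor(gp, d)), numeric(1))
      expect_equal(got, ref, tolerance = 1e-10, info = nm)
    }
  }
})

test_that("descriptor matrices assemble with per-cell failure logging", {
  rec <- data.frame(
    cas = c("71-43-2", "110-54-3", "74-82-8"),
    smiles = c("c1ccccc1", "CCCCCC", "C"),
    canonical_smiles = canonicalize(c("c1ccccc1", "CCCCCC", "C")),
    quality = "high", log_bmf_l = c(0, 0, 0))
  ds <- bmf_dataset(rec, graphs = lapply(rec$smiles,
                                         function(s) curate(parse_smiles(s))))
  M <- compute_matrix(ds, c("GGI5", "SubFPC295", "VE3_Dt"))
  expect_equal(dim(M), c(3L, 3L))
  expect_true(all(is.finite(M$GGI5)))
  # single-atom methane cannot have VE3_Dt: flagged, others still computed
  expect_true(is.na(M$VE3_Dt[3]))
  expect_equal(attr(M, "failures")$descriptor, "VE3_Dt")
  expect_error(compute_matrix(ds, "NoSuchDescriptor"), "supported")
  # permuting records permutes rows identically
  ds2 <- bmf_dataset(rec[c(2, 3, 1), ],
                     graphs = ds$graphs[c(2, 3, 1)])
  M2 <- compute_matrix(ds2, c("GGI5", "SubFPC295", "VE3_Dt"))
  expect_equal(as.matrix(M2), as.matrix(M)[c(2, 3, 1), ],
               ignore_attr = TRUE)
})

test_that("pre-reduction drops constant and correlated columns deterministically", {
  set.seed(31)
  m <- data.frame(a = rnorm(50), zeros = 0, b = rnorm(50))
  m$double_a <- 2 * m$a
  out <- prereduce(m)
  expect_setequal(names(out), c("a", "b"))
  drp <- attr(out, "dropped")
  expect_match(drp$reason[drp$name == "zeros"], "constant")
  expect_match(drp$reason[drp$name == "double_a"], "r", ignore.case = TRUE)
  # independent random columns survive
  set.seed(99)
  m2 <- as.data.frame(matrix(rnorm(50 * 6), 50, 6))
  expect_equal(ncol(prereduce(m2)), 6L)
})
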