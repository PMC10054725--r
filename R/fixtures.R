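## Deterministic synthetic inputs: parameterized molecule templates (PCB-like
## biphenyls, chlorobenzenes, PAHs, heteroatom-bearing aliphatics) and
## synthetic linear responses on the Log BMF_L scale.  The fixtures exercise
## the statistical machinery end-to-end; they do not imitate real
## biomagnification biology.

# kekulized aromatic 6-ring graph rows (orders alternate 2,1)
ring_bonds <- function(offset) {
  data.frame(i = offset + c(1:5, 6), j = offset + c(2:6, 1),
             order = c(2, 1, 2, 1, 2, 1), aromatic = TRUE)
}

# benzene with substituents: named list position -> element or "C_sp3"
substituted_benzene <- function(subs = character()) {
  atoms <- data.frame(element = rep("C", 6), charge = 0L,
                      aromatic = TRUE, hcount = 1L)
  bonds <- ring_bonds(0L)
  for (pos in as.integer(names(subs))) {
    el <- subs[[as.character(pos)]]
    atoms$hcount[pos] <- 0L
    atoms <- rbind(atoms, data.frame(
      element = if (el == "CH3") "C" else el, charge = 0L,
      aromatic = FALSE, hcount = if (el == "CH3") 3L else 0L))
    bonds <- rbind(bonds, data.frame(i = pos, j = nrow(atoms),
                                     order = 1, aromatic = FALSE))
  }
  mol_graph(atoms, bonds)
}

# biphenyl with chlorines at positions drawn from ortho/meta/para slots
# (ring A slots 2..6, ring B slots 8..12; atoms 1 and 7 are the pivot bond)
pcb_graph <- function(cl_slots = integer()) {
  atoms <- data.frame(element = rep("C", 12), charge = 0L,
                      aromatic = TRUE, hcount = 1L)
  atoms$hcount[c(1, 7)] <- 0L
  bonds <- rbind(ring_bonds(0L), ring_bonds(6L),
                 data.frame(i = 1L, j = 7L, order = 1, aromatic = FALSE))
  for (pos in cl_slots) {
    atoms$hcount[pos] <- 0L
    atoms <- rbind(atoms, data.frame(element = "Cl", charge = 0L,
                                     aromatic = FALSE, hcount = 0L))
    bonds <- rbind(bonds, data.frame(i = pos, j = nrow(atoms),
                                     order = 1, aromatic = FALSE))
  }
  mol_graph(atoms, bonds)
}

PAH_SMILES <- c(
  naphthalene  = "c1ccc2ccccc2c1",
  anthracene   = "c1ccc2cc3ccccc3cc2c1",
  phenanthrene = "c1ccc2c(c1)ccc3ccccc23",
  fluoranthene = "c1ccc2c(c1)-c1cccc3cccc2c13",
  pyrene       = "c1cc2ccc3cccc4ccc(c1)c2c34")

HETERO_SMILES <- c(
  "CCOCC", "CCCOC", "CCOC(=O)C", "CC(=O)CC", "CCO", "CCCCO",
  "CCN(CC)CC", "CCNCC", "CCCN", "CCSC", "CCSSCC", "CCCS",
  "C=CCOCC", "C=CCN", "CC(=O)OC", "CCC(=O)O",
  "[O-][N+](=O)c1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "COc1ccccc1",
  "CCc1ccccc1", "C=Cc1ccccc1", "CC(C)c1ccccc1", "CCCCCC", "CCCCCCCC",
  "C=CCCC", "CC(C)CC(C)C")

#' Specification of a synthetic study
#'
#' Parameters of the deterministic fixture generator: library size and
#' template mix, the true descriptor subset and coefficients of the
#' generating linear model, the Gaussian noise level, and the seed.
#' The default noise (0.4 log units) and response location match the scale
#' of measured Log BMF_L data so synthetic statistics land in familiar
#' magnitudes.
#'
#' @param n_molecules library size (>= 10).
#' @param n_true number of descriptors carrying signal.
#' @param noise_sd Gaussian noise standard deviation (log10 units).
#' @param intercept response location.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 200L, n_true = 7L, noise_sd = 0.4,
                           intercept = -1.5, seed = 1L) {
  stopifnot(n_molecules >= 10L, noise_sd >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_true = as.integer(n_true),
                 noise_sd = noise_sd, intercept = intercept,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a deterministic synthetic molecule library
#'
#' Draws (seeded) from four template families -- PCB-like chlorinated
#' biphenyls (0-8 Cl), chlorinated/methylated benzenes, fused PAHs, and
#' heteroatom-bearing aliphatics/monoaromatics -- until `n_molecules`
#' structures with distinct canonical SMILES are collected.  All structures
#' parse and curate cleanly; quality labels are assigned at random
#' (high/medium/low at 40/35/25%).  The response column is initialized to 0
#' and is meant to be filled by [generate_response()].
#'
#' @param spec a [synthetic_spec()].
#' @return a [bmf_dataset()] with curated graphs attached.
#' @export
generate_library <- function(spec = synthetic_spec()) {
  with_seed(spec$seed, {
    graphs <- list()
    seen <- character()
    smiles <- character()
    guard <- 0L
    while (length(graphs) < spec$n_molecules) {
      guard <- guard + 1L
      if (guard > 50L * spec$n_molecules) stop("library generation stalled")
      fam <- sample(c("pcb", "benzene", "pah", "hetero"), 1L,
                    prob = c(0.35, 0.2, 0.1, 0.35))
      g <- switch(fam,
        pcb = {
          k <- sample(0:8, 1L)
          slots <- sort(sample(c(2:6, 8:12), k))
          pcb_graph(slots)
        },
        benzene = {
          k <- sample(0:6, 1L)
          if (k == 0) substituted_benzene() else {
            pos <- sort(sample.int(6, k))
            subs <- stats::setNames(
              sample(c("Cl", "CH3"), k, replace = TRUE, prob = c(0.8, 0.2)),
              pos)
            substituted_benzene(as.list(subs))
          }
        },
        pah = parse_smiles(PAH_SMILES[[sample.int(length(PAH_SMILES), 1L)]]),
        hetero = parse_smiles(HETERO_SMILES[[sample.int(length(HETERO_SMILES), 1L)]]))
      g <- curate(g)
      can <- canonicalize(g)
      if (can %in% seen) next
      seen <- c(seen, can)
      graphs[[length(graphs) + 1L]] <- g
      smiles <- c(smiles, write_smiles(g))
    }
    n <- spec$n_molecules
    records <- data.frame(
      cas = sprintf("%d-%02d-%d", 100000L + seq_len(n),
                    sample.int(99, n, replace = TRUE) - 1L, 0L),
      smiles = smiles,
      canonical_smiles = seen,
      quality = sample(c("high", "medium", "low"), n, replace = TRUE,
                       prob = c(0.40, 0.35, 0.25)),
      log_bmf_l = 0,
      stringsAsFactors = FALSE)
    # repair the advisory CAS check digit so synthetic CAS validate
    records$cas <- vapply(records$cas, function(x) {
      digits <- as.integer(strsplit(gsub("-", "", x), "")[[1L]])
      body <- digits[-length(digits)]
      sub("[0-9]$", sum(body * rev(seq_along(body))) %% 10L, x)
    }, character(1), USE.NAMES = FALSE)
    bmf_dataset(records, name = "synthetic", graphs = graphs)
  })
}

#' Synthetic linear responses over a descriptor matrix
#'
#' Builds y = intercept + X[, true subset] beta + N(0, noise_sd), with the
#' true subset drawn (seeded) from the non-degenerate columns and the
#' coefficients scaled to each column's spread so every true descriptor
#' contributes a comparable signal.  Returns the responses together with
#' the ground truth needed by recovery assertions.
#'
#' @param X descriptor matrix/data.frame.
#' @param spec a [synthetic_spec()].
#' @param true_names optional explicit true descriptor subset.
#' @return list with `y`, `truth` (list: `names`, `beta`, `intercept`,
#'   `noise_sd`).
#' @export
generate_response <- function(X, spec = synthetic_spec(),
                              true_names = NULL) {
  X <- as.data.frame(X, check.names = FALSE)
  with_seed(spec$seed + 1L, {
    usable <- names(X)[vapply(X, function(v)
      all(is.finite(v)) && stats::sd(v) > 0, logical(1))]
    if (is.null(true_names)) {
      if (length(usable) < spec$n_true)
        stop("not enough non-degenerate columns for the true subset")
      true_names <- sort(usable[sample.int(length(usable), spec$n_true)])
    }
    miss <- setdiff(true_names, names(X))
    if (length(miss)) stop("X lacks true descriptor(s): ",
                           paste(miss, collapse = ", "))
    raw <- stats::runif(length(true_names), 0.4, 1) *
      sample(c(-1, 1), length(true_names), replace = TRUE)
    beta <- raw / vapply(X[true_names], stats::sd, numeric(1))
    y <- spec$intercept +
      drop(as.matrix(X[true_names]) %*% beta) +
      stats::rnorm(nrow(X), 0, spec$noise_sd)
    list(y = y, truth = list(names = true_names, beta = beta,
                             intercept = spec$intercept,
                             noise_sd = spec$noise_sd))
  })
}

#' Synthetic descriptor pool
#'
#' A seeded Gaussian descriptor pool with mild AR(1) cross-correlation
#' (rho = 0.3), emulating a pre-reduced descriptor matrix for variable
#' selection studies at widths beyond the package's own descriptor set.
#'
#' @param n rows (chemicals).
#' @param p columns (descriptors), named `D001`...
#' @param rho neighbouring-column correlation.
#' @param seed integer seed.
#' @return data.frame.
#' @export
synthetic_pool <- function(n, p, rho = 0.3, seed = 1L) {
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    X <- Z
    for (j in 2:p) X[, j] <- rho * X[, j - 1L] + sqrt(1 - rho^2) * Z[, j]
    colnames(X) <- sprintf("D%03d", seq_len(p))
    as.data.frame(X)
  })
}
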