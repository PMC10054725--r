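## Two-dimensional molecular descriptor engine.  Everything operates on the
## hydrogen-suppressed mol_graph with attached-H counts; conventions
## (property tables, Burden off-diagonals, path caps) are centralized here
## and recorded in the provenance of every descriptor matrix.

#' Topological autocorrelation descriptors
#'
#' Broto-Moreau (`ATS`), averaged Broto-Moreau (`AATS`), Moran (`MATS`) and
#' Geary (`GATS`) autocorrelations of an atomic property over the
#' hydrogen-suppressed graph.  With \eqn{d_{ij}} the topological distance,
#' \eqn{w} the property values, \eqn{\bar w} their mean and \eqn{\Delta} the
#' number of unordered atom pairs at distance `lag`:
#' \deqn{ATS = \sum_{d_{ij}=lag} w_i w_j, \quad AATS = ATS/\Delta}
#' \deqn{MATS = \frac{\sum_{d_{ij}=lag}(w_i-\bar w)(w_j-\bar w)/\Delta}{\sum_i (w_i-\bar w)^2/n}}
#' \deqn{GATS = \frac{\sum_{d_{ij}=lag}(w_i-w_j)^2/(2\Delta)}{\sum_i (w_i-\bar w)^2/(n-1)}}
#' When no pair sits at the lag, or the property variance is zero (MATS,
#' GATS), the conventional value 0 is returned with a warning.
#'
#' @param g a [mol_graph()].
#' @param lag topological distance (>= 1).
#' @param prop weighting property, `"mass"` or `"ionization"` (first
#'   ionization energy, eV); see [atom_properties()].
#' @param flavor one of `"ATS"`, `"AATS"`, `"MATS"`, `"GATS"`.
#' @return a single numeric value.
#' @export
autocorrelation <- function(g, lag, prop = c("mass", "ionization"),
                            flavor = c("ATS", "AATS", "MATS", "GATS")) {
  prop <- match.arg(prop)
  flavor <- match.arg(flavor)
  stopifnot(lag >= 1)
  n <- n_atoms(g)
  if (n < 2L) stop("autocorrelation needs at least 2 heavy atoms")
  w <- atom_property_values(g, prop)
  D <- distance_matrix(g)
  sel <- which(D == lag & upper.tri(D), arr.ind = TRUE)
  delta <- nrow(sel)
  if (delta == 0L) {
    warning(sprintf("no atom pair at lag %d; returning 0 by convention", lag))
    return(0)
  }
  wc <- w - mean(w)
  if (flavor == "ATS") return(sum(w[sel[, 1]] * w[sel[, 2]]))
  if (flavor == "AATS") return(sum(w[sel[, 1]] * w[sel[, 2]]) / delta)
  varn <- sum(wc^2) / n
  if (varn == 0) {
    warning("zero property variance; returning 0 by convention")
    return(0)
  }
  if (flavor == "MATS")
    return((sum(wc[sel[, 1]] * wc[sel[, 2]]) / delta) / varn)
  # GATS
  varn1 <- sum(wc^2) / (n - 1)
  (sum((w[sel[, 1]] - w[sel[, 2]])^2) / (2 * delta)) / varn1
}

#' Lowest eigenvalue of the mass-weighted Burden matrix (BCUTw-1l)
#'
#' The Burden matrix has atomic masses on the diagonal; bonded atom pairs are
#' set to 0.1 times the conventional bond order (0.15 for aromatic bonds),
#' incremented by 0.01 when the bond is terminal (one endpoint has a single
#' heavy neighbour); all non-bonded entries are 0.001.  Returns the smallest
#' eigenvalue.
#'
#' @param g a [mol_graph()].
#' @param prop weighting scheme for the diagonal (only `"mass"`).
#' @return smallest eigenvalue of the Burden matrix.
#' @export
bcut_lowest <- function(g, prop = "mass") {
  prop <- match.arg(prop, "mass")
  n <- n_atoms(g)
  w <- atom_property_values(g, prop)
  if (n == 1L) return(w)
  B <- matrix(0.001, n, n)
  deg <- heavy_degree(g)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    v <- if (g$bonds$aromatic[k]) 0.15 else 0.1 * g$bonds$order[k]
    if (deg[i] == 1L || deg[j] == 1L) v <- v + 0.01
    B[i, j] <- B[j, i] <- v
  }
  diag(B) <- w
  min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
}

#' Count of double-bonded carbons with three carbon neighbours (C3SP2)
#'
#' Counts carbon atoms that take part in a double or aromatic bond and have
#' exactly three carbon neighbours -- e.g. the ring-fusion carbons of fused
#' aromatics (large values, above 5, are characteristic of PAHs).
#'
#' @param g a [mol_graph()].
#' @return integer count.
#' @export
carbon_type_c3sp2 <- function(g) {
  nb <- neighbor_list(g)
  cnt <- 0L
  for (a in which(g$atoms$element == "C")) {
    kb <- g$bonds$i == a | g$bonds$j == a
    unsat <- any(g$bonds$order[kb] == 2 | g$bonds$aromatic[kb])
    if (!unsat) next
    if (sum(g$atoms$element[nb[[a]]] == "C") == 3L) cnt <- cnt + 1L
  }
  cnt
}

#' Galvez topological charge index of a given order (GGI)
#'
#' With \eqn{A} the adjacency matrix, \eqn{D} the topological distance matrix
#' and \eqn{Q_{ij} = 1/d_{ij}^2} (zero on the diagonal), form
#' \eqn{M = A Q}; the charge index of order \eqn{k} is
#' \eqn{GGI_k = \sum_{i<j,\, d_{ij}=k} |M_{ij} - M_{ji}|}.
#'
#' @param g a [mol_graph()].
#' @param order topological distance of the summed pairs (>= 1).
#' @return numeric value (0 when no pair sits at the order).
#' @export
topological_charge_index <- function(g, order) {
  stopifnot(order >= 1)
  n <- n_atoms(g)
  if (n < 2L) return(0)
  A <- adjacency_matrix(g)
  D <- distance_matrix(g)
  Q <- ifelse(D > 0, 1 / D^2, 0)
  M <- A %*% Q
  sel <- which(D == order & upper.tri(D), arr.ind = TRUE)
  if (!nrow(sel)) return(0)
  sum(abs(M[sel] - M[sel[, c(2, 1), drop = FALSE]]))
}

# aromatic rings: every atom and every consecutive bond flagged aromatic
aromatic_rings <- function(g, rings = NULL) {
  if (is.null(rings)) rings <- find_rings(g)
  Filter(function(r) {
    if (!all(g$atoms$aromatic[r])) return(FALSE)
    rc <- c(r, r[1L])
    for (t in seq_along(r)) {
      kb <- which((g$bonds$i == rc[t] & g$bonds$j == rc[t + 1L]) |
                  (g$bonds$j == rc[t] & g$bonds$i == rc[t + 1L]))
      if (!length(kb) || !g$bonds$aromatic[kb]) return(FALSE)
    }
    TRUE
  }, rings)
}

#' PubChem substructure fingerprint bits used by the models
#'
#' Binary structural keys following the NCBI PubChem fingerprint
#' specification for the four bits appearing in the models: bit 38 (two or
#' more chlorine atoms), bit 257 (two or more aromatic rings), bit 503 (the
#' SMARTS fragment `Cl-C:C-[#1]`: chlorine single-bonded to an aromatic
#' carbon whose aromatic neighbour bears a hydrogen) and bit 738 (aliphatic
#' carbon and chlorine substituents meta to each other on an aromatic ring,
#' `Cc1cccc(Cl)c1`; the section-8 complex-SMARTS series of the
#' specification).
#'
#' @param g a [mol_graph()].
#' @param bit one of 38, 257, 503, 738.
#' @return 0 or 1.
#' @export
pubchem_bit <- function(g, bit) {
  bit <- as.integer(bit)
  if (!bit %in% c(38L, 257L, 503L, 738L))
    stop("supported PubChem bits: 38, 257, 503, 738")
  if (bit == 38L)
    return(as.integer(sum(g$atoms$element == "Cl") >= 2L))
  rings <- find_rings(g)
  if (bit == 257L)
    return(as.integer(length(aromatic_rings(g, rings)) >= 2L))
  nb <- neighbor_list(g)
  if (bit == 503L) {
    for (cl in which(g$atoms$element == "Cl")) {
      for (c1 in nb[[cl]]) {
        if (!(g$atoms$aromatic[c1] && g$atoms$element[c1] == "C")) next
        for (c2 in nb[[c1]]) {
          kb <- which((g$bonds$i == c1 & g$bonds$j == c2) |
                      (g$bonds$j == c1 & g$bonds$i == c2))
          if (g$bonds$aromatic[kb] && g$atoms$element[c2] == "C" &&
              g$atoms$hcount[c2] >= 1L)
            return(1L)
        }
      }
    }
    return(0L)
  }
  # bit 738: meta-substituted aromatic ring, aliphatic C and Cl
  for (r in aromatic_rings(g, rings)) {
    if (length(r) != 6L) next
    pos_c <- pos_cl <- integer()
    for (t in seq_along(r)) {
      a <- r[t]
      for (b in nb[[a]]) {
        if (b %in% r) next
        if (g$atoms$element[b] == "C" && !g$atoms$aromatic[b])
          pos_c <- c(pos_c, t)
        if (g$atoms$element[b] == "Cl") pos_cl <- c(pos_cl, t)
      }
    }
    for (p in pos_c) for (q in pos_cl) {
      dd <- abs(p - q); dd <- min(dd, 6L - dd)
      if (dd == 2L) return(1L)
    }
  }
  0L
}

#' Count of carbon-heteroatom bonds (SubFPC295)
#'
#' Number of bonds of any order (including aromatic) joining a carbon atom to
#' an oxygen, nitrogen or sulfur atom.
#'
#' @param g a [mol_graph()].
#' @return integer count.
#' @export
subfpc_295 <- function(g) {
  ei <- g$atoms$element[g$bonds$i]
  ej <- g$atoms$element[g$bonds$j]
  het <- c("O", "N", "S")
  sum((ei == "C" & ej %in% het) | (ej == "C" & ei %in% het))
}

# enumerate simple paths of length 1..max_len from each atom; returns the
# total count and the total product-of-bond-orders (aromatic bonds 1.5);
# every path is visited from both ends, so totals are halved by the caller
path_enumeration <- function(g, max_len = 10L, budget = 2e6) {
  nb <- neighbor_list(g)
  Bord <- bond_order_matrix(g, aromatic_as = 1.5)
  count <- 0
  wsum <- 0
  steps <- 0
  n <- n_atoms(g)
  in_path <- logical(n)
  dfs <- function(v, len, w) {
    steps <<- steps + 1
    if (steps > budget) stop("path enumeration budget exceeded")
    in_path[v] <<- TRUE
    for (u in nb[[v]]) {
      if (in_path[u]) next
      wu <- w * Bord[v, u]
      count <<- count + 1
      wsum <<- wsum + wu
      if (len + 1L < max_len) dfs(u, len + 1L, wu)
    }
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, 0L, 1)
  list(count = count / 2, wsum = wsum / 2)
}

#' Ratio of bond-order-weighted to plain path counts (R_TpiPCTPC)
#'
#' Enumerates all simple paths over heavy atoms up to length 10 (a length-0
#' path is a single atom).  `TpiPC` sums, over paths, the product of
#' conventional bond orders along the path (single 1, double 2, triple 3,
#' aromatic 1.5; empty product 1); `TPC` counts the paths.  Returns
#' `TpiPC / TPC` (1 for a single atom or any saturated acyclic skeleton).
#'
#' @param g a [mol_graph()].
#' @param max_len longest path length counted (default 10, per the
#'   descriptor definition).
#' @param budget cap on DFS expansions guarding combinatorial blow-up;
#'   exceeding it fails the descriptor cell explicitly.
#' @return numeric ratio.
#' @export
path_count_ratio <- function(g, max_len = 10L, budget = 2e6) {
  n <- n_atoms(g)
  pe <- path_enumeration(g, max_len = max_len, budget = budget)
  (n + pe$wsum) / (n + pe$count)
}

#' Detour (longest simple path) matrix
#'
#' Entry \eqn{\Delta_{ij}} is the number of bonds of the longest simple path
#' between atoms i and j (0 on the diagonal).  Equals the topological
#' distance matrix on acyclic graphs (paths are unique in a tree), which is
#' used as a fast path; cyclic systems are solved by exhaustive depth-first
#' search under an expansion budget.
#'
#' @param g a connected [mol_graph()].
#' @param budget cap on DFS expansions.
#' @return integer matrix.
#' @export
detour_matrix <- function(g, budget = 5e6) {
  n <- n_atoms(g)
  D <- distance_matrix(g)
  if (any(!is.finite(D))) stop("detour matrix requires a connected graph")
  if (nrow(g$bonds) == n - 1L) return(D)   # acyclic: unique paths
  nb <- neighbor_list(g)
  Delta <- matrix(0L, n, n)
  steps <- 0
  in_path <- logical(n)
  dfs <- function(v, start, len) {
    steps <<- steps + 1
    if (steps > budget) stop("detour matrix budget exceeded")
    in_path[v] <<- TRUE
    if (len > Delta[start, v]) Delta[start, v] <<- len
    for (u in nb[[v]]) if (!in_path[u]) dfs(u, start, len + 1L)
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n - 1L)) dfs(s, s, 0L)
  Delta <- pmax(Delta, t(Delta))
  Delta
}

#' Logarithmic coefficient sum of the principal detour-matrix eigenvector (VE3_Dt)
#'
#' Takes the eigenvector belonging to the largest eigenvalue of the detour
#' matrix, sums the absolute values of its (unit-norm) coefficients
#' (\eqn{VE1}) and returns \eqn{\ln(0.1\, n\, VE1)}.
#'
#' @param g a connected [mol_graph()] with at least 2 atoms.
#' @param budget passed to [detour_matrix()].
#' @return numeric value.
#' @export
ve3_detour <- function(g, budget = 5e6) {
  n <- n_atoms(g)
  if (n < 2L) stop("VE3_Dt is undefined for a single atom")
  Dt <- detour_matrix(g, budget = budget)
  e <- eigen(Dt, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  log(0.1 * n * sum(abs(v)))
}

#' Count of non-aromatic single bonds between heavy atoms (nBondsS3)
#'
#' @param g a [mol_graph()].
#' @return integer count.
#' @export
nbonds_s3 <- function(g) {
  sum(g$bonds$order == 1 & !g$bonds$aromatic)
}

#' Names of the descriptors implemented by the package
#' @return character vector of supported descriptor names.
#' @export
descriptor_names <- function() {
  c("AATS5i", "MATS1i", "GATS5m", "GATS2i", "BCUTw-1l", "C3SP2", "GGI5",
    "PubchemFP38", "PubchemFP257", "PubchemFP503", "PubchemFP738",
    "SubFPC295", "R_TpiPCTPC", "MLFER_S", "maxHother", "VE3_Dt", "nBondsS3")
}

# dispatcher for a single named descriptor on one graph
compute_descriptor <- function(g, name) {
  switch(name,
    "AATS5i"       = autocorrelation(g, 5L, "ionization", "AATS"),
    "MATS1i"       = autocorrelation(g, 1L, "ionization", "MATS"),
    "GATS5m"       = autocorrelation(g, 5L, "mass", "GATS"),
    "GATS2i"       = autocorrelation(g, 2L, "ionization", "GATS"),
    "BCUTw-1l"     = bcut_lowest(g, "mass"),
    "C3SP2"        = carbon_type_c3sp2(g),
    "GGI5"         = topological_charge_index(g, 5L),
    "PubchemFP38"  = pubchem_bit(g, 38L),
    "PubchemFP257" = pubchem_bit(g, 257L),
    "PubchemFP503" = pubchem_bit(g, 503L),
    "PubchemFP738" = pubchem_bit(g, 738L),
    "SubFPC295"    = subfpc_295(g),
    "R_TpiPCTPC"   = path_count_ratio(g),
    "MLFER_S"      = mlfer_s(g),
    "maxHother"    = max_h_estate_other(g),
    "VE3_Dt"       = ve3_detour(g),
    "nBondsS3"     = nbonds_s3(g),
    stop("unknown descriptor '", name, "'; supported: ",
         paste(descriptor_names(), collapse = ", "))
  )
}

#' Compute a descriptor matrix for a dataset
#'
#' One row per chemical record (keyed by canonical SMILES), one column per
#' requested descriptor.  Cell-level failures (degenerate structures, budget
#' guards) are recorded with their reason in the `failures` attribute and
#' left as `NA`; callers decide whether a row is usable for a given model.
#' The `provenance` attribute records the conventions in force.
#'
#' @param ds a [bmf_dataset()] (with curated graphs) or a list of
#'   [mol_graph()] objects.
#' @param names descriptor names (default: all of [descriptor_names()]).
#' @return a data.frame of class `descriptor_matrix`.
#' @export
compute_matrix <- function(ds, names = descriptor_names()) {
  unknown <- setdiff(names, descriptor_names())
  if (length(unknown))
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(descriptor_names(), collapse = ", "))
  if (inherits(ds, "bmf_dataset")) {
    graphs <- ds$graphs
    if (is.null(graphs)) graphs <- lapply(ds$records$smiles,
                                          function(s) curate(parse_smiles(s)))
    keys <- ds$records$canonical_smiles
  } else {
    graphs <- ds
    keys <- vapply(graphs, function(g) canonicalize(g), character(1))
  }
  m <- matrix(NA_real_, nrow = length(graphs), ncol = length(names),
              dimnames = list(NULL, names))
  fails <- list()
  for (r in seq_along(graphs)) {
    for (d in names) {
      v <- tryCatch(suppressWarnings(compute_descriptor(graphs[[r]], d)),
                    error = function(e) e)
      if (inherits(v, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(row = r, key = keys[r], descriptor = d,
                     reason = conditionMessage(v))
      } else m[r, d] <- v
    }
  }
  out <- as.data.frame(m, check.names = FALSE)
  rownames(out) <- make.unique(keys)
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(row = integer(), key = character(), descriptor = character(),
               reason = character())
  attr(out, "provenance") <- list(
    package = "bmfqsar",
    property_table = "atom_properties() v1 (CIAAW 2021 masses, NIST first ionization energies)",
    hydrogen_handling = "suppressed graph, attached-H counts",
    burden_offdiagonal = "0.1*order, aromatic 0.15, +0.01 terminal, 0.001 non-bonded",
    path_cap = 10L, degenerate_convention = "0 with warning")
  class(out) <- c("descriptor_matrix", class(out))
  out
}

#' Pre-reduction of a descriptor matrix
#'
#' Drops near-constant columns (a fraction `const_fraction` or more of
#' identical values) and then, scanning column pairs in fixed name order,
#' the later column of any pair whose absolute Pearson correlation exceeds
#' `corr_cut`.  The `dropped` attribute of the result lists removed columns
#' with reasons.
#'
#' @param m descriptor matrix (data.frame, chemicals in rows).
#' @param const_fraction constancy threshold (default 0.95).
#' @param corr_cut absolute-correlation threshold (default 0.98).
#' @return the reduced matrix with a `dropped` attribute.
#' @export
prereduce <- function(m, const_fraction = 0.95, corr_cut = 0.98) {
  stopifnot(nrow(m) >= 2L)
  dropped <- data.frame(name = character(), reason = character())
  keep <- names(m)
  for (cn in names(m)) {
    x <- m[[cn]]
    frac <- max(table(x[!is.na(x)])) / sum(!is.na(x))
    if (frac >= const_fraction) {
      keep <- setdiff(keep, cn)
      dropped <- rbind(dropped, data.frame(
        name = cn, reason = sprintf("near-constant (%.0f%% identical)", 100 * frac)))
    }
  }
  i <- 1L
  while (i < length(keep)) {
    j <- i + 1L
    while (j <= length(keep)) {
      r <- suppressWarnings(stats::cor(m[[keep[i]]], m[[keep[j]]],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > corr_cut) {
        dropped <- rbind(dropped, data.frame(
          name = keep[j],
          reason = sprintf("|r|=%.3f with %s", abs(r), keep[i])))
        keep <- keep[-j]
      } else j <- j + 1L
    }
    i <- i + 1L
  }
  out <- m[, keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  attr(out, "provenance") <- attr(m, "provenance")
  out
}
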