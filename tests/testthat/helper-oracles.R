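# Shared fixture molecules and independent brute-force oracles.  The oracles
# deliberately use naive algorithms (double loops, exhaustive path search)
# so they share no code path with the package implementations they check.

mol <- local({
  smis <- c(
    benzene      = "c1ccccc1",
    ethane       = "CC",
    ethene       = "C=C",
    hexane       = "CCCCCC",
    cyclohexane  = "C1CCCCC1",
    naphthalene  = "c1ccc2ccccc2c1",
    biphenyl     = "c1ccc(cc1)-c1ccccc1",
    styrene      = "C=Cc1ccccc1",
    chlorobenzene = "Clc1ccccc1",
    chloroethane = "CCCl",
    dmso         = "CS(=O)C",
    ether        = "CCOCC",
    pyrene       = "c1cc2ccc3cccc4ccc(c1)c2c34",
    pcb_2cl      = "Clc1ccc(cc1)-c1ccc(Cl)cc1",
    toluene_mCl  = "Cc1cccc(Cl)c1",
    anisole      = "COc1ccccc1",
    nitrobenzene = "[O-][N+](=O)c1ccccc1")
  lapply(smis, function(s) curate(parse_smiles(s)))
})

# shuffle atom order of a graph (for permutation-invariance properties)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  bonds <- g$bonds
  bonds$i <- inv[bonds$i]
  bonds$j <- inv[bonds$j]
  mol_graph(g$atoms[perm, , drop = FALSE], bonds, validate = FALSE)
}

# brute-force autocorrelation over all ordered atom pairs
oracle_autocorr <- function(g, lag, w, flavor) {
  D <- distance_matrix(g)
  n <- nrow(D)
  num <- 0; delta <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && D[i, j] == lag) {
      delta <- delta + 1
      num <- num + switch(flavor,
        ATS = , AATS = w[i] * w[j],
        MATS = (w[i] - mean(w)) * (w[j] - mean(w)),
        GATS = (w[i] - w[j])^2)
    }
  }
  if (delta == 0) return(0)
  switch(flavor,
    ATS  = num,
    AATS = num / delta,
    MATS = (num / delta) / (sum((w - mean(w))^2) / n),
    GATS = (num / (2 * delta)) / (sum((w - mean(w))^2) / (n - 1)))
}

# exhaustive simple-path enumeration (independent DFS over neighbour sets):
# returns count and order-product sum for paths of length 1..max_len,
# each unordered path counted once
oracle_paths <- function(g, max_len = 10L) {
  nb <- lapply(seq_len(nrow(g$atoms)), function(a)
    c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a]))
  ord <- function(a, b) {
    k <- which((g$bonds$i == a & g$bonds$j == b) |
               (g$bonds$i == b & g$bonds$j == a))
    if (g$bonds$aromatic[k]) 1.5 else g$bonds$order[k]
  }
  count <- 0; wsum <- 0
  walk <- function(path, w) {
    last <- path[length(path)]
    for (u in nb[[last]]) {
      if (u %in% path) next
      w2 <- w * ord(last, u)
      if (u > path[1L]) { count <<- count + 1; wsum <<- wsum + w2 }
      if (length(path) < max_len) walk(c(path, u), w2)
    }
  }
  for (s in seq_len(nrow(g$atoms))) walk(s, 1)
  # paths whose endpoints compare the other way were skipped; enumerate both
  # directions by symmetry: a path is counted when its end exceeds its start,
  # which happens exactly once per unordered path
  list(count = count, wsum = wsum)
}

# exhaustive longest-simple-path search per atom pair
oracle_detour <- function(g) {
  n <- nrow(g$atoms)
  nb <- lapply(seq_len(n), function(a)
    c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a]))
  best <- matrix(0L, n, n)
  walk <- function(path) {
    last <- path[length(path)]
    s <- path[1L]
    len <- length(path) - 1L
    if (len > best[s, last]) best[s, last] <<- len
    for (u in nb[[last]]) if (!(u %in% path)) walk(c(path, u))
  }
  for (s in seq_len(n)) walk(s)
  pmax(best, t(best))
}

# small deterministic regression problem
toy_regression <- function(n = 20L, p = 3L, seed = 42L, sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- seq_len(p)
  y <- 1 + drop(X %*% beta) + rnorm(n, 0, sd)
  list(X = X, y = y, beta = beta)
}
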