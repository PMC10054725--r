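## SMILES reading: tokenizer, graph assembly, kekulization and aromaticity
## perception.  Stereochemistry (@, @@, /, \) and isotope labels are parsed
## and discarded: every descriptor in the package is two-dimensional and the
## modelled data exclude stereoisomer-specific records.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S", "Se", "As")

# default valences used for implicit-hydrogen filling (OpenSMILES rules)
DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1, H = 1)

smiles_error <- function(smiles, pos, what) {
  stop(structure(
    class = c("smiles_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error in %s at position %d: %s",
                           dQuote(smiles, q = FALSE), pos, what),
         call = NULL, smiles = smiles, position = pos)))
}

#' Parse a SMILES string into a molecular graph
#'
#' Reads an OpenSMILES-dialect string into a hydrogen-suppressed
#' [mol_graph()].  Aromaticity is perceived both from lowercase aromatic
#' input (which is kekulized internally to assign conventional bond orders)
#' and from Kekule input (alternating-bond rings are detected with a Hueckel
#' electron count and flagged aromatic).  Stereo descriptors are discarded.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a [mol_graph()] with perceived aromaticity and attached-H counts.
#' @examples
#' g <- parse_smiles("c1ccccc1")      # benzene
#' sum(g$atoms$aromatic)              # 6
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  chars <- strsplit(smiles, "")[[1L]]
  np <- length(chars)

  el <- character(); chg <- integer(); arom <- logical(); hset <- integer()
  # hset: explicit H count from brackets, NA = infer
  bi <- integer(); bj <- integer(); bsym <- character()
  ring_open <- list()   # digit -> list(atom, sym, pos)

  prev <- NA_integer_
  pending <- ""         # pending bond symbol
  stack <- integer()
  k <- 1L

  add_atom <- function(sym, charge, aromatic, hcnt) {
    el[length(el) + 1L] <<- sym
    chg[length(chg) + 1L] <<- charge
    arom[length(arom) + 1L] <<- aromatic
    hset[length(hset) + 1L] <<- hcnt
    length(el)
  }
  add_bond <- function(a, b, sym, pos) {
    if (a == b) smiles_error(smiles, pos, "self-bond")
    bi[length(bi) + 1L] <<- a
    bj[length(bj) + 1L] <<- b
    bsym[length(bsym) + 1L] <<- sym
  }

  while (k <= np) {
    ch <- chars[k]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      k <- k + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_error(smiles, k, "branch before any atom")
      stack <- c(stack, prev)
      k <- k + 1L
    } else if (ch == ")") {
      if (!length(stack)) smiles_error(smiles, k, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      k <- k + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      k <- k + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (k + 2L > np || !grepl("^[0-9]{2}$", paste0(chars[k + 1L], chars[k + 2L])))
          smiles_error(smiles, k, "malformed %nn ring closure")
        lab <- paste0(chars[k + 1L], chars[k + 2L]); k <- k + 3L
      } else { lab <- ch; k <- k + 1L }
      if (is.na(prev)) smiles_error(smiles, k, "ring closure before any atom")
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (nzchar(pending)) pending else op$sym
        if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
          smiles_error(smiles, k, sprintf("conflicting ring-bond symbols for closure %s", lab))
        add_bond(op$atom, prev, sym, k)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, sym = pending)
      }
      pending <- ""
    } else if (ch == "[") {
      close <- k
      while (close <= np && chars[close] != "]") close <- close + 1L
      if (close > np) smiles_error(smiles, k, "unterminated bracket atom")
      body <- paste(chars[(k + 1L):(close - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}|@TH[12])?(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
        body))[[1L]]
      if (!length(m)) smiles_error(smiles, k, sprintf("unparsable bracket atom [%s]", body))
      sym <- m[3]
      aromatic <- grepl("^[a-z]", sym)
      elem <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      if (aromatic && !elem %in% AROMATIC_OK)
        smiles_error(smiles, k, sprintf("element %s cannot be aromatic", elem))
      hs <- m[5]
      hcnt <- if (!nzchar(hs)) 0L else if (hs == "H") 1L else as.integer(sub("H", "", hs))
      cs <- m[6]
      charge <- 0L
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(cs)
        } else {
          charge <- sum(ifelse(strsplit(cs, "")[[1L]] == "+", 1L, -1L))
        }
      }
      a <- add_atom(elem, charge, aromatic, hcnt)
      if (!is.na(prev)) add_bond(prev, a, pending, k)
      prev <- a; pending <- ""
      k <- close + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (k < np) paste0(ch, chars[k + 1L]) else ""
      if (two %in% c("Cl", "Br")) { sym <- two; k <- k + 2L }
      else if (two == "Si") { sym <- two; k <- k + 2L }
      else { sym <- ch; k <- k + 1L }
      aromatic <- grepl("^[a-z]", sym)
      elem <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      if (aromatic && !elem %in% c("B", "C", "N", "O", "P", "S"))
        smiles_error(smiles, k, sprintf("unknown aromatic atom '%s'", sym))
      if (!aromatic && !elem %in% c(ORGANIC_SUBSET, "Si", "H"))
        smiles_error(smiles, k, sprintf("unknown atom token '%s' (bracket required?)", sym))
      a <- add_atom(elem, 0L, aromatic, NA_integer_)
      if (!is.na(prev)) add_bond(prev, a, pending, k)
      prev <- a; pending <- ""
    } else {
      smiles_error(smiles, k, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(ring_open))
    smiles_error(smiles, np, sprintf("unclosed ring closure(s): %s",
                                     paste(names(ring_open), collapse = ", ")))
  if (length(stack)) smiles_error(smiles, np, "unmatched '('")
  if (!length(el)) smiles_error(smiles, 1L, "no atoms")

  # drop explicit hydrogens written as atoms; credit them to their neighbour
  hadd <- integer(length(el))
  hidx <- which(el == "H")
  if (length(hidx)) {
    for (h in hidx) {
      at <- c(bj[bi == h], bi[bj == h])
      for (a in at) if (el[a] != "H") hadd[a] <- hadd[a] + 1L
    }
    keep <- setdiff(seq_along(el), hidx)
    remap <- integer(length(el)); remap[keep] <- seq_along(keep)
    kb <- !(bi %in% hidx | bj %in% hidx)
    bi <- remap[bi[kb]]; bj <- remap[bj[kb]]; bsym <- bsym[kb]
    el <- el[keep]; chg <- chg[keep]; arom <- arom[keep]
    hset <- hset[keep]; hadd <- hadd[keep]
  }
  if (!length(el)) smiles_error(smiles, 1L, "hydrogen-only input")

  assemble_graph(smiles, el, chg, arom, hset, hadd, bi, bj, bsym)
}

# shared by parse_smiles: bond-order resolution, kekulization, implicit H,
# aromaticity perception
assemble_graph <- function(smiles, el, chg, arom, hset, hadd, bi, bj, bsym) {
  n <- length(el)
  order <- rep(1, length(bi))
  order[bsym == "="] <- 2
  order[bsym == "#"] <- 3
  barom <- rep(FALSE, length(bi))

  g0 <- mol_graph(
    data.frame(element = el, charge = chg, aromatic = arom,
               hcount = ifelse(is.na(hset), 0L, hset)),
    data.frame(i = bi, j = bj, order = order, aromatic = barom),
    validate = TRUE)
  rings <- find_rings(g0)
  in_common_ring <- function(a, b) {
    for (r in rings) if (a %in% r && b %in% r) return(TRUE)
    FALSE
  }
  # implicit or ':' bonds between declared-aromatic atoms sharing a ring are
  # aromatic; every other implicit bond is single
  if (length(bi)) {
    cand <- (bsym == "" | bsym == ":") & arom[bi] & arom[bj]
    for (k in which(cand)) barom[k] <- in_common_ring(bi[k], bj[k])
    if (any(bsym == ":" & !barom))
      smiles_error(smiles, 1L, "':' bond outside an aromatic ring")
  }

  # kekulize declared-aromatic system: every aromatic atom that needs one
  # double bond must be matched along an aromatic bond
  if (any(barom)) {
    deg <- integer(n)
    for (k in seq_along(bi)) { deg[bi[k]] <- deg[bi[k]] + 1L; deg[bj[k]] <- deg[bj[k]] + 1L }
    has_exo_multi <- logical(n)
    for (k in seq_along(bi)) if (!barom[k] && order[k] >= 2) {
      has_exo_multi[bi[k]] <- TRUE; has_exo_multi[bj[k]] <- TRUE
    }
    needs <- logical(n)
    for (a in which(arom)) {
      hc <- if (is.na(hset[a])) NA_integer_ else hset[a]
      needs[a] <- switch(el[a],
        C = !has_exo_multi[a],
        B = FALSE,
        N = , P = {
          if (!is.na(hc) && hc >= 1L) FALSE
          else if (chg[a] < 0L) FALSE
          else if (chg[a] == 0L && deg[a] >= 3L) FALSE
          else TRUE
        },
        O = , S = , Se = chg[a] > 0L,
        FALSE)
    }
    edges <- which(barom & needs[bi] & needs[bj])
    match <- kekule_matching(which(needs), bi[edges], bj[edges])
    if (is.null(match))
      smiles_error(smiles, 1L, "kekulization of the aromatic system failed")
    order[barom] <- 1
    for (m in match) order[edges[m]] <- 2
  }

  # implicit hydrogen filling for organic-subset atoms without explicit count;
  # hydrogens that were written as explicit atoms (hadd) consume valence too
  bondsum <- numeric(n) + hadd
  for (k in seq_along(bi)) {
    bondsum[bi[k]] <- bondsum[bi[k]] + order[k]
    bondsum[bj[k]] <- bondsum[bj[k]] + order[k]
  }
  hc <- hset
  for (a in seq_len(n)) {
    if (!is.na(hc[a])) { hc[a] <- hc[a] + hadd[a]; next }
    dv <- DEFAULT_VALENCE[[el[a]]]
    if (is.null(dv)) { hc[a] <- hadd[a]; next }
    tgt <- dv[dv >= bondsum[a]]
    hc[a] <- if (length(tgt)) as.integer(min(tgt) - bondsum[a]) else 0L
    hc[a] <- hc[a] + hadd[a]
  }

  g <- mol_graph(
    data.frame(element = el, charge = chg, aromatic = arom, hcount = hc),
    data.frame(i = bi, j = bj, order = order, aromatic = barom),
    validate = TRUE)
  perceive_aromaticity(g, rings)
}

# backtracking perfect matching on the aromatic subgraph restricted to atoms
# that need exactly one double bond; returns indices into the edge list
kekule_matching <- function(need_atoms, ei, ej) {
  if (!length(need_atoms)) return(integer())
  inc <- lapply(need_atoms, function(a) which(ei == a | ej == a))
  names(inc) <- as.character(need_atoms)
  matched <- logical(max(c(need_atoms, 0L)))
  used <- logical(length(ei))
  sel <- integer()
  atoms <- need_atoms[order(lengths(inc))]
  rec <- function(idx) {
    if (idx > length(atoms)) return(TRUE)
    a <- atoms[idx]
    if (matched[a]) return(rec(idx + 1L))
    for (e in inc[[as.character(a)]]) {
      if (used[e]) next
      b <- if (ei[e] == a) ej[e] else ei[e]
      if (matched[b]) next
      matched[a] <<- TRUE; matched[b] <<- TRUE; used[e] <<- TRUE
      sel[length(sel) + 1L] <<- e
      if (rec(idx + 1L)) return(TRUE)
      matched[a] <<- FALSE; matched[b] <<- FALSE; used[e] <<- FALSE
      sel <<- sel[-length(sel)]
    }
    FALSE
  }
  if (!rec(1L)) return(NULL)
  if (!all(matched[need_atoms])) return(NULL)
  sel
}

# Hueckel-style perception over enumerated rings; flags aromatic atoms/bonds.
# An atom contributes 1 pi electron when it carries a double bond to another
# ring-system atom, 2 when it is an N/O/S/P with a free lone pair, and blocks
# aromaticity otherwise (saturated carbon, exocyclic double bond).
perceive_aromaticity <- function(g, rings = NULL) {
  if (is.null(rings)) rings <- find_rings(g)
  if (!length(rings)) return(g)
  n <- n_atoms(g)
  B <- bond_order_matrix(g)
  ring_atoms <- unique(unlist(rings))
  arom_atoms <- g$atoms$aromatic
  arom_bonds <- g$bonds$aromatic
  for (r in rings) {
    if (!length(r) %in% c(5L, 6L)) next
    pi <- 0; ok <- TRUE
    for (a in r) {
      elem <- g$atoms$element[a]
      dbl_partner <- which(B[a, ] == 2)
      if (length(dbl_partner) && any(dbl_partner %in% ring_atoms)) {
        pi <- pi + 1
      } else if (length(dbl_partner)) {
        ok <- FALSE; break            # exocyclic double bond (quinoid)
      } else if (elem %in% c("N", "O", "S", "P", "Se")) {
        pi <- pi + 2                  # lone-pair donor
      } else {
        ok <- FALSE; break            # saturated carbon etc.
      }
    }
    if (ok && pi == 6) {
      arom_atoms[r] <- TRUE
      rc <- c(r, r[1L])
      for (t in seq_len(length(r))) {
        a <- rc[t]; b <- rc[t + 1L]
        kb <- which((g$bonds$i == a & g$bonds$j == b) |
                    (g$bonds$i == b & g$bonds$j == a))
        arom_bonds[kb] <- TRUE
      }
    }
  }
  g$atoms$aromatic <- arom_atoms
  g$bonds$aromatic <- arom_bonds
  g
}
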