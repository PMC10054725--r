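## Structure curation: SMILES writing, canonicalization (OpenBabel),
## salt stripping, nitro standardization, CAS checksum.

# subgraph on a subset of atoms, bonds reindexed
subgraph_of <- function(g, keep) {
  keep <- sort(keep)
  remap <- integer(n_atoms(g)); remap[keep] <- seq_along(keep)
  kb <- g$bonds$i %in% keep & g$bonds$j %in% keep
  bonds <- g$bonds[kb, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  mol_graph(g$atoms[keep, , drop = FALSE], bonds, validate = FALSE)
}

molecular_weight <- function(g) {
  sum(atom_property_values(g, "mass")) +
    1.008 * sum(g$atoms$hcount)
}

#' Write a molecular graph as a SMILES string
#'
#' Produces a valid (not canonical) SMILES string: aromatic atoms are written
#' lowercase, ring closures are numbered along a depth-first traversal.
#' [canonicalize()] passes this output to OpenBabel to obtain a
#' deterministic canonical form.
#'
#' @param g a [mol_graph()].
#' @return a SMILES string covering every component of `g` (dot-separated).
#' @export
write_smiles <- function(g) {
  n <- n_atoms(g)
  nb <- neighbor_list(g)
  bonds <- g$bonds
  bond_id <- matrix(0L, n, n)
  for (k in seq_len(nrow(bonds))) {
    bond_id[bonds$i[k], bonds$j[k]] <- k
    bond_id[bonds$j[k], bonds$i[k]] <- k
  }
  # first pass: depth-first classification of bonds into tree and ring-closure
  tree <- logical(nrow(bonds))
  seen <- logical(n)
  classify <- function(a) {
    seen[a] <<- TRUE
    for (b in nb[[a]]) {
      k <- bond_id[a, b]
      if (!seen[b]) { tree[k] <<- TRUE; classify(b) }
    }
  }
  for (s in seq_len(n)) if (!seen[s]) classify(s)
  ring_bonds <- which(!tree)
  digit_of <- integer(nrow(bonds))
  for (t in seq_along(ring_bonds)) digit_of[ring_bonds[t]] <- t
  fmt_digit <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  digit_opened <- logical(nrow(bonds))

  visited <- logical(n)

  atom_token <- function(a) {
    elem <- g$atoms$element[a]
    aromatic <- g$atoms$aromatic[a]
    charge <- g$atoms$charge[a]
    hcount <- g$atoms$hcount[a]
    sym <- if (aromatic) tolower(elem) else elem
    bare_ok <- charge == 0L && elem %in% ORGANIC_SUBSET
    if (bare_ok && aromatic && elem %in% c("N", "P") && hcount > 0L) bare_ok <- FALSE
    if (bare_ok && !aromatic) {
      bsum <- sum(ifelse(g$bonds$aromatic, 1.5, g$bonds$order)[
        g$bonds$i == a | g$bonds$j == a])
      dv <- DEFAULT_VALENCE[[elem]]
      tgt <- dv[dv >= bsum]
      inferred <- if (length(tgt)) min(tgt) - bsum else 0
      if (inferred != hcount) bare_ok <- FALSE
    }
    if (bare_ok) return(sym)
    hs <- if (hcount == 0L) "" else if (hcount == 1L) "H" else paste0("H", hcount)
    cs <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
          else sprintf("%+d", charge)
    paste0("[", sym, hs, cs, "]")
  }
  bond_token <- function(k, a) {
    if (bonds$aromatic[k]) {
      # aromatic bonds are implicit between lowercase atoms
      if (g$atoms$aromatic[bonds$i[k]] && g$atoms$aromatic[bonds$j[k]]) "" else "="
    } else if (bonds$order[k] == 2) "=" else if (bonds$order[k] == 3) "#"
    else if (g$atoms$aromatic[bonds$i[k]] && g$atoms$aromatic[bonds$j[k]]) "-"
    else ""
  }

  emit <- function(a, via) {
    visited[a] <<- TRUE
    out <- if (is.na(via)) atom_token(a) else
      paste0(bond_token(bond_id[via, a], a), atom_token(a))
    # ring-closure digits incident to this atom (bond symbol at opening end)
    for (b in nb[[a]]) {
      k <- bond_id[a, b]
      if (digit_of[k] > 0L) {
        sym <- if (!digit_opened[k]) bond_token(k, a) else ""
        digit_opened[k] <<- TRUE
        out <- paste0(out, sym, fmt_digit(digit_of[k]))
      }
    }
    subs <- character()
    for (b in nb[[a]]) {
      k <- bond_id[a, b]
      if (tree[k] && !visited[b]) subs <- c(subs, emit(b, a))
    }
    if (length(subs) > 1L)
      subs <- c(paste0("(", subs[-length(subs)], ")"), subs[length(subs)])
    paste0(out, paste(subs, collapse = ""))
  }

  parts <- character()
  for (s in seq_len(n)) {
    if (!visited[s]) parts <- c(parts, emit(s, NA_integer_))
  }
  paste(parts, collapse = ".")
}

#' Canonical SMILES via OpenBabel
#'
#' Converts molecular graphs (or raw SMILES strings) to OpenBabel canonical
#' SMILES.  Two graphs describing the same molecule -- regardless of atom
#' order or Kekule vs. aromatic notation -- yield identical strings.
#'
#' @param x a [mol_graph()] or character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalize(parse_smiles("OCC")) == canonicalize(parse_smiles("CCO"))
#' @export
canonicalize <- function(x) {
  smi <- if (inherits(x, "mol_graph")) write_smiles(x)
         else as.character(x)
  if (!length(smi)) return(character())
  src <- paste0(paste(smi, paste0("m", seq_along(smi)), sep = "\t",
                      collapse = "\n"), "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(lines)]
  res <- sub("[\t ].*$", "", lines)
  ids <- as.integer(sub("^.*[\t ]m", "", lines))
  full <- rep(NA_character_, length(smi))
  full[ids[!is.na(ids)]] <- res[!is.na(ids)]
  if (anyNA(full))
    stop("OpenBabel failed to canonicalize: ",
         paste(smi[is.na(full)], collapse = ", "))
  full
}

#' Curate a molecular graph
#'
#' Applies the standardization steps used before descriptor calculation:
#' salt stripping (the covalently connected component with the most heavy
#' atoms is kept; ties broken by molecular weight, then by lexicographically
#' smallest canonical SMILES), nitro-group standardization to the
#' charge-separated form \code{[N+](=O)[O-]}, and re-perception of
#' aromaticity.  Curation is idempotent.
#'
#' @param g a [mol_graph()].
#' @return the curated [mol_graph()].
#' @export
curate <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      mw <- vapply(best, function(cc) molecular_weight(subgraph_of(g, which(comp == cc))),
                   numeric(1))
      best <- best[mw == max(mw)]
      if (length(best) > 1L) {
        cs <- vapply(best, function(cc) canonicalize(subgraph_of(g, which(comp == cc))),
                     character(1))
        best <- best[order(cs)][1L]
      } else best <- best[1L]
    } else best <- best[1L]
    g <- subgraph_of(g, which(comp == best))
  }
  if (n_atoms(g) == 0L) stop("empty graph after salt stripping")
  g <- standardize_nitro(g)
  perceive_aromaticity(g)
}

# rewrite neutral N(=O)=O groups as charge-separated [N+](=O)[O-]
standardize_nitro <- function(g) {
  deg <- heavy_degree(g)
  for (a in which(g$atoms$element == "N" & g$atoms$charge == 0L)) {
    kb <- which((g$bonds$i == a | g$bonds$j == a) & g$bonds$order == 2 &
                !g$bonds$aromatic)
    if (length(kb) != 2L) next
    partners <- ifelse(g$bonds$i[kb] == a, g$bonds$j[kb], g$bonds$i[kb])
    term_o <- g$atoms$element[partners] == "O" & deg[partners] == 1L &
      g$atoms$charge[partners] == 0L
    if (!all(term_o)) next
    demote <- kb[which.max(partners)]          # deterministic choice
    o <- partners[which.max(partners)]
    g$bonds$order[demote] <- 1
    g$atoms$charge[o] <- -1L
    g$atoms$charge[a] <- 1L
  }
  g
}

#' Validate a CAS registry number
#'
#' Checks the `NNNNNNN-NN-N` format and its checksum (sum of digits weighted
#' by position from the right, modulo 10).  Validation is advisory: dataset
#' loading warns on invalid CAS but keeps the record.
#'
#' @param cas character vector of CAS numbers.
#' @return logical vector.
#' @examples
#' cas_valid("50-00-0")   # formaldehyde, TRUE
#' @export
cas_valid <- function(cas) {
  vapply(as.character(cas), function(x) {
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1L]])
    nd <- length(digits)
    check <- digits[nd]
    body <- digits[-nd]
    sum(body * rev(seq_along(body))) %% 10L == check
  }, logical(1), USE.NAMES = FALSE)
}
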