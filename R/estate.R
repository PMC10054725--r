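## Electrotopological state (E-state) indices.
##
## Heavy atoms: the classic Kier-Hall formulation.  Intrinsic state
##   I_i = ((2/N_i)^2 * deltav_i + 1) / delta_i
## with N the principal quantum number, delta the heavy-atom (sigma) degree
## and deltav = (valence electrons) - (attached hydrogens).  The E-state is
##   S_i = I_i + sum_j (I_i - I_j) / r_ij^2,   r_ij = d_ij + 1.
##
## Hydrogens: the package's documented hydrogen E-state convention is the
## perturbation sum of heavy-atom intrinsic states felt by the hydrogen at
## inverse-square topological distance,
##   SH(i) = I_i + sum_{j != i} I_j / (d_ij + 1)^2,
## for a hydrogen attached to heavy atom i.  It preserves the qualitative
## behaviour of atom-type H E-states (symmetry-equivalent hydrogens score
## equally; electron-rich neighbourhoods raise the value) and is evaluated
## only for the atom types the models use.

# intrinsic states of the heavy atoms
intrinsic_states <- function(g) {
  el <- g$atoms$element
  N <- PRINCIPAL_QUANTUM[el]
  Zv <- VALENCE_ELECTRONS[el]
  if (anyNA(N) || anyNA(Zv))
    stop("no E-state parameters for element(s): ",
         paste(unique(el[is.na(N) | is.na(Zv)]), collapse = ", "))
  delta <- heavy_degree(g)
  if (any(delta == 0L) && n_atoms(g) > 1L)
    stop("isolated atom in multi-atom graph")
  deltav <- Zv - g$atoms$hcount
  ((2 / N)^2 * deltav + 1) / pmax(delta, 1L)
}

#' Kier-Hall E-state indices of the heavy atoms
#'
#' @param g a connected [mol_graph()].
#' @return numeric vector of E-state values, one per heavy atom.
#' @export
estate_indices <- function(g) {
  I <- intrinsic_states(g)
  n <- n_atoms(g)
  if (n == 1L) return(I)
  R <- (distance_matrix(g) + 1)^2
  S <- numeric(n)
  for (i in seq_len(n))
    S[i] <- I[i] + sum((I[i] - I[-i]) / R[i, -i])
  S
}

# hydrogen E-state for a hydrogen attached to heavy atom i (see header)
hydrogen_estate <- function(g, i) {
  I <- intrinsic_states(g)
  n <- n_atoms(g)
  if (n == 1L) return(I[i])
  R <- (distance_matrix(g)[i, ] + 1)^2
  I[i] + sum(I[-i] / R[-i])
}

# atom-type tests for the "other" hydrogen class: aromatic CH, =CH2, =CH-
is_aaCH <- function(g, a) {
  if (g$atoms$element[a] != "C" || !g$atoms$aromatic[a]) return(FALSE)
  if (g$atoms$hcount[a] != 1L) return(FALSE)
  kb <- g$bonds$i == a | g$bonds$j == a
  sum(g$bonds$aromatic[kb]) >= 2L
}
is_dCH2 <- function(g, a) {
  g$atoms$element[a] == "C" && !g$atoms$aromatic[a] &&
    g$atoms$hcount[a] == 2L &&
    any(g$bonds$order[g$bonds$i == a | g$bonds$j == a] == 2)
}
is_dsCH <- function(g, a) {
  if (g$atoms$element[a] != "C" || g$atoms$aromatic[a]) return(FALSE)
  if (g$atoms$hcount[a] != 1L) return(FALSE)
  ord <- g$bonds$order[g$bonds$i == a | g$bonds$j == a]
  sum(ord == 2) == 1L && sum(ord == 1) == 1L && length(ord) == 2L
}

#' Maximum hydrogen E-state over aaCH, dCH2 and dsCH hydrogens (maxHother)
#'
#' Evaluates the hydrogen E-state (see [estate_indices()] for the
#' conventions) for every hydrogen attached to an aromatic CH, a terminal
#' =CH2 or a =CH- carbon, and returns the maximum; 0 when no such hydrogen
#' exists.
#'
#' @param g a connected [mol_graph()].
#' @return numeric value.
#' @export
max_h_estate_other <- function(g) {
  cand <- which(vapply(seq_len(n_atoms(g)), function(a)
    is_aaCH(g, a) || is_dCH2(g, a) || is_dsCH(g, a), logical(1)))
  if (!length(cand)) return(0)
  max(vapply(cand, function(a) hydrogen_estate(g, a), numeric(1)))
}
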