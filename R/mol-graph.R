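#' Molecular graph objects
#'
#' A `mol_graph` is a hydrogen-suppressed molecular graph: heavy atoms carry
#' their element symbol, formal charge, aromaticity flag and attached-hydrogen
#' count; bonds carry the two atom indices, the conventional bond order
#' (1, 2 or 3) and an aromaticity flag.  All descriptor calculations in the
#' package operate on this representation.
#'
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer), `aromatic` (logical), `hcount` (integer).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical).
#' @param validate check the structural invariants (indices in range, no
#'   self-bonds, no duplicated atom pairs).
#' @return An object of class `mol_graph`.
#' @seealso [parse_smiles()], [curate()], [canonicalize()]
#' @export
mol_graph <- function(atoms, bonds, validate = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("a molecular graph needs at least one atom")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$hcount)) atoms$hcount <- 0L
  atoms$charge <- as.integer(atoms$charge)
  atoms$hcount <- as.integer(atoms$hcount)
  if (missing(bonds) || is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(),
                        order = numeric(), aromatic = logical())
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (is.null(bonds$aromatic)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  if (validate && nrow(bonds)) {
    n <- nrow(atoms)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond atom index out of range")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicated bond between an atom pair")
    if (!all(bonds$order %in% c(1, 2, 3)))
      stop("bond order must be 1, 2 or 3")
  }
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  n <- nrow(x$atoms)
  comp <- graph_components(x)
  cat(sprintf("<mol_graph> %d heavy atoms, %d bonds, %d component%s\n",
              n, nrow(x$bonds), max(comp), if (max(comp) > 1L) "s" else ""))
  cat("  formula-ish:", paste0(names(table(x$atoms$element)),
                               table(x$atoms$element), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

# 0/1 adjacency matrix over heavy atoms
adjacency_matrix <- function(g) {
  n <- n_atoms(g)
  A <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    A[cbind(g$bonds$i, g$bonds$j)] <- 1
    A[cbind(g$bonds$j, g$bonds$i)] <- 1
  }
  A
}

# list of neighbour index vectors
neighbor_list <- function(g) {
  n <- n_atoms(g)
  nb <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# connected-component labels (1-based, component 1 need not be largest)
graph_components <- function(g) {
  n <- n_atoms(g)
  comp <- integer(n)
  nb <- neighbor_list(g)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' Topological distance matrix
#'
#' Shortest-path (bond count) distances between all heavy-atom pairs,
#' computed on the hydrogen-suppressed graph.
#'
#' @param g a [mol_graph()].
#' @return integer matrix; `Inf` between disconnected atoms.
#' @export
distance_matrix <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(matrix(0, 1, 1))
  D <- igraph::distances(as_igraph(g))
  D <- D[order(as.integer(rownames(D))), order(as.integer(colnames(D))), drop = FALSE]
  unname(D)
}

# bond lookup table: symmetric matrix of orders (0 = no bond), plus aromatic flag
bond_order_matrix <- function(g, aromatic_as = NULL) {
  n <- n_atoms(g)
  B <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    ord <- g$bonds$order
    if (!is.null(aromatic_as)) ord[g$bonds$aromatic] <- aromatic_as
    B[cbind(g$bonds$i, g$bonds$j)] <- ord
    B[cbind(g$bonds$j, g$bonds$i)] <- ord
  }
  B
}

# heavy-atom degree vector
heavy_degree <- function(g) {
  n <- n_atoms(g)
  d <- integer(n)
  if (nrow(g$bonds)) {
    t1 <- table(factor(g$bonds$i, levels = seq_len(n)))
    t2 <- table(factor(g$bonds$j, levels = seq_len(n)))
    d <- as.integer(t1 + t2)
  }
  d
}

#' Enumerate rings of a molecular graph
#'
#' Returns all simple cycles up to `max_size` atoms as integer index vectors.
#' For the fused polycyclics this package targets (benzenoids, heteroaromatic
#' 5/6-rings) this ring set coincides with the smallest set of smallest rings.
#'
#' @param g a [mol_graph()].
#' @param max_size largest ring size enumerated (default 8).
#' @return list of integer vectors (atom indices, unordered orientation).
#' @export
find_rings <- function(g, max_size = 8L) {
  nb <- neighbor_list(g)
  n <- n_atoms(g)
  rings <- list()
  seen <- character()
  # enumerate cycles whose smallest atom index is the DFS root
  dfs <- function(root, path) {
    v <- path[length(path)]
    for (w in nb[[v]]) {
      if (w == root && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (w > root && !(w %in% path) && length(path) < max_size) {
        dfs(root, c(path, w))
      }
    }
  }
  for (root in seq_len(n)) if (length(nb[[root]]) >= 2L) dfs(root, root)
  rings
}
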