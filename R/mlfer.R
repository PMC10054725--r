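## Abraham dipolarity/polarizability (S) by fragment contributions.
##
## The estimator follows the structure of the Platts fragment-contribution
## scheme: S = intercept + sum over fragments of count * coefficient.  The
## shipped coefficient table is a reduced SYNTHETIC calibration: the
## fragment set and the magnitudes are chosen to behave like published
## Abraham-S group contributions, but the numerical values are the
## package's own and are versioned here, not taken from any external
## regression.  Everything that consumes MLFER_S (the frozen models, the
## GA) only requires the scheme to be deterministic and linear in the
## fragment counts.

#' Fragment table of the dipolarity/polarizability estimator
#'
#' @return data.frame with columns `fragment`, `coefficient`, `description`.
#'   The attribute `intercept` carries the constant term and `version` the
#'   calibration tag (`"bmfqsar-synthetic-1"`).
#' @export
mlfer_s_table <- function() {
  tab <- data.frame(
    fragment = c("C_aromatic", "N_aromatic", "O_hydroxyl", "O_ether",
                 "O_carbonyl", "N_amine", "nitro", "S_thio",
                 "F", "Cl", "Br", "I", "C_sp2", "C_sp3"),
    coefficient = c(0.068, 0.320, 0.310, 0.100,
                    0.330, 0.280, 0.480, 0.250,
                    0.020, 0.110, 0.170, 0.220, 0.050, 0.000),
    description = c(
      "aromatic carbon atom",
      "aromatic nitrogen atom",
      "hydroxyl oxygen (O with >=1 H, single bonds only)",
      "ether/ester oxygen (2 single bonds, no H)",
      "carbonyl oxygen (=O on carbon)",
      "non-aromatic nitrogen without double bonds (amine-like)",
      "charge-separated nitro group",
      "divalent sulfur",
      "fluorine", "chlorine", "bromine", "iodine",
      "non-aromatic double-bonded carbon",
      "saturated carbon (reference, zero)"),
    stringsAsFactors = FALSE)
  attr(tab, "intercept") <- 0.277
  attr(tab, "version") <- "bmfqsar-synthetic-1"
  tab
}

# fragment occurrence counts for one graph, aligned with mlfer_s_table()
mlfer_fragment_counts <- function(g) {
  el <- g$atoms$element
  arom <- g$atoms$aromatic
  hc <- g$atoms$hcount
  chg <- g$atoms$charge
  deg <- heavy_degree(g)
  has_double <- vapply(seq_len(n_atoms(g)), function(a)
    any(g$bonds$order[g$bonds$i == a | g$bonds$j == a] == 2), logical(1))
  dbl_to_c <- vapply(seq_len(n_atoms(g)), function(a) {
    kb <- which((g$bonds$i == a | g$bonds$j == a) & g$bonds$order == 2)
    any(el[setdiff(c(g$bonds$i[kb], g$bonds$j[kb]), a)] == "C")
  }, logical(1))
  nitro_n <- el == "N" & chg == 1L &
    vapply(seq_len(n_atoms(g)), function(a) {
      nbs <- c(g$bonds$j[g$bonds$i == a], g$bonds$i[g$bonds$j == a])
      any(el[nbs] == "O" & chg[nbs] == -1L)
    }, logical(1))
  c(C_aromatic = sum(el == "C" & arom),
    N_aromatic = sum(el == "N" & arom),
    O_hydroxyl = sum(el == "O" & !arom & hc >= 1L & !has_double),
    O_ether    = sum(el == "O" & !arom & hc == 0L & deg == 2L & !has_double),
    O_carbonyl = sum(el == "O" & deg == 1L & dbl_to_c),
    N_amine    = sum(el == "N" & !arom & chg == 0L & !has_double),
    nitro      = sum(nitro_n),
    S_thio     = sum(el == "S" & !arom & deg <= 2L & !has_double),
    F          = sum(el == "F"),
    Cl         = sum(el == "Cl"),
    Br         = sum(el == "Br"),
    I          = sum(el == "I"),
    C_sp2      = sum(el == "C" & !arom & has_double),
    C_sp3      = sum(el == "C" & !arom & !has_double))
}

#' Combined dipolarity/polarizability estimate (MLFER_S)
#'
#' Evaluates the fragment-contribution scheme of [mlfer_s_table()]:
#' intercept plus the sum of fragment counts times coefficients.  A molecule
#' matching no non-zero fragment returns the intercept alone.
#'
#' @param g a [mol_graph()].
#' @return numeric value.
#' @export
mlfer_s <- function(g) {
  tab <- mlfer_s_table()
  counts <- mlfer_fragment_counts(g)
  unname(attr(tab, "intercept") +
           sum(counts[tab$fragment] * tab$coefficient))
}
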