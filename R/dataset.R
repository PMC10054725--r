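#' Chemical record datasets
#'
#' A `bmf_dataset` holds curated chemical records for QSAR modelling: CAS
#' number, input SMILES, canonical SMILES of the curated structure, data
#' quality category (`high`, `medium`, `low`) and the measured response,
#' Log BMF_L (log10 of the biomagnification factor normalized by the lipid
#' content of both the fish and its diet).
#'
#' @param records data.frame with columns `cas`, `smiles`, `canonical_smiles`,
#'   `quality`, `log_bmf_l`.
#' @param name dataset label (for example `"dataset1"` or `"custom"`).
#' @param graphs optional list of curated [mol_graph()] objects, parallel to
#'   `records`.
#' @param exclusions data.frame logging rows dropped during loading.
#' @return an object of class `bmf_dataset`.
#' @export
bmf_dataset <- function(records, name = "custom", graphs = NULL,
                        exclusions = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("cas", "smiles", "canonical_smiles", "quality", "log_bmf_l")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(records$quality %in% c("high", "medium", "low")))
    stop("quality must be one of 'high', 'medium', 'low'")
  if (!all(is.finite(records$log_bmf_l)))
    stop("log_bmf_l must be finite")
  rownames(records) <- NULL
  structure(list(records = records, name = name,
                 graphs = graphs,
                 exclusions = if (is.null(exclusions))
                   data.frame(cas = character(), smiles = character(),
                              reason = character())
                 else exclusions),
            class = "bmf_dataset")
}

#' @export
print.bmf_dataset <- function(x, ...) {
  cat(sprintf("<bmf_dataset '%s'> %d records (%s)\n", x$name,
              nrow(x$records),
              paste(names(table(x$records$quality)),
                    table(x$records$quality), sep = ":", collapse = " ")))
  cat(sprintf("  Log BMF_L range: [%.2f, %.2f]; %d excluded at load\n",
              min(x$records$log_bmf_l), max(x$records$log_bmf_l),
              nrow(x$exclusions)))
  invisible(x)
}

#' @export
length.bmf_dataset <- function(x) nrow(x$records)

# subset records (and graphs) by index, preserving metadata
dataset_subset <- function(ds, idx) {
  bmf_dataset(ds$records[idx, , drop = FALSE], name = ds$name,
              graphs = if (!is.null(ds$graphs)) ds$graphs[idx],
              exclusions = ds$exclusions)
}

#' Load a chemical dataset from a delimited file
#'
#' Reads a CSV/TSV table of chemical records, parses and curates every
#' structure, canonicalizes it, and logs (rather than fails on) rows whose
#' SMILES cannot be parsed -- mirroring the exclusion of uncertain structures
#' during data curation.  Duplicate CAS numbers attached to conflicting
#' structures and identical structures filed under different CAS numbers are
#' reported with warnings as offline consistency checks; invalid CAS
#' checksums are advisory warnings.
#'
#' @param path file path; tab-separated when the extension is `.tsv`.
#' @param columns named character vector mapping the internal names
#'   `cas`, `smiles`, `quality`, `log_bmf_l` to file headers.
#' @param name dataset label.
#' @return a [bmf_dataset()]; the `exclusions` element records dropped rows
#'   with reasons.
#' @export
load_dataset <- function(path,
                         columns = c(cas = "CAS", smiles = "SMILES",
                                     quality = "quality",
                                     log_bmf_l = "LogBMFL"),
                         name = "custom") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  n <- nrow(raw)
  keep <- logical(n)
  reason <- character(n)
  graphs <- vector("list", n)
  for (r in seq_len(n)) {
    res <- tryCatch(curate(parse_smiles(raw[[columns["smiles"]]][r])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      reason[r] <- conditionMessage(res)
    } else {
      graphs[[r]] <- res
      keep[r] <- TRUE
    }
  }
  excl <- data.frame(cas = raw[[columns["cas"]]][!keep],
                     smiles = raw[[columns["smiles"]]][!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  idx <- which(keep)
  records <- data.frame(
    cas = as.character(raw[[columns["cas"]]][idx]),
    smiles = as.character(raw[[columns["smiles"]]][idx]),
    canonical_smiles = if (length(idx))
      canonicalize(vapply(graphs[idx], write_smiles, character(1)))
      else character(),
    quality = tolower(as.character(raw[[columns["quality"]]][idx])),
    log_bmf_l = as.numeric(raw[[columns["log_bmf_l"]]][idx]),
    stringsAsFactors = FALSE)

  bad_cas <- records$cas[!cas_valid(records$cas)]
  if (length(bad_cas))
    warning("CAS number(s) failing format/checksum (kept): ",
            paste(unique(bad_cas), collapse = ", "))
  # one CAS, several structures
  tab <- unique(records[, c("cas", "canonical_smiles")])
  dup_cas <- unique(tab$cas[duplicated(tab$cas)])
  if (length(dup_cas))
    warning("duplicate CAS with conflicting structures (not merged): ",
            paste(dup_cas, collapse = ", "))
  # one structure, several CAS
  dup_str <- unique(tab$canonical_smiles[duplicated(tab$canonical_smiles)])
  if (length(dup_str))
    warning("identical structures filed under different CAS: ",
            paste(dup_str, collapse = ", "))

  bmf_dataset(records, name = name, graphs = graphs[idx], exclusions = excl)
}

#' Average replicate measurements per structure
#'
#' Collapses records sharing a canonical structure to a single record whose
#' Log BMF_L is the arithmetic mean of the replicates.  The merged record
#' keeps the best contributing quality category (high > medium > low) and the
#' CAS of the first contributing record.
#'
#' @param ds a [bmf_dataset()].
#' @return a [bmf_dataset()] with one record per canonical structure.
#' @export
merge_replicates <- function(ds) {
  stopifnot(inherits(ds, "bmf_dataset"))
  rec <- ds$records
  grp <- match(rec$canonical_smiles, unique(rec$canonical_smiles))
  qrank <- c(low = 1L, medium = 2L, high = 3L)
  first <- match(unique(grp), grp)
  merged <- data.frame(
    cas = rec$cas[first],
    smiles = rec$smiles[first],
    canonical_smiles = rec$canonical_smiles[first],
    quality = names(qrank)[vapply(split(qrank[rec$quality], grp), max, numeric(1))],
    log_bmf_l = vapply(split(rec$log_bmf_l, grp), mean, numeric(1)),
    stringsAsFactors = FALSE)
  bmf_dataset(merged, name = ds$name,
              graphs = if (!is.null(ds$graphs)) ds$graphs[first],
              exclusions = ds$exclusions)
}

#' Lipid normalization of the biomagnification factor
#'
#' `lipid_normalize()` converts a wet-weight BMF to the doubly
#' lipid-normalized BMF_L = BMF * L_diet / L_fish, the endpoint modelled by
#' this package.  `bmf_five_percent()` instead standardizes to a reference
#' fish lipid content of 0.05 kg lipid/kg fish: BMF_5\% = (BMF / L_fish) * 0.05,
#' which keeps wet-weight units.
#'
#' @param bmf non-negative wet-weight biomagnification factor
#'   (kg diet / kg fish).
#' @param l_diet,l_fish lipid fractions of diet and fish (kg lipid/kg), > 0.
#' @return the normalized BMF (same length as `bmf`).
#' @export
lipid_normalize <- function(bmf, l_diet, l_fish) {
  if (any(!is.finite(bmf)) || any(bmf < 0)) stop("bmf must be finite and >= 0")
  if (any(l_diet <= 0) || any(l_fish <= 0))
    stop("lipid fractions must be positive")
  bmf * l_diet / l_fish
}

#' @rdname lipid_normalize
#' @export
bmf_five_percent <- function(bmf, l_fish) {
  if (any(!is.finite(bmf)) || any(bmf < 0)) stop("bmf must be finite and >= 0")
  if (any(l_fish <= 0)) stop("l_fish must be positive")
  (bmf / l_fish) * 0.05
}
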