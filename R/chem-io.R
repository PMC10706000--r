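# Molecule ingestion: canonical SMILES, the four conditioning properties
# (logP, TPSA, QED, SAS), Bemis-Murcko scaffolds, and conversion of molecules
# to one-hot featurised heavy-atom graphs.

PROPERTY_NAMES <- c("logP", "TPSA", "QED", "SAS")

# One-hot blocks for atom featurisation. Out-of-range values fall into the
# final ("other" / overflow) bucket of their block, never an error.
ATOM_TYPES <- c("C", "N", "O", "F", "S", "Cl", "Br", "I", "P", "B", "other")
DEGREE_LEVELS <- 0:5
NUMH_LEVELS <- 0:4
IMPVAL_LEVELS <- 0:5

#' Width of the atom one-hot feature vector
#' @return integer, number of columns of a [mol_to_graph()] feature matrix.
#' @export
atom_feature_dim <- function() {
  length(ATOM_TYPES) + length(DEGREE_LEVELS) + length(NUMH_LEVELS) +
    length(IMPVAL_LEVELS)
}

#' Canonicalize SMILES strings
#'
#' Normalizes each SMILES to the toolkit's canonical form so that string
#' equality means molecule identity (the set semantics behind uniqueness and
#' novelty metrics). Canonicalization is idempotent.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  recs <- bridge_records(smiles)
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad)) {
    stop("could not parse SMILES: ",
         paste(sQuote(smiles[bad]), collapse = ", "))
  }
  vapply(recs, function(r) r$smiles, character(1))
}

#' Test whether SMILES strings parse and sanitize
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  if (length(smiles) == 0) return(logical(0))
  ok <- nzchar(smiles) & !is.na(smiles)
  res <- rep(FALSE, length(smiles))
  if (any(ok)) {
    recs <- bridge_records(smiles[ok])
    res[ok] <- !vapply(recs, is.null, logical(1))
  }
  res
}

#' Compute the four conditioning properties of a molecule
#'
#' logP (Crippen lipophilicity), TPSA (topological polar surface area, in
#' square Angstrom), QED (drug-likeness in \[0,1\]) and SAS (synthetic
#' accessibility, 1 = easy to 10 = hard), computed with RDKit.
#'
#' @param smiles a single valid SMILES string.
#' @return named numeric vector with elements logP, TPSA, QED, SAS.
#' @export
compute_properties <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  rec <- bridge_records(smiles)[[1]]
  if (is.null(rec)) stop("could not parse SMILES ", sQuote(smiles))
  unlist(rec[PROPERTY_NAMES])
}

#' Extract the Bemis-Murcko scaffold
#'
#' Returns the ring systems plus linkers of the molecule with side chains
#' removed (standard Bemis-Murcko framework). Acyclic molecules have no ring
#' system and yield the empty string.
#'
#' @param smiles a single valid SMILES string.
#' @return scaffold SMILES, or `""` for acyclic molecules.
#' @export
extract_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  rec <- bridge_records(smiles)[[1]]
  if (is.null(rec)) stop("could not parse SMILES ", sQuote(smiles))
  rec$scaffold
}

one_hot_index <- function(value, levels) {
  i <- match(value, levels)
  ifelse(is.na(i), length(levels), i)
}

#' Convert a molecule to a featurised heavy-atom graph
#'
#' Atoms become nodes carrying a concatenation of four one-hot blocks (atom
#' type, heavy-atom degree, hydrogen count, implicit valence; each row sums to
#' exactly 4) and bonds become undirected edges. Hydrogens are implicit: the
#' hydrogen-count block carries that information.
#'
#' @param smiles a single valid SMILES string.
#' @return a `molecular_graph`: list with `node_features` (N x F binary
#'   matrix), `edges` (E x 2 integer matrix of 1-based node pairs, zero rows
#'   for single atoms), and `num_nodes`.
#' @export
mol_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  .moltwin$graph_calls <- .moltwin$graph_calls + 1L
  g <- bridge_graphs(smiles)[[1]]
  if (is.null(g)) stop("could not parse SMILES ", sQuote(smiles))
  n <- length(g$symbols)
  feat <- matrix(0, nrow = n, ncol = atom_feature_dim())
  off <- 0L
  blocks <- list(
    list(vals = unlist(g$symbols), levels = ATOM_TYPES),
    list(vals = unlist(g$degree), levels = DEGREE_LEVELS),
    list(vals = unlist(g$numhs), levels = NUMH_LEVELS),
    list(vals = unlist(g$impval), levels = IMPVAL_LEVELS)
  )
  for (b in blocks) {
    feat[cbind(seq_len(n), off + one_hot_index(b$vals, b$levels))] <- 1
    off <- off + length(b$levels)
  }
  edges <- matrix(integer(0), ncol = 2)
  if (length(g$bonds) > 0) {
    edges <- do.call(rbind, lapply(g$bonds, function(b) {
      sort(c(b[[1]] + 1L, b[[2]] + 1L))
    }))
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  structure(list(node_features = feat, edges = edges, num_nodes = n),
            class = "molecular_graph")
}

#' Number of molecular-graph constructions so far
#'
#' Instrumentation used to assert the inference-time contract that sampling
#' never touches graph construction (the graph encoder is training-only).
#' @param reset if `TRUE`, reset the counter to zero.
#' @return integer count (before any reset).
#' @export
graph_call_count <- function(reset = FALSE) {
  n <- .moltwin$graph_calls
  if (reset) .moltwin$graph_calls <- 0L
  n
}

#' Build full molecule records from SMILES
#'
#' Canonicalizes each SMILES and attaches the four conditioning properties and
#' the Bemis-Murcko scaffold. Invalid entries are dropped with a warning.
#'
#' @param smiles character vector.
#' @param properties optional data frame of precomputed `logP,TPSA,QED,SAS`
#'   columns aligned with `smiles`; computed with RDKit when absent.
#' @return a data frame with columns `smiles`, `logP`, `TPSA`, `QED`, `SAS`,
#'   `scaffold`; attribute `n_skipped` counts dropped rows.
#' @export
molecule_records <- function(smiles, properties = NULL) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    warning("no molecules supplied; returning an empty record set")
    out <- data.frame(smiles = character(0), logP = numeric(0),
                      TPSA = numeric(0), QED = numeric(0), SAS = numeric(0),
                      scaffold = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  recs <- bridge_records(smiles)
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " invalid SMILES skipped")
  }
  recs <- recs[!bad]
  out <- data.frame(
    smiles = vapply(recs, `[[`, character(1), "smiles"),
    logP = vapply(recs, `[[`, numeric(1), "logP"),
    TPSA = vapply(recs, `[[`, numeric(1), "TPSA"),
    QED = vapply(recs, `[[`, numeric(1), "QED"),
    SAS = vapply(recs, `[[`, numeric(1), "SAS"),
    scaffold = vapply(recs, `[[`, character(1), "scaffold"),
    stringsAsFactors = FALSE
  )
  if (!is.null(properties)) {
    have <- intersect(PROPERTY_NAMES, names(properties))
    props <- properties[!bad, , drop = FALSE]
    for (p in have) out[[p]] <- as.numeric(props[[p]])
  }
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read a molecule dataset from disk
#'
#' @param path file path; either one SMILES per line (`format = "smi"`) or a
#'   CSV with a `smiles` column and optional precomputed property columns
#'   (`format = "csv"`).
#' @param format `"smi"` or `"csv"`; inferred from the extension by default.
#' @return a record data frame as from [molecule_records()].
#' @export
read_dataset <- function(path, format = c("auto", "smi", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  }
  if (format == "smi") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    return(molecule_records(lines))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(tab)) {
    stop("CSV dataset must have a 'smiles' column: ", path)
  }
  props <- if (all(PROPERTY_NAMES %in% names(tab))) {
    tab[PROPERTY_NAMES]
  }
  molecule_records(as.character(tab$smiles), properties = props)
}

#' Write a molecule record set as CSV
#'
#' @param records record data frame from [molecule_records()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(records[c("smiles", PROPERTY_NAMES, "scaffold")], path,
                   row.names = FALSE)
  invisible(path)
}
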