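# Subprocess bridge to RDKit. All cheminformatics primitives (parsing,
# canonical SMILES, descriptors, scaffolds, fingerprints, substructure
# matching) are delegated to a bundled python worker; calls are batched over
# whole SMILES vectors and memoised per session, so repeated use of the same
# molecules costs one subprocess round-trip.

.moltwin <- new.env(parent = emptyenv())
.moltwin$cache <- new.env(parent = emptyenv())
.moltwin$graph_calls <- 0L

bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "moltwin")
  if (!nzchar(path) || !file.exists(path)) {
    stop("chem_bridge.py not found; is moltwin installed correctly?")
  }
  path
}

python_binary <- function() {
  Sys.getenv("MOLTWIN_PYTHON", "python")
}

#' Low-level call into the RDKit worker
#'
#' @param op operation name understood by the worker.
#' @param ... request fields (typically `smiles = <character vector>`).
#' @return the worker's JSON response as an R list.
#' @keywords internal
bridge_call <- function(op, ...) {
  req <- list(op = op, ...)
  # named vectors/lists would serialize as JSON objects instead of arrays
  req <- lapply(req, unname)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(python_binary(), c(shQuote(bridge_script()),
                                       shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("RDKit bridge call '", op, "' failed (python exit status ", status, ")")
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# Memoised per-molecule bridge call: `fetch(smiles)` must return a list of
# per-molecule results aligned with its input. Results (including NULL for
# invalid SMILES) are cached under op:smiles.
bridge_cached <- function(op, smiles, fetch) {
  keys <- paste0(op, ":", smiles)
  missing <- !vapply(keys, exists, logical(1), envir = .moltwin$cache,
                     USE.NAMES = FALSE)
  if (any(missing)) {
    todo <- unique(smiles[missing])
    got <- fetch(todo)
    for (k in seq_along(todo)) {
      assign(paste0(op, ":", todo[[k]]), got[[k]], envir = .moltwin$cache)
    }
  }
  lapply(keys, get, envir = .moltwin$cache)
}

bridge_records <- function(smiles) {
  bridge_cached("record", smiles, function(todo) {
    bridge_call("record", smiles = as.list(todo))$records
  })
}

bridge_graphs <- function(smiles) {
  bridge_cached("graph", smiles, function(todo) {
    bridge_call("graph", smiles = as.list(todo))$graphs
  })
}

bridge_morgan <- function(smiles, radius = 2L, nbits = 2048L) {
  op <- sprintf("morgan%d_%d", radius, nbits)
  bridge_cached(op, smiles, function(todo) {
    bridge_call("morgan", smiles = as.list(todo),
                radius = radius, nbits = nbits)$bits
  })
}

bridge_descriptors <- function(smiles) {
  bridge_cached("desc", smiles, function(todo) {
    bridge_call("descriptors", smiles = as.list(todo))$descriptors
  })
}

bridge_substructure <- function(smiles, query) {
  stopifnot(length(smiles) == length(query))
  res <- bridge_call("substructure", smiles = as.list(smiles),
                     query = as.list(query))$match
  vapply(res, function(x) if (is.null(x)) NA else isTRUE(x), logical(1))
}
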