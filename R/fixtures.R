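# Deterministic synthetic-SMILES generation. Molecules are assembled from a
# closed fragment grammar -- a ring core (benzene, pyridine, cyclohexane) with
# substituents drawn from a small drug-like pool -- so every output is valid by
# construction and ring-containing outputs have non-empty Bemis-Murcko
# scaffolds. The polar substituents (hydroxyl, amino, carbonyl, carboxyl,
# amide) spread TPSA over roughly 0-100 A^2, which gives property conditioning
# something to learn at desk scale.

# cores: SMILES split at substitutable positions. "slots" marks ring atoms
# that can accept one branch each (aromatic N cannot).
.cores <- list(
  benzene = list(atoms = c("c1", "c", "c", "c", "c", "c1"),
                 slots = 1:6, heavy = 6),
  pyridine = list(atoms = c("c1", "c", "c", "n", "c", "c1"),
                  slots = c(1:3, 5:6), heavy = 6),
  cyclohexane = list(atoms = c("C1", "C", "C", "C", "C", "C1"),
                     slots = 1:6, heavy = 6)
)

# substituent pool: branch SMILES and heavy-atom counts
.substituents <- data.frame(
  smiles = c("C", "CC", "CCC", "O", "N", "F", "Cl", "Br",
             "C=O", "C(=O)O", "C(N)=O", "OC", "CO"),
  heavy = c(1, 2, 3, 1, 1, 1, 1, 1, 2, 3, 3, 2, 2),
  stringsAsFactors = FALSE
)

# acyclic fall-back used when the heavy-atom budget cannot fit a ring core
.chain_atoms <- c("C", "N", "O")

#' Describe a synthetic fixture dataset
#'
#' @param n number of molecules.
#' @param seed RNG seed; the same spec always yields the same molecules.
#' @param max_heavy_atoms per-molecule heavy-atom budget.
#' @param max_substituents most substituents attached to a ring core.
#' @return a `synthetic_dataset_spec` list.
#' @export
synthetic_dataset_spec <- function(n, seed = 1L, max_heavy_atoms = 16L,
                                   max_substituents = 3L) {
  stopifnot(n >= 1, max_heavy_atoms >= 1, max_substituents >= 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 max_substituents = as.integer(max_substituents)),
            class = "synthetic_dataset_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

one_synth_smiles <- function(max_heavy, max_sub) {
  if (max_heavy < 7) {
    # no room for a core plus growth: short heteroatom chain
    len <- sample.int(max(1L, min(max_heavy, 4L)), 1)
    atoms <- c(sample(.chain_atoms, 1),
               if (len > 1) sample(c("C", "C", "O"), len - 1, replace = TRUE))
    # avoid O-O / heteroatom-terminal oddities by keeping interior carbons
    if (len > 2) atoms[2:(len - 1)] <- "C"
    return(paste(atoms, collapse = ""))
  }
  core <- .cores[[sample(length(.cores), 1)]]
  budget <- max_heavy - core$heavy
  pool <- .substituents[.substituents$heavy <= budget, , drop = FALSE]
  n_sub <- if (nrow(pool) == 0 || max_sub == 0) 0L else
    sample.int(max_sub + 1L, 1) - 1L
  atoms <- core$atoms
  if (n_sub > 0) {
    positions <- sample(core$slots, min(n_sub, length(core$slots)))
    for (pos in positions) {
      pool_now <- .substituents[.substituents$heavy <= budget, , drop = FALSE]
      if (nrow(pool_now) == 0) break
      pick <- pool_now[sample.int(nrow(pool_now), 1), ]
      atoms[pos] <- paste0(atoms[pos], "(", pick$smiles, ")")
      budget <- budget - pick$heavy
    }
  }
  paste(atoms, collapse = "")
}

#' Generate deterministic, valid synthetic SMILES
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return character vector of `spec$n` canonical SMILES (every one valid by
#'   construction and verified against the parser).
#' @export
synth_smiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  raw <- with_seed(spec$seed, {
    vapply(seq_len(spec$n), function(i) {
      one_synth_smiles(spec$max_heavy_atoms, spec$max_substituents)
    }, character(1))
  })
  canonicalize(raw)
}

#' Generate a synthetic molecule record set
#'
#' Runs [synth_smiles()] and attaches properties and scaffolds via the chem
#' layer, yielding ready-to-train records.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return record data frame as from [molecule_records()].
#' @export
toy_dataset <- function(spec) {
  molecule_records(synth_smiles(spec))
}
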