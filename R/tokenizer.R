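# SMILES tokenizer, vocabulary, and fixed-length sequence encoding with a
# condition prefix: [property slots][SEP][scaffold tokens][SEP][BOS mol EOS][PAD].
# Property targets are not binned into tokens: a conditioned property occupies
# one reserved slot token whose embedding the sequence model replaces by an
# affine map of the (normalised) scalar target.

SPECIAL_TOKENS <- c(PAD = "<pad>", BOS = "<bos>", EOS = "<eos>", SEP = "<sep>")
PROP_SLOT_TOKENS <- c(logP = "<logP>", TPSA = "<TPSA>",
                      QED = "<QED>", SAS = "<SAS>")

# Fixed scales used to bring property targets to O(1) before the affine slot
# embedding; chosen from the spans of drug-like sets (logP ~ [-5,10],
# TPSA ~ [0,150], QED in [0,1], SAS in [1,10]).
PROP_SCALES <- c(logP = 10, TPSA = 150, QED = 1, SAS = 10)

.single_chars <- strsplit("BCNOPSFIbcnops0123456789=#-+()/\\.:~@*$", "")[[1]]

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the model's atomic units: bracket atoms
#' (`[nH]`), two-letter halogens (`Cl`, `Br`), `%nn` ring closures, and single
#' characters (atoms, ring digits, bond and branch symbols). Concatenating the
#' tokens reproduces the input exactly.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom starting at position ", i,
                      " in ", sQuote(smiles))
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tokens <- c(tokens, "Cl")
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tokens <- c(tokens, "Br")
      i <- i + 2L
    } else if (ch == "%") {
      if (i + 2L > n || !all(chars[(i + 1L):(i + 2L)] %in% as.character(0:9))) {
        stop("malformed %nn ring closure at position ", i, " in ",
             sQuote(smiles))
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% .single_chars) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop("character ", sQuote(ch), " at position ", i,
           " is outside the SMILES alphabet")
    }
  }
  tokens
}

#' Build a deterministic vocabulary from a SMILES corpus
#'
#' Ids are contiguous from 0: the four specials first, then the four reserved
#' property-slot markers, then all corpus tokens in sorted order (so the same
#' corpus always yields the same mapping).
#'
#' @param corpus character vector of SMILES (include scaffold strings if
#'   scaffold conditioning will be used).
#' @return a `vocabulary`: list with `token_to_id` (named integer vector,
#'   0-based ids), `id_to_token`, `specials`, and `size`.
#' @export
build_vocab <- function(corpus) {
  if (length(corpus) == 0) stop("cannot build a vocabulary from an empty corpus")
  toks <- sort(unique(unlist(lapply(corpus, smiles_tokenize))))
  all_tokens <- c(unname(SPECIAL_TOKENS), unname(PROP_SLOT_TOKENS), toks)
  ids <- seq_along(all_tokens) - 1L
  names(ids) <- all_tokens
  structure(list(
    token_to_id = ids,
    id_to_token = all_tokens,
    specials = stats::setNames(ids[unname(SPECIAL_TOKENS)],
                               names(SPECIAL_TOKENS)),
    prop_slots = stats::setNames(ids[unname(PROP_SLOT_TOKENS)],
                                 names(PROP_SLOT_TOKENS)),
    size = length(all_tokens)
  ), class = "vocabulary")
}

#' Save / load a vocabulary as JSON
#' @param vocab a vocabulary.
#' @param path JSON file path.
#' @return `save_vocab` returns `path` invisibly; `load_vocab` the vocabulary.
#' @export
save_vocab <- function(vocab, path) {
  jsonlite::write_json(list(token_to_id = as.list(vocab$token_to_id),
                            specials = as.list(vocab$specials)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(path) {
  raw <- jsonlite::read_json(path)
  ids <- unlist(raw$token_to_id)
  ids <- sort(ids)
  tokens <- names(ids)
  stopifnot(identical(unname(ids), seq_along(ids) - 1L))
  names(ids) <- tokens
  structure(list(
    token_to_id = ids,
    id_to_token = tokens,
    specials = stats::setNames(ids[unname(SPECIAL_TOKENS)],
                               names(SPECIAL_TOKENS)),
    prop_slots = stats::setNames(ids[unname(PROP_SLOT_TOKENS)],
                                 names(PROP_SLOT_TOKENS)),
    size = length(ids)
  ), class = "vocabulary")
}

#' Specify a generation condition
#'
#' @param property_targets named numeric vector: a subset of
#'   `logP`, `TPSA`, `QED`, `SAS` with target values. May be empty
#'   (unconditional).
#' @param scaffold optional scaffold SMILES to condition on.
#' @return a `generation_condition` list.
#' @export
generation_condition <- function(property_targets = numeric(0),
                                 scaffold = NULL) {
  if (length(property_targets) > 0) {
    stopifnot(!is.null(names(property_targets)),
              all(names(property_targets) %in% names(PROP_SLOT_TOKENS)))
    # canonical slot order, regardless of how the user named them
    property_targets <-
      property_targets[intersect(names(PROP_SLOT_TOKENS),
                                 names(property_targets))]
  }
  if (!is.null(scaffold)) {
    stopifnot(is.character(scaffold), length(scaffold) == 1, nzchar(scaffold))
    if (!is_valid_smiles(scaffold)) {
      stop("condition scaffold is not valid SMILES: ", sQuote(scaffold))
    }
  }
  structure(list(property_targets = property_targets, scaffold = scaffold),
            class = "generation_condition")
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- vocab$token_to_id[tokens]
  if (anyNA(ids)) {
    stop("token(s) not in vocabulary: ",
         paste(sQuote(tokens[is.na(ids)]), collapse = ", "))
  }
  unname(ids)
}

#' Encode a molecule and its condition into a fixed-length id sequence
#'
#' Layout: `[property slots][SEP][scaffold tokens][SEP][BOS molecule EOS][PAD...]`.
#' A segment absent from the condition is omitted together with its SEP.
#'
#' @param smiles the molecule SMILES (the decoding target).
#' @param condition a [generation_condition()].
#' @param vocab a [build_vocab()] vocabulary.
#' @param max_len fixed sequence length (default 100).
#' @return a `token_sequence`: list with `ids` (0-based, length `max_len`),
#'   `mask` (TRUE on non-PAD), `prop_values` (named targets for the slots, in
#'   slot order), `slot_pos`, `bos_pos`, `eos_pos`, `smiles_span`.
#' @export
encode_sequence <- function(smiles, condition = generation_condition(),
                            vocab, max_len = 100L) {
  prefix <- encode_prefix(condition, vocab)
  mol_ids <- tokens_to_ids(smiles_tokenize(smiles), vocab)
  sp <- vocab$specials
  body <- c(sp[["BOS"]], mol_ids, sp[["EOS"]])
  total <- length(prefix$ids) + length(body)
  if (total > max_len) {
    stop("encoded length ", total, " exceeds max_len ", max_len,
         " for ", sQuote(smiles))
  }
  ids <- c(prefix$ids, body, rep(sp[["PAD"]], max_len - total))
  bos_pos <- length(prefix$ids) + 1L
  structure(list(
    ids = as.integer(ids),
    mask = seq_len(max_len) <= total,
    prop_values = prefix$prop_values,
    slot_pos = prefix$slot_pos,
    bos_pos = bos_pos,
    eos_pos = total,
    smiles_span = if (length(mol_ids) > 0) (bos_pos + 1L):(total - 1L)
                  else integer(0)
  ), class = "token_sequence")
}

# ids + slot bookkeeping for the condition prefix (no BOS)
encode_prefix <- function(condition, vocab) {
  sp <- vocab$specials
  ids <- integer(0)
  slot_pos <- integer(0)
  prop_values <- numeric(0)
  targets <- condition$property_targets
  if (length(targets) > 0) {
    slot_pos <- seq_along(targets)
    ids <- c(unname(vocab$prop_slots[names(targets)]), sp[["SEP"]])
    prop_values <- targets
  }
  if (!is.null(condition$scaffold)) {
    scaf_ids <- tokens_to_ids(smiles_tokenize(condition$scaffold), vocab)
    ids <- c(ids, scaf_ids, sp[["SEP"]])
  }
  list(ids = ids, slot_pos = slot_pos, prop_values = prop_values)
}

#' Decode generated token ids back to a SMILES string
#'
#' Concatenates the tokens strictly between BOS and the first EOS after it;
#' condition prefix, specials, and trailing PAD are stripped. When BOS is
#' missing an empty string is returned; when EOS is missing the truncated
#' string is returned; both cases are flagged with attribute
#' `complete = FALSE`.
#'
#' @param ids integer vector of 0-based token ids.
#' @param vocab the vocabulary used for encoding.
#' @return SMILES string with logical attribute `complete`.
#' @export
decode_ids <- function(ids, vocab) {
  sp <- vocab$specials
  bos <- which(ids == sp[["BOS"]])
  if (length(bos) == 0) {
    return(structure("", complete = FALSE))
  }
  rest <- ids[seq(bos[1] + 1L, length.out = length(ids) - bos[1])]
  eos <- which(rest == sp[["EOS"]])
  complete <- length(eos) > 0
  mol_ids <- if (complete) rest[seq_len(eos[1] - 1L)] else
    rest[rest != sp[["PAD"]]]
  smiles <- paste(vocab$id_to_token[mol_ids + 1L], collapse = "")
  structure(smiles, complete = complete)
}
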