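# Autoregressive sampling under a generation condition, and attention-map
# export for token-level inspection. Sampling runs the sequence model only:
# the graph encoder is inference-suspended and no molecular graph is built.

#' Sample molecules from a trained model
#'
#' Decoding starts from the encoded condition prefix plus BOS and draws
#' multinomial samples from the temperature-scaled next-token distribution
#' until EOS or `max_len`. Generated strings are returned as-is (possibly
#' invalid); validity is a metric, not a filter.
#'
#' @param model a trained `moltwin_model` (or [load_checkpoint()] result).
#' @param n number of molecules to sample.
#' @param condition a [generation_condition()]; its properties must be a
#'   subset of the schema the model was trained with.
#' @param temperature softmax temperature (> 0).
#' @param seed sampling seed; the same seed reproduces the batch exactly.
#' @return a `sample_batch`: list with `smiles` (length n), `complete`
#'   (logical: EOS reached), `condition`, `seed`, `temperature`.
#' @export
sample_molecules <- function(model, n, condition = generation_condition(),
                             temperature = 1.0, seed = 1L) {
  stopifnot(inherits(model, "moltwin_model"), n >= 0, temperature > 0)
  cond_props <- names(condition$property_targets)
  if (!all(cond_props %in% model$config$properties)) {
    stop("condition propert(ies) ",
         paste(sQuote(setdiff(cond_props, model$config$properties)),
               collapse = ", "),
         " not in the trained schema (",
         paste(model$config$properties, collapse = ", "), ")")
  }
  if (!is.null(condition$scaffold) && !isTRUE(model$config$use_scaffold)) {
    stop("model was not trained with scaffold conditioning")
  }
  out <- structure(list(smiles = character(n), complete = logical(n),
                        condition = condition, seed = seed,
                        temperature = temperature),
                   class = "sample_batch")
  if (n == 0) return(out)
  vocab <- model$vocab
  cfg <- model$seq_config
  prefix <- encode_prefix(condition, vocab)
  p0 <- length(prefix$ids) + 1L # prefix + BOS
  L <- cfg$max_len
  ids <- matrix(vocab$specials[["PAD"]], n, L)
  ids[, seq_len(p0)] <- matrix(c(prefix$ids, vocab$specials[["BOS"]]),
                               n, p0, byrow = TRUE)
  prop_values <- NULL
  n_slots <- length(prefix$prop_values)
  if (n_slots > 0) {
    prop_values <- matrix(prefix$prop_values, n, n_slots, byrow = TRUE)
  }
  # model slot order: condition properties occupy the leading positions in
  # the order of the trained schema restricted to the condition
  with_seed(seed, {
    active <- rep(TRUE, n)
    eos <- vocab$specials[["EOS"]]
    t <- p0
    while (t < L && any(active)) {
      rows <- which(active)
      fwd <- minigpt_forward(
        sample_slot_params(model, cond_props), cfg,
        ids[rows, seq_len(t), drop = FALSE],
        prop_values = prop_values[rows, , drop = FALSE],
        n_slots = n_slots, training = FALSE)
      last <- fwd$logits[seq_along(rows) * t, , drop = FALSE] / temperature
      probs <- row_softmax(last)
      nxt <- vapply(seq_along(rows), function(i) {
        sample.int(ncol(probs), 1, prob = probs[i, ]) - 1L
      }, integer(1))
      ids[rows, t + 1L] <- nxt
      active[rows[nxt == eos]] <- FALSE
      t <- t + 1L
    }
  })
  decoded <- lapply(seq_len(n), function(i) decode_ids(ids[i, ], vocab))
  out$smiles <- vapply(decoded, as.character, character(1))
  out$complete <- vapply(decoded, function(x) isTRUE(attr(x, "complete")),
                         logical(1))
  out
}

# When the condition uses a subset of the trained properties, the slot
# parameter rows must be re-aligned with the condition's slot order.
sample_slot_params <- function(model, cond_props) {
  params <- model$params
  if (length(cond_props) == 0 || is.null(params$prop_w)) return(params)
  ord <- intersect(model$config$properties, cond_props)
  params$prop_w <- params$prop_w[ord, , drop = FALSE]
  params$prop_b <- params$prop_b[ord, , drop = FALSE]
  params
}

#' Token-level attention maps
#'
#' Runs the model over the bare token sequence of a SMILES string and returns
#' the causal attention weights of every layer and head: each map is a
#' token x token matrix whose rows sum to 1 over visible (non-future)
#' positions, with exact zeros above the diagonal.
#'
#' @param model a trained `moltwin_model`.
#' @param smiles molecule to inspect; must tokenize within `max_len`.
#' @return nested list `maps[[layer]][[head]]`, each a T x T matrix with the
#'   tokens as dimnames.
#' @export
attention_maps <- function(model, smiles) {
  tokens <- smiles_tokenize(smiles)
  if (length(tokens) > model$seq_config$max_len) {
    stop("input has ", length(tokens), " tokens; max_len is ",
         model$seq_config$max_len)
  }
  ids <- matrix(tokens_to_ids(tokens, model$vocab), nrow = 1)
  fwd <- minigpt_forward(model$params, model$seq_config, ids,
                         training = FALSE, return_attention = TRUE)
  maps <- lapply(fwd$attention, function(layer) {
    heads <- lapply(layer, function(head) {
      m <- head[[1]]
      dimnames(m) <- list(tokens, tokens)
      m
    })
    names(heads) <- paste0("head", seq_along(heads))
    heads
  })
  names(maps) <- paste0("layer", seq_along(maps))
  maps
}

#' Export attention maps as JSON
#' @param maps result of [attention_maps()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_attention_maps <- function(maps, path) {
  jsonlite::write_json(maps, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
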