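# End-to-end training: teacher-forced next-token prediction on condition-
# prefixed SMILES, with the graph encoder active (training only) feeding the
# Barlow Twins alignment term. One seed controls initialisation, shuffling
# and dropout; the same seed and data reproduce the run exactly.

#' Training configuration
#'
#' @param epochs passes over the dataset.
#' @param batch_size sequences per step (>= 2 when `standardize`).
#' @param lr peak AdamW learning rate (linear warm-up, cosine decay).
#' @param weight_decay decoupled weight decay.
#' @param seed master seed for initialisation, shuffling and dropout.
#' @param decoder_layers decoder depth (4/8/12 in the depth ablation).
#' @param n_heads attention heads.
#' @param d_model embedding width.
#' @param max_len fixed sequence length; longer encodings are skipped.
#' @param d_align alignment-space dimension shared by both encoders.
#' @param dropout dropout rate for both encoders.
#' @param use_graph_encoder graph-alignment toggle: when `FALSE`, no molecular
#'   graph is ever constructed and the alignment loss is identically zero.
#' @param lambda Barlow Twins off-diagonal weight.
#' @param standardize batch standardization inside the alignment term.
#' @param properties which properties condition generation (slot order).
#' @param use_scaffold condition on the record's Bemis-Murcko scaffold.
#' @param gat_heads,gat_head_dim first graph-attention layer shape.
#' @param clip_norm global gradient-norm clip (GPT-family default 1.0); the
#'   alignment term's gradient spikes early in training, and clipping keeps
#'   the shared trunk stable. `Inf` disables.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 16L, lr = 6e-4,
                         weight_decay = 0.01, seed = 1L, decoder_layers = 8L,
                         n_heads = 8L, d_model = 256L, max_len = 100L,
                         d_align = 64L, dropout = 0.1,
                         use_graph_encoder = TRUE, lambda = 0.005,
                         standardize = TRUE, properties = character(0),
                         use_scaffold = FALSE, gat_heads = 4L,
                         gat_head_dim = 8L, clip_norm = 1.0) {
  stopifnot(decoder_layers >= 1, epochs >= 1,
            !(standardize && batch_size < 2),
            all(properties %in% names(PROP_SLOT_TOKENS)))
  # slots always appear in canonical property order, whatever order was given
  properties <- intersect(names(PROP_SLOT_TOKENS), properties)
  structure(as.list(environment()), class = "train_config")
}

encode_training_set <- function(records, config, vocab) {
  seqs <- vector("list", nrow(records))
  skipped <- 0L
  for (i in seq_len(nrow(records))) {
    targets <- stats::setNames(
      as.numeric(records[i, config$properties, drop = TRUE]),
      config$properties)
    scaf <- NULL
    if (config$use_scaffold && nzchar(records$scaffold[i])) {
      scaf <- records$scaffold[i]
    }
    cond <- generation_condition(targets, scaffold = scaf)
    seqs[i] <- list(tryCatch(
      encode_sequence(records$smiles[i], cond, vocab, config$max_len),
      error = function(e) NULL))
    if (is.null(seqs[[i]])) skipped <- skipped + 1L
  }
  keep <- !vapply(seqs, is.null, logical(1))
  if (skipped > 0) {
    message(skipped, " over-length molecules skipped")
  }
  list(seqs = seqs[keep], records = records[keep, , drop = FALSE],
       skipped = skipped)
}

# stack a list of token_sequences into batch matrices
collate_batch <- function(seqs, config) {
  L <- config$max_len
  B <- length(seqs)
  ids <- do.call(rbind, lapply(seqs, `[[`, "ids"))
  mask <- do.call(rbind, lapply(seqs, `[[`, "mask"))
  prop_values <- NULL
  if (length(config$properties) > 0) {
    prop_values <- do.call(rbind, lapply(seqs, `[[`, "prop_values"))
  }
  # next-token targets: position t predicts ids[t+1]; supervise exactly the
  # molecule span plus EOS (positions bos..eos-1); the condition prefix and
  # PAD are excluded
  targets <- cbind(ids[, -1, drop = FALSE], 0L)
  loss_mask <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    loss_mask[b, seqs[[b]]$bos_pos:(seqs[[b]]$eos_pos - 1L)] <- TRUE
  }
  list(ids = ids, mask = mask, prop_values = prop_values,
       targets_flat = as.integer(t(targets)),
       loss_mask_flat = as.logical(t(loss_mask)))
}

#' Train the graph-aligned SMILES generator
#'
#' @param records molecule record data frame ([molecule_records()],
#'   [toy_dataset()] or [read_dataset()]).
#' @param config a [train_config()].
#' @return a `moltwin_model`: list with `params` (sequence model),
#'   `gat_params` (or NULL), `config`, `seq_config`, `gat_config`, `vocab`,
#'   and `log` (one row per step: step, epoch, loss, l_bt, l_ground).
#' @export
train_model <- function(records, config) {
  stopifnot(inherits(config, "train_config"), nrow(records) >= 1)
  set.seed(config$seed)
  corpus <- records$smiles
  if (config$use_scaffold) {
    corpus <- c(corpus, records$scaffold[nzchar(records$scaffold)])
  }
  vocab <- build_vocab(corpus)
  seq_config <- minigpt_config(
    vocab_size = vocab$size, n_layers = config$decoder_layers,
    n_heads = config$n_heads, d_model = config$d_model,
    max_len = config$max_len, d_align = config$d_align,
    dropout = config$dropout, properties = config$properties)
  enc <- encode_training_set(records, config, vocab)
  if (length(enc$seqs) == 0) stop("no trainable molecules after encoding")
  params <- minigpt_init(seq_config)
  gcfg <- NULL
  gat_params <- NULL
  graphs <- NULL
  if (config$use_graph_encoder) {
    gcfg <- gat_config(out_dim = config$d_align, heads = config$gat_heads,
                       head_dim = config$gat_head_dim,
                       dropout = config$dropout)
    gat_params <- gat_init(gcfg)
    graphs <- lapply(enc$records$smiles, mol_to_graph)
  }
  n <- length(enc$seqs)
  n_slots <- length(config$properties)
  opt_seq <- adam_init(params)
  opt_gat <- if (config$use_graph_encoder) adam_init(gat_params)
  steps_per_epoch <- length(batch_starts(n, config$batch_size))
  total_steps <- steps_per_epoch * config$epochs
  log <- vector("list", total_steps)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(n)
    for (start in batch_starts(n, config$batch_size)) {
      step <- step + 1L
      take <- order[start:min(start + config$batch_size - 1L, n)]
      batch <- collate_batch(enc$seqs[take], config)
      fwd <- minigpt_forward(params, seq_config, batch$ids,
                             prop_values = batch$prop_values,
                             n_slots = n_slots, training = TRUE,
                             keep_cache = TRUE)
      ce <- ce_forward(fwd$logits, batch$targets_flat, batch$loss_mask_flat)
      dlogits <- ce_backward(fwd$logits, batch$targets_flat,
                             batch$loss_mask_flat)
      l_bt <- 0
      dz_seq <- NULL
      gat_fwds <- NULL
      bt <- NULL
      if (config$use_graph_encoder) {
        gat_fwds <- lapply(graphs[take], function(g) {
          encode_graph(g, gat_params, gcfg, training = TRUE,
                       keep_cache = TRUE)
        })
        z_graph <- do.call(rbind, lapply(gat_fwds, `[[`, "z"))
        z_seq <- map_sequence_embedding(fwd$hidden, batch$mask,
                                        params$mapper)
        bt <- barlow_twins_grad(z_graph, z_seq, lambda = config$lambda,
                                standardize = config$standardize)
        l_bt <- bt$loss
        dz_seq <- bt$dzb
      }
      if (!is.finite(ce$loss) || !is.finite(l_bt)) {
        stop("divergent loss at step ", step, " (l_ground = ", ce$loss,
             ", l_bt = ", l_bt, "); lower the learning rate")
      }
      grads <- minigpt_backward(params, seq_config, fwd, dlogits,
                                dz_seq = dz_seq, mask = batch$mask)
      grads <- clip_global_norm(grads, config$clip_norm)
      lr_t <- lr_schedule(step, total_steps, config$lr)
      st <- adam_step(params, grads, opt_seq, lr_t, config$weight_decay)
      params <- st$params
      opt_seq <- st$state
      if (config$use_graph_encoder) {
        ggrads <- tree_zeros_like(gat_params)
        for (b in seq_along(take)) {
          gb <- encode_graph_backward(bt$dza[b, ], gat_fwds[[b]]$cache,
                                      gat_params, gcfg)
          ggrads <- tree_add(ggrads, gb)
        }
        ggrads <- clip_global_norm(ggrads, config$clip_norm)
        stg <- adam_step(gat_params, ggrads, opt_gat, lr_t,
                         config$weight_decay)
        gat_params <- stg$params
        opt_gat <- stg$state
      }
      log[[step]] <- data.frame(step = step, epoch = epoch,
                                loss = ce$loss + l_bt, l_bt = l_bt,
                                l_ground = ce$loss)
    }
  }
  structure(list(params = params, gat_params = gat_params, config = config,
                 seq_config = seq_config, gat_config = gcfg, vocab = vocab,
                 log = do.call(rbind, log), n_skipped = enc$skipped),
            class = "moltwin_model")
}

# batch start indices; a trailing remainder of size 1 is dropped because the
# batch-standardized alignment term needs at least two samples
batch_starts <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  sizes <- pmin(starts + batch_size - 1L, n) - starts + 1L
  starts[sizes >= min(2L, n)]
}

#' Save / load a model checkpoint
#'
#' Weights and vocabulary go into `weights.rds`; the configuration is
#' duplicated as a readable `manifest.json`. Reloading restores bitwise
#' identical weights.
#'
#' @param model a `moltwin_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint` the
#'   model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config)[setdiff(names(model$config), "")],
         vocab_size = model$vocab$size,
         n_parameters = sum(vapply(
           list(tree_leaves(model$params),
                if (!is.null(model$gat_params)) {
                  tree_leaves(model$gat_params)
                } else numeric(0)),
           length, integer(1)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
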