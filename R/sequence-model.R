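# GPT-style causal SMILES decoder: token + learned position embeddings,
# pre-layer-norm blocks of masked multi-head scaled dot-product attention and
# a 4x GELU feed-forward, a final layer norm, a next-token logits head, and a
# fully connected mapper pooling the final hidden states into the graph
# alignment space. Property-slot positions receive an affine embedding of the
# scalar target instead of a token embedding, so numeric conditions are
# injected continuously rather than through binned tokens.
#
# Batched activations are stored as a flat (B*L) x d matrix; rows
# ((b-1)*L + 1) : (b*L) belong to sample b.

#' Sequence model configuration
#'
#' Defaults follow the published full-scale setting (8 decoder layers, 8
#' heads, width 256, sequence length 100); desk-scale studies shrink them.
#'
#' @param vocab_size vocabulary size.
#' @param n_layers decoder blocks.
#' @param n_heads attention heads; must divide `d_model`.
#' @param d_model embedding width.
#' @param max_len fixed sequence length.
#' @param d_align alignment-space dimension (must equal the graph encoder's
#'   `out_dim`).
#' @param dropout dropout rate on residual branches during training.
#' @param properties character vector naming the conditioned properties, in
#'   slot order (subset of logP, TPSA, QED, SAS).
#' @return a `minigpt_config` list.
#' @export
minigpt_config <- function(vocab_size, n_layers = 8L, n_heads = 8L,
                           d_model = 256L, max_len = 100L, d_align = 64L,
                           dropout = 0.1, properties = character(0)) {
  stopifnot(d_model %% n_heads == 0, n_layers >= 1,
            all(properties %in% names(PROP_SLOT_TOKENS)))
  structure(list(vocab_size = as.integer(vocab_size),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model),
                 max_len = as.integer(max_len),
                 d_align = as.integer(d_align),
                 d_head = as.integer(d_model / n_heads),
                 dropout = dropout,
                 properties = properties),
            class = "minigpt_config")
}

#' Initialise sequence-model parameters
#' @param config a [minigpt_config()]. Uses the current RNG state.
#' @return nested parameter list.
#' @export
minigpt_init <- function(config) {
  d <- config$d_model
  block <- function() {
    list(ln1_g = rep(1, d), ln1_b = rep(0, d),
         Wq = rmat(d, d), bq = rep(0, d),
         Wk = rmat(d, d), bk = rep(0, d),
         Wv = rmat(d, d), bv = rep(0, d),
         Wo = rmat(d, d), bo = rep(0, d),
         ln2_g = rep(1, d), ln2_b = rep(0, d),
         W1 = rmat(d, 4 * d), b1 = rep(0, 4 * d),
         W2 = rmat(4 * d, d), b2 = rep(0, d))
  }
  blocks <- lapply(seq_len(config$n_layers), function(i) block())
  names(blocks) <- paste0("b", seq_len(config$n_layers))
  p <- list(tok_emb = rmat(config$vocab_size, d),
            pos_emb = rmat(config$max_len, d),
            blocks = blocks,
            lnf_g = rep(1, d), lnf_b = rep(0, d),
            W_out = rmat(d, config$vocab_size),
            b_out = rep(0, config$vocab_size),
            mapper = list(Wm = rmat(d, config$d_align),
                          bm = rep(0, config$d_align)))
  if (length(config$properties) > 0) {
    np <- length(config$properties)
    p$prop_w <- rmat(np, d)
    p$prop_b <- rmat(np, d)
    rownames(p$prop_w) <- rownames(p$prop_b) <- config$properties
  }
  p
}

#' Causal scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with a strict causal mask: position t
#' attends only to positions <= t, and the weight on any future position is
#' exactly zero.
#'
#' @param q,k,v L x d_k matrices.
#' @return list with `out` (L x d_k) and `weights` (L x L, rows sum to 1).
#' @export
causal_attention <- function(q, k, v) {
  dk <- ncol(k)
  s <- tcrossprod(q, k) / sqrt(dk)
  s[upper.tri(s)] <- -Inf
  w <- row_softmax(s)
  list(out = w %*% v, weights = w)
}

#' Forward pass of the sequence model
#'
#' @param params from [minigpt_init()].
#' @param config the matching [minigpt_config()].
#' @param ids B x L integer matrix of 0-based token ids (each row one
#'   sequence).
#' @param prop_values optional B x P matrix of raw property values aligned
#'   with `config$properties`; required when P > 0 and slots are present.
#' @param n_slots number of leading property-slot positions (same for every
#'   row; 0 when unconditional).
#' @param training enables dropout (uses the current RNG).
#' @param keep_cache keep intermediates for [minigpt_backward()].
#' @param return_attention also return per-layer, per-head attention
#'   matrices (lists indexed `[[layer]][[head]][[sample]]`).
#' @return list with `logits` ((B*L) x V), `hidden` ((B*L) x d, post final
#'   layer norm), and optionally `cache` / `attention`.
#' @export
minigpt_forward <- function(params, config, ids, prop_values = NULL,
                            n_slots = 0L, training = FALSE,
                            keep_cache = FALSE, return_attention = FALSE) {
  stopifnot(is.matrix(ids))
  B <- nrow(ids)
  L <- ncol(ids)
  stopifnot(L <= config$max_len)
  if (any(ids < 0 | ids >= config$vocab_size)) {
    stop("token id outside the vocabulary")
  }
  d <- config$d_model
  ids_flat <- as.integer(t(ids)) # row r = (b-1)*L + t
  x <- params$tok_emb[ids_flat + 1L, , drop = FALSE]
  slot_rows <- NULL
  if (n_slots > 0) {
    stopifnot(!is.null(prop_values), ncol(prop_values) >= n_slots)
    # slot s corresponds to row s of prop_w (rows may be a re-aligned subset
    # of the trained schema when sampling under a partial condition)
    scales <- PROP_SCALES[rownames(params$prop_w)]
    slot_rows <- as.vector(outer(seq_len(n_slots), (seq_len(B) - 1) * L, "+"))
    for (s in seq_len(n_slots)) {
      rows <- (seq_len(B) - 1) * L + s
      xs <- prop_values[, s] / scales[[s]]
      x[rows, ] <- outer(xs, params$prop_w[s, ]) +
        matrix(params$prop_b[s, ], B, d, byrow = TRUE)
    }
  }
  x <- x + params$pos_emb[rep(seq_len(L), B), , drop = FALSE]
  caches <- vector("list", config$n_layers)
  attn_all <- if (return_attention) vector("list", config$n_layers)
  rows_of <- function(b) ((b - 1) * L + 1):(b * L)
  for (li in seq_len(config$n_layers)) {
    bp <- params$blocks[[li]]
    ln1 <- layernorm_forward(x, bp$ln1_g, bp$ln1_b)
    a1 <- ln1$out
    q <- a1 %*% bp$Wq + matrix(bp$bq, B * L, d, byrow = TRUE)
    k <- a1 %*% bp$Wk + matrix(bp$bk, B * L, d, byrow = TRUE)
    v <- a1 %*% bp$Wv + matrix(bp$bv, B * L, d, byrow = TRUE)
    o <- matrix(0, B * L, d)
    wlist <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- rows_of(b)
      wb <- vector("list", config$n_heads)
      for (h in seq_len(config$n_heads)) {
        cols <- ((h - 1) * config$d_head + 1):(h * config$d_head)
        att <- causal_attention(q[rows, cols, drop = FALSE],
                                k[rows, cols, drop = FALSE],
                                v[rows, cols, drop = FALSE])
        o[rows, cols] <- att$out
        wb[[h]] <- att$weights
      }
      wlist[[b]] <- wb
    }
    if (return_attention) {
      attn_all[[li]] <- lapply(seq_len(config$n_heads), function(h) {
        lapply(wlist, `[[`, h)
      })
    }
    proj <- o %*% bp$Wo + matrix(bp$bo, B * L, d, byrow = TRUE)
    dm1 <- NULL
    if (training && config$dropout > 0) {
      dm1 <- matrix((stats::runif(length(proj)) >= config$dropout) /
                      (1 - config$dropout), B * L, d)
      proj <- proj * dm1
    }
    x2 <- x + proj
    ln2 <- layernorm_forward(x2, bp$ln2_g, bp$ln2_b)
    h1pre <- ln2$out %*% bp$W1 + matrix(bp$b1, B * L, 4 * d, byrow = TRUE)
    phi <- stats::pnorm(h1pre)
    h1 <- h1pre * phi
    m <- h1 %*% bp$W2 + matrix(bp$b2, B * L, d, byrow = TRUE)
    dm2 <- NULL
    if (training && config$dropout > 0) {
      dm2 <- matrix((stats::runif(length(m)) >= config$dropout) /
                      (1 - config$dropout), B * L, d)
      m <- m * dm2
    }
    xout <- x2 + m
    if (keep_cache) {
      caches[[li]] <- list(ln1 = ln1, q = q, k = k, v = v, o = o,
                           weights = wlist, dm1 = dm1, x2 = x2, ln2 = ln2,
                           a2 = ln2$out, h1pre = h1pre, phi = phi, h1 = h1,
                           dm2 = dm2)
    }
    x <- xout
  }
  lnf <- layernorm_forward(x, params$lnf_g, params$lnf_b)
  hidden <- lnf$out
  logits <- hidden %*% params$W_out +
    matrix(params$b_out, B * L, config$vocab_size, byrow = TRUE)
  out <- list(logits = logits, hidden = hidden, B = B, L = L)
  if (keep_cache) {
    out$cache <- list(layers = caches, lnf = lnf, ids_flat = ids_flat,
                      slot_rows = slot_rows, n_slots = n_slots,
                      prop_values = prop_values, B = B, L = L)
  }
  if (return_attention) out$attention <- attn_all
  out
}

#' Pool hidden states into the alignment space
#'
#' Mean of the final-layer hidden states over non-PAD positions, followed by
#' one affine (fully connected) map into the graph alignment space.
#'
#' @param hidden (B*L) x d hidden matrix from [minigpt_forward()].
#' @param mask B x L logical, TRUE on non-PAD positions.
#' @param mapper list with `Wm`, `bm`.
#' @return B x d_align matrix of sequence embeddings.
#' @export
map_sequence_embedding <- function(hidden, mask, mapper) {
  B <- nrow(mask)
  L <- ncol(mask)
  stopifnot(nrow(hidden) == B * L)
  if (any(rowSums(mask) == 0)) stop("fully masked sequence in batch")
  pooled <- t(vapply(seq_len(B), function(b) {
    rows <- ((b - 1) * L + 1):(b * L)
    colMeans(hidden[rows, , drop = FALSE][mask[b, ], , drop = FALSE])
  }, numeric(ncol(hidden))))
  pooled %*% mapper$Wm + matrix(mapper$bm, B, length(mapper$bm), byrow = TRUE)
}

# Backward pass. dlogits: (B*L) x V; dz_seq: optional B x d_align gradient on
# the mapper output (NULL when the alignment loss is off); mask needed when
# dz_seq is given. Returns the gradient tree matching the parameter tree.
minigpt_backward <- function(params, config, fwd, dlogits, dz_seq = NULL,
                             mask = NULL) {
  cache <- fwd$cache
  B <- cache$B
  L <- cache$L
  d <- config$d_model
  hidden <- fwd$hidden
  grads <- list(tok_emb = matrix(0, config$vocab_size, d),
                pos_emb = matrix(0, config$max_len, d),
                blocks = vector("list", config$n_layers),
                lnf_g = NULL, lnf_b = NULL,
                W_out = crossprod(hidden, dlogits),
                b_out = colSums(dlogits),
                mapper = list(Wm = matrix(0, d, config$d_align),
                              bm = rep(0, config$d_align)))
  names(grads$blocks) <- names(params$blocks)
  dhidden <- dlogits %*% t(params$W_out)
  if (!is.null(dz_seq)) {
    stopifnot(!is.null(mask))
    pooled <- t(vapply(seq_len(B), function(b) {
      rows <- ((b - 1) * L + 1):(b * L)
      colMeans(hidden[rows, , drop = FALSE][mask[b, ], , drop = FALSE])
    }, numeric(d)))
    grads$mapper$Wm <- crossprod(pooled, dz_seq)
    grads$mapper$bm <- colSums(dz_seq)
    dpooled <- dz_seq %*% t(params$mapper$Wm)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * L + 1):(b * L)
      nm <- sum(mask[b, ])
      dhidden[rows[mask[b, ]], ] <-
        dhidden[rows[mask[b, ]], , drop = FALSE] +
        matrix(dpooled[b, ] / nm, nm, d, byrow = TRUE)
    }
  }
  lb <- layernorm_backward(dhidden, cache$lnf, params$lnf_g)
  grads$lnf_g <- lb$dg
  grads$lnf_b <- lb$db
  dx <- lb$dx
  rows_of <- function(b) ((b - 1) * L + 1):(b * L)
  for (li in rev(seq_len(config$n_layers))) {
    bp <- params$blocks[[li]]
    lc <- cache$layers[[li]]
    # ---- MLP branch
    dm <- dx
    if (!is.null(lc$dm2)) dm <- dm * lc$dm2
    dW2 <- crossprod(lc$h1, dm)
    db2 <- colSums(dm)
    dh1 <- dm %*% t(bp$W2)
    dh1pre <- dh1 * (lc$phi + lc$h1pre * stats::dnorm(lc$h1pre))
    dW1 <- crossprod(lc$a2, dh1pre)
    db1 <- colSums(dh1pre)
    da2 <- dh1pre %*% t(bp$W1)
    ln2b <- layernorm_backward(da2, lc$ln2, bp$ln2_g)
    dx2 <- dx + ln2b$dx
    # ---- attention branch
    dproj <- dx2
    if (!is.null(lc$dm1)) dproj <- dproj * lc$dm1
    dWo <- crossprod(lc$o, dproj)
    dbo <- colSums(dproj)
    do <- dproj %*% t(bp$Wo)
    dq <- matrix(0, B * L, d)
    dk <- matrix(0, B * L, d)
    dv <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- rows_of(b)
      for (h in seq_len(config$n_heads)) {
        cols <- ((h - 1) * config$d_head + 1):(h * config$d_head)
        w <- lc$weights[[b]][[h]]
        dob <- do[rows, cols, drop = FALSE]
        vb <- lc$v[rows, cols, drop = FALSE]
        dw <- tcrossprod(dob, vb) # dob %*% t(vb): L x L
        dv[rows, cols] <- crossprod(w, dob)
        ds <- row_softmax_backward(dw, w)
        ds[upper.tri(ds)] <- 0
        scale <- 1 / sqrt(config$d_head)
        dq[rows, cols] <- (ds %*% lc$k[rows, cols, drop = FALSE]) * scale
        dk[rows, cols] <- (crossprod(ds, lc$q[rows, cols, drop = FALSE])) * scale
      }
    }
    a1 <- lc$ln1$out
    dWq <- crossprod(a1, dq); dbq <- colSums(dq)
    dWk <- crossprod(a1, dk); dbk <- colSums(dk)
    dWv <- crossprod(a1, dv); dbv <- colSums(dv)
    da1 <- dq %*% t(bp$Wq) + dk %*% t(bp$Wk) + dv %*% t(bp$Wv)
    ln1b <- layernorm_backward(da1, lc$ln1, bp$ln1_g)
    dx <- dx2 + ln1b$dx
    grads$blocks[[li]] <- list(
      ln1_g = ln1b$dg, ln1_b = ln1b$db,
      Wq = dWq, bq = dbq, Wk = dWk, bk = dbk, Wv = dWv, bv = dbv,
      Wo = dWo, bo = dbo,
      ln2_g = ln2b$dg, ln2_b = ln2b$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }
  # ---- embeddings
  grads$pos_emb[seq_len(L), ] <-
    rowsum(dx, rep(seq_len(L), B))
  demb <- dx
  if (!is.null(cache$slot_rows)) {
    scales <- PROP_SCALES[rownames(params$prop_w)]
    np <- cache$n_slots
    grads$prop_w <- matrix(0, nrow(params$prop_w), d,
                           dimnames = dimnames(params$prop_w))
    grads$prop_b <- grads$prop_w
    for (s in seq_len(np)) {
      rows <- (seq_len(B) - 1) * L + s
      xs <- cache$prop_values[, s] / scales[[s]]
      grads$prop_w[s, ] <- colSums(demb[rows, , drop = FALSE] * xs)
      grads$prop_b[s, ] <- colSums(demb[rows, , drop = FALSE])
    }
    demb[cache$slot_rows, ] <- 0
  } else if (!is.null(params$prop_w)) {
    grads$prop_w <- params$prop_w * 0
    grads$prop_b <- params$prop_b * 0
  }
  tok_rows <- cache$ids_flat + 1L
  acc <- rowsum(demb, tok_rows)
  grads$tok_emb[as.integer(rownames(acc)), ] <- acc
  grads
}
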