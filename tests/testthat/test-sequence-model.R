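test_that("causal attention matches the brute-force oracle on pinned input", {
  set.seed(21)
  q <- matrix(rnorm(6), 3, 2)
  k <- matrix(rnorm(6), 3, 2)
  v <- matrix(rnorm(6), 3, 2)
  got <- causal_attention(q, k, v)
  want <- oracle_causal_attention(q, k, v)
  expect_equal(got$out, want$out, tolerance = 1e-6)
  expect_equal(got$weights, want$weights, tolerance = 1e-6)
})

test_that("identical keys give uniform attention over visible positions", {
  L <- 5
  k <- matrix(1, L, 3)
  q <- matrix(rnorm(L * 3), L, 3)
  v <- matrix(rnorm(L * 3), L, 3)
  w <- causal_attention(q, k, v)$weights
  for (t in seq_len(L)) {
    expect_equal(w[t, seq_len(t)], rep(1 / t, t), tolerance = 1e-12)
    if (t < L) expect_identical(w[t, (t + 1):L], rep(0, L - t))
  }
})

test_that("attention rows are stochastic and strictly causal in every layer/head", {
  tg <- tiny_gpt(vocab_size = 14, seed = 31)
  set.seed(32)
  ids <- matrix(sample(0:13, 2 * 9, replace = TRUE), 2, 9)
  fwd <- minigpt_forward(tg$params, tg$config, ids, return_attention = TRUE)
  for (layer in fwd$attention) {
    for (head in layer) {
      for (w in head) {
        expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-6)
        expect_true(all(w[upper.tri(w)] == 0))
      }
    }
  }
})

test_that("multi-head attention equals the per-head oracle on a pinned batch", {
  tg <- tiny_gpt(vocab_size = 12, seed = 33)
  cfg <- tg$config
  p <- tg$params
  set.seed(34)
  ids <- matrix(sample(0:11, 8, replace = TRUE), 1, 8)
  fwd <- minigpt_forward(p, cfg, ids, keep_cache = TRUE,
                         return_attention = TRUE)
  lc <- fwd$cache$layers[[1]]
  for (h in seq_len(cfg$n_heads)) {
    cols <- ((h - 1) * cfg$d_head + 1):(h * cfg$d_head)
    want <- oracle_causal_attention(lc$q[, cols, drop = FALSE],
                                    lc$k[, cols, drop = FALSE],
                                    lc$v[, cols, drop = FALSE])
    expect_equal(fwd$attention[[1]][[h]][[1]], want$weights,
                 tolerance = 1e-6)
  }
})

test_that("logits are causal: future perturbations never leak backwards", {
  tg <- tiny_gpt(vocab_size = 20, seed = 35)
  set.seed(36)
  L <- tg$config$max_len
  for (rep_ in 1:50) {
    ids <- matrix(sample(0:19, L, replace = TRUE), 1, L)
    t_cut <- sample(2:(L - 1), 1)
    ids2 <- ids
    future <- (t_cut + 1):L
    pos <- future[sample.int(length(future), 1)]
    ids2[1, pos] <- (ids2[1, pos] + sample(1:19, 1)) %% 20
    l1 <- minigpt_forward(tg$params, tg$config, ids)$logits
    l2 <- minigpt_forward(tg$params, tg$config, ids2)$logits
    expect_equal(l1[seq_len(t_cut), ], l2[seq_len(t_cut), ],
                 tolerance = 1e-12)
  }
})

test_that("forward is shape-correct, deterministic, and validates ids", {
  tg <- tiny_gpt(vocab_size = 9, seed = 37)
  ids <- matrix(c(1L, 2L, 3L, 4L), 1, 4)
  f1 <- minigpt_forward(tg$params, tg$config, ids)
  f2 <- minigpt_forward(tg$params, tg$config, ids)
  expect_identical(f1$logits, f2$logits) # eval mode is bitwise deterministic
  expect_identical(dim(f1$logits), c(4L, 9L))
  expect_error(minigpt_forward(tg$params, tg$config, matrix(9L, 1, 2)),
               "vocabulary")
})

test_that("sequence pooling ignores PAD and maps to the alignment dim", {
  tg <- tiny_gpt(vocab_size = 10, seed = 38)
  cfg <- tg$config
  set.seed(39)
  core <- sample(0:9, 5, replace = TRUE)
  ids_short <- matrix(c(core, 0L, 0L), 1, 7)
  mask5 <- matrix(c(rep(TRUE, 5), FALSE, FALSE), 1, 7)
  f <- minigpt_forward(tg$params, cfg, ids_short)
  z <- map_sequence_embedding(f$hidden, mask5, tg$params$mapper)
  expect_identical(dim(z), c(1L, cfg$d_align))
  # appending more PAD columns must not change the embedding
  ids_long <- cbind(ids_short, matrix(0L, 1, 3))
  mask_long <- cbind(mask5, matrix(FALSE, 1, 3))
  f2 <- minigpt_forward(tg$params, cfg, ids_long)
  z2 <- map_sequence_embedding(f2$hidden, mask_long, tg$params$mapper)
  expect_equal(z, z2, tolerance = 1e-12)
  expect_error(map_sequence_embedding(f$hidden, mask5 & FALSE,
                                      tg$params$mapper), "masked")
})

test_that("model gradients match finite differences", {
  tg <- tiny_gpt(vocab_size = 11, seed = 40, properties = "TPSA")
  cfg <- tg$config
  p <- tg$params
  set.seed(41)
  B <- 2; L <- 8
  ids <- matrix(sample(0:10, B * L, replace = TRUE), B, L)
  ids[, 1] <- 5L
  pv <- matrix(runif(B, 0, 80), B, 1)
  mask <- matrix(TRUE, B, L)
  targets <- as.integer(t(cbind(ids[, -1], 0L)))
  lmask <- as.logical(t(matrix(c(rep(TRUE, L - 1), FALSE), B, L,
                               byrow = TRUE)))
  wz <- matrix(rnorm(B * cfg$d_align), B, cfg$d_align)
  lossfn <- function(p) {
    f <- minigpt_forward(p, cfg, ids, pv, n_slots = 1L)
    generation_loss(f$logits, targets, lmask) +
      sum(wz * map_sequence_embedding(f$hidden, mask, p$mapper))
  }
  fwd <- minigpt_forward(p, cfg, ids, pv, n_slots = 1L, keep_cache = TRUE)
  gr <- minigpt_backward(p, cfg, fwd,
                         ce_backward(fwd$logits, targets, lmask),
                         dz_seq = wz, mask = mask)
  eps <- 1e-5
  paths <- list("tok_emb", "pos_emb", "prop_w", "prop_b", "lnf_g",
                "W_out", c("blocks", "b1", "Wq"), c("blocks", "b2", "W2"),
                c("blocks", "b1", "ln2_b"), c("mapper", "Wm"))
  getleaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  for (path in paths) {
    leaf <- getleaf(p, path)
    gleaf <- getleaf(gr, path)
    i <- sample(length(leaf), 1)
    bump <- function(p, delta) {
      expr <- paste0("p", paste0(sprintf("[[\"%s\"]]", path), collapse = ""),
                     "[i] <- leaf[i] + delta")
      eval(parse(text = expr))
      p
    }
    num <- (lossfn(bump(p, eps)) - lossfn(bump(p, -eps))) / (2 * eps)
    expect_equal(gleaf[i], num, tolerance = 1e-4)
  }
})
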