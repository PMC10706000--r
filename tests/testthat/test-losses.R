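test_that("cross-correlation matches the explicit double-loop evaluation", {
  set.seed(7)
  za <- matrix(rnorm(12), 4, 3)
  zb <- matrix(rnorm(12), 4, 3)
  C <- cross_correlation(za, zb, standardize = FALSE)
  expect_equal(C, oracle_cross_correlation(za, zb), tolerance = 1e-12)
})

test_that("cross-correlation diagonal pins to +/-1 for (anti-)identical views", {
  set.seed(8)
  za <- matrix(rnorm(20), 5, 4)
  expect_equal(diag(cross_correlation(za, za, standardize = FALSE)),
               rep(1, 4), tolerance = 1e-12)
  expect_equal(diag(cross_correlation(za, -za, standardize = FALSE)),
               rep(-1, 4), tolerance = 1e-12)
})

test_that("cross-correlation entries are bounded by Cauchy-Schwarz", {
  set.seed(9)
  for (rep_ in 1:20) {
    b <- sample(2:10, 1)
    d <- sample(2:6, 1)
    za <- matrix(rnorm(b * d), b, d)
    zb <- matrix(rnorm(b * d), b, d)
    for (std in c(TRUE, FALSE)) {
      C <- cross_correlation(za, zb, standardize = std)
      expect_true(all(abs(C) <= 1 + 1e-12))
    }
  }
})

test_that("degenerate embeddings raise an error naming the dimension", {
  za <- matrix(rnorm(8), 4, 2)
  zb <- za
  zb[, 2] <- 0
  expect_error(cross_correlation(za, zb, standardize = FALSE), "2")
  expect_error(cross_correlation(za, cbind(zb[, 1], 5), standardize = TRUE),
               "constant")
})

test_that("Barlow Twins loss has its analytic values", {
  expect_identical(barlow_twins_loss(diag(4), 0.005), 0)
  expect_identical(barlow_twins_loss(matrix(0, 5, 5), 0.005), 5)
  C <- diag(3)
  C[1, 2] <- 1
  expect_equal(barlow_twins_loss(C, 0.005), 0.005, tolerance = 1e-15)
})

test_that("Barlow Twins loss is non-negative, zero only at the identity", {
  set.seed(10)
  for (rep_ in 1:25) {
    d <- sample(2:6, 1)
    C <- matrix(runif(d * d, -1, 1), d, d)
    l <- barlow_twins_loss(C, 0.005)
    expect_gte(l, 0)
    if (l == 0) expect_equal(C, diag(d))
  }
})

test_that("alignment gradients match finite differences in both modes", {
  set.seed(11)
  za <- matrix(rnorm(20), 5, 4)
  zb <- matrix(rnorm(20), 5, 4)
  eps <- 1e-6
  for (std in c(FALSE, TRUE)) {
    g <- barlow_twins_grad(za, zb, lambda = 0.005, standardize = std)
    for (probe in 1:6) {
      i <- sample(5, 1)
      j <- sample(4, 1)
      zp <- za; zp[i, j] <- zp[i, j] + eps
      zm <- za; zm[i, j] <- zm[i, j] - eps
      num <- (barlow_twins_loss(cross_correlation(zp, zb, std), 0.005) -
                barlow_twins_loss(cross_correlation(zm, zb, std), 0.005)) /
        (2 * eps)
      expect_equal(g$dza[i, j], num, tolerance = 1e-5)
    }
  }
})

test_that("generation loss has its analytic values and respects the mask", {
  V <- 7
  n <- 5
  targets <- c(2L, 0L, 6L, 3L, 1L)
  # near-one-hot logits on the target: loss ~ 0
  hot <- matrix(-1e4, n, V)
  hot[cbind(seq_len(n), targets + 1L)] <- 1e4
  expect_equal(generation_loss(hot, targets, rep(TRUE, n)), 0,
               tolerance = 1e-9)
  # uniform logits: ln V per token
  unif <- matrix(0, n, V)
  expect_equal(generation_loss(unif, targets, rep(TRUE, n)), log(V),
               tolerance = 1e-12)
  # masking removes exactly the masked position's contribution
  set.seed(12)
  lg <- matrix(rnorm(n * V), n, V)
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  per_pos <- vapply(seq_len(n), function(i) {
    generation_loss(lg[i, , drop = FALSE], targets[i], TRUE)
  }, numeric(1))
  expect_equal(generation_loss(lg, targets, mask), mean(per_pos[mask]),
               tolerance = 1e-12)
  expect_error(generation_loss(lg, targets, rep(FALSE, n)), "masked")
})

test_that("total loss is the exact unweighted sum of its parts", {
  set.seed(13)
  za <- matrix(rnorm(24), 6, 4)
  zb <- matrix(rnorm(24), 6, 4)
  lg <- matrix(rnorm(5 * 7), 5, 7)
  targets <- sample(0:6, 5, replace = TRUE)
  mask <- rep(TRUE, 5)
  bd <- total_loss(za, zb, lg, targets, mask, lambda = 0.005)
  expect_identical(bd$total, bd$alignment + bd$generation)
  expect_gte(bd$alignment, 0)
  # lambda = 0 with perfectly correlated diagonal: total = generation term
  bd0 <- total_loss(za, za, lg, targets, mask, lambda = 0,
                    standardize = FALSE)
  expect_equal(bd0$alignment, 0, tolerance = 1e-12)
  expect_equal(bd0$total, bd0$generation, tolerance = 1e-12)
  # alignment disabled entirely
  bdn <- total_loss(NULL, NULL, lg, targets, mask)
  expect_identical(bdn$alignment, 0)
})

test_that("combined gradient equals the sum of component gradients", {
  # finite-difference check through a tiny model: d(total)/dw must equal
  # d(alignment)/dw + d(generation)/dw for a shared weight
  tg <- tiny_gpt(vocab_size = 10, seed = 5)
  cfg <- tg$config
  p <- tg$params
  set.seed(6)
  ids <- matrix(sample(0:9, 2 * 8, replace = TRUE), 2, 8)
  targets <- as.integer(t(cbind(ids[, -1], 0L)))
  lmask <- rep(c(rep(TRUE, 7), FALSE), 2)
  mask <- matrix(TRUE, 2, 8)
  zg <- matrix(rnorm(2 * cfg$d_align), 2, cfg$d_align)
  comp <- function(p) {
    f <- minigpt_forward(p, cfg, ids)
    zs <- map_sequence_embedding(f$hidden, mask, p$mapper)
    c(gen = generation_loss(f$logits, targets, lmask),
      bt = barlow_twins_loss(cross_correlation(zg, zs, FALSE), 0.005))
  }
  eps <- 1e-5
  i <- 7
  for (field in c("W_out", "pos_emb")) {
    pp <- p; pp[[field]][i] <- pp[[field]][i] + eps
    pm <- p; pm[[field]][i] <- pm[[field]][i] - eps
    up <- comp(pp); um <- comp(pm)
    d_total <- (sum(up) - sum(um)) / (2 * eps)
    d_parts <- (up - um) / (2 * eps)
    expect_equal(d_total, sum(d_parts), tolerance = 1e-7)
  }
})
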