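# Numeric primitives shared by the graph encoder and the sequence model:
# layer norm, GELU, row softmax, parameter-tree utilities and the AdamW
# optimiser. Everything is plain matrix code with hand-derived backward
# passes; gradients are validated against finite differences in the tests.

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * istd
  list(out = sweep(xhat, 2, g, "*") + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, istd = istd)
}

layernorm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# numerically stable softmax over rows; -Inf entries get exactly 0 (every
# row is assumed to have at least one finite entry)
row_softmax <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}

row_softmax_backward <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter trees ------------------------------------------------------
# Parameters, gradients and optimiser state share one nested-list structure
# whose leaves are numeric vectors/matrices.

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_leaves <- function(tree) {
  if (is.list(tree)) unlist(lapply(tree, tree_leaves), use.names = FALSE)
  else as.numeric(tree)
}

tree_has_nonfinite <- function(tree) any(!is.finite(tree_leaves(tree)))

#' @keywords internal
adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# One AdamW step (decoupled weight decay). Returns updated params and state.
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u - lr * weight_decay * p,
                      params, upd)
  list(params = params, state = state)
}

# rescale a gradient tree so its global L2 norm is at most max_norm
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(list(tree_leaves(grads)),
                           function(v) sum(v^2), numeric(1))))
  if (is.finite(max_norm) && total > max_norm) {
    grads <- tree_map(function(g) g * (max_norm / total), grads)
  }
  grads
}

# linear warm-up then cosine decay to min_frac * lr
lr_schedule <- function(step, total_steps, lr, warmup_frac = 0.05,
                        min_frac = 0.1) {
  warm <- max(1, round(warmup_frac * total_steps))
  if (step <= warm) return(lr * step / warm)
  prog <- (step - warm) / max(1, total_steps - warm)
  lr * (min_frac + (1 - min_frac) * 0.5 * (1 + cos(pi * min(1, prog))))
}

rmat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}
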