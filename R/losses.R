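# The combined training objective L = L_BT + L_ground: a Barlow Twins
# redundancy-reduction term on the cross-correlation between the graph and
# sequence embeddings, plus next-token cross-entropy on the SMILES.

#' Cross-correlation between two embedding batches
#'
#' `C[i, j] = sum_b A[b,i] B[b,j] / (||A[,i]|| ||B[,j]||)`, the norm-scaled
#' batch cross-correlation between the graph-view and sequence-view
#' embeddings. With `standardize = TRUE` (the default, matching the original
#' Barlow Twins recipe) each dimension is first centred and scaled to unit
#' variance across the batch, which makes `C` a true correlation matrix; with
#' `standardize = FALSE` the formula is applied to the raw embeddings.
#' Entries are bounded in \[-1, 1\] either way (Cauchy-Schwarz).
#'
#' @param za,zb batch x d matrices (graph and sequence embeddings).
#' @param standardize per-dimension batch standardization before scaling.
#' @return d x d cross-correlation matrix.
#' @export
cross_correlation <- function(za, zb, standardize = TRUE) {
  stopifnot(is.matrix(za), is.matrix(zb), all(dim(za) == dim(zb)))
  if (standardize) {
    stopifnot(nrow(za) >= 2)
    za <- batch_standardize(za)$z
    zb <- batch_standardize(zb)$z
  }
  na <- sqrt(colSums(za^2))
  nb <- sqrt(colSums(zb^2))
  if (any(na == 0)) {
    stop("zero-norm embedding dimension(s) in the graph view: ",
         paste(which(na == 0), collapse = ", "))
  }
  if (any(nb == 0)) {
    stop("zero-norm embedding dimension(s) in the sequence view: ",
         paste(which(nb == 0), collapse = ", "))
  }
  crossprod(za, zb) / outer(na, nb)
}

batch_standardize <- function(z) {
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu)
  sd_pop <- sqrt(colMeans(zc^2))
  if (any(sd_pop == 0)) {
    stop("degenerate (constant) embedding dimension(s): ",
         paste(which(sd_pop == 0), collapse = ", "))
  }
  list(z = sweep(zc, 2, sd_pop, "/"), sd = sd_pop)
}

#' Barlow Twins redundancy-reduction loss
#'
#' `sum_i (1 - C_ii)^2 + lambda * sum_{i != j} C_ij^2`: drives the
#' cross-correlation matrix toward the identity, aligning the two views while
#' decorrelating embedding dimensions. Zero exactly when `C` is the identity.
#'
#' @param C square cross-correlation matrix.
#' @param lambda off-diagonal weight (default 0.005).
#' @return non-negative scalar.
#' @export
barlow_twins_loss <- function(C, lambda = 0.005) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), lambda >= 0)
  on_diag <- sum((1 - diag(C))^2)
  off <- C
  diag(off) <- 0
  on_diag + lambda * sum(off^2)
}

# Loss + analytic gradients w.r.t. the (raw) embeddings. Returns
# list(loss, C, dza, dzb). Chain: (optional batch standardization) ->
# norm-scaled cross-correlation -> Barlow Twins loss.
barlow_twins_grad <- function(za, zb, lambda = 0.005, standardize = TRUE) {
  a <- za
  b <- zb
  sa <- sb <- NULL
  if (standardize) {
    sa <- batch_standardize(za); a <- sa$z
    sb <- batch_standardize(zb); b <- sb$z
  }
  na <- sqrt(colSums(a^2))
  nb <- sqrt(colSums(b^2))
  if (any(na == 0) || any(nb == 0)) stop("zero-norm embedding dimension")
  C <- crossprod(a, b) / outer(na, nb)
  loss <- barlow_twins_loss(C, lambda)
  G <- 2 * lambda * C
  diag(G) <- -2 * (1 - diag(C))
  H <- G / outer(na, nb)
  da <- b %*% t(H) - sweep(a, 2, rowSums(G * C) / na^2, "*")
  db <- a %*% H - sweep(b, 2, colSums(G * C) / nb^2, "*")
  if (standardize) {
    da <- standardize_backward(da, a, sa$sd)
    db <- standardize_backward(db, b, sb$sd)
  }
  list(loss = loss, C = C, dza = da, dzb = db)
}

# backward through z_std = (z - mean) / sd_pop (per column)
standardize_backward <- function(dzs, zs, sd_pop) {
  m1 <- colMeans(dzs)
  m2 <- colMeans(dzs * zs)
  sweep(dzs - matrix(m1, nrow(dzs), ncol(dzs), byrow = TRUE) -
          sweep(zs, 2, m2, "*"), 2, sd_pop, "/")
}

#' Next-token cross-entropy
#'
#' Mean token-level cross-entropy of the logits against the left-shifted
#' target ids, restricted to unmasked positions (PAD and the condition prefix
#' are excluded from the mask upstream).
#'
#' @param logits n x V matrix.
#' @param targets length-n integer vector of 0-based target ids.
#' @param mask length-n logical; positions contributing to the loss.
#' @return non-negative scalar.
#' @export
generation_loss <- function(logits, targets, mask) {
  stopifnot(nrow(logits) == length(targets), length(mask) == length(targets))
  if (!any(mask)) stop("all positions masked out of the generation loss")
  ce_forward(logits, targets, mask)$loss
}

ce_forward <- function(logits, targets, mask) {
  idx <- which(mask)
  lg <- logits[idx, , drop = FALSE]
  m <- lg[cbind(seq_along(idx), max.col(lg, ties.method = "first"))]
  lse <- m + log(rowSums(exp(lg - m)))
  picked <- lg[cbind(seq_along(idx), targets[idx] + 1L)]
  list(loss = mean(lse - picked), idx = idx, lg = lg, lse = lse)
}

# dlogits for the mean CE over masked positions
ce_backward <- function(logits, targets, mask) {
  idx <- which(mask)
  lg <- logits[idx, , drop = FALSE]
  p <- row_softmax(lg)
  p[cbind(seq_along(idx), targets[idx] + 1L)] <-
    p[cbind(seq_along(idx), targets[idx] + 1L)] - 1
  d <- matrix(0, nrow(logits), ncol(logits))
  d[idx, ] <- p / length(idx)
  d
}

#' Combined loss breakdown
#'
#' `L = L_BT + L_ground`, summed unweighted. The alignment term is computed
#' from the paired graph and sequence embeddings; the generation term from the
#' next-token logits.
#'
#' @param z_graph,z_seq batch x d embedding matrices (graph view, sequence
#'   view); pass `NULL` for both to disable the alignment term (then
#'   `alignment = 0`).
#' @param logits,targets,mask as in [generation_loss()].
#' @param lambda Barlow Twins off-diagonal weight.
#' @param standardize see [cross_correlation()].
#' @return a `loss_breakdown`: list with `total`, `alignment`, `generation`,
#'   satisfying `total == alignment + generation` exactly.
#' @export
total_loss <- function(z_graph = NULL, z_seq = NULL, logits, targets, mask,
                       lambda = 0.005, standardize = TRUE) {
  l_gen <- generation_loss(logits, targets, mask)
  l_bt <- if (is.null(z_graph)) 0 else {
    barlow_twins_loss(cross_correlation(z_graph, z_seq, standardize), lambda)
  }
  structure(list(total = l_bt + l_gen, alignment = l_bt, generation = l_gen),
            class = "loss_breakdown")
}
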