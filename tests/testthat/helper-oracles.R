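# Independent brute-force oracles used to validate the vectorized
# implementations on pinned small inputs.

# dense graph-attention coefficients: explicit N x N masked softmax of
# e_ij = LeakyReLU(a^T [W h_i || W h_j]) over each neighbourhood (self-loops
# included)
oracle_gat_attention <- function(graph, hp, slope) {
  n <- graph$num_nodes
  h <- graph$node_features %*% hp$W
  adj <- diag(n) > 0
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      adj[graph$edges[r, 1], graph$edges[r, 2]] <- TRUE
      adj[graph$edges[r, 2], graph$edges[r, 1]] <- TRUE
    }
  }
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- rep(-Inf, n)
    for (j in which(adj[i, ])) {
      z <- sum(hp$a1 * h[i, ]) + sum(hp$a2 * h[j, ])
      e[j] <- if (z > 0) z else slope * z
    }
    ex <- exp(e - max(e))
    ex[is.na(ex)] <- 0
    a[i, ] <- ex / sum(ex)
  }
  a
}

# direct evaluation of softmax(Q K^T / sqrt(d_k)) V with an explicit loop
oracle_causal_attention <- function(q, k, v) {
  L <- nrow(q)
  dk <- ncol(k)
  out <- matrix(0, L, ncol(v))
  w <- matrix(0, L, L)
  for (t in seq_len(L)) {
    s <- sapply(seq_len(t), function(j) sum(q[t, ] * k[j, ]) / sqrt(dk))
    e <- exp(s - max(s))
    w[t, seq_len(t)] <- e / sum(e)
    out[t, ] <- colSums(w[t, seq_len(t), drop = TRUE] *
                          v[seq_len(t), , drop = FALSE])
  }
  list(out = out, weights = w)
}

# two-loop evaluation of the batch cross-correlation
oracle_cross_correlation <- function(za, zb) {
  d <- ncol(za)
  C <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      C[i, j] <- sum(za[, i] * zb[, j]) /
        (sqrt(sum(za[, i]^2)) * sqrt(sum(zb[, j]^2)))
    }
  }
  C
}

# explicit double-loop IntDiv over all ordered pairs including self-pairs
oracle_intdiv <- function(fp, p) {
  n <- nrow(fp)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- sum(fp[i, ] & fp[j, ])
      uni <- sum(fp[i, ] | fp[j, ])
      t <- if (uni == 0) 0 else inter / uni
      tot <- tot + t^p
    }
  }
  1 - tot / n^2
}

# Frechet distance through an eigendecomposition of the (non-symmetric)
# covariance product
oracle_frechet <- function(g, d) {
  prod <- g$cov %*% d$cov
  ev <- eigen(prod)
  vals <- Re(ev$values)
  vals[vals < 0] <- 0
  sum((g$mean - d$mean)^2) + sum(diag(g$cov)) + sum(diag(d$cov)) -
    2 * sum(sqrt(vals))
}

# random small molecular-graph stand-in (a path graph with random one-hot
# features) for structural property tests that need no chemistry
random_path_graph <- function(n, f = atom_feature_dim()) {
  blocks <- c(11, 6, 5, 6)
  feat <- matrix(0, n, f)
  off <- 0
  for (w in blocks) {
    feat[cbind(seq_len(n), off + sample.int(w, n, replace = TRUE))] <- 1
    off <- off + w
  }
  edges <- if (n > 1) cbind(seq_len(n - 1), 2:n) else
    matrix(integer(0), ncol = 2)
  structure(list(node_features = feat, edges = edges, num_nodes = n),
            class = "molecular_graph")
}

permute_graph <- function(graph, perm) {
  inv <- order(perm)
  edges <- graph$edges
  if (nrow(edges) > 0) {
    edges <- matrix(inv[edges], ncol = 2)
  }
  structure(list(node_features = graph$node_features[perm, , drop = FALSE],
                 edges = edges, num_nodes = graph$num_nodes),
            class = "molecular_graph")
}
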