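# Two-layer multi-head graph-attention encoder of the molecular graph.
# Per layer and head: e_ij = LeakyReLU(a^T [W h_i || W h_j]) over the
# neighbourhood of i (self-loop included), attention a_ij = softmax_j(e_ij),
# node update sigmoid(sum_j a_ij W h_j); head outputs are concatenated and
# dropout applied in training. After the second layer a ReLU and a global
# max pool over nodes produce the fixed-length graph embedding that the
# alignment loss compares against the sequence embedding. The encoder runs
# during training only; sampling never constructs a graph.

#' Graph encoder configuration
#'
#' @param input_dim width of the atom one-hot features.
#' @param heads attention heads in the first layer (the second layer uses a
#'   single head projecting to `out_dim`).
#' @param head_dim per-head width of the first layer.
#' @param out_dim embedding dimension; must equal the sequence mapper's
#'   alignment dimension.
#' @param dropout dropout rate applied to each layer's output in training.
#' @param slope negative slope of the LeakyReLU in the attention logits.
#' @return a `gat_config` list (the layer count is fixed at two).
#' @export
gat_config <- function(input_dim = atom_feature_dim(), heads = 4L,
                       head_dim = 8L, out_dim = 32L, dropout = 0.1,
                       slope = 0.2) {
  stopifnot(heads >= 1, head_dim >= 1, out_dim >= 1,
            dropout >= 0, dropout < 1)
  structure(list(num_layers = 2L, input_dim = as.integer(input_dim),
                 heads = as.integer(heads), head_dim = as.integer(head_dim),
                 out_dim = as.integer(out_dim), dropout = dropout,
                 slope = slope),
            class = "gat_config")
}

#' Initialise graph-encoder parameters
#' @param config a [gat_config()]. Uses the current RNG state.
#' @return nested parameter list.
#' @export
gat_init <- function(config) {
  head_params <- function(fin, fout) {
    list(W = rmat(fin, fout), a1 = stats::rnorm(fout, sd = 0.02),
         a2 = stats::rnorm(fout, sd = 0.02))
  }
  l1 <- lapply(seq_len(config$heads), function(h) {
    head_params(config$input_dim, config$head_dim)
  })
  names(l1) <- paste0("h", seq_len(config$heads))
  list(l1 = l1,
       l2 = list(h1 = head_params(config$heads * config$head_dim,
                                  config$out_dim)))
}

# dense symmetric adjacency with self-loops; molecular graphs are small
# (tens of atoms), so dense N x N attention is both simpler and faster than
# edge-list scatter operations
graph_edge_arrays <- function(graph) {
  e <- graph$edges
  n <- graph$num_nodes
  adj <- diag(n) > 0
  if (nrow(e) > 0) {
    adj[e] <- TRUE
    adj[e[, c(2, 1), drop = FALSE]] <- TRUE
  }
  list(adj = adj, n = n)
}

#' Single graph-attention layer (one head)
#'
#' Computes attention logits with LeakyReLU, normalises them with a softmax
#' over each node's neighbourhood (self-loop included), aggregates neighbour
#' features, and applies the sigmoid activation.
#'
#' @param x N x F_in node features.
#' @param arr edge arrays from `graph_edge_arrays`.
#' @param hp head parameters (`W`, `a1`, `a2` with the attention vector
#'   `a = [a1; a2]` split over the two concatenated halves).
#' @param slope LeakyReLU negative slope.
#' @return list with `out` (N x F_out) and a cache for the backward pass;
#'   `cache$alpha` holds the per-edge attention coefficients.
#' @keywords internal
gat_head_forward <- function(x, arr, hp, slope) {
  h <- x %*% hp$W
  s1 <- drop(h %*% hp$a1)
  s2 <- drop(h %*% hp$a2)
  epre <- outer(s1, s2, "+") # e_ij before activation, dense
  e <- leaky_relu(epre, slope)
  e[!arr$adj] <- -Inf
  alpha <- row_softmax(e) # exact zeros off-neighbourhood
  m <- alpha %*% h
  out <- sigmoid(m)
  list(out = out,
       cache = list(x = x, h = h, epre = epre, alpha = alpha, out = out))
}

gat_head_backward <- function(dout, arr, hp, cache, slope) {
  m_grad <- dout * cache$out * (1 - cache$out)
  h <- cache$h
  alpha <- cache$alpha
  dh <- crossprod(alpha, m_grad)
  dalpha <- tcrossprod(m_grad, h)
  de <- row_softmax_backward(dalpha, alpha)
  dz <- de * ifelse(cache$epre > 0, 1, slope)
  dz[!arr$adj] <- 0
  ds1 <- rowSums(dz)
  ds2 <- colSums(dz)
  dh <- dh + outer(ds1, hp$a1) + outer(ds2, hp$a2)
  list(dW = crossprod(cache$x, dh),
       da1 = drop(crossprod(h, ds1)),
       da2 = drop(crossprod(h, ds2)),
       dx = dh %*% t(hp$W))
}

#' Encode a molecular graph into a fixed-length embedding
#'
#' @param graph a [mol_to_graph()] graph.
#' @param params from [gat_init()].
#' @param config the matching [gat_config()].
#' @param training if `TRUE`, dropout is active (uses the current RNG).
#' @param keep_cache keep intermediate values for the backward pass.
#' @return list with `z` (length `out_dim`, non-negative) and `cache`.
#' @export
encode_graph <- function(graph, params, config, training = FALSE,
                         keep_cache = FALSE) {
  arr <- graph_edge_arrays(graph)
  x <- graph$node_features
  caches <- list()
  layers <- list(params$l1, params$l2)
  for (li in 1:2) {
    hp_list <- layers[[li]]
    heads <- lapply(hp_list, function(hp) {
      gat_head_forward(x, arr, hp, config$slope)
    })
    out <- do.call(cbind, lapply(heads, `[[`, "out"))
    drop_mask <- NULL
    if (training && config$dropout > 0) {
      drop_mask <- matrix(
        (stats::runif(length(out)) >= config$dropout) / (1 - config$dropout),
        nrow(out), ncol(out))
      out <- out * drop_mask
    }
    caches[[li]] <- list(heads = lapply(heads, `[[`, "cache"),
                         drop_mask = drop_mask, x_in = x)
    x <- out
  }
  act <- pmax(x, 0) # ReLU (identity after sigmoid, kept for fidelity)
  pool_idx <- apply(act, 2, which.max)
  z <- act[cbind(pool_idx, seq_len(ncol(act)))]
  cache <- if (keep_cache) {
    list(arr = arr, layers = caches, act = act, pool_idx = pool_idx)
  }
  list(z = z, cache = cache)
}

# gradient of a scalar loss w.r.t. graph-encoder parameters given dL/dz
encode_graph_backward <- function(dz, cache, params, config) {
  arr <- cache$arr
  n <- arr$n
  dact <- matrix(0, n, length(dz))
  dact[cbind(cache$pool_idx, seq_along(dz))] <- dz
  dact[cache$act <= 0] <- 0
  dx <- dact
  grads <- list(l1 = NULL, l2 = NULL)
  layers <- list(params$l1, params$l2)
  for (li in 2:1) {
    lc <- cache$layers[[li]]
    if (!is.null(lc$drop_mask)) dx <- dx * lc$drop_mask
    hp_list <- layers[[li]]
    widths <- vapply(lapply(lc$heads, `[[`, "out"), ncol, integer(1))
    offsets <- cumsum(c(0, widths))
    dxin <- matrix(0, n, ncol(lc$x_in))
    hgrads <- vector("list", length(hp_list))
    for (h in seq_along(hp_list)) {
      cols <- (offsets[h] + 1):offsets[h + 1]
      hb <- gat_head_backward(dx[, cols, drop = FALSE], arr, hp_list[[h]],
                              lc$heads[[h]], config$slope)
      hgrads[[h]] <- list(W = hb$dW, a1 = hb$da1, a2 = hb$da2)
      dxin <- dxin + hb$dx
    }
    names(hgrads) <- names(hp_list)
    grads[[li]] <- hgrads
    dx <- dxin
  }
  grads
}

#' Graph-attention coefficients of a layer
#'
#' Exposes the per-edge attention weights (after the neighbourhood softmax) of
#' one head on one graph, mainly for inspection and testing. Self-loops are
#' included in each neighbourhood.
#'
#' @param graph a [mol_to_graph()] graph.
#' @param hp head parameters (`W`, `a1`, `a2`).
#' @param slope LeakyReLU negative slope.
#' @return an N x N dense matrix `A` with `A[i, j]` the attention of node `i`
#'   on neighbour `j` (zero off-neighbourhood); rows sum to 1.
#' @export
gat_attention_matrix <- function(graph, hp, slope = 0.2) {
  arr <- graph_edge_arrays(graph)
  fw <- gat_head_forward(graph$node_features, arr, hp, slope)
  fw$cache$alpha
}
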