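#' Initialize GIN encoder parameters
#'
#' The atom-level encoder is a K-layer graph isomorphism network. Each
#' layer updates a node by `MLP((1 + eps) * h_v + sum of neighbour h_u)`
#' where the MLP is Linear-ReLU-Linear (optionally followed by row-wise
#' layer normalization), and `eps` is a learnable scalar
#' initialized at 0. The readout pools node embeddings of every layer `k =
#' 0..K`, concatenates the pooled vectors and projects them linearly to
#' `hidden_dim`.
#'
#' @param atom_dim width of the atom feature vectors.
#' @param hidden_dim embedding width (default 128).
#' @param K number of message-passing layers (default 3).
#' @param readout_mode `"sum"` (default) or `"mean"` node pooling.
#' @param use_layernorm row-normalize each layer's MLP output.
#' @param seed seed for the weight initialization.
#' @return A `gin_params` list.
#' @export
gin_params <- function(atom_dim, hidden_dim = 128L, K = 3L,
                       readout_mode = c("sum", "mean"),
                       use_layernorm = FALSE, seed = 1L) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(K >= 1L, hidden_dim >= 1L)
  with_seed(seed, {
    layers <- vector("list", K)
    d_in <- atom_dim
    for (k in seq_len(K)) {
      layers[[k]] <- list(
        eps = 0,
        W1 = glorot(d_in, hidden_dim), b1 = numeric(hidden_dim),
        W2 = glorot(hidden_dim, hidden_dim), b2 = numeric(hidden_dim),
        use_layernorm = use_layernorm)
      d_in <- hidden_dim
    }
    cat_dim <- atom_dim + K * hidden_dim
    structure(list(K = K, hidden_dim = hidden_dim, atom_dim = atom_dim,
                   readout_mode = readout_mode, layers = layers,
                   W_out = glorot(cat_dim, hidden_dim),
                   b_out = numeric(hidden_dim)),
              class = "gin_params")
  })
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

adjacency_01 <- function(graph) {
  A <- matrix(0, graph$n_v, graph$n_v)
  if (graph$n_e > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

mlp_forward <- function(X, layer) {
  if (is.null(layer$W1)) return(X)  # identity MLP (used by contract tests)
  Z <- sweep(X %*% layer$W1, 2, layer$b1, `+`)
  Z <- pmax(Z, 0)
  Z <- sweep(Z %*% layer$W2, 2, layer$b2, `+`)
  if (isTRUE(layer$use_layernorm)) Z <- layernorm_rows(Z)
  Z
}

layernorm_rows <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  xc / sqrt(rowMeans(xc^2) + eps)
}

#' One GIN message-passing layer
#'
#' Computes, for every node `v`, `MLP((1 + eps) * h_v + sum of h_u over
#' neighbours u)`. Nodes without neighbours aggregate only their own scaled
#' embedding. A layer without MLP weights (`W1 = NULL`) applies the
#' identity map after aggregation.
#'
#' @param graph a `mol_graph`.
#' @param h_prev matrix of per-node embeddings (`n_v` rows).
#' @param layer one element of `gin_params$layers` (fields `eps`, `W1`,
#'   `b1`, `W2`, `b2`, `use_layernorm`).
#' @return Matrix of updated per-node embeddings.
#' @export
gin_layer <- function(graph, h_prev, layer) {
  h_prev <- as.matrix(h_prev)
  if (nrow(h_prev) != graph$n_v) {
    stop_input("h_prev must have one row per node")
  }
  agg <- adjacency_01(graph) %*% h_prev
  mlp_forward((1 + layer$eps) * h_prev + agg, layer)
}

#' Graph-level readout
#'
#' Pools per-node embeddings of every GIN layer (including the raw atom
#' features as layer 0) into one vector per layer, concatenates them, and
#' optionally applies a linear projection. Permutation-invariant over node
#' order.
#'
#' @param per_layer list of per-node embedding matrices, one per layer `k =
#'   0..K` (equal row counts).
#' @param mode `"sum"` or `"mean"`.
#' @param W_out,b_out optional linear projection applied to the
#'   concatenated pooled vector.
#' @return The molecular embedding vector `h_g`.
#' @export
readout <- function(per_layer, mode = c("sum", "mean"), W_out = NULL,
                    b_out = NULL) {
  mode <- match.arg(mode)
  if (!length(per_layer)) stop_input("empty embedding list")
  nv <- vapply(per_layer, nrow, 0L)
  if (any(nv != nv[1]) || nv[1] < 1L) {
    stop_input("all layers must cover the same non-empty node set")
  }
  pooled <- lapply(per_layer, function(H) {
    if (mode == "sum") colSums(H) else colMeans(H)
  })
  hg <- unlist(pooled, use.names = FALSE)
  if (!is.null(W_out)) hg <- as.numeric(hg %*% W_out + b_out)
  hg
}

#' Encode molecules into an embedding matrix
#'
#' Runs the K-layer GIN plus readout over each molecular graph; row `i` of
#' the result is the initial molecular embedding of molecule `i`.
#' Deterministic given fixed parameters, and independent of how the list is
#' partitioned into batches.
#'
#' @param graphs list of `mol_graph` objects.
#' @param params a [gin_params()].
#' @param batch_size optional chunk size (results do not depend on it).
#' @return Numeric matrix, one row per molecule (`EmbeddingMatrix`).
#' @export
encode_molecules <- function(graphs, params, batch_size = NULL) {
  encode_one <- function(g) {
    per_layer <- vector("list", params$K + 1L)
    h <- g$node_features
    per_layer[[1]] <- h
    for (k in seq_len(params$K)) {
      h <- gin_layer(g, h, params$layers[[k]])
      per_layer[[k + 1L]] <- h
    }
    readout(per_layer, params$readout_mode, params$W_out, params$b_out)
  }
  idx <- seq_along(graphs)
  chunks <- if (is.null(batch_size)) list(idx) else
    split(idx, ceiling(idx / batch_size))
  rows <- vector("list", length(graphs))
  for (ch in chunks) for (i in ch) rows[[i]] <- encode_one(graphs[[i]])
  out <- do.call(rbind, rows)
  if (any(!is.finite(out))) stop_input("non-finite molecular embedding")
  out
}
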