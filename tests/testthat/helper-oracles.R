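## Independent straight-line oracles: deliberately naive loop
## implementations, kept free of the package's own vectorized code paths.

oracle_tanimoto <- function(bits_a, bits_b) {
  A <- which(bits_a); B <- which(bits_b)
  u <- union(A, B)
  if (!length(u)) return(0)
  length(intersect(A, B)) / length(u)
}

oracle_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

oracle_weighted_cosine <- function(H, W_persp) {
  n <- nrow(H); m <- nrow(W_persp)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (p in seq_len(m)) {
      acc <- acc + oracle_cosine(W_persp[p, ] * H[i, ],
                                 W_persp[p, ] * H[j, ])
    }
    S[i, j] <- acc / m
  }
  S
}

## Eq.-style per-node GIN aggregation with identity MLP
oracle_gin_aggregate <- function(graph, h_prev, eps) {
  out <- matrix(0, graph$n_v, ncol(h_prev))
  for (v in seq_len(graph$n_v)) {
    acc <- (1 + eps) * h_prev[v, ]
    if (graph$n_e > 0) {
      for (e in seq_len(graph$n_e)) {
        i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
        if (i == v) acc <- acc + h_prev[j, ]
        if (j == v) acc <- acc + h_prev[i, ]
      }
    }
    out[v, ] <- acc
  }
  out
}

## Straight-line trace of T refinement rounds (identity propagation
## weights supported through explicit matrix products).
oracle_gsl_trace <- function(X, A0, w, lambda, eta, eps_sp, T_rounds,
                             W_list, normalize = FALSE) {
  learn_A <- function(H) {
    n <- nrow(H); A <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- oracle_cosine(w * H[i, ], w * H[j, ])
      A[i, j] <- if (i != j && s >= eps_sp) s else 0
    }
    A
  }
  H <- X; A1 <- NULL
  rounds <- list()
  for (t in seq_len(T_rounds)) {
    At <- learn_A(H)
    if (t == 1) A1 <- At
    Af <- lambda * A0 + (1 - lambda) * (eta * At + (1 - eta) * A1)
    P <- if (normalize) {
      B <- Af + diag(nrow(Af))
      d <- rowSums(B)
      B / sqrt(outer(d, d))
    } else Af
    H <- X
    for (W in W_list) H <- pmax(P %*% H %*% W, 0)
    rounds[[t]] <- list(At = At, fused = Af, H = H)
  }
  rounds
}

## Mann-Whitney pair-counting AUC
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (i in pos) for (j in neg) {
    wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  wins / (length(pos) * length(neg))
}

## random small attributed graph in the package's mol_graph layout
random_mol_graph <- function(n_v, p_edge = 0.5, dim = 3) {
  edges <- matrix(integer(0), ncol = 2)
  if (n_v >= 2) {
    cand <- t(utils::combn(n_v, 2))
    keep <- stats::runif(nrow(cand)) < p_edge
    edges <- cand[keep, , drop = FALSE]
  }
  structure(list(node_features = matrix(stats::rnorm(n_v * dim), n_v, dim),
                 edges = edges, bond_orders = rep(1, nrow(edges)),
                 elements = rep("C", n_v), charges = rep(0L, n_v),
                 aromatic = rep(FALSE, n_v), n_v = n_v,
                 n_e = nrow(edges), smiles = NA_character_),
            class = "mol_graph")
}
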