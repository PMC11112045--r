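#' Multi-perspective weighted cosine similarity
#'
#' The metric function of the structure learner: each perspective `p` has a
#' learnable weight vector `w_p`; the similarity of molecules `i` and `j`
#' is the mean over perspectives of `cos(w_p * v_i, w_p * v_j)`
#' (elementwise products). All-zero rows get similarity 0 (with a
#' warning).
#'
#' @param H embedding matrix (one row per molecule).
#' @param W_persp `m x ncol(H)` matrix of perspective weight vectors (one
#'   row per perspective).
#' @return Dense symmetric similarity matrix with entries in `[-1, 1]`.
#' @export
weighted_cosine <- function(H, W_persp) {
  H <- as.matrix(H)
  W_persp <- matrix(W_persp, ncol = ncol(H))
  m <- nrow(W_persp)
  S <- matrix(0, nrow(H), nrow(H))
  any_zero <- FALSE
  for (p in seq_len(m)) {
    M <- sweep(H, 2, W_persp[p, ], `*`)
    r <- sqrt(rowSums(M^2))
    any_zero <- any_zero || any(r == 0)
    N <- M / ifelse(r > 0, r, 1)
    S <- S + tcrossprod(N)
  }
  if (any_zero) warning("all-zero rows have similarity 0 to everything")
  S / m
}

#' Epsilon-neighbourhood sparsification
#'
#' Zeroes every entry below `epsilon_sparsify` (negative entries always
#' drop out) and the diagonal, yielding the sparse non-negative learned
#' adjacency `A(t)`.
#'
#' @param S dense similarity matrix.
#' @param epsilon_sparsify non-negative threshold.
#' @return Matrix of the same shape with small entries and diagonal set
#'   to 0.
#' @export
sparsify <- function(S, epsilon_sparsify = 0.1) {
  if (epsilon_sparsify < 0) stop_input("epsilon_sparsify must be >= 0")
  A <- S
  A[A < epsilon_sparsify] <- 0
  diag(A) <- 0
  A
}

#' Fuse learned and initial adjacencies
#'
#' `fused = lambda * A0 + (1 - lambda) * (eta * At + (1 - eta) * A1)`,
#' where `A0` is the fingerprint similarity graph, `At` the adjacency
#' learned in the current round, and `A1` the adjacency learned from the
#' initial embeddings in round 1 (kept to preserve the initial node
#' information). A convex combination for `lambda`, `eta` in `[0, 1]`, so
#' entries stay in `[0, 1]`.
#'
#' @param A0,A1,At matrices of one shape.
#' @param lambda,eta mixing weights in `[0, 1]`.
#' @return The fused adjacency matrix.
#' @export
fuse_adjacency <- function(A0, A1, At, lambda = 0.8, eta = 0.5) {
  check_fraction(lambda, "lambda"); check_fraction(eta, "eta")
  A0 <- as.matrix(A0)
  if (!identical(dim(A0), dim(as.matrix(A1))) ||
      !identical(dim(A0), dim(as.matrix(At)))) {
    stop_input("A0, A1, At must share one shape")
  }
  lambda * A0 + (1 - lambda) * (eta * as.matrix(At) +
                                  (1 - eta) * as.matrix(A1))
}

## Unit self-loops plus symmetric degree normalization.
sym_normalize <- function(A) {
  B <- as.matrix(A) + diag(nrow(A))
  s <- 1 / sqrt(rowSums(B))
  B * outer(s, s)
}

#' Inter-molecule GNN propagation
#'
#' Applies `L` rounds of `H <- ReLU(Adj %*% H %*% W_l)` starting from
#' `H = X_r`. With `normalize = TRUE` (default) the adjacency is first
#' augmented with unit self-loops and symmetrically degree-normalized,
#' which keeps repeated propagation numerically stable; `normalize =
#' FALSE` multiplies by the raw fused adjacency (the literal update rule).
#'
#' @param X_r embedding matrix (`H_r(t, 0)`).
#' @param A_fused fused adjacency.
#' @param W_list list of `L >= 1` layer weight matrices.
#' @param normalize self-loop + symmetric degree normalization switch.
#' @return The propagated embedding matrix `H_r(t)`.
#' @export
propagate <- function(X_r, A_fused, W_list, normalize = TRUE) {
  if (!length(W_list)) stop_input("at least one propagation layer required")
  Ah <- if (normalize) sym_normalize(A_fused) else as.matrix(A_fused)
  H <- as.matrix(X_r)
  for (W in W_list) H <- pmax(Ah %*% H %*% W, 0)
  H
}

#' Iterative graph structure learning on the MSG
#'
#' Runs `T` refinement rounds. Round `t` learns `A(t) =
#' sparsify(weighted_cosine(H(t-1)))` with `H(0) = X_r`, caches `A(1)` at
#' the first round, fuses `A(0)`, `A(t)` and `A(1)` via
#' [fuse_adjacency()], and re-propagates from `X_r` through the
#' inter-molecule GNN. Embeddings and adjacency are thus refined
#' alternately.
#'
#' @param X_r initial embedding matrix.
#' @param A0 initial fingerprint adjacency (matrix or `similarity_graph`).
#' @param W_persp perspective weight matrix (see [weighted_cosine()]).
#' @param epsilon_sparsify sparsification threshold.
#' @param lambda,eta fusion weights.
#' @param W_list inter-molecule GNN layer weights.
#' @param T_rounds number of refinement rounds (`T >= 1`).
#' @param normalize propagation normalization switch.
#' @return List with final embeddings `H`, fused adjacency `A_fused`,
#'   cached `A1`, and per-round `trace` of edge counts.
#' @export
gsl_iterate <- function(X_r, A0, W_persp, epsilon_sparsify = 0.1,
                        lambda = 0.8, eta = 0.5, W_list, T_rounds = 2L,
                        normalize = TRUE) {
  if (T_rounds < 1L) stop_input("T_rounds must be >= 1")
  if (inherits(A0, "similarity_graph")) A0 <- as.matrix(A0$adjacency)
  H <- as.matrix(X_r)
  A1 <- NULL
  trace <- vector("list", T_rounds)
  for (t in seq_len(T_rounds)) {
    At <- sparsify(weighted_cosine(H, W_persp), epsilon_sparsify)
    if (t == 1L) A1 <- At
    A_fused <- fuse_adjacency(A0, A1, At, lambda, eta)
    H <- propagate(X_r, A_fused, W_list, normalize)
    if (any(!is.finite(H))) {
      stop_input("non-finite embeddings at refinement round ", t)
    }
    trace[[t]] <- list(t = t, learned_edges = sum(At > 0) / 2,
                       fused_edges = sum(A_fused > 0) / 2)
  }
  list(H = H, A_fused = A_fused, A1 = A1, trace = trace)
}
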