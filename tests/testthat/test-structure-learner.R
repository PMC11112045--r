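test_that("weighted cosine identities hold", {
  H <- rbind(c(1, 0), c(1, 0), c(0, 1))
  S <- weighted_cosine(H, matrix(1, 1, 2))
  expect_equal(S[1, 2], 1)   # identical vectors
  expect_equal(S[1, 3], 0)   # orthogonal vectors
  expect_equal(diag(S), rep(1, 3))
  expect_true(isSymmetric(S))
})

test_that("multi-perspective similarity is the mean over perspectives", {
  H <- rbind(c(1, 2), c(2, 1))
  W <- rbind(c(1, 0.5), c(0.2, 2))
  S <- weighted_cosine(H, W)
  s1 <- oracle_cosine(W[1, ] * H[1, ], W[1, ] * H[2, ])
  s2 <- oracle_cosine(W[2, ] * H[1, ], W[2, ] * H[2, ])
  expect_equal(S[1, 2], (s1 + s2) / 2, tolerance = 1e-12)
})

test_that("weighted cosine with unit weight reduces to plain cosine", {
  set.seed(41)
  for (k in seq_len(20)) {
    n <- sample(2:20, 1); d <- sample(2:8, 1)
    H <- matrix(rnorm(n * d), n, d)
    S <- weighted_cosine(H, matrix(1, 1, d))
    expect_lt(max(abs(S - oracle_weighted_cosine(H, matrix(1, 1, d)))),
              1e-6)
  }
})

test_that("all-zero rows get similarity 0 with a warning", {
  H <- rbind(c(1, 1), c(0, 0))
  expect_warning(S <- weighted_cosine(H, matrix(1, 1, 2)), "all-zero")
  expect_equal(S[1, 2], 0)
  expect_equal(S[2, 2], 0)
})

test_that("sparsification thresholds, zeroes the diagonal, keeps symmetry", {
  S <- rbind(c(1.0, 0.9, 0.1), c(0.9, 1.0, -0.4), c(0.1, -0.4, 1.0))
  A <- sparsify(S, 0.2)
  expect_equal(A[1, 2], 0.9)
  expect_equal(A[1, 3], 0)
  expect_equal(A[2, 3], 0)
  expect_equal(diag(A), rep(0, 3))
  expect_true(isSymmetric(A))
  ## threshold 0 removes negatives only
  A0 <- sparsify(S, 0)
  expect_equal(A0[1, 3], 0.1)
  expect_equal(A0[2, 3], 0)
  ## threshold above the cosine maximum empties the matrix
  expect_true(all(sparsify(S, 1.1) == 0))
  expect_error(sparsify(S, -0.1), ">= 0")
})

test_that("sparsify edge sets are nested in the threshold", {
  set.seed(43)
  S <- weighted_cosine(matrix(rnorm(60), 10, 6), matrix(1, 1, 6))
  prev <- NULL
  for (eps in c(0, 0.2, 0.5, 0.8)) {
    A <- sparsify(S, eps) > 0
    if (!is.null(prev)) expect_true(all(prev | !A))
    prev <- A
  }
})

test_that("adjacency fusion follows the stated algebra", {
  A0 <- matrix(1); A1 <- matrix(0.3); At <- matrix(0.5)
  expect_equal(fuse_adjacency(A0, A1, At, lambda = 1, eta = 0.5),
               matrix(1))
  expect_equal(fuse_adjacency(A0, A1, At, lambda = 0, eta = 1),
               matrix(0.5))
  ## hand evaluation: 0.8*1 + 0.2*(0.5*0.5 + 0.5*0.3) = 0.88
  expect_equal(fuse_adjacency(A0, A1, At, lambda = 0.8, eta = 0.5),
               matrix(0.88))
  expect_error(fuse_adjacency(matrix(1), matrix(1, 2, 2), matrix(1)),
               "shape")
  expect_error(fuse_adjacency(A0, A1, At, lambda = 1.2), "\\[0, 1\\]")
})

test_that("propagation matches hand matrix products", {
  X <- rbind(c(1, 2), c(3, 4))
  ## identity adjacency, identity weights: elementwise ReLU of X
  expect_equal(propagate(X, diag(2), list(diag(2)), normalize = FALSE),
               pmax(X, 0))
  ## all-zero adjacency annihilates
  expect_equal(propagate(X, matrix(0, 2, 2), list(diag(2)),
                         normalize = FALSE), matrix(0, 2, 2))
  ## swap graph exchanges (non-negative) rows
  swap <- rbind(c(0, 1), c(1, 0))
  expect_equal(propagate(X, swap, list(diag(2)), normalize = FALSE),
               X[2:1, ])
  expect_error(propagate(X, swap, list()), "at least one")
})

test_that("normalized propagation uses self-loops and degree scaling", {
  A <- rbind(c(0, 1), c(1, 0))
  X <- rbind(c(2, 0), c(0, 2))
  ## B = A + I has all degrees 2 -> Ahat = B/2
  out <- propagate(X, A, list(diag(2)), normalize = TRUE)
  expect_equal(out, pmax((A + diag(2)) %*% X / 2, 0))
})

test_that("the refinement loop matches the straight-line oracle trace", {
  fx <- micro_fixture()
  p <- fx$params
  res <- gsl_iterate(fx$X_r, fx$A0, p$w, p$epsilon_sparsify, p$lambda,
                     p$eta, p$W_list, p$T_rounds, normalize = p$normalize)
  oracle <- oracle_gsl_trace(fx$X_r, fx$A0, as.numeric(p$w), p$lambda,
                             p$eta, p$epsilon_sparsify, p$T_rounds,
                             p$W_list, normalize = p$normalize)
  for (t in seq_len(p$T_rounds)) {
    expect_lt(max(abs(res$trace[[t]]$learned_edges -
                        sum(oracle[[t]]$At > 0) / 2)), 1e-9)
  }
  expect_lt(max(abs(res$A_fused - oracle[[2]]$fused)), 1e-6)
  expect_lt(max(abs(res$H - oracle[[2]]$H)), 1e-6)
  expect_lt(max(abs(res$A1 - oracle[[1]]$At)), 1e-6)
  ## frozen spot values from the one-time straight-line evaluation
  expect_equal(res$A_fused[1, 2], 0.67738917, tolerance = 1e-6)
  expect_equal(res$A_fused[3, 4], 0.30842033, tolerance = 1e-6)
  expect_equal(res$H[4, 1], 0.4229794, tolerance = 1e-6)
})

test_that("one refinement round collapses the fusion algebra", {
  fx <- micro_fixture()
  p <- fx$params
  res <- gsl_iterate(fx$X_r, fx$A0, p$w, p$epsilon_sparsify, p$lambda,
                     p$eta, p$W_list, T_rounds = 1, normalize = FALSE)
  ## at T = 1: eta*A1 + (1-eta)*A1 = A1 regardless of eta
  expect_equal(res$A_fused,
               p$lambda * fx$A0 + (1 - p$lambda) * res$A1,
               tolerance = 1e-12)
  res_eta9 <- gsl_iterate(fx$X_r, fx$A0, p$w, p$epsilon_sparsify,
                          p$lambda, 0.9, p$W_list, T_rounds = 1,
                          normalize = FALSE)
  expect_equal(res$A_fused, res_eta9$A_fused, tolerance = 1e-12)
})

test_that("refinement is deterministic and keeps the fused matrix admissible", {
  set.seed(47)
  X <- matrix(rnorm(24), 8, 3)
  A0 <- sparsify(abs(weighted_cosine(matrix(rnorm(24), 8, 3),
                                     matrix(1, 1, 3))), 0.2)
  W <- matrix(rnorm(9, sd = 0.5), 3, 3)
  ## ReLU can zero whole rows mid-refinement; the similarity warning for
  ## those rows is expected here
  r1 <- suppressWarnings(
    gsl_iterate(X, A0, matrix(1, 1, 3), 0.1, 0.8, 0.5, list(W), 3))
  r2 <- suppressWarnings(
    gsl_iterate(X, A0, matrix(1, 1, 3), 0.1, 0.8, 0.5, list(W), 3))
  expect_identical(r1$H, r2$H)
  expect_identical(r1$A_fused, r2$A_fused)
  ## convex combination of matrices in [0, 1] stays in [0, 1], symmetric
  expect_true(isSymmetric(r1$A_fused))
  expect_true(all(r1$A_fused >= 0 & r1$A_fused <= 1))
})
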