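## Finite-difference validation of the reverse-mode tape. Each check
## builds a scalar loss from one op and compares analytic and central
## finite-difference gradients entry by entry.

fd_gradient <- function(make_loss, X, eps = 1e-6) {
  num <- X * 0
  for (ii in seq_along(X)) {
    Xp <- X; Xp[ii] <- Xp[ii] + eps
    Xm <- X; Xm[ii] <- Xm[ii] - eps
    tp1 <- molgsl:::tp_new()
    r1 <- make_loss(tp1, molgsl:::tp_param(tp1, Xp, "x"))
    tp2 <- molgsl:::tp_new()
    r2 <- make_loss(tp2, molgsl:::tp_param(tp2, Xm, "x"))
    num[ii] <- (molgsl:::tp_val(tp1, r1) - molgsl:::tp_val(tp2, r2)) /
      (2 * eps)
  }
  num
}

expect_grad_ok <- function(make_loss, X, tol = 1e-5) {
  tape <- molgsl:::tp_new()
  root <- make_loss(tape, molgsl:::tp_param(tape, X, "x"))
  ana <- molgsl:::tp_param_grads(tape, root)$x
  num <- fd_gradient(make_loss, X)
  expect_lt(max(abs(ana - num)) / max(1, max(abs(num))), tol)
}

scalarize <- function(tape, id) {
  V <- molgsl:::tp_val(tape, id)
  molgsl:::tp_node(tape, sum((V - 0.3)^2), id,
                   function(g) list(2 * g * (V - 0.3)))
}

test_that("matrix op gradients match finite differences", {
  set.seed(61)
  X <- matrix(rnorm(20), 5, 4)
  W <- rnorm(4)
  B <- matrix(rnorm(12), 4, 3)
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_rownorm(t, i)), X)
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_tcrossprod(t, i)),
                 X)
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_layernorm(t, i)),
                 X)
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_colnorm(t, i)),
                 X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_matmul(t, i, molgsl:::tp_const(t, B)))
  }, X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_matmul(t, molgsl:::tp_const(t, X), i))
  }, B)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_colscale(t, i, molgsl:::tp_const(t, W)))
  }, X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_colscale(t, molgsl:::tp_const(t, X), i))
  }, matrix(W, 1))
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_addbias(t, i, molgsl:::tp_const(t, W)))
  }, X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_addbias(t, molgsl:::tp_const(t, X), i))
  }, matrix(W, 1))
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_relu(t, i)),
                 X + 0.5)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_scale1p(t, molgsl:::tp_const(t, 0.3), i))
  }, X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_scale1p(t, i, molgsl:::tp_const(t, X)))
  }, matrix(0.2))
})

test_that("graph-specific op gradients match finite differences", {
  set.seed(62)
  A <- matrix(abs(rnorm(25)), 5, 5); A <- (A + t(A)) / 2; diag(A) <- 0
  mask <- matrix(rbinom(25, 1, 0.6), 5, 5)
  idx <- cbind(c(1, 2, 4), c(3, 5, 2))
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_symnorm(t, i)), A)
  ## asymmetric input exercises the two degree-chain terms separately
  A2 <- matrix(abs(rnorm(25)), 5, 5)
  expect_grad_ok(function(t, i) scalarize(t, molgsl:::tp_symnorm(t, i)), A2)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_maskmul(t, i, mask))
  }, A)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_lincomb(t, list(i, i), c(0.3, 0.4),
                                     const_term = A))
  }, A + 1)
  expect_grad_ok(function(t, i) {
    molgsl:::tp_sum_sq_diff(t, molgsl:::tp_gather(t, i, idx), c(1, 0, 0.5))
  }, A)
  Agg <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 3, 1), x = 1,
                              dims = c(5, 5))
  X <- matrix(rnorm(20), 5, 4)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_lmul_const(t, Agg, i))
  }, X)
  expect_grad_ok(function(t, i) {
    scalarize(t, molgsl:::tp_cbind(t, list(i, molgsl:::tp_const(t, X))))
  }, X * 2)
})

test_that("loss op gradients match finite differences", {
  set.seed(63)
  X <- matrix(rnorm(20), 5, 4)
  y <- matrix(rnorm(20), 5, 4)
  yb <- matrix(rbinom(20, 1, 0.5), 5, 4)
  mk <- matrix(rbinom(20, 1, 0.7), 5, 4)
  expect_grad_ok(function(t, i) molgsl:::tp_masked_mse(t, i, y, mk), X)
  expect_grad_ok(function(t, i) molgsl:::tp_masked_bce(t, i, yb, mk), X)
})

test_that("whole-model gradients match finite differences", {
  rec <- fixture_records(10)
  rec <- random_split(rec, c(0.6, 0.2, 0.2), seed = 2)
  scheme <- featurization_scheme()
  graphs <- featurize_molecules(rec$smiles)
  batch <- molgsl:::build_batch(graphs, "sum")
  A0 <- as.matrix(build_initial_adjacency(rec, 0.3)$adjacency)
  tr <- which(rec$split == "train")
  ys <- (rec$targets - mean(rec$targets[tr, 1])) / sd(rec$targets[tr, 1])
  pairs <- molgsl:::train_pairs(tr)
  cfg <- run_config(task_type = "regression", K = 2, hidden_dim = 6,
                    m = 2, L = 2, T_rounds = 2, seed = 5)
  data <- list(y = ys, mask = rec$target_mask * 1, train_idx = tr,
               pairs = pairs,
               qualifying = abs(ys[pairs[, 1], 1] - ys[pairs[, 2], 1]) >
                 cfg$epsilon_y)
  flat <- molgsl:::init_model_params(cfg, scheme$dim, 1)
  fw <- molgsl:::model_forward(flat, cfg, batch, A0, data)
  grads <- molgsl:::tp_param_grads(fw$tape, fw$loss)
  loss_at <- function(fl) {
    w <- molgsl:::model_forward(fl, cfg, batch, A0, data)
    molgsl:::tp_val(w$tape, w$loss)
  }
  set.seed(6)
  eps <- 1e-6
  for (nm in c("gin_eps_1", "gin_W1_1", "persp_w_2", "inter_W_1",
               "inter_W_2", "head_W", "gin_Wout")) {
    v <- flat[[nm]]
    for (ii in sample(length(v), min(3, length(v)))) {
      fp <- flat; fp[[nm]][ii] <- fp[[nm]][ii] + eps
      fm <- flat; fm[[nm]][ii] <- fm[[nm]][ii] - eps
      num <- (loss_at(fp) - loss_at(fm)) / (2 * eps)
      ana <- as.numeric(grads[[nm]])[ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})
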