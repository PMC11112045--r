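## Tape-based forward pass of the full two-level model, plus Adam. The
## exported plain operations (gin_layer, weighted_cosine, ...) define the
## semantics; this file wires the same math through the autodiff tape for
## training, and the test suite pins the two paths together.

## Stack a list of molecular graphs into one block-diagonal batch.
build_batch <- function(graphs, readout_mode = "sum") {
  n <- length(graphs)
  nv <- vapply(graphs, function(g) g$n_v, 0L)
  offs <- cumsum(c(0L, utils::head(nv, -1L)))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  N <- nrow(X)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    if (g$n_e > 0L) {
      ei <- c(ei, g$edges[, 1] + offs[i], g$edges[, 2] + offs[i])
      ej <- c(ej, g$edges[, 2] + offs[i], g$edges[, 1] + offs[i])
    }
  }
  Agg <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(N, N))
  pool_w <- if (readout_mode == "mean") rep(1 / nv, nv) else rep(1, N)
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), nv), j = seq_len(N),
                            x = pool_w, dims = c(n, N))
  list(X = X, Agg = Agg, P = P, n_mol = n, n_atoms = N)
}

## Flat parameter list for the whole model (names are stable across runs).
init_model_params <- function(config, atom_dim, n_tasks) {
  h <- config$hidden_dim
  with_seed(derive_seed(config$seed, 1L), {
    p <- list()
    d_in <- atom_dim
    for (k in seq_len(config$K)) {
      p[[paste0("gin_eps_", k)]] <- 0
      p[[paste0("gin_W1_", k)]] <- glorot(d_in, h)
      p[[paste0("gin_b1_", k)]] <- numeric(h)
      p[[paste0("gin_W2_", k)]] <- glorot(h, h)
      p[[paste0("gin_b2_", k)]] <- numeric(h)
      d_in <- h
    }
    p$gin_Wout <- glorot(atom_dim + config$K * h, h)
    p$gin_bout <- numeric(h)
    if (config$ablation_variant %in% c("full", "only_gsl", "no_gsl_loss")) {
      ## perspectives start near plain cosine: all-ones plus small noise
      for (q in seq_len(config$m)) {
        p[[paste0("persp_w_", q)]] <- 1 + stats::rnorm(h, 0, 0.01)
      }
    }
    if (config$ablation_variant != "not_any") {
      for (l in seq_len(config$L)) {
        p[[paste0("inter_W_", l)]] <- glorot(h, h)
      }
    }
    p$head_W <- glorot(h, n_tasks)
    p$head_b <- numeric(n_tasks)
    p
  })
}

## Assemble a gin_params object from the flat list (for the exported plain
## encoder and for checkpoints).
as_gin_params <- function(flat, config, atom_dim) {
  layers <- lapply(seq_len(config$K), function(k) {
    list(eps = flat[[paste0("gin_eps_", k)]],
         W1 = flat[[paste0("gin_W1_", k)]],
         b1 = flat[[paste0("gin_b1_", k)]],
         W2 = flat[[paste0("gin_W2_", k)]],
         b2 = flat[[paste0("gin_b2_", k)]],
         use_layernorm = config$use_layernorm)
  })
  structure(list(K = config$K, hidden_dim = config$hidden_dim,
                 atom_dim = atom_dim, readout_mode = config$readout_mode,
                 layers = layers, W_out = flat$gin_Wout,
                 b_out = flat$gin_bout),
            class = "gin_params")
}

## Full forward pass on the tape.
##   inputs: batch (build_batch), A0 dense matrix (or NULL for not_any),
##   data = list(y, mask, train_idx, pairs, a_star / eps_y qualifying).
## Returns tape plus node ids of the quantities the trainer needs.
model_forward <- function(flat, config, batch, A0, data,
                          with_grad = TRUE) {
  tape <- tp_new()
  ## one tape node per parameter, however many times it is used (uses
  ## accumulate into the same node during backward)
  par_ids <- new.env(parent = emptyenv())
  par <- function(name) {
    if (is.null(par_ids[[name]])) {
      par_ids[[name]] <- if (with_grad) {
        tp_param(tape, flat[[name]], name)
      } else {
        tp_const(tape, flat[[name]])
      }
    }
    par_ids[[name]]
  }
  variant <- config$ablation_variant

  ## --- GIN over the stacked atom graph ---
  X <- tp_const(tape, batch$X)
  pooled <- list(tp_node(tape, as.matrix(batch$P %*% batch$X)))
  H <- X
  for (k in seq_len(config$K)) {
    eps <- par(paste0("gin_eps_", k))
    pre <- tp_add(tape, tp_scale1p(tape, eps, H),
                  tp_lmul_const(tape, batch$Agg, H))
    Z <- tp_addbias(tape, tp_matmul(tape, pre, par(paste0("gin_W1_", k))),
                    par(paste0("gin_b1_", k)))
    Z <- tp_relu(tape, Z)
    Z <- tp_addbias(tape, tp_matmul(tape, Z, par(paste0("gin_W2_", k))),
                    par(paste0("gin_b2_", k)))
    if (config$use_layernorm) Z <- tp_layernorm(tape, Z)
    H <- Z
    pooled[[k + 1L]] <- tp_lmul_const(tape, batch$P, H)
  }
  X_raw <- tp_addbias(tape, tp_matmul(tape, tp_cbind(tape, pooled),
                                      par("gin_Wout")), par("gin_bout"))
  ## standardize embedding columns over the population: the cosine metric
  ## can rescale dimensions but not centre them, and uncentred pooled
  ## embeddings share one dominant direction (all pairwise cosines near
  ## 1), which degenerates the learned graph
  X_r <- tp_colnorm(tape, X_raw)

  ## --- molecule-level refinement ---
  round_states <- list()
  if (variant == "not_any") {
    H_final <- X_r
    fused <- NULL
  } else if (variant == "only_a0") {
    fused <- tp_const(tape, A0)
    H_final <- tp_propagate(tape, X_r, fused, flat, par, config)
    round_states[[1]] <- list(fused = fused)
  } else {
    w_ids <- lapply(seq_len(config$m), function(q) par(paste0("persp_w_", q)))
    H_prev <- X_r
    A1 <- NULL
    for (t in seq_len(config$T_rounds)) {
      S_ps <- lapply(w_ids, function(w) {
        tp_tcrossprod(tape, tp_rownorm(tape, tp_colscale(tape, H_prev, w)))
      })
      S <- tp_lincomb(tape, S_ps, rep(1 / config$m, config$m))
      Sv <- tp_val(tape, S)
      mask <- (Sv >= config$epsilon_sparsify)
      diag(mask) <- FALSE
      At <- tp_maskmul(tape, S, mask)
      if (t == 1L) A1 <- At
      la <- if (variant == "only_gsl") 0 else config$lambda
      fused <- tp_lincomb(
        tape, list(At, A1),
        c((1 - la) * config$eta, (1 - la) * (1 - config$eta)),
        const_term = if (la > 0) la * A0 else NULL)
      Hl <- tp_propagate(tape, X_r, fused, flat, par, config,
                         return_layers = TRUE)
      round_states[[t]] <- list(At = At, fused = fused, H_layers = Hl)
      H_prev <- Hl[[length(Hl)]]
    }
    H_final <- H_prev
  }

  pred <- tp_addbias(tape, tp_matmul(tape, H_final, par("head_W")),
                     par("head_b"))

  ## --- losses (train rows only) ---
  train_mask <- matrix(0, batch$n_mol, ncol(data$y))
  train_mask[data$train_idx, ] <- 1
  train_mask <- train_mask * data$mask
  l_pred <- if (sum(train_mask) == 0) {  # inference-only pass
    tp_const(tape, 0)
  } else if (config$task_type == "regression") {
    tp_masked_mse(tape, pred, data$y, train_mask)
  } else {
    tp_masked_bce(tape, pred, data$y, train_mask)
  }
  use_gsl_loss <- config$gsl_weight > 0 &&
    variant %in% c("full", "only_gsl") && !is.null(fused)
  if (use_gsl_loss && nrow(data$pairs) > 0L) {
    ## the pair sums grow with O(n_train^2) while the prediction loss is
    ## a mean; normalize per summed pair so the two terms share scale
    ## across dataset sizes
    if (config$task_type == "classification") {
      g <- tp_gather(tape, fused, data$pairs)
      raw <- tp_sum_sq_diff(tape, g, data$a_star)
      l_gsl <- tp_scalar_comb(tape, list(raw), 1 / nrow(data$pairs))
    } else {
      qual <- if (config$gsl_on_predictions) {
        pv <- tp_val(tape, pred)[, 1]
        abs(pv[data$pairs[, 1]] - pv[data$pairs[, 2]]) > config$epsilon_y
      } else data$qualifying
      if (any(qual)) {
        g <- tp_gather(tape, fused, data$pairs[qual, , drop = FALSE])
        raw <- tp_sum_sq_diff(tape, g, 0)
        l_gsl <- tp_scalar_comb(tape, list(raw), 1 / sum(qual))
      } else l_gsl <- tp_const(tape, 0)
    }
    loss <- tp_scalar_comb(tape, list(l_pred, l_gsl),
                           c(1, config$gsl_weight))
  } else {
    l_gsl <- tp_const(tape, 0)
    loss <- l_pred
  }

  list(tape = tape, loss = loss, l_pred = l_pred, l_gsl = l_gsl,
       pred = pred, X_r = X_r, X_raw = X_raw, H_final = H_final,
       fused = fused, round_states = round_states)
}

tp_propagate <- function(tape, X_r, fused, flat, par, config,
                         return_layers = FALSE) {
  Ah <- if (config$normalize_adjacency) tp_symnorm(tape, fused) else fused
  H <- X_r
  layers <- vector("list", config$L)
  for (l in seq_len(config$L)) {
    H <- tp_relu(tape, tp_matmul(tape, tp_matmul(tape, Ah, H),
                                 par(paste0("inter_W_", l))))
    layers[[l]] <- H
  }
  if (return_layers) layers else H
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(flat = flat, state = state)
}
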