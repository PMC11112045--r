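## Minimal reverse-mode automatic differentiation on a tape of matrix ops.
## Internal machinery: the model forward pass builds a tape, `tp_backward()`
## accumulates gradients for every parameter node. Values are plain base-R
## matrices/vectors; each op registers a backward closure over its forward
## intermediates. Gradient correctness is pinned down by finite-difference
## checks in the test suite.

tp_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e$params <- list()
  e
}

tp_node <- function(tape, val, parents = integer(0), bw = NULL,
                    requires = FALSE) {
  requires <- requires ||
    any(vapply(parents, function(p) tape$nodes[[p]]$requires, TRUE))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- list(val = val, parents = parents, bw = bw,
                               requires = requires)
  tape$n
}

tp_const <- function(tape, val) tp_node(tape, val)

tp_param <- function(tape, val, name) {
  id <- tp_node(tape, val, requires = TRUE)
  tape$params[[name]] <- id
  id
}

tp_val <- function(tape, id) {
  force(id)  # inline op arguments append to the tape before indexing it
  tape$nodes[[id]]$val
}

## ---- ops ------------------------------------------------------------------

tp_add <- function(tape, a, b) {
  tp_node(tape, tp_val(tape, a) + tp_val(tape, b), c(a, b),
          function(g) list(g, g))
}

tp_addbias <- function(tape, m, b) {
  M <- tp_val(tape, m)
  tp_node(tape, sweep(M, 2, tp_val(tape, b), `+`), c(m, b),
          function(g) list(g, colSums(g)))
}

tp_matmul <- function(tape, a, b) {
  A <- tp_val(tape, a); B <- tp_val(tape, b)
  tp_node(tape, A %*% B, c(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

## left-multiplication by a constant (possibly sparse) matrix
tp_lmul_const <- function(tape, C, b) {
  B <- tp_val(tape, b)
  tp_node(tape, as.matrix(C %*% B), b,
          function(g) list(as.matrix(Matrix::crossprod(C, g))))
}

## (1 + s) * M for a scalar parameter s
tp_scale1p <- function(tape, s, m) {
  sv <- as.numeric(tp_val(tape, s)); M <- tp_val(tape, m)
  tp_node(tape, (1 + sv) * M, c(s, m),
          function(g) list(sum(g * M), (1 + sv) * g))
}

tp_relu <- function(tape, a) {
  V <- tp_val(tape, a)
  pos <- V > 0
  tp_node(tape, V * pos, a, function(g) list(g * pos))
}

## row-wise standardization (layer normalization without affine terms)
tp_layernorm <- function(tape, a, eps = 1e-5) {
  X <- tp_val(tape, a)
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  Y <- xc * inv
  tp_node(tape, Y, a, function(g) {
    gy <- g * inv
    list(gy - rowMeans(gy) - Y * inv * rowMeans(g * Y) * 1)
  })
}

## column-wise standardization over the full molecule population
## (deterministic batch normalization without affine terms)
tp_colnorm <- function(tape, a, eps = 1e-5) {
  X <- tp_val(tape, a)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  Y <- sweep(xc, 2, inv, `*`)
  tp_node(tape, Y, a, function(g) {
    gy <- sweep(g, 2, inv, `*`)
    list(sweep(gy, 2, colMeans(gy)) -
           sweep(Y, 2, inv * colMeans(g * Y), `*`))
  })
}

tp_cbind <- function(tape, ids) {
  vals <- lapply(ids, tp_val, tape = tape)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tp_node(tape, do.call(cbind, vals), as.integer(ids), function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

## multiply column j of M by w[j] (w a parameter vector)
tp_colscale <- function(tape, m, w) {
  M <- tp_val(tape, m); W <- as.numeric(tp_val(tape, w))
  tp_node(tape, sweep(M, 2, W, `*`), c(m, w),
          function(g) list(sweep(g, 2, W, `*`), colSums(g * M)))
}

## scale every row to unit L2 norm; all-zero rows stay zero
tp_rownorm <- function(tape, m) {
  M <- tp_val(tape, m)
  r <- sqrt(rowSums(M^2))
  safe <- ifelse(r > 0, r, 1)
  Y <- M / safe
  tp_node(tape, Y, m, function(g) {
    gm <- (g - Y * rowSums(g * Y)) / safe
    gm[r == 0, ] <- 0
    list(gm)
  })
}

tp_tcrossprod <- function(tape, a) {
  N <- tp_val(tape, a)
  tp_node(tape, tcrossprod(N), a, function(g) list((g + t(g)) %*% N))
}

## elementwise product with a constant 0/1 mask (epsilon-sparsification)
tp_maskmul <- function(tape, a, mask) {
  tp_node(tape, tp_val(tape, a) * mask, a, function(g) list(g * mask))
}

## coefs[1]*x1 + coefs[2]*x2 + ... (+ const_term)
tp_lincomb <- function(tape, ids, coefs, const_term = NULL) {
  vals <- lapply(ids, tp_val, tape = tape)
  out <- const_term %||% 0
  for (k in seq_along(ids)) out <- out + coefs[k] * vals[[k]]
  tp_node(tape, out, as.integer(ids), function(g) {
    lapply(coefs, function(ck) ck * g)
  })
}

## add unit self-loops and symmetrically degree-normalize:
## Ahat = D^{-1/2} (A + I) D^{-1/2}, d_i = 1 + sum_j A_ij (A non-negative)
tp_symnorm <- function(tape, a) {
  A <- tp_val(tape, a)
  B <- A + diag(nrow(A))
  d <- rowSums(B)
  s <- 1 / sqrt(d)
  Ah <- B * outer(s, s)
  tp_node(tape, Ah, a, function(g) {
    ## d_k depends on every entry of row k, so both degree-chain terms
    ## broadcast along columns of row k
    P <- g * B
    dd <- -0.5 * d^(-1.5)
    u <- rowSums(sweep(P, 2, s, `*`)) * dd  # through s_i of Ah_ij
    w <- colSums(P * s) * dd                # through s_j of Ah_ij
    list(g * outer(s, s) + outer(u + w, rep(1, ncol(A))))
  })
}

## extract entries at (i, j) index pairs as a vector
tp_gather <- function(tape, m, idx) {
  M <- tp_val(tape, m)
  tp_node(tape, M[idx], m, function(g) {
    G <- matrix(0, nrow(M), ncol(M))
    ## accumulate (idx pairs are unique here, but be safe)
    for (k in seq_len(nrow(idx))) {
      G[idx[k, 1], idx[k, 2]] <- G[idx[k, 1], idx[k, 2]] + g[k]
    }
    list(G)
  })
}

## sum((x - target)^2) of a vector node
tp_sum_sq_diff <- function(tape, a, target = 0) {
  V <- tp_val(tape, a)
  tp_node(tape, sum((V - target)^2), a,
          function(g) list(2 * g * (V - target)))
}

## masked mean squared error over observed entries
tp_masked_mse <- function(tape, pred, y, mask) {
  P <- tp_val(tape, pred)
  n_obs <- sum(mask)
  if (n_obs == 0) stop_input("no observed labels in loss")
  diff <- (P - y) * mask
  tp_node(tape, sum(diff^2) / n_obs, pred,
          function(g) list(g * 2 * diff / n_obs))
}

## masked binary cross entropy with logits (mean over observed entries)
tp_masked_bce <- function(tape, logits, y, mask) {
  Z <- tp_val(tape, logits)
  n_obs <- sum(mask)
  if (n_obs == 0) stop_input("no observed labels in loss")
  sp <- pmax(Z, 0) + log1p(exp(-abs(Z)))   # stable softplus(z)
  val <- sum(mask * (sp - y * Z)) / n_obs
  sig <- 1 / (1 + exp(-Z))
  tp_node(tape, val, logits,
          function(g) list(g * mask * (sig - y) / n_obs))
}

tp_scalar_comb <- function(tape, ids, coefs) {
  vals <- vapply(ids, function(i) as.numeric(tp_val(tape, i)), 0)
  tp_node(tape, sum(coefs * vals), as.integer(ids),
          function(g) as.list(g * coefs))
}

## ---- backward -------------------------------------------------------------

tp_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  rv <- tp_val(tape, root)
  grads[[root]] <- if (length(rv) == 1L) 1 else array(1, dim(rv))
  for (i in seq(root, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(grads[[i]]) || !node$requires || is.null(node$bw)) next
    pg <- node$bw(grads[[i]])
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (!tape$nodes[[p]]$requires || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

## gradient of a scalar root with respect to every named parameter
tp_param_grads <- function(tape, root) {
  grads <- tp_backward(tape, root)
  out <- lapply(tape$params, function(id) {
    g <- grads[[id]]
    if (is.null(g)) {
      v <- tp_val(tape, id)
      g <- if (length(v) == 1L) 0 else array(0, dim(v) %||% length(v))
    }
    g
  })
  out
}
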