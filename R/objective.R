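#' Prediction head
#'
#' A single fully connected map from the final molecular embeddings to one
#' output per task. Classification consumers apply the logistic transform
#' to these outputs to obtain probabilities; regression outputs are
#' un-standardized to original units before metrics.
#'
#' @param H_final embedding matrix.
#' @param W,b head weights (`ncol(H_final) x n_tasks`) and bias.
#' @return Prediction (logit/standardized-value) matrix, one column per
#'   task.
#' @export
predict_head <- function(H_final, W, b = numeric(ncol(W))) {
  sweep(as.matrix(H_final) %*% W, 2, b, `+`)
}

#' Task prediction loss
#'
#' Masked mean over observed labels: binary cross entropy on logits for
#' classification, mean squared error for regression. Values stored at
#' masked positions are never read.
#'
#' @param y_hat prediction matrix (logits for classification).
#' @param y label matrix of the same shape.
#' @param mask logical matrix marking observed labels.
#' @param task_type `"classification"` or `"regression"`.
#' @return Scalar loss.
#' @export
prediction_loss <- function(y_hat, y, mask,
                            task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  y_hat <- as.matrix(y_hat); y <- as.matrix(y); mask <- as.matrix(mask)
  stopifnot(identical(dim(y_hat), dim(y)), identical(dim(y), dim(mask)))
  n_obs <- sum(mask)
  if (n_obs == 0) stop_input("no observed labels")
  if (task_type == "regression") {
    sum(((y_hat - y) * mask)^2) / n_obs
  } else {
    z <- y_hat
    sp <- pmax(z, 0) + log1p(exp(-abs(z)))
    sum(mask * (sp - y * z)) / n_obs
  }
}

## Unordered train pairs i < j; subsampled (seeded) beyond `max_exact`
## molecules to bound the O(n^2) pair sum.
train_pairs <- function(train_idx, max_exact = 3000L, seed = 0L) {
  n <- length(train_idx)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  if (n <= max_exact) {
    cmb <- utils::combn(train_idx, 2L)
    return(cbind(cmb[1, ], cmb[2, ]))
  }
  msg_log(sprintf(
    "subsampling GSL-loss pairs (%d train molecules > %d)", n, max_exact))
  n_pairs <- as.integer(max_exact * (max_exact - 1) / 2)
  with_seed(seed, {
    i <- sample(train_idx, n_pairs, replace = TRUE)
    j <- sample(train_idx, n_pairs, replace = TRUE)
    keep <- i < j
    unique(cbind(i[keep], j[keep]))
  })
}

## A* targets for classification: 1 iff labels agree on every co-observed
## task; pairs with no co-observed task are dropped (NA target).
pair_label_agreement <- function(labels, mask, pairs) {
  labels <- as.matrix(labels); mask <- as.matrix(mask)
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    co <- mask[i, ] & mask[j, ]
    if (!any(co)) return(NA_real_)
    as.numeric(all(labels[i, co] == labels[j, co]))
  }, 0)
}

#' Graph-quality loss for classification
#'
#' Same-label training molecules should be connected: the loss sums
#' `(fused_ij - A*_ij)^2` over unordered train pairs `i < j`, where
#' `A*_ij = 1` iff the two molecules agree on every co-observed task and 0
#' otherwise. Pairs with no co-observed task are skipped.
#'
#' @param A_final fused adjacency after the last refinement round.
#' @param labels label matrix (0/1), all molecules.
#' @param train_idx indices of training molecules.
#' @param mask logical matrix of observed labels (default all observed).
#' @return Non-negative scalar.
#' @export
gsl_loss_classification <- function(A_final, labels, train_idx,
                                    mask = NULL) {
  labels <- as.matrix(labels)
  mask <- mask %||% matrix(TRUE, nrow(labels), ncol(labels))
  if (length(train_idx) < 2L) {
    warning("fewer than 2 training molecules; GSL loss is 0")
    return(0)
  }
  pairs <- train_pairs(train_idx)
  a_star <- pair_label_agreement(labels, mask, pairs)
  keep <- !is.na(a_star)
  w <- as.matrix(A_final)[pairs[keep, , drop = FALSE]]
  sum((w - a_star[keep])^2)
}

#' Graph-quality loss for regression
#'
#' Penalizes edge weight between property-discordant training molecules:
#' sums `fused_ij^2` over unordered train pairs whose target difference
#' exceeds `epsilon_y`. Zero when no pair qualifies.
#'
#' @param A_final fused adjacency after the last refinement round.
#' @param y numeric target vector (or one-column matrix), all molecules,
#'   on the scale on which `epsilon_y` is meant (standardized during
#'   training).
#' @param train_idx indices of training molecules.
#' @param epsilon_y positive discordance threshold.
#' @return Non-negative scalar.
#' @export
gsl_loss_regression <- function(A_final, y, train_idx, epsilon_y = 0.5) {
  if (epsilon_y <= 0) stop_input("epsilon_y must be > 0")
  y <- as.numeric(as.matrix(y)[, 1])
  if (length(train_idx) < 2L) {
    warning("fewer than 2 training molecules; GSL loss is 0")
    return(0)
  }
  pairs <- train_pairs(train_idx)
  keep <- abs(y[pairs[, 1]] - y[pairs[, 2]]) > epsilon_y
  if (!any(keep)) return(0)
  w <- as.matrix(A_final)[pairs[keep, , drop = FALSE]]
  sum(w^2)
}

#' Combined training loss
#'
#' `L = Lpred + gsl_weight * LGSL`; with `gsl_weight = 1` (default) this
#' is the plain sum of task loss and graph-quality loss, and
#' `gsl_weight = 0` gives the no-graph-loss ablation.
#'
#' @param l_pred,l_gsl finite scalars.
#' @param gsl_weight non-negative weight on the graph-quality term.
#' @return Scalar total loss.
#' @export
total_loss <- function(l_pred, l_gsl, gsl_weight = 1) {
  if (!is.finite(l_pred) || !is.finite(l_gsl)) {
    stop_input("non-finite loss component")
  }
  if (gsl_weight < 0) stop_input("gsl_weight must be >= 0")
  l_pred + gsl_weight * l_gsl
}
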