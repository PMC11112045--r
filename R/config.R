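#' Run configuration
#'
#' Collects and validates every hyperparameter of the two-level model.
#' Defaults follow community practice for the pieces the method leaves
#' open (GIN depth/width, fingerprint settings, learner sizes) and the
#' reported sweeps for the fusion weight (`lambda` large, default 0.8) and
#' refinement rounds (`T_rounds` default 2).
#'
#' @param task_type `"classification"` or `"regression"`.
#' @param K GIN message-passing layers.
#' @param hidden_dim embedding width.
#' @param readout_mode `"sum"` or `"mean"` graph pooling.
#' @param use_layernorm row-normalization inside the GIN MLPs.
#' @param radius,n_bits circular-fingerprint settings (ECFP4-style
#'   defaults).
#' @param epsilon_tc Tanimoto threshold of the initial MSG.
#' @param m number of weighted-cosine perspectives.
#' @param epsilon_sparsify epsilon-neighbourhood threshold on learned
#'   similarities.
#' @param lambda,eta adjacency fusion weights in `[0, 1]`.
#' @param L inter-molecule GNN layers.
#' @param T_rounds graph refinement rounds.
#' @param normalize_adjacency self-loop + symmetric degree normalization
#'   before propagation (`FALSE` gives the literal update rule).
#' @param epsilon_y discordance threshold of the regression graph loss, on
#'   the standardized target scale.
#' @param gsl_on_predictions select regression loss pairs by predicted
#'   instead of true train targets.
#' @param gsl_weight weight of the graph-quality loss (1 reproduces the
#'   plain summed loss; 0 is the no-graph-loss ablation).
#' @param learning_rate,epochs,patience Adam step size, epoch budget and
#'   early-stopping patience (in epochs without validation improvement).
#' @param seed master seed for initialization.
#' @param ablation_variant one of `"full"`, `"not_any"` (GIN + head only),
#'   `"only_a0"` (propagate on the fingerprint graph, no structure
#'   learning), `"only_gsl"` (learn the graph from scratch, no fingerprint
#'   reference), `"no_gsl_loss"` (full graph machinery, prediction loss
#'   only).
#' @param max_nodes guard on the dense O(n^2) similarity computations.
#' @return A validated `run_config` list.
#' @export
run_config <- function(task_type = c("classification", "regression"),
                       K = 3L, hidden_dim = 128L,
                       readout_mode = c("sum", "mean"),
                       use_layernorm = FALSE,
                       radius = 2L, n_bits = 2048L, epsilon_tc = 0.3,
                       m = 4L, epsilon_sparsify = 0.1,
                       lambda = 0.8, eta = 0.5, L = 2L, T_rounds = 2L,
                       normalize_adjacency = TRUE,
                       epsilon_y = 0.5, gsl_on_predictions = FALSE,
                       gsl_weight = 1,
                       learning_rate = 1e-3, epochs = 300L, patience = 30L,
                       seed = 0L,
                       ablation_variant = c("full", "not_any", "only_a0",
                                            "only_gsl", "no_gsl_loss"),
                       max_nodes = 20000L) {
  task_type <- match.arg(task_type)
  readout_mode <- match.arg(readout_mode)
  ablation_variant <- match.arg(ablation_variant)
  stopifnot(K >= 1L, hidden_dim >= 1L, radius >= 0L, n_bits >= 1L,
            m >= 1L, L >= 1L, T_rounds >= 1L, epochs >= 1L,
            patience >= 1L, epsilon_sparsify >= 0, epsilon_y > 0,
            gsl_weight >= 0, learning_rate > 0)
  check_fraction(epsilon_tc, "epsilon_tc")
  check_fraction(lambda, "lambda")
  check_fraction(eta, "eta")
  structure(list(
    task_type = task_type, K = as.integer(K),
    hidden_dim = as.integer(hidden_dim), readout_mode = readout_mode,
    use_layernorm = use_layernorm, radius = as.integer(radius),
    n_bits = as.integer(n_bits), epsilon_tc = epsilon_tc,
    m = as.integer(m), epsilon_sparsify = epsilon_sparsify,
    lambda = lambda, eta = eta, L = as.integer(L),
    T_rounds = as.integer(T_rounds),
    normalize_adjacency = normalize_adjacency,
    epsilon_y = epsilon_y, gsl_on_predictions = gsl_on_predictions,
    gsl_weight = gsl_weight, learning_rate = learning_rate,
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed), ablation_variant = ablation_variant,
    max_nodes = as.integer(max_nodes)), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s (%s): K=%d hidden=%d T=%d L=%d m=%d lambda=%.2f eta=%.2f\n",
    x$task_type, x$ablation_variant, x$K, x$hidden_dim, x$T_rounds, x$L,
    x$m, x$lambda, x$eta))
  invisible(x)
}
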