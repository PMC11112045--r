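#' Train the two-level molecular property model
#'
#' Full-batch, transductive training: every molecule (train, valid and
#' test) sits in the similarity graph and is propagated over, but losses
#' only ever read training labels. Each epoch re-encodes the molecules
#' with the GIN, refreshes the graph-structure-learning state for
#' `T_rounds`, predicts, and takes one Adam step on `L = Lpred +
#' gsl_weight * LGSL`. Early stopping tracks the validation metric with
#' the configured patience and returns the best-validation weights.
#'
#' @param records a [molecule_set()] with split assignments and at least
#'   one observed training label.
#' @param config a [run_config()].
#' @param verbose print a progress line every 25 epochs.
#' @return A `molgsl_model` with the trained weights, the frozen reference
#'   MSG, predictions/embeddings for the reference molecules, and a
#'   metrics report (per-epoch loss trace, best epoch, per-split metrics).
#' @export
train_model <- function(records, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(records, "molecule_set"),
            inherits(config, "run_config"))
  train_idx <- split_index(records, "train")
  if (!length(train_idx) || !any(records$target_mask[train_idx, ])) {
    stop_input("need at least one training molecule with an observed label")
  }
  scheme <- featurization_scheme()
  graphs <- featurize_molecules(records$smiles, scheme)
  if (any(vapply(graphs, is.null, TRUE))) {
    stop_input("unparseable SMILES in training records")
  }
  batch <- build_batch(graphs, config$readout_mode)

  ## initial MSG from fingerprints (skipped entirely for the GIN-only
  ## ablation; learned-from-scratch ablation needs no fingerprint graph
  ## either but keeps the refinement machinery)
  A0 <- NULL
  msg <- NULL
  if (config$ablation_variant %in% c("full", "only_a0", "no_gsl_loss")) {
    msg <- build_initial_adjacency(records, config$epsilon_tc,
                                   radius = config$radius,
                                   n_bits = config$n_bits,
                                   max_nodes = config$max_nodes)
    A0 <- as.matrix(msg$adjacency)
  }

  ## targets: regression targets are z-scored on train statistics
  y <- records$targets
  mask <- records$target_mask * 1
  y[mask == 0] <- 0
  scaler <- NULL
  if (config$task_type == "regression") {
    obs <- records$targets[train_idx, , drop = FALSE]
    om <- records$target_mask[train_idx, , drop = FALSE]
    mu <- vapply(seq_len(ncol(y)), function(j) mean(obs[om[, j], j]), 0)
    sd_ <- vapply(seq_len(ncol(y)), function(j) {
      s <- stats::sd(obs[om[, j], j]); if (is.na(s) || s == 0) 1 else s
    }, 0)
    scaler <- list(mean = mu, sd = sd_)
    y <- sweep(sweep(y, 2, mu), 2, sd_, `/`)
    y[mask == 0] <- 0
  }

  ## constant pair structure of the graph-quality loss
  pairs <- train_pairs(train_idx, seed = derive_seed(config$seed, 2L))
  a_star <- NULL; qualifying <- NULL
  if (config$task_type == "classification") {
    a_star <- pair_label_agreement(records$targets, records$target_mask,
                                   pairs)
    keep <- !is.na(a_star)
    pairs <- pairs[keep, , drop = FALSE]
    a_star <- a_star[keep]
  } else if (nrow(pairs) > 0L) {
    ys <- y[, 1]
    qualifying <- abs(ys[pairs[, 1]] - ys[pairs[, 2]]) > config$epsilon_y
  }
  data <- list(y = y, mask = mask, train_idx = train_idx, pairs = pairs,
               a_star = a_star, qualifying = qualifying)

  flat <- init_model_params(config, scheme$dim, n_tasks(records))
  state <- adam_init(flat)
  valid_idx <- split_index(records, "valid")
  if (!length(valid_idx)) {
    warning("empty validation split; early stopping disabled")
  }
  best <- list(metric = NA_real_, flat = flat, epoch = 0L)
  stall <- 0L
  trace <- vector("list", config$epochs)
  higher_better <- config$task_type == "classification"

  for (epoch in seq_len(config$epochs)) {
    fw <- model_forward(flat, config, batch, A0, data)
    lv <- tp_val(fw$tape, fw$loss)
    if (!is.finite(lv)) {
      stop_input("training diverged (non-finite loss) at epoch ", epoch)
    }
    grads <- tp_param_grads(fw$tape, fw$loss)
    upd <- adam_step(flat, grads, state, lr = config$learning_rate)
    flat_next <- upd$flat; state <- upd$state

    pred <- tp_val(fw$tape, fw$pred)
    vm <- if (length(valid_idx)) {
      split_metric(pred, records, valid_idx, config, scaler)
    } else NA_real_
    trace[[epoch]] <- data.frame(
      epoch = epoch, loss = lv,
      l_pred = as.numeric(tp_val(fw$tape, fw$l_pred)),
      l_gsl = as.numeric(tp_val(fw$tape, fw$l_gsl)),
      valid_metric = vm)
    if (verbose && epoch %% 25L == 0L) {
      msg_log(sprintf("epoch %d: loss %.4f (pred %.4f gsl %.4f) valid %.4f",
                      epoch, lv, trace[[epoch]]$l_pred,
                      trace[[epoch]]$l_gsl, vm))
    }
    improved <- length(valid_idx) && (is.na(best$metric) ||
      (higher_better && vm > best$metric + 1e-6) ||
      (!higher_better && vm < best$metric - 1e-6))
    if (improved) {
      best <- list(metric = vm, flat = flat, epoch = epoch)
      stall <- 0L
    } else stall <- stall + 1L
    flat <- flat_next
    if (length(valid_idx) && stall >= config$patience) break
  }
  if (!length(valid_idx) || is.na(best$metric)) {
    best <- list(metric = NA_real_, flat = flat, epoch = epoch)
  }

  model <- structure(list(
    flat = best$flat, config = config, scheme = scheme, scaler = scaler,
    records = records, msg = msg, A0 = A0, batch = batch,
    task_names = colnames(records$targets),
    loss_trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
    best_epoch = best$epoch, cache = new.env(parent = emptyenv())),
    class = "molgsl_model")
  model$metrics <- metrics_report(model)
  model
}

#' @export
print.molgsl_model <- function(x, ...) {
  cat(sprintf("<molgsl_model> %s (%s), %d molecules, best epoch %d\n",
              x$config$task_type, x$config$ablation_variant,
              length(x$records), x$best_epoch))
  if (!is.null(x$metrics)) {
    for (s in names(x$metrics$splits)) {
      m <- x$metrics$splits[[s]]
      cat(sprintf("  %s: %s\n", s,
                  paste(sprintf("%s=%.4f", names(m), unlist(m)),
                        collapse = " ")))
    }
  }
  invisible(x)
}

## Deterministic forward pass over the stored reference molecules with the
## trained weights (cached).
forward_reference <- function(model) {
  if (!is.null(model$cache$fw)) return(model$cache$fw)
  data <- list(y = matrix(0, model$batch$n_mol,
                          length(model$task_names)),
               mask = matrix(0, model$batch$n_mol,
                             length(model$task_names)),
               train_idx = split_index(model$records, "train"),
               pairs = matrix(integer(0), ncol = 2))
  fw <- model_forward(model$flat, model$config, model$batch, model$A0,
                      data, with_grad = FALSE)
  X_raw <- tp_val(fw$tape, fw$X_raw)
  out <- list(
    X_r = tp_val(fw$tape, fw$X_r),
    ## population statistics of the raw embeddings; the inductive path
    ## standardizes new molecules with these reference statistics
    X_stats = list(mean = colMeans(X_raw),
                   sd = sqrt(colMeans(sweep(X_raw, 2,
                                            colMeans(X_raw))^2) + 1e-5)),
    H_final = tp_val(fw$tape, fw$H_final),
    pred = tp_val(fw$tape, fw$pred),
    fused = if (!is.null(fw$fused)) tp_val(fw$tape, fw$fused),
    rounds = lapply(fw$round_states, function(st) {
      list(At = if (!is.null(st$At)) tp_val(fw$tape, st$At),
           fused = tp_val(fw$tape, st$fused),
           H_layers = if (!is.null(st$H_layers))
             lapply(st$H_layers, tp_val, tape = fw$tape))
    }))
  model$cache$fw <- out
  out
}

## Predictions on the original target scale (probabilities stay logits
## here; metrics apply the logistic transform).
reference_predictions <- function(model) {
  pred <- forward_reference(model)$pred
  if (!is.null(model$scaler)) {
    pred <- sweep(sweep(pred, 2, model$scaler$sd, `*`), 2,
                  model$scaler$mean, `+`)
  }
  colnames(pred) <- model$task_names
  pred
}

## ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_roc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

split_metrics_all <- function(pred_orig, records, idx, config) {
  y <- records$targets[idx, , drop = FALSE]
  mk <- records$target_mask[idx, , drop = FALSE]
  p <- pred_orig[idx, , drop = FALSE]
  if (config$task_type == "classification") {
    aucs <- vapply(seq_len(ncol(y)), function(j) {
      o <- mk[, j]
      if (!any(o)) return(NA_real_)
      a <- auc_roc(stats::plogis(p[o, j]), y[o, j])
      a
    }, 0)
    if (anyNA(aucs)) {
      warning("task(s) with a single class in this split skipped in AUC")
    }
    list(auc = mean(aucs, na.rm = TRUE))
  } else {
    d <- (p - y)[mk]
    list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
  }
}

## scalar metric used for early stopping (AUC up, RMSE down)
split_metric <- function(pred, records, idx, config, scaler) {
  if (!is.null(scaler)) {
    pred <- sweep(sweep(pred, 2, scaler$sd, `*`), 2, scaler$mean, `+`)
  }
  m <- split_metrics_all(pred, records, idx, config)
  if (config$task_type == "classification") m$auc else m$rmse
}

metrics_report <- function(model) {
  pred <- reference_predictions(model)
  splits <- list()
  for (s in c("train", "valid", "test")) {
    idx <- split_index(model$records, s)
    if (length(idx)) {
      splits[[s]] <- suppressWarnings(
        split_metrics_all(pred, model$records, idx, model$config))
    }
  }
  list(splits = splits, best_epoch = model$best_epoch,
       loss_trace = model$loss_trace)
}

#' Benchmark protocol: repeated scaffold-split runs
#'
#' Replicates the standard evaluation protocol for user-supplied
#' benchmark CSVs: several independent runs, each on a differently
#' seeded scaffold split, reporting the mean and standard deviation of
#' the test metric.
#'
#' @param records a [molecule_set()] (split assignments are overwritten).
#' @param config a [run_config()]; each run reuses it with the run's seed.
#' @param seeds integer vector, one scaffold split + training run per
#'   entry.
#' @param fractions train/valid/test fractions.
#' @return A list with per-run test metrics, their `mean` and `sd`, and
#'   the metric name.
#' @export
benchmark_protocol <- function(records, config, seeds = 0:2,
                               fractions = c(0.8, 0.1, 0.1)) {
  metric_name <- if (config$task_type == "classification") "auc" else "rmse"
  vals <- vapply(seeds, function(s) {
    rec <- scaffold_split(records, fractions, seed = s)
    cfg <- config
    cfg$seed <- as.integer(s)
    model <- train_model(rec, cfg)
    evaluate_model(model, "test")[[metric_name]]
  }, 0)
  list(metric = metric_name, runs = stats::setNames(vals, seeds),
       mean = mean(vals), sd = stats::sd(vals))
}

#' Evaluate a trained model on one split
#'
#' AUC-ROC (unweighted task mean, masked labels ignored) for
#' classification; RMSE and MAE on original target units for regression.
#' Tasks with a single observed class in the split are skipped with a
#' warning.
#'
#' @param model a trained `molgsl_model`.
#' @param split `"train"`, `"valid"` or `"test"`.
#' @return Named list of metrics.
#' @export
evaluate_model <- function(model, split = "test") {
  idx <- split_index(model$records, split)
  if (!length(idx)) stop_input("split '", split, "' is empty")
  split_metrics_all(reference_predictions(model), model$records, idx,
                    model$config)
}

#' Export final molecular embeddings
#'
#' Writes the refined molecular representations (one row per reference
#' molecule) with identifiers and observed labels as tab-separated text,
#' ready for external projection (t-SNE and friends).
#'
#' @param model a trained `molgsl_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(model, path) {
  H <- forward_reference(model)$H_final
  colnames(H) <- paste0("dim", seq_len(ncol(H)))
  tg <- model$records$targets
  tg[!model$records$target_mask] <- NA
  colnames(tg) <- paste0("label_", model$task_names)
  df <- cbind(data.frame(id = model$records$id), as.data.frame(H),
              as.data.frame(tg))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
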