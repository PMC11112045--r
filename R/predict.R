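#' Predict properties of new molecules
#'
#' The model is transductive: reference molecules (the population present
#' at training time) live on the similarity graph. New molecules are
#' attached inductively as receive-only nodes: each gets fingerprint
#' edges to every reference node (thresholded at the trained
#' `epsilon_tc`), participates in every refinement round by receiving
#' messages from reference nodes, but sends none back — so reference
#' predictions are untouched by construction, and a structural duplicate
#' of a reference molecule reproduces that molecule's prediction exactly
#' under the default normalized propagation.
#'
#' @param model a trained `molgsl_model`.
#' @param smiles character vector of new SMILES.
#' @return A data.frame with `smiles`, one prediction column per task
#'   (probabilities for classification, original units for regression),
#'   and an `error` column (`NA` rows carry the parse error message).
#' @export
predict_new <- function(model, smiles) {
  cfg <- model$config
  n_task <- length(model$task_names)
  out <- data.frame(smiles = as.character(smiles),
                    stringsAsFactors = FALSE)
  pred_mat <- matrix(NA_real_, length(smiles), n_task)
  errors <- rep(NA_character_, length(smiles))
  if (!length(smiles)) {
    out$error <- character(0)
    return(cbind(out, stats::setNames(as.data.frame(pred_mat),
                                      model$task_names)[0, , drop = FALSE]))
  }
  graphs <- featurize_molecules(smiles, model$scheme)
  ok <- which(!vapply(graphs, is.null, TRUE))
  errors[setdiff(seq_along(smiles), ok)] <- "unparseable SMILES"
  if (length(ok)) {
    gp <- as_gin_params(model$flat, cfg, model$scheme$dim)
    X_new_raw <- encode_molecules(graphs[ok], gp)
    st <- forward_reference(model)$X_stats
    X_new <- sweep(sweep(X_new_raw, 2, st$mean), 2, st$sd, `/`)
    H_new <- inductive_embed(model, graphs[ok], X_new)
    logits <- predict_head(H_new, model$flat$head_W, model$flat$head_b)
    if (cfg$task_type == "regression") {
      logits <- sweep(sweep(logits, 2, model$scaler$sd, `*`), 2,
                      model$scaler$mean, `+`)
    } else {
      logits <- stats::plogis(logits)
    }
    pred_mat[ok, ] <- logits
  }
  res <- stats::setNames(as.data.frame(pred_mat), model$task_names)
  out <- cbind(out, res)
  out$error <- errors
  out
}

## Receive-only inductive forward: new nodes aggregate from reference
## nodes (never among themselves, never back), mirroring the reference
## rounds stored by forward_reference().
inductive_embed <- function(model, graphs, X_new) {
  cfg <- model$config
  ref <- forward_reference(model)
  if (cfg$ablation_variant == "not_any") return(X_new)

  ## fingerprint rows against the reference set
  A0_new <- NULL
  if (cfg$ablation_variant %in% c("full", "only_a0", "no_gsl_loss")) {
    fp_new <- fingerprint_matrix(graphs, cfg$radius, cfg$n_bits)$bits
    ref_graphs <- featurize_molecules(model$records$smiles, model$scheme)
    fp_ref <- fingerprint_matrix(ref_graphs, cfg$radius, cfg$n_bits)$bits
    inter <- fp_new %*% t(fp_ref)
    uni <- outer(rowSums(fp_new), rowSums(fp_ref), `+`) - inter
    S0 <- ifelse(uni > 0, inter / uni, 0)
    A0_new <- ifelse(S0 >= cfg$epsilon_tc, S0, 0)
  }

  prop_new <- function(fused_new, round_t) {
    ## reference per-layer states of this round, starting at X_r
    H_ref_layers <- c(list(ref$X_r), ref$rounds[[round_t]]$H_layers)
    if (cfg$normalize_adjacency) {
      d_new <- rowSums(fused_new)
      d_ref <- 1 + rowSums(ref$rounds[[round_t]]$fused)
      s_new <- ifelse(d_new > 0, 1 / sqrt(d_new), 0)
      Nrow <- fused_new * outer(s_new, 1 / sqrt(d_ref))
    } else Nrow <- fused_new
    H <- X_new
    for (l in seq_len(cfg$L)) {
      H <- pmax((Nrow %*% H_ref_layers[[l]]) %*%
                  model$flat[[paste0("inter_W_", l)]], 0)
    }
    H
  }

  if (cfg$ablation_variant == "only_a0") {
    return(prop_new(A0_new, 1L))
  }

  W_persp <- do.call(rbind, lapply(seq_len(cfg$m), function(q) {
    model$flat[[paste0("persp_w_", q)]]
  }))
  cross_cosine <- function(Hn, Hr) {
    S <- 0
    for (p in seq_len(nrow(W_persp))) {
      a <- sweep(Hn, 2, W_persp[p, ], `*`)
      b <- sweep(Hr, 2, W_persp[p, ], `*`)
      ra <- sqrt(rowSums(a^2)); rb <- sqrt(rowSums(b^2))
      a <- a / ifelse(ra > 0, ra, 1); b <- b / ifelse(rb > 0, rb, 1)
      S <- S + tcrossprod(a, b)
    }
    S / nrow(W_persp)
  }

  la <- if (cfg$ablation_variant == "only_gsl") 0 else cfg$lambda
  H_prev_new <- X_new
  H_prev_ref <- ref$X_r
  A1_new <- NULL
  H <- X_new
  for (t in seq_len(cfg$T_rounds)) {
    S <- cross_cosine(H_prev_new, H_prev_ref)
    At_new <- ifelse(S >= cfg$epsilon_sparsify, S, 0)
    if (t == 1L) A1_new <- At_new
    fused_new <- (1 - la) * (cfg$eta * At_new + (1 - cfg$eta) * A1_new)
    if (la > 0) fused_new <- fused_new + la * A0_new
    H <- prop_new(fused_new, t)
    H_prev_new <- H
    H_prev_ref <- ref$rounds[[t]]$H_layers[[cfg$L]]
  }
  H
}

#' Save / load a trained model
#'
#' The checkpoint bundles every learnable weight together with the run
#' configuration, featurization scheme, fingerprint settings, target
#' scaler and the reference molecule order, so predictions are exactly
#' reproducible after reload.
#'
#' @param model a trained `molgsl_model`.
#' @param path file path (RDS).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  payload <- model[setdiff(names(model), c("cache", "batch"))]
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  graphs <- featurize_molecules(payload$records$smiles, payload$scheme)
  payload$batch <- build_batch(graphs, payload$config$readout_mode)
  payload$cache <- new.env(parent = emptyenv())
  structure(payload, class = "molgsl_model")
}
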