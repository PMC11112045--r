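## Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_records <- function(n = 40, task = "regression", seed = 7,
                            noise_sd = 0.2, ac = 0) {
  memo(sprintf("rec_%d_%s_%d_%g_%d", n, task, seed, noise_sd, ac), {
    generate_dataset(synthetic_spec(
      n_molecules = n, n_clusters = 4, task_type = task,
      noise_sd = noise_sd, flip_prob = 0, ac_pair_count = ac, seed = seed))
  })
}

fixture_fps <- function(smiles, radius = 2, n_bits = 2048) {
  memo(paste0("fps_", substr(paste(smiles, collapse = ""), 1, 60),
              length(smiles), radius, n_bits), {
    lapply(smiles, compute_fingerprint, radius = radius, n_bits = n_bits)
  })
}

## a small MoleculeNet-dialect CSV on disk
fixture_csv <- function(dir, rows) {
  path <- file.path(dir, "mini.csv")
  writeLines(rows, path)
  path
}

## random bit-vector fingerprint
random_fp <- function(n_bits = 64, density = 0.3, radius = 2L) {
  structure(list(bits = stats::runif(n_bits) < density,
                 radius = radius, n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

quick_config <- function(task = "regression", epochs = 30L,
                         patience = 30L, ...) {
  run_config(task_type = task, K = 2, hidden_dim = 16, m = 2, L = 2,
             T_rounds = 2, epochs = epochs, patience = patience,
             learning_rate = 5e-3, seed = 1, ...)
}
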