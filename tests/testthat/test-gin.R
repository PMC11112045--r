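identity_layer <- function(eps = 0) list(eps = eps, W1 = NULL)

test_that("gin_layer aggregation matches hand evaluation", {
  ## star graph: center node 1 linked to 2, 3, 4
  g <- structure(list(node_features = matrix(0, 4, 1),
                      edges = cbind(1L, 2:4), bond_orders = rep(1, 3),
                      elements = rep("C", 4), charges = rep(0L, 4),
                      aromatic = rep(FALSE, 4), n_v = 4L, n_e = 3L,
                      smiles = NA), class = "mol_graph")
  h <- matrix(c(0, 1, 2, 3), ncol = 1)
  out <- gin_layer(g, h, identity_layer(eps = 0))
  expect_equal(out[1, 1], 6)           # 0 + (1+2+3)
  expect_equal(out[2, 1], 1)           # leaf keeps self + center(0)
  ## isolated node: empty neighbour sum
  iso <- structure(list(node_features = matrix(0, 1, 1),
                        edges = matrix(integer(0), ncol = 2),
                        bond_orders = numeric(0), elements = "C",
                        charges = 0L, aromatic = FALSE, n_v = 1L,
                        n_e = 0L, smiles = NA), class = "mol_graph")
  expect_equal(gin_layer(iso, matrix(5), identity_layer(0)), matrix(5))
  expect_equal(gin_layer(iso, matrix(5), identity_layer(1)), matrix(10))
})

test_that("gin_layer equals the per-node loop oracle on random graphs", {
  set.seed(21)
  for (k in seq_len(25)) {
    g <- random_mol_graph(sample(2:6, 1), p_edge = 0.5, dim = 3)
    h <- matrix(rnorm(g$n_v * 3), g$n_v, 3)
    eps <- runif(1, -0.5, 0.5)
    expect_equal(gin_layer(g, h, identity_layer(eps)),
                 oracle_gin_aggregate(g, h, eps))
  }
})

test_that("gin_layer validates shapes", {
  g <- random_mol_graph(3)
  expect_error(gin_layer(g, matrix(0, 2, 3), identity_layer()),
               "one row per node")
})

test_that("readout pools per layer, concatenates and projects", {
  one <- list(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  expect_equal(readout(one, "sum"), c(1, 2, 3, 4, 5, 6))
  ## two equal nodes, mean pooling: pooled vector equals either node's
  two <- list(rbind(c(1, 2), c(1, 2)))
  expect_equal(readout(two, "mean"), c(1, 2))
  expect_equal(readout(two, "sum"), c(2, 4))
  W <- matrix(rnorm(12), 6, 2)
  expect_equal(readout(one, "sum", W, c(1, 1)),
               as.numeric(c(1:6) %*% W + c(1, 1)))
  expect_error(readout(list(), "sum"), "empty")
})

test_that("readout is permutation-invariant over node order", {
  set.seed(31)
  params <- gin_params(atom_dim = 4, hidden_dim = 8, K = 2, seed = 2)
  g <- random_mol_graph(6, dim = 4)
  base <- encode_molecules(list(g), params)
  for (k in seq_len(50)) {
    perm <- sample(g$n_v)
    inv <- order(perm)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    gp$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
    permuted <- encode_molecules(list(gp), params)
    expect_lt(max(abs(base - permuted)), 1e-5)
  }
})

test_that("encode_molecules is deterministic and batch-independent", {
  rec <- fixture_records(12)
  graphs <- featurize_molecules(rec$smiles)
  params <- gin_params(atom_dim = ncol(graphs[[1]]$node_features),
                       hidden_dim = 16, K = 2, seed = 3)
  full <- encode_molecules(graphs, params)
  expect_true(all(is.finite(full)))
  ## duplicate molecule -> identical rows
  dup <- encode_molecules(c(graphs[1], graphs[1]), params)
  expect_identical(dup[1, ], dup[2, ])
  ## batch size 1 vs full batch
  single <- encode_molecules(graphs, params, batch_size = 1)
  expect_lt(max(abs(full - single)), 1e-5)
  ## bitwise stability across two runs
  expect_identical(full, encode_molecules(graphs, params))
})

test_that("tape-based GIN matches the plain encoder", {
  rec <- fixture_records(12)
  graphs <- featurize_molecules(rec$smiles)
  cfg <- quick_config(ablation_variant = "not_any")
  scheme <- featurization_scheme()
  flat <- molgsl:::init_model_params(cfg, scheme$dim, 1)
  batch <- molgsl:::build_batch(graphs, cfg$readout_mode)
  data <- list(y = matrix(0, length(graphs), 1),
               mask = matrix(0, length(graphs), 1),
               train_idx = integer(0), pairs = matrix(integer(0), ncol = 2))
  fw <- molgsl:::model_forward(flat, cfg, batch, NULL, data,
                               with_grad = FALSE)
  tape_Xraw <- molgsl:::tp_val(fw$tape, fw$X_raw)
  plain <- encode_molecules(graphs,
                            molgsl:::as_gin_params(flat, cfg, scheme$dim))
  expect_equal(tape_Xraw, plain, tolerance = 1e-10, ignore_attr = TRUE)
})
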