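test_that("generation is seeded and deterministic", {
  spec <- synthetic_spec(n_molecules = 30, n_clusters = 3, seed = 9)
  r1 <- generate_dataset(spec)
  r2 <- generate_dataset(spec)
  expect_identical(r1$smiles, r2$smiles)
  expect_identical(r1$targets, r2$targets)
  r3 <- generate_dataset(synthetic_spec(n_molecules = 30, n_clusters = 3,
                                        seed = 10))
  expect_false(identical(r1$smiles, r3$smiles))
})

test_that("noise-free targets are an exact function of cluster and substituent", {
  spec <- synthetic_spec(n_molecules = 24, n_clusters = 3,
                         task_type = "regression", noise_sd = 0,
                         seed = 2)
  rec <- generate_dataset(spec)
  truth <- attr(rec, "truth")
  expect_equal(rec$targets[, 1], truth$effect)
  specc <- synthetic_spec(n_molecules = 24, n_clusters = 3,
                          task_type = "classification", flip_prob = 0,
                          seed = 2)
  recc <- generate_dataset(specc)
  truthc <- attr(recc, "truth")
  expect_equal(recc$targets[, 1], as.numeric(truthc$effect > 0))
})

test_that("infeasible specifications are rejected", {
  expect_error(synthetic_spec(n_molecules = 1e5, n_clusters = 2),
               "infeasible")
  expect_error(synthetic_spec(n_clusters = 1), "n_clusters")
  expect_error(synthetic_spec(flip_prob = 0.6), "flip_prob")
  expect_error(synthetic_spec(n_clusters = 99), "at most")
})

test_that("within-cluster similarity exceeds between-cluster similarity", {
  rec <- generate_dataset(synthetic_spec(n_molecules = 100, n_clusters = 5,
                                         seed = 4))
  truth <- attr(rec, "truth")
  fps <- fixture_fps(rec$smiles)
  n <- length(fps)
  within <- c(); between <- c()
  set.seed(1)
  for (k in seq_len(600)) {
    ij <- sample(n, 2)
    v <- oracle_tanimoto(fps[[ij[1]]]$bits, fps[[ij[2]]]$bits)
    if (truth$cluster[ij[1]] == truth$cluster[ij[2]]) {
      within <- c(within, v)
    } else between <- c(between, v)
  }
  expect_gt(mean(within), mean(between))
})

test_that("planted structure is recoverable by nearest-centroid assignment", {
  rec <- generate_dataset(synthetic_spec(n_molecules = 60, n_clusters = 4,
                                         noise_sd = 0, seed = 6))
  truth <- attr(rec, "truth")
  fps <- fixture_fps(rec$smiles)
  B <- do.call(rbind, lapply(fps, function(f) as.numeric(f$bits)))
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(B)), truth$cluster),
                                     function(ix) colMeans(B[ix, ])))
  sim <- B %*% t(centroids) /
    outer(sqrt(rowSums(B^2)), sqrt(rowSums(centroids^2)))
  assigned <- max.col(sim)
  expect_equal(assigned, truth$cluster)
})

test_that("activity-cliff pairs are similar in structure, discordant in target", {
  rec <- generate_dataset(synthetic_spec(n_molecules = 40, n_clusters = 4,
                                         task_type = "regression",
                                         noise_sd = 0, ac_pair_count = 3,
                                         seed = 8))
  truth <- attr(rec, "truth")
  expect_equal(sum(truth$activity_cliff), 6)  # 3 anchors + 3 partners
  pairs <- which(!is.na(truth$ac_partner) & seq_along(truth$ac_partner) <
                   truth$ac_partner)
  expect_length(pairs, 3)
  for (a in pairs) {
    p <- truth$ac_partner[a]
    tc <- tanimoto(compute_fingerprint(rec$smiles[a]),
                   compute_fingerprint(rec$smiles[p]))
    expect_gte(tc, 0.7)
    ## discordance beyond the full spread of cluster means
    expect_gt(abs(rec$targets[a, 1] - rec$targets[p, 1]), 2)
  }
})

test_that("the micro-fixture satisfies its construction contracts", {
  fx <- micro_fixture()
  expect_true(isSymmetric(fx$A0))
  expect_equal(diag(fx$A0), rep(0, 4))
  expect_true(all(fx$A0 >= 0 & fx$A0 <= 1))
  expect_equal(nrow(fx$X_r), 4)
})
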