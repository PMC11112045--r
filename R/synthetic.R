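## Core scaffolds and substituents for synthetic compound sets. Cores end
## at a ring-closure atom, so pasting a substituent SMILES after a core
## always yields a valid molecule.
SCAFFOLD_CORES <- c(
  "c1ccccc1",          # benzene
  "c1ccncc1",          # pyridine
  "C1CCCCC1",          # cyclohexane
  "c1ccc2ccccc2c1",    # naphthalene
  "c1ccoc1",           # furan
  "c1ccsc1",           # thiophene
  "C1CCNCC1",          # piperidine
  "c1cncnc1",          # pyrimidine
  "C1CCOC1",           # tetrahydrofuran
  "C1CCNC1"            # pyrrolidine
)

SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CO", "CCO", "CCCO", "CN", "CCN",
  "CCCN", "CCl", "CCCl", "CF", "CCF", "CBr", "C(C)C", "CC(C)C", "COC",
  "CCOC", "C(F)F", "CCCCO", "CCCCN", "CCCCCC", "CCOCC", "CCNC", "CCCF"
)

## Larger decoration pool: single substituents plus concatenated chains
## (all remain valid SMILES suffixes on a ring-closure atom).
decoration_pool <- function() {
  unique(c(SUBSTITUENTS,
           as.vector(outer(SUBSTITUENTS, SUBSTITUENTS, paste0))))
}

heavy_count <- function(smiles) {
  nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", smiles)))
}

#' Specification of a synthetic compound set
#'
#' Describes a seeded synthetic dataset: `n_clusters` scaffold families
#' (members of a family share a core and differ by small substituents, so
#' fingerprint similarity is informative about family membership), a known
#' property function (family mean plus a substituent-size effect), noise,
#' and optionally planted activity-cliff pairs — structurally
#' near-duplicate molecules assigned maximally discordant targets.
#'
#' @param n_molecules total number of molecules.
#' @param n_clusters number of scaffold families (`>= 2`, at most
#'   `length(SCAFFOLD_CORES)`).
#' @param task_type `"classification"` or `"regression"`.
#' @param noise_sd Gaussian target noise (regression).
#' @param flip_prob label flip probability in `[0, 0.5)` (classification).
#' @param ac_pair_count planted activity-cliff pairs.
#' @param seed master seed; all randomness flows from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 100L, n_clusters = 5L,
                           task_type = c("regression", "classification"),
                           noise_sd = 0.3, flip_prob = 0.05,
                           ac_pair_count = 0L, seed = 0L) {
  task_type <- match.arg(task_type)
  stopifnot(n_clusters >= 2L, noise_sd >= 0, ac_pair_count >= 0L)
  if (flip_prob < 0 || flip_prob >= 0.5) {
    stop_input("flip_prob must be in [0, 0.5)")
  }
  if (n_clusters > length(SCAFFOLD_CORES)) {
    stop_input("at most ", length(SCAFFOLD_CORES), " clusters supported")
  }
  if (n_clusters * length(decoration_pool()) < n_molecules) {
    stop_input("infeasible spec: clusters x decorations < n_molecules")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_clusters = as.integer(n_clusters),
                 task_type = task_type, noise_sd = noise_sd,
                 flip_prob = flip_prob,
                 ac_pair_count = as.integer(ac_pair_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic compound dataset
#'
#' Builds molecules by decorating scaffold cores with enumerated
#' substituents. The regression target is `cluster mean + 0.1 *
#' substituent heavy-atom count + Gaussian noise`; the classification
#' label thresholds the noise-free value at the overall mean with seeded
#' label flips. Activity-cliff pairs are planted by appending a
#' near-duplicate (substituent extended by one carbon) of a randomly
#' chosen molecule with a maximally discordant target; if the
#' near-duplicate's Tanimoto similarity to its partner falls below 0.7 an
#' exact structural duplicate is used instead.
#'
#' @param spec a [synthetic_spec()].
#' @return A [molecule_set()] with a `truth` attribute (`data.frame` with
#'   cluster id, planted noise-free effect and activity-cliff flag).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_base <- spec$n_molecules - spec$ac_pair_count
  if (n_base < spec$n_clusters) {
    stop_input("too many activity-cliff pairs for the requested size")
  }
  cluster_means <- seq(-2, 2, length.out = spec$n_clusters)
  with_seed(derive_seed(spec$seed, 11L), {
    cluster <- rep(seq_len(spec$n_clusters), length.out = n_base)
    ## per cluster, distinct decorations (small substituents first)
    pool <- decoration_pool()
    sub_idx <- integer(n_base)
    for (cl in seq_len(spec$n_clusters)) {
      ix <- which(cluster == cl)
      k <- length(ix)
      cand <- if (k <= length(SUBSTITUENTS)) length(SUBSTITUENTS) else
        length(pool)
      sub_idx[ix] <- sample(cand, k)
    }
    smiles <- paste0(SCAFFOLD_CORES[cluster], pool[sub_idx])
    effect <- cluster_means[cluster] +
      0.1 * vapply(pool[sub_idx], heavy_count, 0L)
    ac_flag <- rep(FALSE, n_base)
    ac_partner <- rep(NA_integer_, n_base)

    if (spec$ac_pair_count > 0L) {
      anchors <- sample(n_base, spec$ac_pair_count)
      for (a in anchors) {
        partner <- paste0(smiles[a], "C")  # one-carbon extension
        tc <- tanimoto(compute_fingerprint(partner),
                       compute_fingerprint(smiles[a]))
        if (tc < 0.7) partner <- smiles[a]  # exact duplicate fallback
        smiles <- c(smiles, partner)
        cluster <- c(cluster, cluster[a])
        ## maximal discordance with the anchor's planted value
        flipped <- if (effect[a] > mean(range(cluster_means))) {
          min(cluster_means) - 0.5
        } else max(cluster_means) + 0.5
        effect <- c(effect, flipped)
        ac_flag[a] <- TRUE
        ac_flag <- c(ac_flag, TRUE)
        ac_partner[a] <- length(smiles)
        ac_partner <- c(ac_partner, a)
      }
    }
    n <- length(smiles)
    if (spec$task_type == "regression") {
      y <- effect + stats::rnorm(n, 0, spec$noise_sd)
    } else {
      y <- as.numeric(effect > mean(cluster_means))
      flips <- stats::runif(n) < spec$flip_prob
      y[flips] <- 1 - y[flips]
    }
    records <- molecule_set(sprintf("syn%04d", seq_len(n)), smiles,
                            matrix(y, ncol = 1,
                                   dimnames = list(NULL, "target")))
    attr(records, "truth") <- data.frame(
      id = records$id, cluster = cluster, effect = effect,
      activity_cliff = ac_flag, ac_partner = ac_partner)
    records
  })
}

#' Hand-specified micro-fixture for the structure learner
#'
#' Four molecules with a hand-set embedding matrix, a hand-set initial
#' adjacency, single-perspective unit metric weights and identity
#' propagation weights, small enough that every refinement step can be
#' followed with pencil and paper (the test suite walks the full trace
#' against an independent straight-line evaluation).
#'
#' @return A list: `smiles`, `X_r`, `A0`, `labels`, `train_idx`, and
#'   `params` (`w`, `W_list`, `lambda`, `eta`, `epsilon_sparsify`,
#'   `T_rounds`, `normalize`).
#' @export
micro_fixture <- function() {
  X_r <- rbind(c(1.0, 0.0),
               c(0.9, 0.2),
               c(0.7, 0.4),
               c(0.0, 1.0))
  A0 <- rbind(c(0.0, 0.6, 0.5, 0.0),
              c(0.6, 0.0, 0.7, 0.0),
              c(0.5, 0.7, 0.0, 0.2),
              c(0.0, 0.0, 0.2, 0.0))
  list(smiles = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1"),
       X_r = X_r, A0 = A0, labels = c(1, 1, 0, 0), train_idx = 1:3,
       params = list(w = matrix(1, 1, 2), W_list = list(diag(2)),
                     lambda = 0.8, eta = 0.5, epsilon_sparsify = 0.1,
                     T_rounds = 2L, normalize = FALSE))
}
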