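#' Bemis-Murcko scaffold key of a molecule
#'
#' Strips all acyclic side chains by repeatedly deleting degree-one atoms,
#' leaving the ring systems plus the linkers that connect them, then hashes
#' a canonical certificate of that subgraph (BLISS canonical labelling with
#' atoms coloured by element/aromaticity and bond orders encoded by edge
#' subdivision). Two molecules share a key exactly when their scaffolds are
#' isomorphic as labelled graphs; fully acyclic molecules share the empty
#' scaffold `""`.
#'
#' @param smiles a single SMILES string.
#' @return A character scaffold key.
#' @export
murcko_scaffold_key <- function(smiles) {
  g <- featurize_molecule(smiles)
  scaffold_key_from_graph(g)
}

scaffold_key_from_graph <- function(g) {
  keep <- rep(TRUE, g$n_v)
  edges <- g$edges
  orders <- g$bond_orders
  repeat {
    deg <- tabulate(c(edges[keep[edges[, 1]] & keep[edges[, 2]], 1],
                      edges[keep[edges[, 1]] & keep[edges[, 2]], 2]),
                    nbins = g$n_v)
    leaves <- which(keep & deg <= 1L)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
  }
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- match(seq_len(g$n_v), idx)
  e_keep <- keep[edges[, 1]] & keep[edges[, 2]]
  e <- cbind(remap[edges[e_keep, 1]], remap[edges[e_keep, 2]])
  ord <- orders[e_keep]
  arom_edge <- g$aromatic[edges[e_keep, 1]] & g$aromatic[edges[e_keep, 2]]
  ord[arom_edge] <- 4
  n <- length(idx)
  ## subdivide each bond with a node coloured by bond order so the (vertex
  ## coloured) canonical labelling also distinguishes bond types
  n_edge_nodes <- nrow(e)
  edge_nodes <- n + seq_len(n_edge_nodes)
  el <- rbind(cbind(e[, 1], edge_nodes), cbind(e[, 2], edge_nodes))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  atom_color <- match(g$elements[idx], names(DEFAULT_VALENCE),
                      nomatch = 0L) * 2L + as.integer(g$aromatic[idx])
  colors <- c(atom_color, 100L + as.integer(ord))
  cp <- igraph::canonical_permutation(ig, colors = colors)
  igc <- igraph::permute(ig, cp$labeling)
  ce <- igraph::as_edgelist(igc)
  ce <- cbind(pmin(ce[, 1], ce[, 2]), pmax(ce[, 1], ce[, 2]))
  ce <- ce[order(ce[, 1], ce[, 2]), , drop = FALSE]
  cert <- paste(c(n, n_edge_nodes, colors[order(cp$labeling)], t(ce)),
                collapse = ",")
  sprintf("S%d_%s", n, format(hash_ints(utf8ToInt(cert)), scientific = FALSE))
}

#' Scaffold split of a molecule set
#'
#' Assigns molecules to train/valid/test so that molecules sharing a
#' Bemis-Murcko scaffold never straddle splits. Follows the balanced
#' scaffold-split procedure: scaffold groups larger than half the target
#' valid (or test) size go to train first, the remaining groups are shuffled
#' with the given seed and greedily assigned to whichever split is furthest
#' below its target.
#'
#' @param records a [molecule_set()].
#' @param fractions train/valid/test fractions, positive, summing to 1.
#' @param seed integer seed controlling the shuffle of scaffold groups.
#' @param balanced if `FALSE`, groups are assigned in decreasing size order
#'   (deterministic in group sizes) instead of seed-shuffled.
#' @return `records` with the `split` field assigned.
#' @export
scaffold_split <- function(records, fractions = c(0.8, 0.1, 0.1),
                           seed = 0L, balanced = TRUE) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_input("fractions must be positive and sum to 1")
  }
  graphs <- featurize_molecules(records$smiles)
  if (any(vapply(graphs, is.null, TRUE))) {
    stop_input("scaffold_split requires all SMILES to be parseable")
  }
  keys <- vapply(graphs, scaffold_key_from_graph, "")
  groups <- split(seq_along(keys), keys)
  n <- length(records)
  if (length(groups) < 3L) {
    warning("fewer than 3 distinct scaffolds; assigning all molecules to train")
    records$split <- rep("train", n)
    return(records)
  }
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  sizes <- lengths(groups)
  ## groups too large for the small splits go straight to train;
  ## singletons always stay assignable
  big <- sizes > pmax(1, max(n_valid, n_test) / 2)
  assign_order <- if (balanced) {
    c(which(big)[order(-sizes[big])],
      with_seed(seed, sample(which(!big))))
  } else {
    order(-sizes)
  }
  split <- rep("train", n)
  cnt <- c(train = 0L, valid = 0L, test = 0L)
  target <- c(train = n - n_valid - n_test, valid = n_valid, test = n_test)
  for (gi in assign_order) {
    members <- groups[[gi]]
    dest <- if (balanced && big[gi]) "train" else {
      deficit <- target - cnt
      ## prefer filling valid/test; ties (and no deficit) go to train
      if (deficit["valid"] >= length(members) &&
          deficit["valid"] >= deficit["test"]) "valid"
      else if (deficit["test"] >= length(members)) "test"
      else "train"
    }
    split[members] <- dest
    cnt[dest] <- cnt[dest] + length(members)
  }
  ## every scaffold group can be too large for the small splits (few,
  ## coarse scaffolds); fall back to whole-group assignment of the two
  ## smallest groups so valid and test are never empty
  if (!any(split == "valid") || !any(split == "test")) {
    split <- rep("train", n)
    bysize <- order(lengths(groups))
    split[groups[[bysize[1]]]] <- "valid"
    split[groups[[bysize[2]]]] <- "test"
    warning("coarse scaffold structure: assigned one whole scaffold ",
            "group each to valid and test")
  }
  records$split <- split
  records
}

#' Random (record-level) split of a molecule set
#'
#' Seeded uniform assignment of individual molecules to train/valid/test.
#' Unlike [scaffold_split()], members of one scaffold may straddle splits;
#' use it when held-out molecules should retain structurally similar
#' neighbours in the similarity graph.
#'
#' @inheritParams scaffold_split
#' @return `records` with the `split` field assigned.
#' @export
random_split <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(length(fractions) == 3L)
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_input("fractions must be positive and sum to 1")
  }
  n <- length(records)
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- with_seed(seed, sample(n))
  split <- rep("train", n)
  split[perm[seq_len(n_valid)]] <- "valid"
  split[perm[n_valid + seq_len(n_test)]] <- "test"
  records$split <- split
  records
}
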