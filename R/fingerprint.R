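#' Circular (Morgan/ECFP-style) fingerprints
#'
#' Computes a fixed-length binary substructure fingerprint by iteratively
#' hashing atom environments: each atom starts from an invariant built from
#' its element, degree, charge, hydrogen count, aromaticity and ring
#' membership; `radius` rounds of neighbour hashing grow the environments,
#' and every environment identifier from rounds `0..radius` is folded into
#' `n_bits` positions. Aromatic bonds share one bond-type code so the bits
#' do not depend on an arbitrary Kekule assignment; SMILES are
#' canonicalized before featurization, so equivalent writings of one
#' molecule give identical bits.
#'
#' @param smiles a single SMILES string.
#' @param radius environment radius in bonds (ECFP4 corresponds to 2).
#' @param n_bits fingerprint length.
#' @return A `fingerprint` object: logical `bits` of length `n_bits`, plus
#'   `radius` and `n_bits`.
#' @export
compute_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (radius < 0L) stop_input("radius must be >= 0")
  if (n_bits < 1L) stop_input("n_bits must be >= 1")
  g <- featurize_molecule(smiles)
  fingerprint_from_graph(g, radius, n_bits)
}

fingerprint_from_graph <- function(g, radius = 2L, n_bits = 2048L) {
  n_v <- g$n_v
  ## bond type code: aromatic bonds collapse to one class
  edge_arom <- if (g$n_e > 0L) {
    g$aromatic[g$edges[, 1]] & g$aromatic[g$edges[, 2]]
  } else logical(0)
  bond_code <- ifelse(edge_arom, 4L, g$bond_orders)
  nbrs <- vector("list", n_v)
  if (g$n_e > 0L) {
    for (e in seq_len(g$n_e)) {
      i <- g$edges[e, 1]; j <- g$edges[e, 2]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, bond_code[e]))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, bond_code[e]))
    }
  }
  deg <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  in_ring <- atom_in_ring(g)
  inv <- vapply(seq_len(n_v), function(v) {
    el <- match(g$elements[v], names(DEFAULT_VALENCE), nomatch = 0L)
    inc <- if (deg[v] > 0L) sum(g$bond_orders[g$edges[, 1] == v |
                                                g$edges[, 2] == v]) else 0
    n_h <- implicit_h(g$elements[v], g$charges[v], inc)
    hash_ints(c(el, deg[v], g$charges[v] + 8L, as.integer(g$aromatic[v]),
                as.integer(in_ring[v]), n_h,
                as.integer(round(inc * 2))))
  }, 0)
  ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- vapply(seq_len(n_v), function(v) {
      if (deg[v] == 0L) return(hash_ints(c(r, inv[v])))
      nb <- nbrs[[v]]
      pairs <- nb[order(nb[, 2], inv[nb[, 1]]), , drop = FALSE]
      hash_ints(c(r, inv[v], as.vector(t(cbind(pairs[, 2],
                                               inv[pairs[, 1]])))))
    }, 0)
    inv <- new_inv
    ids <- c(ids, inv)
  }
  bits <- logical(n_bits)
  bits[(ids %% n_bits) + 1L] <- TRUE
  structure(list(bits = bits, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

atom_in_ring <- function(g) {
  if (g$n_e == 0L) return(rep(FALSE, g$n_v))
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  if (igraph::vcount(ig) < g$n_v) {
    ig <- igraph::add_vertices(ig, g$n_v - igraph::vcount(ig))
  }
  ## an edge lies on a cycle iff it is not a bridge
  br <- igraph::bridges(ig)
  cyc <- setdiff(seq_len(g$n_e), br)
  res <- rep(FALSE, g$n_v)
  res[as.vector(g$edges[cyc, , drop = FALSE])] <- TRUE
  res
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> radius %d, %d bits, %d set\n",
              x$radius, x$n_bits, sum(x$bits)))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits. Two all-zero
#' fingerprints have no evidence of similarity and score 0 (with a
#' warning).
#'
#' @param a,b comparable [compute_fingerprint()] objects (same radius and
#'   length).
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!inherits(a, "fingerprint") || !inherits(b, "fingerprint")) {
    stop_input("tanimoto() expects fingerprint objects")
  }
  if (a$radius != b$radius || a$n_bits != b$n_bits) {
    stop_input("fingerprints are not comparable (radius or n_bits differ)")
  }
  u <- sum(a$bits | b$bits)
  if (u == 0L) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a$bits & b$bits) / u
}

## Stack fingerprints of many molecules as a 0/1 matrix (rows = molecules).
fingerprint_matrix <- function(graphs, radius = 2L, n_bits = 2048L) {
  fps <- lapply(graphs, fingerprint_from_graph, radius = radius,
                n_bits = n_bits)
  list(bits = do.call(rbind, lapply(fps, function(f) as.numeric(f$bits))),
       fingerprints = fps)
}
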