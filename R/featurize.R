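#' Atom featurization scheme
#'
#' Describes how heavy atoms are encoded as feature vectors: element one-hot
#' over a fixed vocabulary (with an "other" bucket), heavy-atom degree
#' one-hot, formal charge, an aromaticity flag, implicit hydrogen count
#' one-hot, and a hybridization one-hot. Bond features are deliberately not
#' used: the atom-level encoder is a plain GIN without edge-conditioned
#' message passing.
#'
#' @param elements element vocabulary; anything else falls into "other".
#' @param max_degree degrees `0..max_degree` get their own one-hot slot.
#' @param max_h implicit hydrogen counts `0..max_h` get their own slot.
#' @return A `featurization_scheme` list with a `dim` field.
#' @export
featurization_scheme <- function(elements = c("B", "C", "N", "O", "F", "Si",
                                              "P", "S", "Cl", "Br", "I",
                                              "Se"),
                                 max_degree = 5L, max_h = 4L) {
  hyb <- c("sp", "sp2", "sp3", "other")
  dim <- (length(elements) + 1L) + (max_degree + 1L) + 1L + 1L +
    (max_h + 1L) + length(hyb)
  structure(list(elements = elements, max_degree = max_degree,
                 max_h = max_h, hybridizations = hyb, dim = dim),
            class = "featurization_scheme")
}

## Default valence used to infer implicit hydrogen counts from kekulized
## bond orders; charge shifts valence for N/P (cations) and O/S (anions).
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Br = 1, I = 1, Se = 2)

implicit_h <- function(element, charge, order_sum) {
  val <- unname(DEFAULT_VALENCE[element])
  if (is.na(val)) return(0L)
  val <- switch(element,
                N = , P = val + charge,
                O = , S = , Se = val + charge,
                C = val - abs(charge),
                val)
  max(0L, as.integer(round(val - order_sum)))
}

## Split multi-record SDF text into per-molecule blocks.
split_sdf_text <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) lines[s:(e - 1L)], starts, ends)
}

## Parse one V2000 molfile block into atoms/bonds. ChemmineR's reader drops
## single-atom records, so the counts/atom/bond lines are read directly;
## aromatic ring perception is delegated to ChemmineR below.
parse_molfile_block <- function(lines) {
  counts <- lines[4]
  n_v <- as.integer(substr(counts, 1, 3))
  n_e <- as.integer(substr(counts, 4, 6))
  if (is.na(n_v) || n_v < 1L) return(NULL)
  atom_lines <- lines[5:(4 + n_v)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(n_v)
  if (n_e > 0L) {
    bond_lines <- lines[(5 + n_v):(4 + n_v + n_e)]
    edges <- cbind(as.integer(substr(bond_lines, 1, 3)),
                   as.integer(substr(bond_lines, 4, 6)))
    orders <- as.integer(substr(bond_lines, 7, 9))
  } else {
    edges <- matrix(integer(0), ncol = 2)
    orders <- numeric(0)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charges[f[2 * j]] <- f[2 * j + 1]
  }
  list(elements = elements, charges = charges, edges = edges,
       orders = orders, n_v = n_v, n_e = n_e)
}

## Aromatic atom detection for one molfile block via ChemmineR ring
## perception. Returns a logical vector over atoms.
aromatic_atoms_of <- function(lines, n_v) {
  arom <- rep(FALSE, n_v)
  if (n_v < 3L) return(arom)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(c(lines, "$$$$"))),
    error = function(e) NULL)
  if (is.null(sdf)) return(arom)
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE,
                                      inner = FALSE)),
    error = function(e) NULL)
  if (is.null(r) || !length(r$RINGS)) return(arom)
  for (k in seq_along(r$RINGS)) {
    if (isTRUE(r$AROMATIC[[k]])) {
      idx <- as.integer(sub(".*_", "", r$RINGS[[k]]))
      arom[idx] <- TRUE
    }
  }
  arom
}

atom_feature_row <- function(scheme, element, degree, charge, aromatic,
                             n_h, hybrid) {
  el <- c(scheme$elements, "other")
  v <- numeric(scheme$dim)
  i <- 0L
  v[i + match(element, el, nomatch = length(el))] <- 1
  i <- i + length(el)
  v[i + min(degree, scheme$max_degree) + 1L] <- 1
  i <- i + scheme$max_degree + 1L
  v[i + 1L] <- charge
  i <- i + 1L
  v[i + 1L] <- as.numeric(aromatic)
  i <- i + 1L
  v[i + min(n_h, scheme$max_h) + 1L] <- 1
  i <- i + scheme$max_h + 1L
  v[i + match(hybrid, scheme$hybridizations)] <- 1
  v
}

mol_graph_from_block <- function(lines, scheme, smiles = NA_character_) {
  p <- parse_molfile_block(lines)
  if (is.null(p)) return(NULL)
  arom <- aromatic_atoms_of(lines, p$n_v)
  deg <- tabulate(c(p$edges[, 1], p$edges[, 2]), nbins = p$n_v)
  feats <- matrix(0, p$n_v, scheme$dim)
  for (v in seq_len(p$n_v)) {
    inc <- p$orders[p$edges[, 1] == v | p$edges[, 2] == v]
    n_h <- implicit_h(p$elements[v], p$charges[v], sum(inc))
    hyb <- if (any(inc == 3) || sum(inc == 2) >= 2) "sp"
      else if (any(inc == 2) || arom[v]) "sp2"
      else if (p$elements[v] %in% names(DEFAULT_VALENCE)) "sp3"
      else "other"
    feats[v, ] <- atom_feature_row(scheme, p$elements[v], deg[v],
                                   p$charges[v], arom[v], n_h, hyb)
  }
  structure(
    list(node_features = feats, edges = p$edges, bond_orders = p$orders,
         elements = p$elements, charges = p$charges, aromatic = arom,
         n_v = p$n_v, n_e = p$n_e, smiles = smiles),
    class = "mol_graph"
  )
}

#' Featurize SMILES into atom-level molecular graphs
#'
#' Each parseable SMILES becomes an attributed undirected graph with one
#' node per heavy atom, one edge per bond, and node feature vectors built
#' according to `scheme`. SMILES are canonicalized first, so any rewriting
#' of the same molecule yields the same graph.
#'
#' @param smiles character vector of SMILES.
#' @param scheme a [featurization_scheme()].
#' @return A list of `mol_graph` objects (`NULL` entries for unparseable
#'   SMILES).
#' @export
featurize_molecules <- function(smiles, scheme = featurization_scheme()) {
  can <- canonical_smiles(smiles)
  out <- vector("list", length(smiles))
  ok <- which(!is.na(can))
  if (!length(ok)) return(out)
  sdf_text <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(can[ok], "\n", collapse = ""))
  blocks <- split_sdf_text(sdf_text)
  if (length(blocks) != length(ok)) {
    stop_input("internal: SDF conversion dropped molecules unexpectedly")
  }
  for (j in seq_along(ok)) {
    out[[ok[j]]] <- mol_graph_from_block(blocks[[j]], scheme, can[ok[j]])
  }
  out
}

#' @rdname featurize_molecules
#' @param error_on_failure abort on unparseable SMILES (default) instead of
#'   returning `NULL`.
#' @export
featurize_molecule <- function(smiles, scheme = featurization_scheme(),
                               error_on_failure = TRUE) {
  stopifnot(length(smiles) == 1L)
  g <- featurize_molecules(smiles, scheme)[[1]]
  if (is.null(g) && error_on_failure) {
    stop_input("unparseable SMILES: ", smiles)
  }
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d aromatic\n",
              x$smiles, x$n_v, x$n_e, sum(x$aromatic)))
  invisible(x)
}
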