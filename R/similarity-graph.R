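#' Build the initial molecule similarity graph (MSG)
#'
#' Computes all pairwise Tanimoto similarities between fingerprints and
#' keeps every off-diagonal entry at or above the threshold `epsilon_tc`;
#' everything smaller is masked off, which yields a sparse symmetric
#' weighted adjacency. The diagonal is excluded at construction:
#' self-connectivity enters only during propagation.
#'
#' @param fingerprints list of comparable [compute_fingerprint()] objects,
#'   or a `molecule_set` (fingerprints are computed with the given radius
#'   and length).
#' @param epsilon_tc similarity threshold in `[0, 1]`; entries `>=
#'   epsilon_tc` are kept (the inclusive comparison means equality
#'   survives).
#' @param molecule_ids optional node identifiers.
#' @param radius,n_bits fingerprint settings when `fingerprints` is a
#'   molecule set.
#' @param max_nodes guard on the dense O(n^2) similarity computation; an
#'   error beyond this size points to the (unimplemented) anchor
#'   approximation for large collections.
#' @return A `similarity_graph`: `molecule_ids`, sparse symmetric
#'   `adjacency` ([Matrix::sparseMatrix()]), and `epsilon_tc`.
#' @export
build_initial_adjacency <- function(fingerprints, epsilon_tc = 0.3,
                                    molecule_ids = NULL, radius = 2L,
                                    n_bits = 2048L, max_nodes = 20000L) {
  check_fraction(epsilon_tc, "epsilon_tc")
  if (inherits(fingerprints, "molecule_set")) {
    records <- fingerprints
    graphs <- featurize_molecules(records$smiles)
    if (any(vapply(graphs, is.null, TRUE))) {
      stop_input("unparseable SMILES in molecule set")
    }
    fingerprints <- fingerprint_matrix(graphs, radius, n_bits)$fingerprints
    molecule_ids <- molecule_ids %||% records$id
  }
  n <- length(fingerprints)
  if (n == 0L) stop_input("empty molecule list")
  if (n > max_nodes) {
    stop_input(sprintf(
      "%d molecules exceeds the dense similarity guard (%d); an anchor-based
approximation for large collections is not implemented", n, max_nodes))
  }
  S <- tanimoto_matrix(fingerprints)
  molecule_ids <- molecule_ids %||% as.character(seq_len(n))
  keep <- S >= epsilon_tc
  diag(keep) <- FALSE
  adj <- Matrix::Matrix(ifelse(keep, S, 0), sparse = TRUE)
  adj <- methods::as(Matrix::forceSymmetric(adj), "generalMatrix")
  structure(list(molecule_ids = molecule_ids, adjacency = adj,
                 epsilon_tc = epsilon_tc),
            class = "similarity_graph")
}

## Dense pairwise Tanimoto matrix from a fingerprint list (vectorized:
## intersections via crossproduct of the bit matrix).
tanimoto_matrix <- function(fingerprints) {
  first <- fingerprints[[1]]
  ok <- vapply(fingerprints, function(f) {
    inherits(f, "fingerprint") && f$radius == first$radius &&
      f$n_bits == first$n_bits
  }, TRUE)
  if (!all(ok)) stop_input("fingerprints are not mutually comparable")
  B <- do.call(rbind, lapply(fingerprints, function(f) as.numeric(f$bits)))
  inter <- tcrossprod(B)
  pop <- rowSums(B)
  uni <- outer(pop, pop, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  diag(S) <- ifelse(pop > 0, 1, 0)
  S
}

#' @export
print.similarity_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf(
    "<similarity_graph> %d molecules, %d edges (density %.3f), eps_tc %.2f\n",
    s$n_nodes, s$n_edges, s$density, x$epsilon_tc))
  invisible(x)
}

#' Summary statistics of a similarity graph
#'
#' @param graph a `similarity_graph` (or any symmetric adjacency matrix).
#' @return A list: `n_nodes`, `n_edges`, `density` (`2 e / (n (n-1))`),
#'   `n_isolated`, and `weight_quantiles` of the stored edge weights.
#' @export
graph_stats <- function(graph) {
  A <- if (inherits(graph, "similarity_graph")) graph$adjacency else graph
  n <- nrow(A)
  up <- Matrix::triu(methods::as(A, "CsparseMatrix"), k = 1)
  w <- up@x[up@x != 0]
  n_edges <- length(w)
  deg <- Matrix::rowSums(A != 0)
  list(
    n_nodes = n,
    n_edges = n_edges,
    density = if (n > 1) 2 * n_edges / (n * (n - 1)) else 0,
    n_isolated = sum(deg == 0),
    weight_quantiles = if (n_edges) stats::quantile(w) else
      stats::setNames(rep(NA_real_, 5),
                      c("0%", "25%", "50%", "75%", "100%"))
  )
}

#' Export / import a similarity graph as an edge list
#'
#' Plain-text `node_i node_j weight` triples with 0-based node indices, one
#' undirected edge per line.
#'
#' @param graph a `similarity_graph`.
#' @param path output (input) file path.
#' @return `path` invisibly; `read_edge_list()` returns a
#'   `similarity_graph`.
#' @export
write_edge_list <- function(graph, path) {
  A <- methods::as(Matrix::triu(graph$adjacency, k = 1), "TsparseMatrix")
  keep <- A@x != 0
  df <- data.frame(node_i = A@i[keep], node_j = A@j[keep],
                   weight = A@x[keep])
  df <- df[order(df$node_i, df$node_j), ]
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_nodes number of nodes (isolated trailing nodes are not
#'   recoverable from the edge list alone).
#' @param epsilon_tc threshold recorded on the graph object.
#' @export
read_edge_list <- function(path, n_nodes, epsilon_tc = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  adj <- Matrix::sparseMatrix(i = df$node_i + 1L, j = df$node_j + 1L,
                              x = df$weight, dims = c(n_nodes, n_nodes),
                              symmetric = FALSE)
  adj <- adj + Matrix::t(adj)
  structure(list(molecule_ids = as.character(seq_len(n_nodes)),
                 adjacency = adj, epsilon_tc = epsilon_tc),
            class = "similarity_graph")
}

#' Export / import a similarity graph in MatrixMarket format
#'
#' @param graph a `similarity_graph`.
#' @param path `.mtx` file path.
#' @return `path` invisibly; `read_mtx_graph()` returns a
#'   `similarity_graph`.
#' @export
write_mtx_graph <- function(graph, path) {
  Matrix::writeMM(methods::as(graph$adjacency, "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_mtx_graph
#' @param epsilon_tc threshold recorded on the graph object.
#' @export
read_mtx_graph <- function(path, epsilon_tc = NA_real_) {
  adj <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  structure(list(molecule_ids = as.character(seq_len(nrow(adj))),
                 adjacency = adj, epsilon_tc = epsilon_tc),
            class = "similarity_graph")
}
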