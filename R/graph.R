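# Temporal graph representation of one serve: 101 time nodes, fully
# connected, each node carrying the six joint-angle features of its time
# point. Complete connectivity encodes the assumption that the whole-cycle
# joint configuration is coordinated (uncontrolled-manifold view), so every
# node may exchange information with every other.

#' Build the fully connected serve graph
#'
#' Converts a normalized trial into a graph of 101 temporal nodes. Node `t`
#' carries column `t` of the 6 x 101 angle matrix as its feature vector; all
#' ordered pairs of distinct nodes are materialized as directed edges (plus
#' self-loops when requested), each with edge attribute 1 — edge features
#' are not informative, so the attribute matrix is all ones.
#'
#' @param trial A `normalized_trial` (or a bare 6 x 101 matrix).
#' @param self_loops Materialize `(u, u)` edges (default TRUE; the graph
#'   convolution's normalization uses adjacency-plus-identity either way).
#' @return A `serve_graph` object: list with `node_features` (101 x 6),
#'   `edge_index` (E x 2 integer matrix of ordered pairs, lexicographically
#'   sorted), `edge_attr` (length E, all 1), `target` (length 101 or NULL),
#'   `self_loops`.
#' @export
build_graph <- function(trial, self_loops = TRUE) {
  if (inherits(trial, "normalized_trial")) {
    feats <- t(trial$angles)
    target <- trial$resultant_moment
  } else {
    feats <- t(as.matrix(trial))
    target <- NULL
  }
  if (ncol(feats) != 6 || nrow(feats) != N_NODES) {
    abort_data(sprintf(
      "expected a 6 x %d input matrix, got %d x %d",
      N_NODES, ncol(feats), nrow(feats)
    ))
  }
  n <- N_NODES
  src <- rep(seq_len(n), each = n)
  dst <- rep.int(seq_len(n), n)
  keep <- if (self_loops) rep(TRUE, n * n) else src != dst
  edge_index <- cbind(src = src[keep], dst = dst[keep])
  colnames(feats) <- JOINT_NAMES
  structure(
    list(
      node_features = feats,
      edge_index = edge_index,
      edge_attr = rep(1, nrow(edge_index)),
      target = target,
      self_loops = isTRUE(self_loops)
    ),
    class = "serve_graph"
  )
}

#' Validate a serve graph
#'
#' Checks every structural invariant of the graph representation and
#' reports, without raising: node count, completeness (every ordered pair
#' of distinct nodes present exactly once), duplicate edges, all-ones edge
#' attributes, directional symmetry, and feature finiteness.
#'
#' @param graph A `serve_graph` (possibly malformed).
#' @return A data frame with columns `check`, `pass`, `detail`.
#' @export
validate_graph <- function(graph) {
  feats <- graph$node_features
  ei <- graph$edge_index
  n_nodes <- nrow(feats)
  keys <- paste(ei[, 1], ei[, 2])
  dup <- sum(duplicated(keys))
  off_diag <- ei[ei[, 1] != ei[, 2], , drop = FALSE]
  expected_pairs <- n_nodes * (n_nodes - 1)
  have_pairs <- length(unique(paste(off_diag[, 1], off_diag[, 2])))
  rev_keys <- paste(ei[, 2], ei[, 1])
  asym <- sum(!(rev_keys %in% keys))
  checks <- list(
    node_count = list(
      pass = n_nodes == N_NODES,
      detail = sprintf("%d nodes (expected %d)", n_nodes, N_NODES)
    ),
    feature_width = list(
      pass = ncol(feats) == 6,
      detail = sprintf("%d feature dims (expected 6)", ncol(feats))
    ),
    complete = list(
      pass = have_pairs == expected_pairs,
      detail = sprintf("%d / %d ordered pairs present", have_pairs, expected_pairs)
    ),
    no_duplicate_edges = list(
      pass = dup == 0,
      detail = sprintf("%d duplicated edges", dup)
    ),
    all_ones_edge_attr = list(
      pass = all(graph$edge_attr == 1),
      detail = sprintf("%d non-unit attributes", sum(graph$edge_attr != 1))
    ),
    symmetric = list(
      pass = asym == 0,
      detail = sprintf("%d unreciprocated edges", asym)
    ),
    finite_features = list(
      pass = all(is.finite(feats)),
      detail = sprintf("%d non-finite feature values", sum(!is.finite(feats)))
    )
  )
  data.frame(
    check = names(checks),
    pass = vapply(checks, `[[`, logical(1), "pass"),
    detail = vapply(checks, `[[`, character(1), "detail"),
    row.names = NULL
  )
}

# Symmetric-normalized adjacency D^(-1/2) (A + I) D^(-1/2) of a graph given
# by an edge list over n nodes. Self-loops in the edge list and the added
# identity are collapsed (adjacency entries are 0/1).
normalized_adjacency <- function(edge_index, n_nodes) {
  A <- matrix(0, n_nodes, n_nodes)
  A[edge_index] <- 1
  diag(A) <- 1
  dinv <- 1 / sqrt(rowSums(A))
  A * (dinv %o% dinv)
}

#' Write a serve graph as plain-text TSVs
#'
#' Writes `<stem>_nodes.tsv` (node_index + six features) and
#' `<stem>_edges.tsv` (src, dst, attr) for inspection.
#'
#' @param graph A `serve_graph`.
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_graph_tsv <- function(graph, stem) {
  nodes <- data.frame(node_index = seq_len(nrow(graph$node_features)) - 1L,
                      graph$node_features)
  edges <- data.frame(
    src = graph$edge_index[, 1] - 1L,
    dst = graph$edge_index[, 2] - 1L,
    attr = graph$edge_attr
  )
  nf <- paste0(stem, "_nodes.tsv")
  ef <- paste0(stem, "_edges.tsv")
  write.table(nodes, nf, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(edges, ef, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(nf, ef))
}
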