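# Accept a hyperbrain_graph or a plain binary adjacency matrix.
as_adjacency <- function(g) {
  if (inherits(g, "hyperbrain_graph")) {
    return(g$adjacency)
  }
  A <- as.matrix(g)
  if (nrow(A) != ncol(A) || !all(A %in% c(0, 1)) || any(diag(A) != 0) ||
      !isTRUE(all.equal(A, t(A)))) {
    stop("expected a symmetric binary adjacency matrix with zero diagonal")
  }
  A
}

#' Edge number
#'
#' Number of distinct undirected edges (each connected unordered node pair
#' counted once). For the 58-node hyperbrain graph the maximum is 1653.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Integer edge count.
#' @export
edge_number <- function(g) {
  A <- as_adjacency(g)
  sum(A) / 2
}

#' Pairwise shortest-path hop counts
#'
#' Breadth-first shortest paths on the binary undirected graph;
#' unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Numeric distance matrix.
#' @export
graph_shortest_paths <- function(g) {
  A <- as_adjacency(g)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(ig, algorithm = "unweighted")
}

#' Global efficiency
#'
#' Average inverse shortest-path length over all ordered node pairs, with
#' `1/Inf = 0` for unreachable pairs. 1 on a complete graph, 0 on an empty
#' one; a network-wide integration measure.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  A <- as_adjacency(g)
  s <- nrow(A)
  if (s < 2) stop("global efficiency undefined for fewer than 2 nodes")
  D <- graph_shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (s * (s - 1))
}

#' Local efficiency
#'
#' For each node i, the efficiency of the subgraph induced by i's
#' neighbors: the average inverse shortest-path length between neighbor
#' pairs, where paths may only traverse neighbors of i, normalized by
#' `d_i (d_i - 1)`. Nodes with fewer than two neighbors contribute 0.
#' The network value is the mean over all `s` nodes; it measures
#' fault-tolerant communication among each node's immediate neighborhood.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- as_adjacency(g)
  s <- nrow(A)
  le <- vapply(seq_len(s), function(i) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) {
      return(0)
    }
    Dsub <- graph_shortest_paths(A[nb, nb, drop = FALSE])
    inv <- 1 / Dsub
    diag(inv) <- 0
    sum(inv) / (d * (d - 1))
  }, numeric(1))
  mean(le)
}

#' Fixed-partition modularity
#'
#' Newman's Q for a predefined node partition (no community detection):
#' `Q = 1/(2 EN) * sum_ik (A_ik - d_i d_k / (2 EN)) delta(c_i, c_k)`,
#' summed over all ordered node pairs. With the partition fixed at the two
#' participants' brains, high Q means few between-brain edges relative to
#' a degree-preserving null.
#'
#' @param g a [hyperbrain_graph()] (its stored partition is used) or a
#'   binary adjacency matrix (then `module_of` is required).
#' @param module_of integer module labels per node.
#' @return Scalar in `[-0.5, 1]`.
#' @export
fixed_modularity <- function(g, module_of = NULL) {
  A <- as_adjacency(g)
  if (is.null(module_of)) {
    if (inherits(g, "hyperbrain_graph")) {
      module_of <- g$module_of
    } else {
      stop("module_of is required for a plain adjacency matrix")
    }
  }
  if (length(module_of) != nrow(A)) stop("module_of must assign every node")
  two_en <- sum(A)
  if (two_en == 0) stop("modularity undefined for an edgeless graph")
  d <- rowSums(A)
  same <- outer(module_of, module_of, `==`)
  sum((A - outer(d, d) / two_en) * same) / two_en
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable ordered node pairs. The
#' fraction of unreachable pairs is attached as attribute
#' `frac_unreachable`.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Scalar >= 1 with attribute `frac_unreachable`.
#' @export
char_path_length <- function(g) {
  A <- as_adjacency(g)
  D <- graph_shortest_paths(A)
  off <- D[row(D) != col(D)]
  reachable <- is.finite(off)
  if (!any(reachable)) stop("no reachable node pair; path length undefined")
  structure(mean(off[reachable]),
            frac_unreachable = mean(!reachable))
}

#' Clustering coefficient
#'
#' Per node, the density of edges among its neighbors (triangle fraction);
#' nodes with degree < 2 contribute 0. The network value is the mean over
#' all nodes.
#'
#' @param g a [hyperbrain_graph()] or binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  A <- as_adjacency(g)
  cc <- vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) {
      return(0)
    }
    sum(A[nb, nb]) / (d * (d - 1))
  }, numeric(1))
  mean(cc)
}

#' All topology metrics of a hyperbrain graph
#'
#' Edge number, global and local efficiency, fixed-partition modularity,
#' characteristic path length, and clustering coefficient, plus per-block
#' edge counts (within participant 1, within participant 2, between).
#'
#' @param g a [hyperbrain_graph()].
#' @return One-row data.frame.
#' @export
graph_metrics <- function(g) {
  stopifnot(inherits(g, "hyperbrain_graph"))
  A <- g$adjacency
  idx1 <- which(g$module_of == 1)
  idx2 <- which(g$module_of == 2)
  en <- edge_number(A)
  pl <- tryCatch(char_path_length(A), error = function(e) NA_real_)
  q <- tryCatch(fixed_modularity(A, g$module_of),
                error = function(e) NA_real_)
  data.frame(
    edge_number = en,
    en_intra1 = sum(A[idx1, idx1]) / 2,
    en_intra2 = sum(A[idx2, idx2]) / 2,
    en_inter = sum(A[idx1, idx2]),
    global_efficiency = global_efficiency(A),
    local_efficiency = local_efficiency(A),
    modularity = q,
    char_path_length = as.numeric(pl),
    frac_unreachable = if (is.na(pl[1])) NA_real_
                       else attr(pl, "frac_unreachable"),
    clustering_coefficient = clustering_coefficient(A),
    n_nodes = nrow(A)
  )
}
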