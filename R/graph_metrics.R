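# Node-level graph-theory measures on sparse binary or weighted brain graphs.
#
# Conventions (Brain Connectivity Toolbox style): weights are connection
# strengths; whenever a path length is needed the edge length is 1/weight.
# Weighted clustering uses the Onnela geometric-mean formula with weights
# normalized by the maximum weight.  k < 2 nodes get 0 for clustering, local
# efficiency and flow coefficient.

check_adjacency <- function(G, binary = FALSE) {
  A <- as_adjacency(G)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (any(diag(A) != 0)) stop("diagonal must be zero")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (binary && !graph_is_binary(A)) stop("binary graph required")
  A
}

#' Node strength
#'
#' Row sums of the adjacency matrix (= degree on binary graphs).
#'
#' @param G `sparse_graph` or adjacency matrix.
#' @return named numeric vector, one value per node.
#' @export
node_strength <- function(G) {
  A <- check_adjacency(G)
  rowSums(A)
}

#' Clustering coefficient (binary or Onnela weighted)
#'
#' Binary: 2 * triangles / (k (k - 1)).  Weighted: Onnela's geometric-mean
#' triangle intensity on weights normalized by the maximum weight, with k the
#' binary degree.  Nodes with k < 2 get 0.
#'
#' @param G graph. @param mode `"binary"` or `"weighted"`.
#' @return per-node clustering values.
#' @export
clustering_coefficient <- function(G, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  A <- check_adjacency(G)
  B <- (A > 0) * 1
  k <- rowSums(B)
  W <- if (mode == "binary") B else {
    if (max(A) > 0) (A / max(A))^(1 / 3) else A
  }
  # diagonal of W^3 counts (weighted) closed triples through each node
  t3 <- diag(W %*% W %*% W)
  out <- ifelse(k >= 2, t3 / (k * (k - 1)), 0)
  stats::setNames(out, rownames(A))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbors
#' (neighbors = nonzero adjacency); weighted path lengths use 1/weight within
#' the induced subgraph.  Nodes with fewer than 2 neighbors get 0.
#'
#' @param G graph.
#' @return per-node local efficiency.
#' @export
local_efficiency <- function(G) {
  A <- check_adjacency(G)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) next
    out[v] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  stats::setNames(out, rownames(A))
}

#' PageRank centrality
#'
#' Stationary distribution of the damped random walk on the (weighted) graph;
#' dangling (isolated) nodes teleport uniformly.  Sums to 1.
#'
#' @param G graph. @param damping damping factor (default 0.85).
#' @param tol convergence tolerance. @param max_iter iteration cap.
#' @return per-node PageRank values.
#' @export
pagerank_centrality <- function(G, damping = 0.85, tol = 1e-12,
                                max_iter = 10000) {
  A <- check_adjacency(G)
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- if (s[i] > 0) A[i, ] / s[i] else 1 / n
  }
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- (1 - damping) / n + damping * as.vector(crossprod(P, x))
    if (max(abs(x_new - x)) < tol) {
      return(stats::setNames(x_new / sum(x_new), rownames(A)))
    }
    x <- x_new
  }
  stop("PageRank did not converge in ", max_iter, " iterations")
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node (Brandes semantics),
#' with weighted path length 1/weight, normalized by (N-1)(N-2)/2.
#'
#' @param G graph.
#' @return per-node normalized betweenness.
#' @export
betweenness_centrality <- function(G) {
  A <- check_adjacency(G)
  n <- nrow(A)
  if (n < 3) return(stats::setNames(rep(0, n), rownames(A)))
  g <- as_igraph(A)
  if (igraph::ecount(g) == 0) {
    return(stats::setNames(rep(0, n), rownames(A)))
  }
  w <- if (graph_is_binary(A)) NULL else 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, weights = w, normalized = FALSE)
  stats::setNames(as.vector(b) / ((n - 1) * (n - 2) / 2), rownames(A))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix restricted to the largest
#' connected component (zeros elsewhere), sign-fixed nonnegative and scaled to
#' unit Euclidean norm.
#'
#' @param G graph (must contain at least one edge).
#' @return per-node eigenvector centrality.
#' @export
eigenvector_centrality <- function(G) {
  A <- check_adjacency(G)
  if (all(A == 0)) stop("graph has no edges")
  g <- as_igraph(A)
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  e <- eigen(A[big, big, drop = FALSE], symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-14] <- 0
  v <- abs(v)
  out <- numeric(nrow(A))
  out[big] <- v / sqrt(sum(v^2))
  stats::setNames(out, rownames(A))
}

#' Flow coefficient
#'
#' For a node with binary degree k >= 2: the fraction of its unordered
#' neighbor pairs that are not directly connected, i.e. length-2 paths through
#' the node that are non-redundant, over k(k-1)/2.  k < 2 gives 0.  A star
#' center scores 1; every node of a complete graph scores 0.
#'
#' @param G binary graph.
#' @return per-node flow coefficient.
#' @export
flow_coefficient <- function(G) {
  A <- check_adjacency(G, binary = TRUE)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    linked <- sum(sub) / 2
    out[v] <- 1 - linked / (k * (k - 1) / 2)
  }
  stats::setNames(out, rownames(A))
}

#' k-coreness centrality
#'
#' Binary: the largest k such that the node survives iterative removal of all
#' nodes with degree < k.  Weighted: the analogous s-core level, the largest
#' strength threshold s at which the node survives iterative pruning of nodes
#' with strength < s (real-valued).
#'
#' @param G graph. @param weighted use the s-core generalization?
#' @return per-node coreness (integer for binary graphs).
#' @export
kcoreness_centrality <- function(G, weighted = FALSE) {
  A <- check_adjacency(G, binary = !weighted)
  n <- nrow(A)
  if (!weighted) {
    g <- as_igraph(A)
    out <- if (igraph::ecount(g) == 0) rep(0L, n) else
      as.integer(igraph::coreness(g))
    return(stats::setNames(out, rownames(A)))
  }
  # s-core: repeatedly remove the weakest remaining node; its core level is
  # the running maximum of the minimum strength at removal time
  alive <- rep(TRUE, n)
  core <- numeric(n)
  level <- 0
  while (any(alive)) {
    s <- rowSums(A[alive, alive, drop = FALSE])
    level <- max(level, min(s))
    weakest <- which(alive)[s <= min(s) + 1e-12]
    core[weakest] <- level
    alive[weakest] <- FALSE
  }
  stats::setNames(core, rownames(A))
}

#' Assemble the node-by-metric table
#'
#' Default configuration: binary and weighted variants of strength,
#' clustering, local efficiency, PageRank, betweenness, eigenvector and
#' k-coreness, plus the binary-only flow coefficient — 15 columns.  Column
#' order is deterministic; 246 nodes yield 246 x 15 = 3690 values when
#' flattened.
#'
#' @param G_bin binary `sparse_graph` (or 0/1 adjacency).
#' @param G_wt weighted `sparse_graph` on the same node set.
#' @return data.frame with `node_id` plus one column per metric variant,
#'   columns named `<metric>_bin` / `<metric>_wt`.
#' @export
metric_table <- function(G_bin, G_wt) {
  Ab <- check_adjacency(G_bin, binary = TRUE)
  Aw <- check_adjacency(G_wt)
  if (nrow(Ab) != nrow(Aw)) stop("node sets differ in size")
  ids <- rownames(Ab)
  if (is.null(ids)) ids <- default_node_ids(nrow(Ab))
  if (!is.null(rownames(Aw)) && !identical(ids, rownames(Aw))) {
    stop("node ids differ between the binary and weighted graphs")
  }
  out <- data.frame(
    node_id = ids,
    strength_bin = unname(node_strength(Ab)),
    clustering_bin = unname(clustering_coefficient(Ab, "binary")),
    local_efficiency_bin = unname(local_efficiency(Ab)),
    pagerank_bin = unname(pagerank_centrality(Ab)),
    betweenness_bin = unname(betweenness_centrality(Ab)),
    eigenvector_bin = unname(if (all(Ab == 0)) rep(0, nrow(Ab)) else
      eigenvector_centrality(Ab)),
    kcoreness_bin = unname(kcoreness_centrality(Ab)),
    flow_coefficient_bin = unname(flow_coefficient(Ab)),
    strength_wt = unname(node_strength(Aw)),
    clustering_wt = unname(clustering_coefficient(Aw, "weighted")),
    local_efficiency_wt = unname(local_efficiency(Aw)),
    pagerank_wt = unname(pagerank_centrality(Aw)),
    betweenness_wt = unname(betweenness_centrality(Aw)),
    eigenvector_wt = unname(if (all(Aw == 0)) rep(0, nrow(Aw)) else
      eigenvector_centrality(Aw)),
    kcoreness_wt = unname(kcoreness_centrality(Aw, weighted = TRUE)),
    stringsAsFactors = FALSE)
  stopifnot(all(is.finite(as.matrix(out[, -1]))))
  out
}

#' Write a node-metric table as TSV
#'
#' @param tab output of [metric_table()]. @param path file path.
#' @return `path`, invisibly.
#' @export
write_metric_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], format_num)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
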