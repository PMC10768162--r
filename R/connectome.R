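# Functional-connectivity matrices, their edge vectorization, and
# efficiency-driven sparsification.
#
# Conventions used throughout the package:
#   * an FC matrix is a base R numeric matrix with identical row/col names
#     (the node ids), symmetric within 1e-10, unit diagonal;
#   * edge vectors enumerate the upper triangle (i < j) in row-major order:
#     (1,2), (1,3), ..., (1,N), (2,3), ...;
#   * graph-metric computations zero out negative FC weights first (the usual
#     connectomics convention); signed values are kept for regression/GCN
#     features.

#' Validate a connectivity matrix
#'
#' Checks symmetry (within `tol`), unit diagonal and off-diagonal range
#' \eqn{[-1, 1]}.
#'
#' @param C numeric square matrix.
#' @param tol symmetry tolerance.
#' @return `C`, invisibly, after validation.
#' @export
validate_fc <- function(C, tol = 1e-10) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  asym <- max(abs(C - t(C)))
  if (asym > tol) {
    stop("matrix is not symmetric (max |C - t(C)| = ", format(asym), ")")
  }
  if (max(abs(diag(C) - 1)) > 1e-12) stop("diagonal must be exactly 1")
  off <- C[upper.tri(C)]
  if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12)) {
    stop("off-diagonal entries must lie in [-1, 1]")
  }
  invisible(C)
}

#' Pearson functional connectivity from a regional time-series matrix
#'
#' Computes the region-by-region Pearson correlation matrix of a timepoints
#' \eqn{\times} regions matrix, the standard FC estimate for parcellated fMRI
#' series.
#'
#' @param ts numeric T x N matrix, columns are regions.  Column names are used
#'   as node ids (defaulting to `n001, ...`).
#' @return N x N correlation matrix with unit diagonal and node-id dimnames.
#' @examples
#' ts <- matrix(rnorm(200), 50, 4)
#' C <- compute_fc(ts)
#' @export
compute_fc <- function(ts) {
  stopifnot(is.matrix(ts))
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  ids <- colnames(ts)
  if (is.null(ids)) ids <- default_node_ids(ncol(ts))
  v <- apply(ts, 2, stats::var)
  if (any(v <= 0)) {
    stop("constant time series for node(s): ",
         paste(ids[v <= 0], collapse = ", "))
  }
  C <- stats::cor(ts)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(ids, ids)
  C
}

default_node_ids <- function(n) sprintf("n%03d", seq_len(n))

#' Upper-triangle edge ordering of an N-node graph
#'
#' @param n number of nodes.
#' @return two-column integer matrix of (i, j) pairs, i < j, row-major order.
#' @export
edge_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Vectorize / reconstruct a connectivity matrix
#'
#' `vectorize_fc` extracts the upper triangle (i < j) in row-major order;
#' `devectorize_fc` inverts it.  An N-node matrix yields a vector of length
#' N(N-1)/2 (e.g. 246 nodes give 30135 edges).
#'
#' @param C connectivity matrix.
#' @param v edge vector of triangular length.
#' @param node_ids optional node ids for the reconstructed matrix.
#' @return numeric vector, resp. symmetric matrix with unit diagonal.
#' @export
vectorize_fc <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  # row-major upper triangle of a symmetric matrix == column-major lower
  v <- C[lower.tri(C)]
  ids <- rownames(C)
  if (is.null(ids)) ids <- default_node_ids(nrow(C))
  ep <- edge_pairs(nrow(C))
  names(v) <- paste0(ids[ep[, 1]], "-", ids[ep[, 2]])
  v
}

#' @rdname vectorize_fc
#' @export
devectorize_fc <- function(v, node_ids = NULL) {
  m <- length(v)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (n != round(n)) stop("length ", m, " is not a triangular number")
  n <- as.integer(n)
  C <- matrix(0, n, n)
  C[lower.tri(C)] <- v
  C <- C + t(C)
  diag(C) <- 1
  if (is.null(node_ids)) node_ids <- default_node_ids(n)
  dimnames(C) <- list(node_ids, node_ids)
  C
}

#' Proportional threshold of a connectivity matrix
#'
#' Zeroes negative weights, then keeps the strongest `density` fraction of the
#' remaining edges.  Ties at the cutoff are broken by (i, j) lexicographic
#' order.  In `"binary"` mode retained edges get weight 1.
#'
#' @param C connectivity matrix.
#' @param density fraction of the N(N-1)/2 possible edges to retain, in (0, 1].
#' @param mode `"weighted"` or `"binary"`.
#' @return a `sparse_graph`: list with `adjacency` (N x N), `density`
#'   (realized), and `mode`.
#' @export
threshold_graph <- function(C, density, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- nrow(C)
  ep <- edge_pairs(n)
  w <- vectorize_fc(C)
  w[w < 0] <- 0
  m <- length(w)
  k <- floor(density * m + 1e-9)
  if (k < 1) stop("density ", density, " retains zero edges")
  ord <- order(-w, ep[, 1], ep[, 2])
  keep <- ord[seq_len(k)]
  keep <- keep[w[keep] > 0]          # never create zero-weight "edges"
  A <- matrix(0, n, n, dimnames = dimnames(C))
  for (e in keep) {
    val <- if (mode == "binary") 1 else w[e]
    A[ep[e, 1], ep[e, 2]] <- val
    A[ep[e, 2], ep[e, 1]] <- val
  }
  structure(list(adjacency = A,
                 density = length(keep) / m,
                 mode = mode),
            class = "sparse_graph")
}

as_adjacency <- function(G) {
  if (inherits(G, "sparse_graph")) G$adjacency else G
}

graph_is_binary <- function(A) all(A %in% c(0, 1))

# igraph view of an adjacency matrix; weights attached as attribute "weight"
as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# All-pairs shortest-path distances with edge length 1/weight (weighted) or 1
# (binary).  Infinite = unreachable.
shortest_path_lengths <- function(A) {
  g <- as_igraph(A)
  if (igraph::ecount(g) == 0) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    return(D)
  }
  w <- if (graph_is_binary(A)) NULL else 1 / igraph::E(g)$weight
  igraph::distances(g, weights = w)
}

#' Global efficiency of a sparse graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' weighted path length defined as the sum of 1/weight along the path and
#' unreachable pairs contributing 0.  Lies in \eqn{[0, 1]} for binary graphs.
#'
#' @param G a `sparse_graph` or adjacency matrix (nonnegative, zero diagonal).
#' @return scalar efficiency.
#' @export
global_efficiency <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  D <- shortest_path_lengths(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Efficiency-optimized sparsity selection
#'
#' Sweeps a density grid, binarizes at each density, and picks the density
#' maximizing cost-efficiency = global efficiency - density (raw efficiency is
#' trivially maximized at density 1).  Ties go to the smaller density.
#'
#' @param C connectivity matrix.
#' @param grid candidate densities in (0, 1].
#' @param mode graph mode passed to [threshold_graph()] for the returned graph.
#' @return list with `graph` (the thresholded graph at the chosen density),
#'   `density`, and `sweep` (data.frame of density, efficiency, cost_efficiency).
#' @export
optimize_density <- function(C, grid = seq(0.05, 0.5, by = 0.05),
                             mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  if (length(grid) == 0) stop("density grid is empty")
  if (any(grid <= 0 | grid > 1)) stop("grid densities must be in (0, 1]")
  grid <- sort(grid)
  eff <- vapply(grid, function(d) {
    g <- tryCatch(threshold_graph(C, d, mode = "binary"),
                  error = function(e) NULL)
    if (is.null(g)) 0 else global_efficiency(g)
  }, numeric(1))
  ce <- eff - grid
  best <- which(ce == max(ce))[1]   # grid sorted => first max is smallest density
  list(graph = threshold_graph(C, grid[best], mode = mode),
       density = grid[best],
       sweep = data.frame(density = grid, efficiency = eff,
                          cost_efficiency = ce))
}

## ---- TSV input/output -----------------------------------------------------

format_num <- function(x) sprintf("%.10g", x)

#' Read / write square matrices and time series as TSV
#'
#' Matrices are written with a header row of node ids and node ids as the
#' first column; loading re-checks symmetry within 1e-8.
#'
#' @param C,ts matrix to write.
#' @param path file path.
#' @return the matrix (read functions) or the path, invisibly (write).
#' @export
write_fc_tsv <- function(C, path) {
  ids <- rownames(C)
  if (is.null(ids)) ids <- default_node_ids(nrow(C))
  df <- cbind(node_id = ids,
              as.data.frame(matrix(format_num(C), nrow(C), ncol(C),
                                   dimnames = list(NULL, ids))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_tsv
#' @export
read_fc_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  C <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(C) <- "double"
  dimnames(C) <- list(ids, ids)
  if (max(abs(C - t(C))) > 1e-8) {
    stop("matrix in ", path, " is not symmetric within 1e-8")
  }
  C <- (C + t(C)) / 2
  C
}

#' @rdname write_fc_tsv
#' @export
write_timeseries_tsv <- function(ts, path) {
  ids <- colnames(ts)
  if (is.null(ids)) ids <- default_node_ids(ncol(ts))
  df <- as.data.frame(matrix(format_num(ts), nrow(ts), ncol(ts),
                             dimnames = list(NULL, ids)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_tsv
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ts <- as.matrix(df)
  storage.mode(ts) <- "double"
  ts
}
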