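# Turning decoded task subnetworks into per-subject classification features:
# task patterns (edge/node sets), task unions, FC + graph-metric feature
# assembly, and ridge-classifier recursive feature elimination.

#' Task pattern: the decoded edge set of one task
#'
#' Holds the edges (as node-id pairs, i < j by node-id order) that survived
#' aggregation for one task, and the node set they span.
#'
#' @param task_name task label (its initial is used when combining).
#' @param edges two-column character matrix / data.frame of node-id pairs.
#' @return object of class `task_pattern` with `task_name`, `edges`, `nodes`.
#' @export
task_pattern <- function(task_name, edges) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (length(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edge")
  }
  nodes <- sort(unique(as.vector(edges)))
  structure(list(task_name = task_name, edges = edges, nodes = nodes),
            class = "task_pattern")
}

#' Node set of a task pattern
#'
#' @param pattern a `task_pattern`.
#' @return sorted character vector of the endpoint union (empty with a
#'   warning if the pattern has no edges).
#' @export
task_nodes <- function(pattern) {
  stopifnot(inherits(pattern, "task_pattern"))
  if (length(pattern$nodes) == 0) warning("pattern has no edges")
  pattern$nodes
}

#' Build a task pattern from a decoding result
#'
#' @param result a `decoding_result`. @param node_ids node labels of the FC
#'   matrices the decode ran on. @param task_name label.
#' @param freq_threshold aggregation threshold for [aggregate_edges()].
#' @return a `task_pattern`.
#' @export
pattern_from_decode <- function(result, node_ids, task_name = "task",
                                freq_threshold = 0.5) {
  idx <- aggregate_edges(result, freq_threshold)
  ep <- edge_pairs(length(node_ids))
  edges <- cbind(node_ids[ep[idx, 1]], node_ids[ep[idx, 2]])
  task_pattern(task_name, edges)
}

#' Union of task patterns
#'
#' Edge and node union across tasks; the combined name joins the sorted
#' upper-cased task initials with underscores (e.g. motor + relational +
#' social + working-memory -> "M_R_S_W").
#'
#' @param patterns list of `task_pattern`s (>= 1).
#' @return combined `task_pattern`.
#' @export
combine_patterns <- function(patterns) {
  if (inherits(patterns, "task_pattern")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1,
            all(vapply(patterns, inherits, logical(1), "task_pattern")))
  edges <- do.call(rbind, lapply(patterns, `[[`, "edges"))
  initials <- toupper(substr(vapply(patterns, `[[`, character(1), "task_name"),
                             1, 1))
  name <- paste(sort(unique(initials)), collapse = "_")
  task_pattern(name, edges)
}

#' Per-subject classification features from a task pattern
#'
#' For each subject, the FC values among all pattern-node pairs (m(m-1)/2
#' columns named `fc:<i>-<j>`) concatenated with the node's graph-metric
#' values (m x n_metrics columns named `metric:<node>:<name>`).  Restricting
#' FC columns to the decoded edges only is available via `edges_only`.
#'
#' @param fc N x N x S array of FC matrices (node-id dimnames required).
#' @param pattern a `task_pattern`.
#' @param metrics optional list (one per subject) of [metric_table()] outputs.
#' @param include_fc,include_metrics feature blocks to include.
#' @param edges_only use only the pattern's decoded edges as FC columns.
#' @return numeric subjects x features matrix with provenance-tagged column
#'   names; attribute `feature_names` mirrors colnames.
#' @export
build_features <- function(fc, pattern, metrics = NULL, include_fc = TRUE,
                           include_metrics = !is.null(metrics),
                           edges_only = FALSE) {
  stopifnot(inherits(pattern, "task_pattern"))
  node_ids <- dimnames(fc)[[1]]
  missing <- setdiff(pattern$nodes, node_ids)
  if (length(missing)) {
    stop("pattern node(s) absent from cohort: ", paste(missing, collapse = ", "))
  }
  subj <- dimnames(fc)[[3]]
  ns <- dim(fc)[3]
  blocks <- list()
  if (include_fc) {
    if (edges_only) {
      pairs <- pattern$edges
    } else {
      m <- length(pattern$nodes)
      ep <- edge_pairs(m)
      pairs <- cbind(pattern$nodes[ep[, 1]], pattern$nodes[ep[, 2]])
    }
    B <- matrix(NA_real_, ns, nrow(pairs))
    for (e in seq_len(nrow(pairs))) B[, e] <- fc[pairs[e, 1], pairs[e, 2], ]
    colnames(B) <- paste0("fc:", pairs[, 1], "-", pairs[, 2])
    blocks$fc <- B
  }
  if (include_metrics) {
    if (is.null(metrics)) stop("metrics requested but not supplied")
    stopifnot(length(metrics) == ns)
    mt1 <- metrics[[1]]
    mnames <- setdiff(colnames(mt1), "node_id")
    cols <- as.vector(t(outer(pattern$nodes, mnames,
                              function(n, m) paste0("metric:", n, ":", m))))
    B <- matrix(NA_real_, ns, length(cols), dimnames = list(NULL, cols))
    for (s in seq_len(ns)) {
      mt <- metrics[[s]]
      ridx <- match(pattern$nodes, mt$node_id)
      if (anyNA(ridx)) {
        stop("metric table ", s, " is missing node(s): ",
             paste(pattern$nodes[is.na(ridx)], collapse = ", "))
      }
      B[s, ] <- as.vector(t(as.matrix(mt[ridx, mnames, drop = FALSE])))
    }
    blocks$metrics <- B
  }
  if (length(blocks) == 0) stop("no feature block selected")
  X <- do.call(cbind, blocks)
  rownames(X) <- subj
  if (anyNA(X)) stop("NA in assembled features")
  if (anyDuplicated(colnames(X))) stop("duplicated feature names")
  attr(X, "feature_names") <- colnames(X)
  X
}

#' Recursive feature elimination with a ridge classifier
#'
#' Fits a ridge classifier (closed-form ridge regression on labels coded
#' -1/+1, unpenalised intercept), removes the `step` fraction of remaining
#' features with the smallest |coefficient| (at least one; never dropping
#' below `n_keep`), and repeats until `n_keep` features remain.  Ties in
#' |coefficient| are broken by dropping the higher column index first.
#'
#' @param X subjects x features matrix (standardize beforehand).
#' @param labels binary vector (two classes required).
#' @param n_keep target feature count. @param step fraction (0, 1) or integer
#'   count of features removed per iteration. @param lambda ridge penalty.
#' @return sorted integer vector of retained (original) column indices, with
#'   the elimination order stored in attribute `elimination_order`.
#' @export
rfe_ridge <- function(X, labels, n_keep = 200, step = 0.1, lambda = 1) {
  stopifnot(is.matrix(X))
  if (n_keep > ncol(X)) stop("n_keep exceeds the feature count")
  if (length(unique(labels)) != 2) stop("labels must contain two classes")
  y <- ifelse(labels == sort(unique(labels))[2], 1, -1)
  keep <- seq_len(ncol(X))
  elim <- integer(0)
  while (length(keep) > n_keep) {
    b <- ridge_coef(X[, keep, drop = FALSE], y, lambda)
    n_rm <- if (step < 1) max(1L, floor(step * length(keep))) else as.integer(step)
    n_rm <- min(n_rm, length(keep) - n_keep)
    ord <- order(abs(b), -seq_along(b))   # weakest first; ties drop later column
    drop_local <- ord[seq_len(n_rm)]
    elim <- c(elim, keep[drop_local])
    keep <- keep[-drop_local]
  }
  structure(sort(keep), elimination_order = elim)
}

# closed-form ridge regression coefficients with unpenalised intercept
ridge_coef <- function(X, y, lambda) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(Xc)
  as.vector(solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, yc)))
}

#' Write / read a feature matrix as TSV
#'
#' @param X feature matrix with subject rownames. @param path file path.
#' @return path / matrix.
#' @export
write_features_tsv <- function(X, path) {
  df <- data.frame(subject_id = rownames(X),
                   matrix(format_num(X), nrow(X), ncol(X),
                          dimnames = list(NULL, colnames(X))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df[[1]])
  X
}
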