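# Independent brute-force oracles for graph quantities.  These deliberately
# avoid the code paths of the package (igraph shortest paths, power
# iterations): Floyd-Warshall, dense linear solves, and exhaustive
# enumeration only.

rand_graph <- function(n, p_edge = 0.4, weighted = FALSE, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  on <- which(upper.tri(A) & matrix(runif(n * n), n, n) < p_edge, arr.ind = TRUE)
  w <- if (weighted) runif(nrow(on), 0.1, 1) else rep(1, nrow(on))
  for (k in seq_len(nrow(on))) {
    A[on[k, 1], on[k, 2]] <- w[k]
    A[on[k, 2], on[k, 1]] <- w[k]
  }
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

# all-pairs shortest paths, edge length = 1/weight, by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1 / A, Inf)
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_clustering_binary <- function(A) {
  B <- (A > 0) * 1
  vapply(seq_len(nrow(B)), function(v) {
    nb <- which(B[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      tri <- tri + B[nb[a], nb[b]]
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_clustering_onnela <- function(A) {
  W <- if (max(A) > 0) A / max(A) else A
  B <- (A > 0) * 1
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(B[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      s <- s + (W[v, nb[a]] * W[v, nb[b]] * W[nb[a], nb[b]])^(1 / 3)
    }
    2 * s / (k * (k - 1))
  }, numeric(1))
}

# shortest-path counts sigma[s, t] from Floyd-Warshall distances
oracle_path_counts <- function(A, D, tol = 1e-9) {
  n <- nrow(A)
  len <- ifelse(A > 0, 1 / A, Inf)
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & abs(D[s, ] + len[, t] - D[s, t]) < tol)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < 1e-9) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    b[v] <- acc / 2              # unordered pairs
  }
  b / ((n - 1) * (n - 2) / 2)
}

# PageRank by direct linear solve: x = (1-d)/n * (I - d P')^{-1} 1
oracle_pagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  s <- rowSums(A)
  P <- matrix(1 / n, n, n)
  for (i in which(s > 0)) P[i, ] <- A[i, ] / s[i]
  x <- solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
  x / sum(x)
}

oracle_kcore <- function(A) {
  B <- (A > 0) * 1
  n <- nrow(B)
  core <- integer(n)
  for (k in 1:n) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(B[, alive, drop = FALSE])[alive]
      bad <- which(alive)[deg < k]
      if (length(bad) == 0) break
      alive[bad] <- FALSE
    }
    core[alive] <- k
    if (!any(alive)) break
  }
  core
}

# does `node` survive pruning of all nodes with strength < s?
oracle_score_survives <- function(A, node, s) {
  alive <- rep(TRUE, nrow(A))
  repeat {
    st <- rowSums(A[alive, alive, drop = FALSE])
    bad <- which(alive)[st < s - 1e-9]
    if (length(bad) == 0) break
    alive[bad] <- FALSE
  }
  alive[node]
}

oracle_flow <- function(A) {
  B <- (A > 0) * 1
  vapply(seq_len(nrow(B)), function(v) {
    nb <- which(B[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    miss <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (B[nb[a], nb[b]] == 0) miss <- miss + 1
    }
    miss / (k * (k - 1) / 2)
  }, numeric(1))
}

# eigenvector centrality on the largest component by long power iteration
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in 1:n) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(A[u, ] > 0 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  M <- A[big, big, drop = FALSE]
  # shift so the Perron eigenvalue is strictly dominant even on bipartite
  # components (where +/- lambda_max tie and plain power iteration oscillates)
  shift <- 1 + max(rowSums(M))
  M <- M + shift * diag(length(big))
  x <- rep(1, length(big))
  for (i in 1:5000) {
    x_new <- as.vector(M %*% x)
    nx <- sqrt(sum(x_new^2))
    if (nx == 0) break
    x_new <- x_new / nx
    if (max(abs(x_new - x)) < 1e-13) { x <- x_new; break }
    x <- x_new
  }
  out <- numeric(n)
  out[big] <- abs(x)
  out
}
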