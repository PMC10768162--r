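# Closed-form fixtures first, then randomized brute-force oracle checks.

star5 <- function() {
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- A[2:5, 1] <- 1
  dimnames(A) <- list(sprintf("n%02d", 1:5), sprintf("n%02d", 1:5))
  A
}
complete <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

test_that("metrics match closed forms on canonical graphs", {
  K4 <- complete(4)
  expect_equal(unname(node_strength(K4)), rep(3, 4))
  expect_equal(unname(clustering_coefficient(K4, "binary")), rep(1, 4))
  expect_equal(unname(clustering_coefficient(K4, "weighted")), rep(1, 4))
  expect_equal(unname(local_efficiency(K4)), rep(1, 4))
  expect_equal(unname(pagerank_centrality(K4)), rep(0.25, 4), tolerance = 1e-10)
  expect_equal(unname(betweenness_centrality(K4)), rep(0, 4))
  expect_equal(unname(eigenvector_centrality(K4)), rep(0.5, 4),
               tolerance = 1e-10)
  expect_equal(unname(flow_coefficient(K4)), rep(0, 4))
  expect_equal(unname(kcoreness_centrality(K4)), rep(3L, 4))

  S <- star5()
  expect_equal(unname(node_strength(S)), c(4, 1, 1, 1, 1))
  expect_equal(unname(clustering_coefficient(S, "binary")), rep(0, 5))
  expect_equal(unname(flow_coefficient(S)), c(1, 0, 0, 0, 0))
  # center lies on all C(4,2) = 6 leaf pairs, normalized by 6
  expect_equal(unname(betweenness_centrality(S)), c(1, 0, 0, 0, 0))
  expect_equal(unname(kcoreness_centrality(S)), rep(1L, 5))
  # s-core of the star: pruning at s > 1 kills the leaves first
  expect_equal(unname(kcoreness_centrality(S, weighted = TRUE)),
               c(1, 1, 1, 1, 1))
})

test_that("weighted strength and Onnela clustering use the weights", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 1
  A[2, 3] <- A[3, 2] <- 0.25
  expect_equal(unname(node_strength(A)), c(1.5, 0.75, 1.25))
  # Onnela with w_max = 1: c_1 = (0.5 * 1 * 0.25)^(1/3) / 1
  expect_equal(unname(clustering_coefficient(A, "weighted"))[1],
               (0.5 * 1 * 0.25)^(1 / 3), tolerance = 1e-12)
})

test_that("input validation rejects malformed adjacencies", {
  A <- complete(4)
  A[1, 2] <- 2; expect_error(node_strength(A), "symmetric")
  B <- complete(4); diag(B) <- 1
  expect_error(node_strength(B), "diagonal")
  C <- complete(4); C[1, 2] <- C[2, 1] <- -1
  expect_error(node_strength(C), "nonnegative")
  W <- complete(4) * 0.5
  expect_error(flow_coefficient(W), "binary")
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "no edges")
})

test_that("binary metrics agree with brute-force oracles on random graphs", {
  for (s in 1:50) {
    n <- sample(4:12, 1)
    A <- rand_graph(n, runif(1, 0.2, 0.7), weighted = FALSE, seed = s)
    expect_equal(unname(node_strength(A)), unname(rowSums(A)))
    expect_equal(unname(clustering_coefficient(A, "binary")),
                 oracle_clustering_binary(A), tolerance = 1e-10)
    expect_equal(unname(local_efficiency(A)), oracle_local_efficiency(A),
                 tolerance = 1e-10)
    expect_equal(unname(pagerank_centrality(A)), oracle_pagerank(A),
                 tolerance = 1e-8)
    expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
                 tolerance = 1e-8)
    expect_equal(unname(flow_coefficient(A)), oracle_flow(A),
                 tolerance = 1e-12)
    expect_equal(as.integer(kcoreness_centrality(A)), oracle_kcore(A))
    if (any(A > 0)) {
      expect_equal(unname(eigenvector_centrality(A)), oracle_eigenvector(A),
                   tolerance = 1e-7)
    }
  }
})

test_that("weighted metrics agree with brute-force oracles on random graphs", {
  for (s in 1:50) {
    n <- sample(4:10, 1)
    A <- rand_graph(n, runif(1, 0.3, 0.7), weighted = TRUE, seed = 1000 + s)
    expect_equal(unname(node_strength(A)), unname(rowSums(A)))
    expect_equal(unname(clustering_coefficient(A, "weighted")),
                 oracle_clustering_onnela(A), tolerance = 1e-10)
    expect_equal(unname(local_efficiency(A)), oracle_local_efficiency(A),
                 tolerance = 1e-10)
    expect_equal(unname(pagerank_centrality(A)), oracle_pagerank(A),
                 tolerance = 1e-8)
    expect_equal(unname(betweenness_centrality(A)), oracle_betweenness(A),
                 tolerance = 1e-8)
    if (any(A > 0)) {
      expect_equal(unname(eigenvector_centrality(A)), oracle_eigenvector(A),
                   tolerance = 1e-7)
    }
  }
})

test_that("weighted s-core levels are consistent with pruning survival", {
  for (s in 1:10) {
    A <- rand_graph(8, 0.5, weighted = TRUE, seed = 2000 + s)
    core <- kcoreness_centrality(A, weighted = TRUE)
    for (v in seq_len(nrow(A))) {
      expect_true(oracle_score_survives(A, v, core[v]))
      expect_false(oracle_score_survives(A, v, core[v] + 1e-6))
    }
  }
})

test_that("weighted metrics reduce to binary ones on 0/1 graphs", {
  A <- rand_graph(9, 0.4, weighted = FALSE, seed = 71)
  expect_equal(clustering_coefficient(A, "weighted"),
               clustering_coefficient(A, "binary"), tolerance = 1e-12)
  expect_equal(unname(kcoreness_centrality(A, weighted = FALSE)),
               as.integer(oracle_kcore(A)))
})

test_that("metrics are invariant under node relabeling", {
  A <- rand_graph(8, 0.5, weighted = TRUE, seed = 5)
  perm <- sample(8)
  B <- A[perm, perm]
  for (f in list(node_strength,
                 function(g) clustering_coefficient(g, "weighted"),
                 local_efficiency, pagerank_centrality,
                 betweenness_centrality, eigenvector_centrality)) {
    expect_equal(unname(f(B)), unname(f(A))[perm], tolerance = 1e-8)
  }
})

test_that("the metric table has the documented shape and is fully finite", {
  set.seed(33)
  C <- compute_fc(matrix(rnorm(80 * 20), 80, 20))
  gb <- threshold_graph(C, 0.3, "binary")
  gw <- threshold_graph(C, 0.3, "weighted")
  tab <- metric_table(gb, gw)
  expect_equal(dim(tab), c(20, 16))          # node_id + 15 metric columns
  expect_identical(names(tab)[1], "node_id")
  expect_equal(sum(grepl("_bin$", names(tab))), 8)
  expect_equal(sum(grepl("_wt$", names(tab))), 7)
  expect_true(all(is.finite(as.matrix(tab[, -1]))))
  expect_equal(tab$strength_bin, unname(node_strength(gb)))

  # 246-node scale: 246 x 15 = 3690 metric values
  set.seed(34)
  C246 <- compute_fc(matrix(rnorm(300 * 246), 300, 246))
  gb246 <- threshold_graph(C246, 0.1, "binary")
  gw246 <- threshold_graph(C246, 0.1, "weighted")
  tab246 <- metric_table(gb246, gw246)
  expect_equal(prod(dim(tab246[, -1])), 3690)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_metric_tsv(tab, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), as.matrix(tab[, -1]), tolerance = 1e-9,
               ignore_attr = TRUE)
})
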