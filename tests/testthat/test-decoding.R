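test_that("behavioral scores follow their definitions", {
  expect_equal(throughput_score(0.9, 0.5), 1.8)
  expect_equal(throughput_score(0, 2), 0)
  expect_equal(throughput_score(1, 1), 1)
  expect_error(throughput_score(0.5, 0), "median_rt")
  expect_error(throughput_score(1.4, 1), "accuracy")

  expect_equal(delay_discount_score(0.7, 0.4), 0.3)
  expect_equal(delay_discount_score(0.5, 0.5), 0)
  expect_equal(delay_discount_score(0.2, 0.5), -0.3)
})

test_that("composite score is the unit-variance first principal component", {
  set.seed(6)
  x <- rnorm(200)
  two_same <- cbind(a = 3 * x + 5, b = 3 * x + 5)
  s <- composite_score(two_same)
  expect_equal(s, as.vector(scale(x)), tolerance = 1e-10)

  noise <- matrix(rnorm(1000 * 3), 1000, 3)
  expect_equal(var(composite_score(noise)), 1, tolerance = 1e-12)

  # eigen-decomposition oracle on correlated columns
  base <- rnorm(150)
  M <- cbind(base + rnorm(150, sd = 0.5), -base + rnorm(150, sd = 0.5),
             base + rnorm(150, sd = 0.8))
  s <- composite_score(M)
  Z <- scale(M)
  ev <- eigen(cov(Z))$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  oracle <- as.vector(Z %*% ev)
  oracle <- oracle / sd(oracle)
  expect_equal(s, oracle, tolerance = 1e-8)

  expect_error(composite_score(cbind(rnorm(10), rep(1, 10))), "constant")
})

test_that("screening ranks edges by absolute correlation with ties to lower index", {
  set.seed(12)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- rnorm(50)
  X[, 7] <- y                        # perfect edge always selected
  expect_true(7 %in% screen_edges(X, y, 5))
  expect_identical(sort(screen_edges(X, y, 30)), 1:30)

  idx <- screen_edges(X, y, 5)
  r <- abs(as.vector(cor(X, y)))
  oracle <- order(-r, seq_along(r))[1:5]
  expect_identical(idx, oracle)

  X[, 3] <- 0                        # zero variance -> r = 0, never tops
  expect_message(out <- screen_edges(X, y, 29), "zero-variance")
  expect_false(3 %in% out)
  expect_error(screen_edges(X, y, 31), "top_k")
})

test_that("prediction metrics match direct arithmetic", {
  y <- c(1, 2, 3, 4); yh <- c(1, 2, 3, 5)
  m <- evaluate_predictions(y, yh)
  expect_equal(unname(m["MSE"]), 0.25)
  expect_equal(unname(m["MAE"]), 0.25)
  expect_equal(unname(m["r"]), cor(y, yh))
  expect_equal(unname(m["R2"]), 1 - 1 / sum((y - 2.5)^2))
  expect_equal(unname(m["EVS"]), 1 - var(y - yh) / var(y))

  set.seed(2); yy <- rnorm(30)
  perfect <- evaluate_predictions(yy, yy)
  expect_equal(unname(perfect), c(1, 1, 0, 1, 0), tolerance = 1e-12)
  base <- evaluate_predictions(yy, rep(mean(yy), 30))
  expect_equal(unname(base["R2"]), 0, tolerance = 1e-12)
  expect_equal(unname(base["EVS"]), 0, tolerance = 1e-12)
  expect_error(evaluate_predictions(rep(1, 5), rnorm(5)), "constant")
  expect_error(evaluate_predictions(1:4, 1:3), "length")
})

test_that("cross-validated decoding recovers a noiseless linear signal", {
  set.seed(19)
  X <- matrix(rnorm(60 * 25), 60, 25)
  y <- 3 * X[, 5]
  dec <- cross_validated_decode(X, y, enet_config(lambda = 1e-4, alpha = 0.5),
                                n_folds = 10, top_k = 10, seed = 2)
  expect_gte(unname(dec$metrics["r"]), 0.99)
  expect_equal(unname(dec$edge_frequency[5]), 1)
})

test_that("decoding is deterministic under a fixed seed", {
  set.seed(23)
  X <- matrix(rnorm(50 * 15), 50, 15)
  y <- X[, 2] + rnorm(50, sd = 0.5)
  a <- cross_validated_decode(X, y, enet_config(lambda = 5), n_folds = 5,
                              top_k = 10, seed = 42)
  b <- cross_validated_decode(X, y, enet_config(lambda = 5), n_folds = 5,
                              top_k = 10, seed = 42)
  expect_identical(a$folds, b$folds)
  expect_identical(a$oof_predictions, b$oof_predictions)
  expect_identical(a$metrics, b$metrics)
})

test_that("null decoding is centred on zero correlation", {
  set.seed(77)
  rs <- replicate(100, {
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rnorm(40)
    dec <- cross_validated_decode(X, y, enet_config(lambda = 8, alpha = 0.5),
                                  n_folds = 5, top_k = 10,
                                  seed = sample.int(1e6, 1))
    unname(dec$metrics["r"])
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("aggregation respects the fold-frequency threshold", {
  set.seed(4)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- X[, 1] + rnorm(60, sd = 0.2)
  dec <- cross_validated_decode(X, y, enet_config(lambda = 10), n_folds = 10,
                                top_k = 10, seed = 5)
  expect_true(1 %in% aggregate_edges(dec, 0.5))
  inter <- aggregate_edges(dec, 1.0)
  expect_true(all(dec$edge_frequency[inter] == 1))
  fake <- dec
  fake$edge_frequency[] <- 0
  expect_warning(out <- aggregate_edges(fake, 0.5), "no edge")
  expect_length(out, 0)
  expect_error(aggregate_edges(dec, 0), "freq_threshold")
})

test_that("permutation p respects the add-one lower bound and detects signal", {
  set.seed(9)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- X[, 4] + rnorm(60, sd = 0.3)
  pt <- permutation_test(X, y, enet_config(lambda = 1), n_permutations = 19,
                         n_folds = 5, top_k = 6, seed = 3)
  expect_equal(pt$p, 1 / 20)
  expect_gte(pt$p, 1 / (pt$n_permutations + 1))
})

test_that("fold-restricted fitting gives a held-out-only marker no advantage", {
  set.seed(55)
  n <- 100
  X <- matrix(rnorm(n * 30), n, 30)
  y <- rnorm(n)
  folds <- taskgcn:::make_folds(n, 5, seed = 8)
  marker <- rnorm(n)
  marker[folds == 1] <- y[folds == 1]   # informative only where held out
  Xm <- cbind(X, marker = marker)
  dec <- cross_validated_decode(Xm, y, enet_config(lambda = 5, alpha = 0.5),
                                n_folds = 5, top_k = 10, seed = 8)
  expect_lt(abs(unname(dec$metrics["r"])), 0.3)
})
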