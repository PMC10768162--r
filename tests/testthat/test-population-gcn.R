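test_that("phenotype agreement implements the unit-step gamma", {
  expect_equal(phenotype_agreement(10, 11.5, theta = 2, type = "continuous"), 1L)
  expect_equal(phenotype_agreement(10, 12, theta = 2, type = "continuous"), 0L)
  expect_equal(phenotype_agreement(c(1, 5), c(2, 1), theta = 2,
                                   type = "continuous"), c(1L, 0L))
  expect_equal(phenotype_agreement("a", "a", type = "categorical"), 1L)
  expect_equal(phenotype_agreement(1, 2, type = "categorical"), 0L)
  expect_error(phenotype_agreement(1, 2, type = "continuous"), "theta")
})

test_that("feature similarity is the Gaussian kernel of correlation distance", {
  x <- c(1, 2, 3, 4)
  expect_equal(feature_similarity(x, x, sigma = 0.7), 1)
  # perfect anticorrelation: rho = 2 -> exp(-4 / (2 sigma^2))
  expect_equal(feature_similarity(x, -x, sigma = 1), exp(-2), tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  rho <- 1 - cor(a, b)
  expect_equal(feature_similarity(a, b, sigma = 0.5),
               exp(-rho^2 / (2 * 0.25)), tolerance = 1e-12)
  expect_error(feature_similarity(a, b, sigma = 0), "sigma")
  expect_error(feature_similarity(rep(1, 5), 1:5), "constant")
})

test_that("the population graph matches a three-subject hand computation", {
  F3 <- rbind(c(1, 2, 3, 4),
              c(2, 4, 6, 8),      # r = 1 with subject 1
              c(4, 3, 2, 1))      # r = -1 with subject 1
  phen <- data.frame(age = c(10, 11, 15), sex = c(0, 0, 1),
                     site = c(1, 1, 1))
  pg <- build_population_graph(F3, phen, sigma = 1)
  # gammas: (1,2) age|diff 1|<2 yes, sex yes, site yes -> 3; (1,3): age no,
  # sex no, site yes -> 1; (2,3): age no, sex no, site yes -> 1
  expect_equal(pg$W[1, 2], exp(0) * 3, tolerance = 1e-12)
  expect_equal(pg$W[1, 3], exp(-4 / 2) * 1, tolerance = 1e-12)
  expect_equal(pg$W[2, 3], exp(-4 / 2) * 1, tolerance = 1e-12)
  expect_equal(diag(pg$W), rep(0, 3))
  expect_equal(pg$W, t(pg$W))
  # auto sigma = median pairwise correlation distance (0, 2, 2) -> 2
  pg2 <- build_population_graph(F3, phen, sigma = "auto")
  expect_equal(pg2$sigma, 2)
  expect_error(build_population_graph(F3, phen[, 1:2, drop = FALSE]),
               "missing")
})

test_that("the normalized Laplacian has the known spectrum", {
  # complete graph K_n: eigenvalues 0 and n/(n-1)
  for (n in c(4, 7)) {
    W <- matrix(1, n, n); diag(W) <- 0
    L <- normalized_laplacian(W)
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(ev[1], 0, tolerance = 1e-12)
    expect_equal(ev[2:n], rep(n / (n - 1), n - 1), tolerance = 1e-12)
  }
  # two-node path: eigenvalues 0 and 2
  L2 <- normalized_laplacian(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sort(eigen(L2, only.values = TRUE)$values), c(0, 2),
               tolerance = 1e-12)
  # isolated node gets an identity row
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  L <- normalized_laplacian(W)
  expect_equal(L[3, ], c(0, 0, 1))
  # random graphs: spectrum within [0, 2]
  for (s in 1:100) {
    set.seed(s)
    n <- sample(3:12, 1)
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    W[W < 0.3] <- 0
    ev <- eigen(normalized_laplacian(W), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_lte(max(ev), 2 + 1e-10)
  }
  expect_error(normalized_laplacian(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("Chebyshev filtering equals the spectral-domain definition", {
  set.seed(14)
  n <- 10; p <- 4; q <- 3; K <- 3
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
  L <- normalized_laplacian(W)
  lam_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  X <- matrix(rnorm(n * p), n, p)
  Theta <- lapply(1:K, function(k) matrix(rnorm(p * q), p, q))

  out <- chebyshev_conv(L, X, Theta)

  # spectral oracle: U diag(T_k(lambda_tilde)) U' X Theta_k summed over k
  e <- eigen(L, symmetric = TRUE)
  lt <- 2 * e$values / lam_max - 1
  cheb <- function(k, x) cos(k * acos(pmin(pmax(x, -1), 1)))
  oracle <- matrix(0, n, q)
  for (k in 0:(K - 1)) {
    Fk <- e$vectors %*% diag(cheb(k, lt)) %*% t(e$vectors)
    oracle <- oracle + Fk %*% X %*% Theta[[k + 1]]
  }
  expect_equal(out, oracle, tolerance = 1e-10)

  # K = 1 is a plain dense layer: X Theta_0
  expect_equal(chebyshev_conv(L, X, Theta[1]), X %*% Theta[[1]],
               tolerance = 1e-12)

  # permutation equivariance
  perm <- sample(n)
  out_p <- chebyshev_conv(normalized_laplacian(W[perm, perm]),
                          X[perm, , drop = FALSE], Theta)
  expect_equal(out_p, out[perm, , drop = FALSE], tolerance = 1e-9)
})

test_that("training reduces the masked loss and fits separable data", {
  pop <- simulate_population(n = 60, n_features = 12, n_informative = 6,
                             shift = 3, seed = 4)
  pg <- build_population_graph(scale(pop$features), pop$phenotypes)
  mask <- rep(c(TRUE, TRUE, FALSE), 20)
  model <- train_gcn(pg, scale(pop$features), pop$labels, mask,
                     hidden = 8, epochs = 150, seed = 2)
  expect_lt(mean(tail(model$loss_trace, 10)), model$loss_trace[1])
  # strongly separable features: training subjects are classified correctly
  pred_tr <- (model$probs[mask, "class1"] > 0.5) * 1
  expect_gte(mean(pred_tr == pop$labels[mask]), 0.95)
  expect_equal(unname(rowSums(model$probs)), rep(1, 60), tolerance = 1e-10)
  expect_error(train_gcn(pg, scale(pop$features), rep(0, 60), mask),
               "both classes")
})

test_that("training is deterministic under a fixed seed", {
  pop <- simulate_population(n = 40, n_features = 10, seed = 9)
  pg <- build_population_graph(scale(pop$features), pop$phenotypes)
  mask <- seq_len(40) <= 30
  a <- train_gcn(pg, scale(pop$features), pop$labels, mask, hidden = 4,
                 epochs = 30, seed = 7)
  b <- train_gcn(pg, scale(pop$features), pop$labels, mask, hidden = 4,
                 epochs = 30, seed = 7)
  expect_identical(a$probs, b$probs)
  expect_identical(a$loss_trace, b$loss_trace)
})

test_that("cross-validated GCN reaches ceiling on separable data", {
  pop <- simulate_population(n = 100, n_features = 20, n_informative = 10,
                             shift = 4, seed = 11)
  res <- evaluate_cv(pop$features, pop$phenotypes, pop$labels, k = 5,
                     seed = 3, n_keep = NULL, hidden = 8, epochs = 150)
  expect_gte(res$mean_auc, 0.99)
  expect_gte(res$mean_acc, 0.95)
  expect_equal(nrow(res$per_fold), 5)
  # folds are stratified: every fold holds both classes
  for (f in 1:5) {
    expect_setequal(unique(pop$labels[res$folds == f]), 0:1)
  }
})

test_that("cross-validated GCN stays at chance on pure noise", {
  aucs <- vapply(1:10, function(s) {
    pop <- simulate_population(n = 60, n_features = 10, n_informative = 0,
                               shift = 0, seed = 100 + s)
    res <- evaluate_cv(pop$features, pop$phenotypes, pop$labels, k = 5,
                       seed = s, n_keep = NULL, hidden = 4, epochs = 60)
    res$mean_auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("the transductive mask prevents test-label leakage", {
  # cheat feature: equals the label on training subjects, noise on held-out
  # ones.  A leak-free pipeline can exploit it only where labels are known, so
  # held-out AUC must remain near chance.
  set.seed(21)
  n <- 90
  labels <- rep(0:1, length.out = n)
  folds <- stratified_folds(labels, 3, seed = 5)
  X <- matrix(rnorm(n * 8), n, 8)
  cheat <- rnorm(n)
  tr <- folds != 1
  cheat[tr] <- labels[tr]
  X <- cbind(X, cheat = cheat)
  phen <- data.frame(age = runif(n, 8, 18), sex = rbinom(n, 1, 0.5),
                     site = sample.int(2, n, TRUE))
  pg <- build_population_graph(scale(X), phen, train_idx = which(tr))
  model <- train_gcn(pg, scale(X), labels, tr, hidden = 8, epochs = 150,
                     seed = 9)
  auc_test <- taskgcn:::binary_auc(labels[!tr], model$probs[!tr, "class1"])
  expect_lte(auc_test, 0.75)
  # the same model exploits the cheat feature on training subjects
  auc_train <- taskgcn:::binary_auc(labels[tr], model$probs[tr, "class1"])
  expect_gte(auc_train, 0.9)
})
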