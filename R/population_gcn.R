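# Population-graph construction and the Chebyshev spectral graph
# convolutional classifier.
#
# Subjects are the nodes of a population graph whose edge weights multiply an
# imaging-feature similarity kernel, Sim(x, y) = exp(-rho^2 / (2 sigma^2))
# with rho the correlation distance 1 - Pearson(F(x), F(y)), by the number of
# phenotype columns on which the two subjects agree (unit-step gamma with
# threshold theta for continuous columns, exact match for categorical).  The
# classifier filters node features with order-K Chebyshev polynomials of the
# rescaled normalized Laplacian and is trained transductively: the loss is
# evaluated on the training-mask subjects only.

#' Phenotype column specification
#'
#' @param age_theta agreement threshold for the continuous age column (years).
#' @return named list, one entry per column: `type` ("continuous" or
#'   "categorical") and `theta` (continuous only).
#' @export
default_phenotype_spec <- function(age_theta = 2) {
  list(age = list(type = "continuous", theta = age_theta),
       sex = list(type = "categorical"),
       site = list(type = "categorical"))
}

#' Phenotype agreement (unit-step gamma)
#'
#' Continuous columns agree when |a - b| < theta; categorical columns when
#' equal.
#'
#' @param a,b phenotype values. @param theta threshold (continuous, > 0).
#' @param type column type.
#' @return 0 or 1 (vectorized).
#' @export
phenotype_agreement <- function(a, b, theta = NULL,
                                type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (type == "continuous") {
    if (is.null(theta) || theta <= 0) stop("continuous columns need theta > 0")
    if (!is.numeric(a) || !is.numeric(b)) stop("type mismatch: numeric expected")
    as.integer(abs(a - b) < theta)
  } else {
    as.integer(a == b)
  }
}

#' Feature-similarity kernel
#'
#' \eqn{Sim = \exp(-\rho^2 / (2\sigma^2))} with \eqn{\rho = 1 - r(f_x, f_y)}
#' the correlation distance; lies in (0, 1].
#'
#' @param fx,fy feature vectors (equal length, non-constant).
#' @param sigma kernel width (> 0).
#' @return scalar similarity.
#' @export
feature_similarity <- function(fx, fy, sigma = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (stats::sd(fx) == 0 || stats::sd(fy) == 0) stop("constant feature vector")
  rho <- 1 - stats::cor(fx, fy)
  exp(-rho^2 / (2 * sigma^2))
}

#' Build the population graph
#'
#' W(x, y) = Sim(x, y) * sum_h gamma_h(x, y); symmetric, zero diagonal,
#' entries in \[0, H\].
#'
#' @param features subjects x features matrix (rows non-constant).
#' @param phenotypes data.frame with the columns named in `spec` (rows aligned
#'   with `features`).
#' @param spec phenotype specification, see [default_phenotype_spec()].
#' @param sigma kernel width, or `"auto"` = median pairwise correlation
#'   distance among `train_idx` subjects (all subjects if omitted).
#' @param train_idx indices used for the sigma auto-selection, keeping test
#'   subjects out of any fitted statistic.
#' @return object of class `population_graph`: `W`, `sigma`, `n_phenotypes`.
#' @export
build_population_graph <- function(features, phenotypes, spec = default_phenotype_spec(),
                                   sigma = "auto", train_idx = NULL) {
  stopifnot(is.matrix(features), nrow(features) == nrow(phenotypes))
  if (!all(names(spec) %in% colnames(phenotypes))) {
    stop("phenotype column(s) missing: ",
         paste(setdiff(names(spec), colnames(phenotypes)), collapse = ", "))
  }
  n <- nrow(features)
  if (any(apply(features, 1, stats::sd) == 0)) stop("constant feature row")
  R <- stats::cor(t(features))
  rho <- 1 - R
  if (identical(sigma, "auto")) {
    idx <- if (is.null(train_idx)) seq_len(n) else train_idx
    d <- rho[idx, idx][upper.tri(diag(length(idx)))]
    sigma <- stats::median(d)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1e-3
  }
  Sim <- exp(-rho^2 / (2 * sigma^2))
  Gam <- matrix(0, n, n)
  for (col in names(spec)) {
    v <- phenotypes[[col]]
    if (spec[[col]]$type == "continuous") {
      A <- abs(outer(v, v, "-")) < spec[[col]]$theta
    } else {
      A <- outer(v, v, "==")
    }
    Gam <- Gam + A
  }
  W <- Sim * Gam
  W <- (W + t(W)) / 2
  diag(W) <- 0
  structure(list(W = W, sigma = sigma, n_phenotypes = length(spec)),
            class = "population_graph")
}

#' Symmetric normalized graph Laplacian
#'
#' \eqn{L = I - D^{-1/2} W D^{-1/2}} with D the diagonal degree (row-sum)
#' matrix; isolated nodes get identity rows.  Eigenvalues lie in \[0, 2\].
#'
#' @param W symmetric nonnegative adjacency.
#' @return symmetric Laplacian matrix.
#' @export
normalized_laplacian <- function(W) {
  if (inherits(W, "population_graph")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) stop("negative entry in W")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -W * (dinv %o% dinv)
  diag(L) <- 1
  (L + t(L)) / 2
}

# Chebyshev polynomial basis T_0 ... T_{K-1} of the rescaled Laplacian
# Lt = 2 L / lambda_max - I.
chebyshev_basis <- function(L, K, lambda_max = NULL) {
  stopifnot(K >= 1)
  if (is.null(lambda_max)) {
    lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (lambda_max <= 0) stop("lambda_max must be > 0")
  n <- nrow(L)
  Lt <- 2 * L / lambda_max - diag(n)
  Tk <- vector("list", K)
  Tk[[1]] <- diag(n)
  if (K >= 2) Tk[[2]] <- Lt
  if (K >= 3) {
    for (k in 3:K) Tk[[k]] <- 2 * Lt %*% Tk[[k - 1]] - Tk[[k - 2]]
  }
  Tk
}

#' Chebyshev spectral graph convolution
#'
#' Evaluates \eqn{\sum_{k=0}^{K-1} T_k(\tilde L)\, X\, \Theta_k} with
#' \eqn{\tilde L = 2L/\lambda_{max} - I}, the polynomial form of the spectral
#' filter \eqn{U g_\theta(\Lambda) U^\top X}; linear in X and equivariant to
#' node permutations.
#'
#' @param L normalized Laplacian. @param X node-feature matrix (n x p).
#' @param Theta list of K coefficient matrices (p x q).
#' @param lambda_max optional precomputed spectral radius.
#' @return n x q filtered features.
#' @export
chebyshev_conv <- function(L, X, Theta, lambda_max = NULL) {
  K <- length(Theta)
  Tk <- chebyshev_basis(L, K, lambda_max)
  out <- matrix(0, nrow(X), ncol(Theta[[1]]))
  for (k in seq_len(K)) out <- out + Tk[[k]] %*% X %*% Theta[[k]]
  out
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Train the Chebyshev graph convolutional classifier
#'
#' Two Chebyshev convolution layers (hidden ReLU width `hidden`, softmax
#' output over 2 classes) trained with Adam on the masked cross-entropy of the
#' training subjects only (transductive semi-supervised setting).  Gradients
#' are computed with explicit backpropagation; inverted dropout is applied to
#' the hidden activations during training.
#'
#' @param W population adjacency (or `population_graph`).
#' @param X subjects x features matrix.
#' @param labels 0/1 vector. @param train_mask logical vector; both classes
#'   must appear among the training subjects.
#' @param hidden hidden channels. @param K Chebyshev order (>= 1).
#' @param dropout hidden dropout rate. @param lr Adam learning rate.
#' @param epochs training epochs. @param weight_decay L2 penalty on weights.
#' @param seed integer seed (initialization + dropout).
#' @return object of class `gcn_model`: parameters, `loss_trace`, `probs`
#'   (posterior class probabilities for all subjects, dropout off), and the
#'   cached Chebyshev basis.
#' @export
train_gcn <- function(W, X, labels, train_mask, hidden = 16, K = 3,
                      dropout = 0.3, lr = 0.005, epochs = 200,
                      weight_decay = 5e-4, seed = 1) {
  if (inherits(W, "population_graph")) W <- W$W
  stopifnot(is.matrix(X), length(labels) == nrow(X),
            length(train_mask) == nrow(X))
  if (length(unique(labels[train_mask])) < 2) {
    stop("training mask must contain both classes")
  }
  set.seed(derive_seed(seed, "gcn"))
  n <- nrow(X); p <- ncol(X)
  L <- normalized_laplacian(W)
  Tk <- chebyshev_basis(L, K)
  TX <- lapply(Tk, function(Tm) Tm %*% X)
  Y <- cbind(1 - labels, labels)           # one-hot, class order 0, 1
  n_train <- sum(train_mask)

  Th1 <- lapply(seq_len(K), function(k) glorot(p, hidden))
  b1 <- rep(0, hidden)
  Th2 <- lapply(seq_len(K), function(k) glorot(hidden, 2))
  b2 <- rep(0, 2)

  params <- c(Th1, list(b1), Th2, list(b2))
  m_adam <- lapply(params, function(q) q * 0)
  v_adam <- lapply(params, function(q) q * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  forward <- function(drop_mask = NULL) {
    Z1 <- Reduce(`+`, Map(function(tx, th) tx %*% th, TX, Th1))
    Z1 <- sweep(Z1, 2, b1, "+")
    H <- relu(Z1)
    Hd <- if (is.null(drop_mask)) H else H * drop_mask / (1 - dropout)
    TH <- lapply(Tk, function(Tm) Tm %*% Hd)
    Z2 <- Reduce(`+`, Map(function(th_in, th) th_in %*% th, TH, Th2))
    Z2 <- sweep(Z2, 2, b2, "+")
    list(Z1 = Z1, H = H, Hd = Hd, TH = TH, P = softmax_rows(Z2))
  }

  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    drop_mask <- if (dropout > 0) {
      matrix(stats::rbinom(n * hidden, 1, 1 - dropout), n, hidden)
    } else NULL
    fw <- forward(drop_mask)
    P <- fw$P
    ll <- -sum(log(pmax(P[cbind(which(train_mask),
                                labels[train_mask] + 1L)], 1e-12))) / n_train
    reg <- weight_decay / 2 *
      (sum(vapply(Th1, function(q) sum(q^2), numeric(1))) +
       sum(vapply(Th2, function(q) sum(q^2), numeric(1))))
    loss_trace[ep] <- ll + reg
    if (!is.finite(loss_trace[ep])) {
      stop("non-finite loss at epoch ", ep, " (loss = ", loss_trace[ep], ")")
    }

    G2 <- P - Y
    G2[!train_mask, ] <- 0
    G2 <- G2 / n_train
    dTh2 <- Map(function(th_in, th) crossprod(th_in, G2) + weight_decay * th,
                fw$TH, Th2)
    db2 <- colSums(G2)
    dHd <- Reduce(`+`, Map(function(Tm, th) Tm %*% G2 %*% t(th), Tk, Th2))
    dH <- if (is.null(drop_mask)) dHd else dHd * drop_mask / (1 - dropout)
    dZ1 <- dH * (fw$Z1 > 0)
    dTh1 <- Map(function(tx, th) crossprod(tx, dZ1) + weight_decay * th,
                TX, Th1)
    db1 <- colSums(dZ1)

    grads <- c(dTh1, list(db1), dTh2, list(db2))
    params <- c(Th1, list(b1), Th2, list(b2))
    for (q in seq_along(params)) {
      m_adam[[q]] <- beta1 * m_adam[[q]] + (1 - beta1) * grads[[q]]
      v_adam[[q]] <- beta2 * v_adam[[q]] + (1 - beta2) * grads[[q]]^2
      mhat <- m_adam[[q]] / (1 - beta1^ep)
      vhat <- v_adam[[q]] / (1 - beta2^ep)
      params[[q]] <- params[[q]] - lr * mhat / (sqrt(vhat) + eps)
    }
    Th1 <- params[seq_len(K)]
    b1 <- params[[K + 1]]
    Th2 <- params[(K + 2):(2 * K + 1)]
    b2 <- params[[2 * K + 2]]
  }

  probs <- forward(NULL)$P
  colnames(probs) <- c("class0", "class1")
  structure(list(Theta1 = Th1, bias1 = b1, Theta2 = Th2, bias2 = b2,
                 K = K, hidden = hidden, dropout = dropout, lr = lr,
                 epochs = epochs, weight_decay = weight_decay, seed = seed,
                 basis = Tk, loss_trace = loss_trace, probs = probs),
            class = "gcn_model")
}

#' Posterior class probabilities of a trained GCN
#'
#' @param model a `gcn_model`. @param X feature matrix on the same graph
#'   (defaults to the cached training-time posteriors when omitted).
#' @return n x 2 probability matrix.
#' @export
predict_gcn <- function(model, X = NULL) {
  if (is.null(X)) return(model$probs)
  Tk <- model$basis
  TX <- lapply(Tk, function(Tm) Tm %*% X)
  Z1 <- Reduce(`+`, Map(function(tx, th) tx %*% th, TX, model$Theta1))
  Z1 <- sweep(Z1, 2, model$bias1, "+")
  H <- relu(Z1)
  TH <- lapply(Tk, function(Tm) Tm %*% H)
  Z2 <- Reduce(`+`, Map(function(th_in, th) th_in %*% th, TH, model$Theta2))
  Z2 <- sweep(Z2, 2, model$bias2, "+")
  P <- softmax_rows(Z2)
  colnames(P) <- c("class0", "class1")
  P
}

stratified_folds <- function(labels, k, seed) {
  set.seed(derive_seed(seed, "strat_folds"))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

binary_auc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Cross-validated population-GCN classification
#'
#' Stratified k-fold evaluation.  Per fold: features are z-scored with
#' training-subject statistics, ridge-RFE (optional) is fitted on training
#' subjects only, the population graph is built over all subjects from the
#' transformed features (sigma auto-selected from training pairs), and the GCN
#' is trained with the training mask; AUC and accuracy are computed on the
#' held-out mask.
#'
#' @param features subjects x features matrix.
#' @param phenotypes aligned phenotype data.frame.
#' @param labels 0/1 vector. @param spec phenotype spec.
#' @param k folds (default 5). @param seed integer seed.
#' @param n_keep RFE target size (`NULL` or >= ncol disables RFE).
#' @param sigma kernel width or `"auto"`.
#' @param ... passed to [train_gcn()] (hidden, K, dropout, lr, epochs, ...).
#' @return list with `per_fold` (data.frame fold/auc/acc), `mean_auc`,
#'   `sd_auc`, `mean_acc`, `sd_acc`, `folds`, `seed`.
#' @export
evaluate_cv <- function(features, phenotypes, labels,
                        spec = default_phenotype_spec(), k = 5, seed = 1,
                        n_keep = 200, sigma = "auto", ...) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  folds <- stratified_folds(labels, k, seed)
  if (any(tabulate(folds, k) < 2)) stop("a fold has fewer than 2 subjects")
  per <- data.frame(fold = seq_len(k), auc = NA_real_, acc = NA_real_)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[!tr])) < 2 || length(unique(labels[tr])) < 2) {
      stop("single-class fold; reduce k or rebalance")
    }
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- sweep(sweep(features, 2, mu), 2, sdv, "/")
    if (!is.null(n_keep) && n_keep < ncol(Z)) {
      sel <- rfe_ridge(Z[tr, , drop = FALSE], labels[tr], n_keep = n_keep)
      Z <- Z[, sel, drop = FALSE]
    }
    pg <- build_population_graph(Z, phenotypes, spec, sigma = sigma,
                                 train_idx = which(tr))
    model <- train_gcn(pg, Z, labels, train_mask = tr,
                       seed = derive_seed(seed, paste0("fold", f)), ...)
    scores <- model$probs[!tr, "class1"]
    per$auc[f] <- binary_auc(labels[!tr], scores)
    per$acc[f] <- mean((scores > 0.5) == (labels[!tr] == 1))
  }
  list(per_fold = per,
       mean_auc = mean(per$auc), sd_auc = stats::sd(per$auc),
       mean_acc = mean(per$acc), sd_acc = stats::sd(per$acc),
       folds = folds, seed = seed)
}
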