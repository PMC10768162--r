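# Elastic-net solver for the behavioral decoding model.
#
# The objective (intercept unpenalised) is
#
#   sum_i (y_i - b0 - x_i' beta)^2
#     + lambda * sum_j ( alpha |beta_j| + (1/2) (1 - alpha) beta_j^2 )
#
# i.e. the residual sum of squares carries no 1/(2n) factor: lambda here is
# 2n times the lambda of glmnet's parameterisation (alpha is identical).
# alpha = 1 is the lasso, alpha = 0 ridge regression with exact minimizer
# (X'X + (lambda/2) I)^{-1} X'y on centred data.

#' Elastic-net configuration
#'
#' @param lambda penalty weight (>= 0), or `NULL` to request nested
#'   cross-validated tuning where supported.
#' @param alpha L1/L2 mixing in \[0, 1\]; 1 = lasso, 0 = ridge.
#' @param max_iter maximum coordinate-descent sweeps.
#' @param tol convergence tolerance on the max coefficient change per sweep.
#' @param standardize z-score columns of X (and report coefficients on the
#'   original scale)?  The penalty always applies on the fitting scale.
#' @return object of class `enet_config`.
#' @export
enet_config <- function(lambda = NULL, alpha = 0.5, max_iter = 100000L,
                        tol = 1e-8, standardize = TRUE) {
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  structure(list(lambda = lambda, alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 standardize = isTRUE(standardize)),
            class = "enet_config")
}

#' Smallest lambda that zeroes all coefficients (alpha > 0)
#'
#' For the package's objective, beta = 0 is optimal iff
#' \eqn{2 |x_j' y_c| \le \lambda\alpha} for all columns, where y_c is the
#' centred response and x_j the (centred, possibly standardized) column.
#'
#' @param X design matrix. @param y response. @param alpha mixing parameter.
#' @param standardize match the fitting scale.
#' @return scalar lambda_max.
#' @export
lambda_max <- function(X, y, alpha = 0.5, standardize = TRUE) {
  if (alpha <= 0) stop("lambda_max is defined for alpha > 0")
  Xc <- scale(X, center = TRUE, scale = standardize)
  Xc[is.na(Xc)] <- 0
  yc <- y - mean(y)
  # relative guard so beta = 0 exactly at lambda >= lambda_max even when the
  # solver's compiled dot products round differently from crossprod()
  2 * max(abs(crossprod(Xc, yc))) / alpha * (1 + 1e-10)
}

#' Evaluate the penalised least-squares objective
#'
#' @param X,y data. @param beta,intercept coefficients.
#' @param lambda,alpha penalty parameters.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, beta, intercept, lambda, alpha) {
  r <- y - intercept - as.vector(X %*% beta)
  sum(r^2) + lambda * sum(alpha * abs(beta) + 0.5 * (1 - alpha) * beta^2)
}

#' Fit the elastic-net regression
#'
#' Cyclic coordinate descent on the exact objective above; the intercept is
#' unpenalised.  With `standardize = TRUE` the penalty applies to coefficients
#' of z-scored columns and the returned `beta` is mapped back to the original
#' scale (`beta_std` keeps the fitting-scale coefficients).
#'
#' @param X numeric matrix (n x p), n >= 2. @param y numeric response.
#' @param cfg an [enet_config()] with numeric `lambda`.
#' @return list with `beta`, `intercept`, `beta_std`, `lambda`, `alpha`,
#'   `iter`, `converged`.
#' @export
fit_elastic_net <- function(X, y, cfg = enet_config(lambda = 1)) {
  stopifnot(inherits(cfg, "enet_config"), is.matrix(X))
  if (is.null(cfg$lambda)) stop("cfg$lambda must be numeric for a single fit")
  if (nrow(X) < 2) stop("need n >= 2")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  scales <- rep(1, ncol(X))
  Xf <- X
  if (cfg$standardize) {
    scales <- apply(X, 2, stats::sd)
    scales[scales == 0] <- 1
    Xf <- sweep(X, 2, scales, "/")
  }
  fit <- .enet_cd(Xf, y, cfg$lambda, cfg$alpha, cfg$max_iter, cfg$tol)
  if (!fit$converged) {
    stop("coordinate descent did not converge in ", cfg$max_iter,
         " sweeps (last max coefficient change ", format(fit$last_delta), ")")
  }
  beta_std <- fit$beta
  beta <- beta_std / scales
  intercept <- mean(y) - sum(beta * colMeans(X))
  names(beta) <- names(beta_std) <- colnames(X)
  list(beta = beta, intercept = intercept, beta_std = beta_std,
       lambda = cfg$lambda, alpha = cfg$alpha,
       iter = fit$iter, converged = fit$converged)
}

predict_enet <- function(fit, X) {
  fit$intercept + as.vector(X %*% fit$beta)
}

# Fit the whole decreasing-lambda path with warm starts; returns coefficients
# on the original X scale (p x nlambda) plus intercepts.
enet_path <- function(X, y, lambdas, alpha, standardize = TRUE,
                      max_iter = 100000L, tol = 1e-6) {
  scales <- rep(1, ncol(X))
  Xf <- X
  if (standardize) {
    scales <- apply(X, 2, stats::sd)
    scales[scales == 0] <- 1
    Xf <- sweep(X, 2, scales, "/")
  }
  path <- .enet_cd_path(Xf, y, lambdas, alpha, max_iter, tol)
  B <- path$beta / scales
  intercepts <- mean(y) - as.vector(colMeans(X) %*% B)
  list(beta = B, intercept = intercepts, lambdas = lambdas,
       converged = path$converged)
}

# Inner-CV grid tuning with a global 1-SE parsimony rule: among all
# (alpha, lambda) whose mean inner-CV MSE lies within one standard error of
# the global minimum, pick the candidate with the fewest nonzero coefficients
# (ties: larger alpha, then larger lambda).  When `top_k` is given, edge
# screening is repeated inside every inner training fold — screening once
# before the inner split would let the held-in validation subjects influence
# the screen and bias the tuner toward over-selection.  Warm-started lambda
# paths keep the grid cheap.  Returns the chosen (lambda, alpha).
tune_enet <- function(X, y, alphas = c(0.1, 0.5, 0.9), n_lambda = 10,
                      lambda_min_ratio = 1e-3, inner_folds = 3, seed = 1,
                      standardize = TRUE, top_k = NULL) {
  set.seed(derive_seed(seed, "tune_enet"))
  n <- nrow(X)
  folds <- sample(rep_len(seq_len(inner_folds), n))
  screen_k <- if (is.null(top_k)) ncol(X) else min(top_k, ncol(X))
  # a common lambda grid per alpha, anchored on the full training design
  anchor_idx <- if (screen_k < ncol(X)) {
    suppressMessages(screen_edges(X, y, screen_k))
  } else {
    seq_len(ncol(X))
  }
  inner_idx <- lapply(seq_len(inner_folds), function(f) {
    tr <- folds != f
    if (screen_k < ncol(X)) {
      suppressMessages(screen_edges(X[tr, , drop = FALSE], y[tr], screen_k))
    } else {
      seq_len(ncol(X))
    }
  })
  grid <- NULL
  for (a in alphas) {
    lmax <- lambda_max(X[, anchor_idx, drop = FALSE], y,
                       alpha = max(a, 0.05), standardize = standardize)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambda))
    mse <- matrix(NA_real_, inner_folds, n_lambda)
    nnz <- matrix(NA_real_, inner_folds, n_lambda)
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      idx <- inner_idx[[f]]
      path <- enet_path(X[tr, idx, drop = FALSE], y[tr], lambdas, a,
                        standardize = standardize)
      pred <- X[!tr, idx, drop = FALSE] %*% path$beta
      pred <- sweep(pred, 2, path$intercept, "+")
      mse[f, ] <- colMeans((y[!tr] - pred)^2)
      nnz[f, ] <- colSums(path$beta != 0)
    }
    grid <- rbind(grid,
                  data.frame(alpha = a, lambda = lambdas,
                             mse = colMeans(mse),
                             se = apply(mse, 2, stats::sd) / sqrt(inner_folds),
                             nnz = colMeans(nnz)))
  }
  best <- which.min(grid$mse)
  ok <- grid[grid$mse <= grid$mse[best] + grid$se[best], , drop = FALSE]
  ok <- ok[order(ok$nnz, -ok$alpha, -ok$lambda), , drop = FALSE]
  list(lambda = ok$lambda[1], alpha = ok$alpha[1])
}
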