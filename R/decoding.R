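# Behavior-driven decoding of task-specific FC edges: behavioral scores,
# univariate edge screening, cross-validated elastic-net fits, coefficient
# aggregation across folds, a permutation test, and prediction metrics.

## ---- behavioral scores ------------------------------------------------------

#' Behavioral scores
#'
#' `throughput_score` is accuracy divided by median reaction time (a
#' speed-accuracy composite); `delay_discount_score` is the difference in
#' delay-discounting area-under-curve between a large and a small reward
#' magnitude; `composite_score` collapses several measures into a general
#' factor: columns are z-scored and the first principal-component score is
#' rescaled to unit variance, sign-fixed so the loading sum is positive.
#'
#' @param accuracy proportion correct in \[0, 1\].
#' @param median_rt median reaction time (seconds, > 0).
#' @param auc_large,auc_small discounting AUCs for the large/small magnitude.
#' @param measures numeric matrix or data.frame, subjects x measures (>= 2
#'   measures, >= 3 subjects, no missing values, no constant column).
#' @return scalar score, or one composite score per subject.
#' @export
throughput_score <- function(accuracy, median_rt) {
  if (any(median_rt <= 0)) stop("median_rt must be > 0")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must be in [0, 1]")
  accuracy / median_rt
}

#' @rdname throughput_score
#' @export
delay_discount_score <- function(auc_large, auc_small) {
  stopifnot(is.finite(auc_large), is.finite(auc_small))
  auc_large - auc_small
}

#' @rdname throughput_score
#' @export
composite_score <- function(measures) {
  M <- as.matrix(measures)
  if (ncol(M) < 2) stop("need at least 2 measures")
  if (nrow(M) < 3) stop("need at least 3 subjects")
  if (anyNA(M)) stop("missing values not allowed")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  }
  Z <- scale(M)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  if (sum(pc$rotation[, 1]) < 0) s <- -s
  as.vector(s / stats::sd(s))
}

## ---- screening and cross-validated decoding ---------------------------------

#' Univariate edge screening
#'
#' Ranks edges by the absolute Pearson correlation of their FC values with the
#' behavioral score and keeps the strongest `top_k`; ties break toward the
#' lower column index.  Zero-variance edges get r = 0.
#'
#' @param X subjects x edges matrix. @param y behavioral score.
#' @param top_k number of edges to keep (<= ncol(X)).
#' @return integer vector of column indices, sorted by decreasing |r|.
#' @export
screen_edges <- function(X, y, top_k) {
  if (top_k > ncol(X)) stop("top_k exceeds the number of edges")
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  if (any(!ok)) message(sum(!ok), " zero-variance edge(s) assigned r = 0")
  r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  order(-abs(r), seq_along(r))[seq_len(top_k)]
}

make_folds <- function(n, n_folds, seed) {
  set.seed(derive_seed(seed, "folds"))
  sample(rep_len(seq_len(n_folds), n))
}

# One pass of leak-free CV decoding.  Screening, scaling statistics and the
# elastic-net fit use training subjects only; held-out subjects are predicted
# with training-fold statistics.  Returns out-of-fold predictions plus
# per-fold coefficient supports.
cv_decode_core <- function(X, y, cfg, folds, top_k, tune = FALSE,
                           seed = 1, light = FALSE) {
  n <- nrow(X)
  n_folds <- max(folds)
  oof <- rep(NA_real_, n)
  supports <- vector("list", n_folds)
  coefs <- vector("list", n_folds)
  chosen <- matrix(NA_real_, n_folds, 2,
                   dimnames = list(NULL, c("lambda", "alpha")))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(!tr) < 1 || sum(tr) < 2) stop("fold ", f, " has too few subjects")
    idx <- screen_edges(X[tr, , drop = FALSE], y[tr], min(top_k, ncol(X)))
    Xtr <- X[tr, idx, drop = FALSE]
    cfg_f <- cfg
    if (tune) {
      # tune on the unscreened training design: the inner CV re-screens
      # within each inner fold so validation subjects never shape the screen
      tuned <- tune_enet(X[tr, , drop = FALSE], y[tr],
                         seed = derive_seed(seed, paste0("in", f)),
                         standardize = cfg$standardize, top_k = top_k)
      cfg_f <- enet_config(lambda = tuned$lambda, alpha = tuned$alpha,
                           standardize = cfg$standardize,
                           max_iter = cfg$max_iter, tol = cfg$tol)
    }
    fit <- fit_elastic_net(Xtr, y[tr], cfg_f)
    oof[!tr] <- predict_enet(fit, X[!tr, idx, drop = FALSE])
    nz <- idx[fit$beta != 0]
    supports[[f]] <- sort(nz)
    cc <- stats::setNames(rep(0, ncol(X)), colnames(X))
    cc[idx] <- fit$beta
    if (!light) coefs[[f]] <- cc
    chosen[f, ] <- c(cfg_f$lambda, cfg_f$alpha)
  }
  list(oof = oof, supports = supports, coefficients = coefs,
       chosen = chosen, screened_k = min(top_k, ncol(X)))
}

#' Cross-validated elastic-net decoding of behavior from FC edges
#'
#' For each of `n_folds` folds: screens edges and fits the elastic net on the
#' training subjects only, then predicts the held-out subjects.  Out-of-fold
#' predictions are assembled across folds and evaluated with
#' [evaluate_predictions()].  With `cfg$lambda = NULL` the penalty is tuned by
#' a nested inner-CV grid search (1-SE rule) inside each training fold.
#'
#' @param X subjects x edges matrix. @param y behavioral score.
#' @param cfg an [enet_config()]. @param n_folds folds (default 10).
#' @param top_k screened edge count (default 500, capped at ncol(X)).
#' @param seed integer; fixes the fold assignment and tuning.
#' @return object of class `decoding_result`: `oof_predictions`, `metrics`,
#'   `folds`, per-fold `supports` / `coefficients` / `chosen` (lambda, alpha),
#'   `edge_frequency` (nonzero frequency per edge across folds).
#' @export
cross_validated_decode <- function(X, y, cfg = enet_config(), n_folds = 10,
                                   top_k = 500, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < n_folds) stop("need at least n_folds subjects")
  folds <- make_folds(nrow(X), n_folds, seed)
  core <- cv_decode_core(X, y, cfg, folds, top_k,
                         tune = is.null(cfg$lambda), seed = seed)
  freq <- rep(0, ncol(X))
  for (s in core$supports) freq[s] <- freq[s] + 1
  freq <- freq / n_folds
  names(freq) <- colnames(X)
  structure(list(oof_predictions = core$oof,
                 y = y,
                 metrics = evaluate_predictions(y, core$oof),
                 folds = folds,
                 supports = core$supports,
                 coefficients = core$coefficients,
                 chosen = core$chosen,
                 edge_frequency = freq,
                 screened_k = core$screened_k,
                 seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  m <- x$metrics
  cat("Cross-validated decoding (", max(x$folds), " folds)\n", sep = "")
  cat(sprintf("  out-of-fold r = %.3f, R2 = %.3f, MSE = %.4g, EVS = %.3f, MAE = %.4g\n",
              m["r"], m["R2"], m["MSE"], m["EVS"], m["MAE"]))
  cat("  edges ever selected:", sum(x$edge_frequency > 0), "\n")
  invisible(x)
}

#' Aggregate the per-fold elastic-net supports into a task subnetwork
#'
#' Keeps the edges whose coefficient was nonzero in at least
#' `freq_threshold` of the folds.
#'
#' @param result a `decoding_result`. @param freq_threshold fraction in (0, 1].
#' @return integer vector of edge (column) indices, sorted.
#' @export
aggregate_edges <- function(result, freq_threshold = 0.5) {
  stopifnot(inherits(result, "decoding_result"))
  if (freq_threshold <= 0 || freq_threshold > 1) {
    stop("freq_threshold must be in (0, 1]")
  }
  out <- which(result$edge_frequency >= freq_threshold - 1e-12)
  if (length(out) == 0) warning("no edge reaches the frequency threshold")
  sort(out)
}

#' Permutation test of the decoding correlation
#'
#' Re-runs the cross-validated decode with the behavioral scores randomly
#' shuffled (same fold assignment), recording the out-of-fold Pearson r of
#' each permutation; p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations),
#' so p is never 0.  `cfg` must carry a numeric lambda; with `lambda = NULL`
#' the penalty is tuned once on the observed data and frozen (per-fold median
#' of the tuned values) for all permutations.
#'
#' @param X,y data. @param cfg an [enet_config()].
#' @param n_permutations number of shuffles (default 10000).
#' @param n_folds,top_k,seed as in [cross_validated_decode()].
#' @return list with `p`, `r_observed`, `r_permuted`, `n_permutations`,
#'   and the `observed` decoding_result.
#' @export
permutation_test <- function(X, y, cfg = enet_config(), n_permutations = 10000,
                             n_folds = 10, top_k = 500, seed = 1) {
  stopifnot(n_permutations >= 1)
  observed <- cross_validated_decode(X, y, cfg, n_folds = n_folds,
                                     top_k = top_k, seed = seed)
  if (is.null(cfg$lambda)) {
    cfg <- enet_config(lambda = stats::median(observed$chosen[, "lambda"]),
                       alpha = stats::median(observed$chosen[, "alpha"]),
                       standardize = cfg$standardize,
                       max_iter = cfg$max_iter, tol = cfg$tol)
  }
  r_obs <- observed$metrics[["r"]]
  folds <- observed$folds
  set.seed(derive_seed(seed, "permutations"))
  r_perm <- vapply(seq_len(n_permutations), function(b) {
    yp <- sample(y)
    core <- cv_decode_core(X, yp, cfg, folds, top_k, light = TRUE)
    suppressWarnings(stats::cor(yp, core$oof))
  }, numeric(1))
  r_perm[is.na(r_perm)] <- 0
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_permutations)
  list(p = p, r_observed = r_obs, r_permuted = r_perm,
       n_permutations = n_permutations, observed = observed)
}

#' Regression evaluation metrics
#'
#' Pearson r, coefficient of determination R2 = 1 - SS_res/SS_tot, mean
#' squared error, explained-variance score EVS = 1 - Var(y - y_hat)/Var(y),
#' and mean absolute error.
#'
#' @param y observed values (non-constant, length >= 3).
#' @param y_hat predictions of equal length.
#' @return named numeric vector (r, R2, MSE, EVS, MAE).
#' @export
evaluate_predictions <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("lengths differ")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(y) == 0) stop("constant y")
  r <- if (stats::sd(y_hat) == 0) 0 else stats::cor(y, y_hat)
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  c(r = r,
    R2 = 1 - ss_res / ss_tot,
    MSE = mean((y - y_hat)^2),
    EVS = 1 - stats::var(y - y_hat) / stats::var(y),
    MAE = mean(abs(y - y_hat)))
}

#' Persist a decoding result as JSON
#'
#' Stores the selected edges (as node-id pairs), per-edge fold frequencies,
#' metrics, permutation p (if supplied), penalty choices and seed.
#'
#' @param result a `decoding_result`. @param node_ids node labels.
#' @param path output file. @param task_name stored label.
#' @param permutation optional result of [permutation_test()].
#' @param freq_threshold aggregation threshold.
#' @return `path`, invisibly.
#' @export
write_decode_json <- function(result, node_ids, path, task_name = "task",
                              permutation = NULL, freq_threshold = 0.5) {
  idx <- aggregate_edges(result, freq_threshold)
  ep <- edge_pairs(length(node_ids))
  payload <- list(
    task_name = task_name,
    node_ids = node_ids,
    edges = if (length(idx)) {
      data.frame(node_i = node_ids[ep[idx, 1]],
                 node_j = node_ids[ep[idx, 2]],
                 frequency = unname(result$edge_frequency[idx]))
    } else list(),
    freq_threshold = freq_threshold,
    metrics = as.list(result$metrics),
    permutation_p = if (!is.null(permutation)) permutation$p else NULL,
    n_permutations = if (!is.null(permutation)) permutation$n_permutations else NULL,
    chosen = as.data.frame(result$chosen),
    screened_k = result$screened_k,
    seed = result$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
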