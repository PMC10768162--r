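# Synthetic cohorts with planted structure.
#
# The generator emulates the statistical structure the decoding and
# classification stages assume: per-subject FC correlation matrices sharing a
# low-rank "functional system" background, a set of planted edges whose values
# linearly predict a continuous behavioral score at a configurable R-squared,
# a case/control contrast as a mean FC shift on the planted subnetwork, and
# phenotype columns (age, sex, site).

#' Configuration of a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 10).
#' @param n_nodes number of regions.
#' @param n_timepoints timepoints for [generate_timeseries()]; 0 means FC
#'   matrices are emitted directly.
#' @param planted_edges two-column matrix of node index pairs (1-based,
#'   i < j) carrying the behavioral signal; `NULL` for a null cohort.
#' @param beta effect weight per planted edge (scalar or one per edge).
#' @param target_r2 fraction of behavioral variance explained by the planted
#'   linear signal, in \[0, 1); 0 means pure-noise behavior (requires
#'   `beta = 0` semantics: any planted signal is ignored in the score).
#' @param group_delta mean FC shift added to planted edges for case subjects.
#' @param background_rank rank of the shared latent-factor background.
#' @param edge_noise_sd sd of subject-specific edge deviations around the
#'   background correlation structure.
#' @param phenotype_spec list with `age_range` (length 2), `sex_prop`
#'   (proportion coded 1), `n_sites` (number of sites).
#' @param seed integer seed; identical configs reproduce bit-identical cohorts.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 200, n_nodes = 30, n_timepoints = 0,
                             planted_edges = NULL, beta = 1, target_r2 = 0.5,
                             group_delta = 0, background_rank = 3,
                             edge_noise_sd = 0.05,
                             phenotype_spec = list(age_range = c(8, 18),
                                                   sex_prop = 0.5,
                                                   n_sites = 2),
                             seed = 1) {
  if (n_subjects < 10) stop("n_subjects must be >= 10")
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    stopifnot(ncol(planted_edges) == 2)
    if (any(planted_edges[, 1] >= planted_edges[, 2]) ||
        any(planted_edges < 1) || any(planted_edges > n_nodes)) {
      stop("planted edges must satisfy 1 <= i < j <= n_nodes")
    }
    if (anyDuplicated(paste(planted_edges[, 1], planted_edges[, 2]))) {
      stop("planted edges must be distinct")
    }
  }
  if (target_r2 < 0 || target_r2 >= 1) stop("target_r2 must be in [0, 1)")
  has_signal <- !is.null(planted_edges) && any(beta != 0)
  if (target_r2 > 0 && !has_signal) stop("no signal configured")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 planted_edges = planted_edges,
                 beta = beta, target_r2 = target_r2,
                 group_delta = group_delta,
                 background_rank = background_rank,
                 edge_noise_sd = edge_noise_sd,
                 phenotype_spec = phenotype_spec,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Repair a symmetric matrix with unit diagonal to a valid correlation matrix
# by uniform diagonal shrinkage: (S + cI) / (1 + c) with the smallest c that
# lifts the minimum eigenvalue to eps.  Unlike eigenvalue clipping followed by
# cov2cor rescaling, this scales every off-diagonal entry by the same factor,
# so it cannot mix signal between edges; the planted signal stays confined to
# the planted edges.
nearest_correlation <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2
  lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < eps) {
    cc <- (eps - lmin) / (1 - eps)
    S <- (S + cc * diag(nrow(S))) / (1 + cc)
  }
  diag(S) <- 1
  S
}

#' Generate a synthetic FC cohort with planted behavioral signal
#'
#' Each subject's FC matrix is a shared rank-`background_rank` latent-factor
#' correlation structure plus subject-specific edge noise, projected back to a
#' valid correlation matrix.  The behavioral score is the planted linear
#' combination of (post-projection) planted-edge values plus Gaussian noise
#' whose variance is solved analytically so the sample R-squared of the signal
#' matches `target_r2`.  Cases (label 1, exactly half the cohort) additionally
#' get `group_delta` added to planted edges before projection.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `synthetic_cohort`: list with `fc` (N x N x
#'   n_subjects array), `behavior`, `phenotypes` (data.frame subject_id, age,
#'   sex, site), `labels` (0/1), and `truth` (config echo, planted edge
#'   indices into the edge vector, realized R-squared).
#' @export
generate_fc_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, "fc_population"))
  n <- cfg$n_subjects; p <- cfg$n_nodes
  ids <- default_node_ids(p)
  subj <- sprintf("sub%04d", seq_len(n))

  # shared background correlation from latent loadings
  L <- matrix(stats::rnorm(p * cfg$background_rank, sd = 0.4), p)
  B <- tcrossprod(L)
  diag(B) <- diag(B) + 0.6
  B <- stats::cov2cor(B)

  labels <- sample(rep(c(0L, 1L), length.out = n))
  pe <- cfg$planted_edges

  fc <- array(0, dim = c(p, p, n), dimnames = list(ids, ids, subj))
  for (s in seq_len(n)) {
    E <- matrix(0, p, p)
    E[lower.tri(E)] <- stats::rnorm(p * (p - 1) / 2, sd = cfg$edge_noise_sd)
    E <- E + t(E)
    S <- B + E
    if (!is.null(pe) && labels[s] == 1L && cfg$group_delta != 0) {
      for (k in seq_len(nrow(pe))) {
        i <- pe[k, 1]; j <- pe[k, 2]
        S[i, j] <- S[i, j] + cfg$group_delta
        S[j, i] <- S[i, j]
      }
    }
    S[S > 0.99] <- 0.99; S[S < -0.99] <- -0.99
    diag(S) <- 1
    fc[, , s] <- nearest_correlation(S)
  }

  # behavioral score from post-projection planted edge values
  has_signal <- !is.null(pe) && any(cfg$beta != 0) && cfg$target_r2 > 0
  if (has_signal) {
    betas <- rep_len(cfg$beta, nrow(pe))
    sig <- numeric(n)
    for (k in seq_len(nrow(pe))) {
      sig <- sig + betas[k] * fc[pe[k, 1], pe[k, 2], ]
    }
    sig <- unname(sig)
    vs <- stats::var(sig)
    if (vs <= 0) stop("no signal configured")
    noise_var <- vs * (1 - cfg$target_r2) / cfg$target_r2
    behavior <- sig + stats::rnorm(n, sd = sqrt(noise_var))
    realized_r2 <- summary(stats::lm(behavior ~ sig))$r.squared
  } else {
    sig <- rep(0, n)
    behavior <- stats::rnorm(n)
    realized_r2 <- 0
  }

  ps <- cfg$phenotype_spec
  phen <- data.frame(
    subject_id = subj,
    age = stats::runif(n, ps$age_range[1], ps$age_range[2]),
    sex = stats::rbinom(n, 1, ps$sex_prop),
    site = sample.int(ps$n_sites, n, replace = TRUE),
    stringsAsFactors = FALSE)

  planted_vec_idx <- if (!is.null(pe)) {
    ep <- edge_pairs(p)
    vapply(seq_len(nrow(pe)), function(k) {
      which(ep[, 1] == pe[k, 1] & ep[, 2] == pe[k, 2])
    }, integer(1))
  } else integer(0)

  structure(list(fc = fc, behavior = behavior, phenotypes = phen,
                 labels = labels,
                 truth = list(config = cfg,
                              planted_edge_index = planted_vec_idx,
                              signal = sig,
                              realized_r2 = realized_r2)),
            class = "synthetic_cohort")
}

#' Edge-vector design matrix of a cohort
#'
#' Stacks each subject's upper-triangle FC values into a subjects x edges
#' matrix, the input to the decoding stage.
#'
#' @param cohort a `synthetic_cohort` or an N x N x S array.
#' @return numeric matrix, one row per subject, edge-named columns.
#' @export
cohort_edge_matrix <- function(cohort) {
  fc <- if (inherits(cohort, "synthetic_cohort")) cohort$fc else cohort
  ns <- dim(fc)[3]
  X <- t(vapply(seq_len(ns), function(s) vectorize_fc(fc[, , s]),
                numeric(dim(fc)[1] * (dim(fc)[1] - 1) / 2)))
  rownames(X) <- dimnames(fc)[[3]]
  X
}

#' Sample time series with a prescribed population correlation matrix
#'
#' Draws T multivariate-Gaussian timepoints per subject whose population
#' correlation equals the subject's FC matrix, so [compute_fc()] on the output
#' converges to the target as T grows.  Non-PSD targets are repaired by
#' eigenvalue clipping (message emitted).
#'
#' @param cohort a `synthetic_cohort` (targets = its FC matrices).
#' @param n_timepoints series length; defaults to the config value.
#' @return list of T x N matrices, one per subject.
#' @export
generate_timeseries <- function(cohort, n_timepoints = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$truth$config
  T_ <- if (is.null(n_timepoints)) cfg$n_timepoints else n_timepoints
  if (T_ < 2) stop("n_timepoints must be >= 2")
  p <- cfg$n_nodes
  if (T_ < 2 * p) {
    warning("n_timepoints < 2 * n_nodes; FC estimates will be noisy")
  }
  set.seed(derive_seed(cfg$seed, "timeseries"))
  out <- vector("list", dim(cohort$fc)[3])
  names(out) <- dimnames(cohort$fc)[[3]]
  for (s in seq_along(out)) {
    S <- cohort$fc[, , s]
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < 0) {
      message("target FC for subject ", s,
              " not positive semi-definite; clipped eigenvalues")
    }
    lam <- pmax(e$values, 0)
    A <- e$vectors %*% diag(sqrt(lam), p)
    Z <- matrix(stats::rnorm(T_ * p), T_, p)
    ts <- Z %*% t(A)
    colnames(ts) <- dimnames(cohort$fc)[[1]]
    out[[s]] <- ts
  }
  out
}

#' Separable synthetic population for the classifier
#'
#' Direct feature-space cohort: standard-normal features, with cases shifted
#' by `shift` standard deviations on `n_informative` features, plus random
#' phenotypes.  Used to probe classifier power and null behavior without the
#' decoding stage.
#'
#' @param n subjects. @param n_features,n_informative feature counts.
#' @param shift case mean shift in units of the feature sd.
#' @param seed integer seed.
#' @return list with `features`, `labels`, `phenotypes`.
#' @export
simulate_population <- function(n = 200, n_features = 40, n_informative = 10,
                                shift = 2, seed = 1) {
  set.seed(derive_seed(seed, "population"))
  labels <- sample(rep(c(0L, 1L), length.out = n))
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  X[labels == 1L, seq_len(n_informative)] <-
    X[labels == 1L, seq_len(n_informative)] + shift
  colnames(X) <- sprintf("f%03d", seq_len(n_features))
  rownames(X) <- sprintf("sub%04d", seq_len(n))
  phen <- data.frame(subject_id = rownames(X),
                     age = stats::runif(n, 8, 18),
                     sex = stats::rbinom(n, 1, 0.5),
                     site = sample.int(2, n, replace = TRUE))
  list(features = X, labels = labels, phenotypes = phen)
}

## ---- cohort I/O -------------------------------------------------------------

#' Write / read a synthetic cohort to a directory
#'
#' Layout: `fc/<subject_id>.tsv` (N x N with node-id header),
#' `phenotypes.tsv` (subject_id, age, sex, site, behavior, label) and
#' `truth.json` (config echo and planted edges).
#'
#' @param cohort a `synthetic_cohort`. @param dir target directory.
#' @return the directory (write) or a `synthetic_cohort`-like list (read).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "fc"), recursive = TRUE, showWarnings = FALSE)
  subj <- dimnames(cohort$fc)[[3]]
  for (s in seq_along(subj)) {
    write_fc_tsv(cohort$fc[, , s], file.path(dir, "fc", paste0(subj[s], ".tsv")))
  }
  ph <- cohort$phenotypes
  ph$behavior <- format_num(cohort$behavior)
  ph$label <- cohort$labels
  ph$age <- format_num(ph$age)
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$truth$config
  truth <- list(planted_edges = cfg$planted_edges,
                planted_edge_index = cohort$truth$planted_edge_index,
                beta = cfg$beta, target_r2 = cfg$target_r2,
                group_delta = cfg$group_delta,
                realized_r2 = cohort$truth$realized_r2,
                seed = cfg$seed,
                n_subjects = cfg$n_subjects, n_nodes = cfg$n_nodes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ph <- utils::read.delim(file.path(dir, "phenotypes.tsv"))
  subj <- as.character(ph$subject_id)
  fc1 <- read_fc_tsv(file.path(dir, "fc", paste0(subj[1], ".tsv")))
  p <- nrow(fc1)
  fc <- array(0, dim = c(p, p, length(subj)),
              dimnames = list(rownames(fc1), rownames(fc1), subj))
  for (s in seq_along(subj)) {
    fc[, , s] <- read_fc_tsv(file.path(dir, "fc", paste0(subj[s], ".tsv")))
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  structure(list(fc = fc, behavior = ph$behavior,
                 phenotypes = ph[, c("subject_id", "age", "sex", "site")],
                 labels = ph$label, truth = truth),
            class = "synthetic_cohort")
}
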