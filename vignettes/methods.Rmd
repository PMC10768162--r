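---
title: "Methods: connectome decoding and population-graph classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome decoding and population-graph classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `taskgcn`, the meaning
and defaults of every tunable parameter, what the synthetic-cohort generator
does and does not emulate, and the numerical choices that affect results.

## 1. The model

The package implements a two-stage analysis of functional connectivity (FC)
data.

**Stage 1 — behavioral decoding.** Each subject contributes an $N \times N$
Pearson FC matrix; its strictly upper triangle in row-major order is the edge
vector $x \in \mathbb{R}^{N(N-1)/2}$ (for $N = 246$ nodes, $30{,}135$ edges).
A linear model $f(x) = \beta_0 + x^\top \beta$ predicts a behavioral score $y$
by minimizing the elastic-net objective

$$\sum_{i=1}^{n} \bigl(f(x_i) - y_i\bigr)^2 \;+\;
  \lambda \sum_{j} \Bigl(\alpha\,|\beta_j| + \tfrac{1}{2}(1-\alpha)\,\beta_j^2\Bigr),$$

with an unpenalized intercept. Decoding is evaluated by 10-fold
cross-validation: within each fold, edges are screened to the `top_k` most
behavior-correlated *training* edges, the model is fitted on training subjects
only, and out-of-fold predictions are scored by Pearson $r$, $R^2$, MSE,
explained-variance score, and MAE. Edges with nonzero coefficients in at
least a fraction `freq_threshold` of folds form the decoded **task pattern**.
Significance comes from a permutation test that refits the whole
cross-validated procedure on label-permuted responses.

**Stage 2 — population-graph classification.** The decoded pattern's node set
yields per-subject features: FC values among all pattern-node pairs plus
eight node-level graph metrics (binary and weighted variants; 15 columns per
node) computed on proportionally thresholded graphs at the
cost-efficiency-optimal density. Subjects become nodes of a *population
graph* with weights

$$W(x, y) = \mathrm{Sim}(x, y) \sum_{h} \gamma_h\bigl(M_h(x), M_h(y)\bigr),
\qquad
\mathrm{Sim}(x, y) = \exp\!\Bigl(-\frac{\rho(x,y)^2}{2\sigma^2}\Bigr),$$

where $\rho$ is the correlation distance between feature vectors and
$\gamma_h$ is a unit step: $|a - b| < \theta$ for continuous phenotypes
(age, $\theta = 2$ years) and exact equality for categorical ones (sex,
site). A two-layer Chebyshev spectral graph convolutional network (GCN)
classifies subjects transductively: the filter is

$$g_\theta \star X = \sum_{k=0}^{K-1} \Theta_k\, T_k(\tilde L)\, X,
\qquad \tilde L = \tfrac{2}{\lambda_{\max}} L - I,$$

on the symmetric normalized Laplacian $L = I - D^{-1/2} W D^{-1/2}$, and the
cross-entropy loss is evaluated on training-mask subjects only. Evaluation is
stratified 5-fold cross-validation reporting AUC and accuracy on the held-out
mask.

## 2. Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| `alpha` (elastic net) | 0.5 | balanced sparsity/shrinkage; tuned over {0.1, 0.5, 0.9} when `lambda = NULL` |
| `lambda` | tuned | 10 log-spaced values from $\lambda_{\max}$ down 3 decades, 3 inner folds, 1-SE rule |
| `n_folds` (decoding) | 10 | standard for $n \approx$ 200–400; keeps fold test sets above ~20 subjects |
| `top_k` (screening) | 200 | keeps the per-fold design well-conditioned ($p < n$ after screening at the default cohort size) |
| `freq_threshold` | 0.5 | an edge must be selected in a majority of folds |
| `n_permutations` | 100 (pipeline), 500 (acceptance) | add-one estimator floor $1/(B+1)$; 500 resolves $p \le 0.01$ |
| density grid | 0.05–0.50 by 0.05 | the usual proportional-threshold range; optimum maximizes global efficiency − density |
| `age_theta` | 2 years | phenotype agreement window for the continuous column |
| `sigma` | `"auto"` | median training-pair correlation distance; never uses test pairs |
| GCN `hidden`, `K` | 16, 3 | small order-3 polynomial filter; enough capacity for the feature sizes here |
| GCN `lr`, `epochs` | 0.005, 200 | Adam with early plateau well before 200 epochs on these problem sizes |
| GCN `dropout`, `weight_decay` | 0.3, 5e-4 | standard regularization for small transductive graphs |
| `n_keep` (RFE) | 100–200 | ridge-RFE drops 10% of the weakest features per iteration down to `n_keep` |

Problem sizes used in tests and the acceptance script (e.g. $n = 400$
subjects, $N = 40$ nodes for recovery; $n = 200$, 40 features for
classification) are package choices meant to be fast yet statistically
informative, not properties of any external dataset.

## 3. The synthetic generator: scope and limits

`generate_fc_population()` builds, per subject, a correlation matrix from a
shared low-rank (rank-3) latent background plus subject-specific edge noise
(sd 0.05); cases additionally receive `group_delta` added to the planted
edges. Each matrix is repaired to a valid correlation matrix (unit diagonal,
symmetric, positive semidefinite) by *uniform diagonal shrinkage*
$(S + cI)/(1+c)$ rather than eigenvalue clipping: shrinkage scales every
off-diagonal entry by the same factor, so the planted signal cannot leak into
other edges through the repair step (clipping plus `cov2cor` rescaling mixes
eigenvectors and was measured to induce spurious population-level
edge–behavior correlations up to $|r| \approx 0.13$). The behavioral score is
$y_i = \sum_{e} \beta_e\, x_{ie} + \varepsilon_i$ over the planted edges
**after** projection, with the noise variance solved analytically so that the
population $R^2$ of the planted linear signal equals `target_r2`.
`target_r2 = 0` with `beta = 0` produces a null cohort. Labels are exactly
balanced; phenotypes (age, sex, site) are drawn independently.
`generate_timeseries()` can emit Gaussian time series whose sample
correlation converges to the subject's FC matrix.

What is *not* emulated: temporal autocorrelation and scanner artifacts,
head-motion confounds, site effects correlated with FC, network modularity
and hub structure of real connectomes, and non-Gaussian behavioral
distributions. Results on these cohorts validate the *machinery* (recovery,
calibration, leak-freedom, determinism), not neuroscientific effect sizes.

## 4. Numerical and design decisions

- **Ridge closed form.** The exact minimizer of the objective above at
  $\alpha = 0$ is $(X_c^\top X_c + \tfrac{\lambda}{2} I)^{-1} X_c^\top y_c$
  on centred data — note the $\lambda/2$, which follows from the
  $\tfrac12(1-\alpha)$ factor. Tests assert this form, and the mapping to
  `glmnet` is $\lambda_{\text{glmnet}} = \lambda / (2n)$.
- **Solver.** Coordinate descent in C++ (via Rcpp) with soft-thresholding,
  warm-started along decreasing $\lambda$ paths for the nested tuning loop.
  Convergence tolerance `1e-8` on the maximum coefficient change
  (`1e-6` inside inner tuning folds, where only model ranking matters).
- **Permutation tests.** When `lambda = NULL`, hyperparameters are tuned once
  on the observed data and the per-fold median $(\lambda, \alpha)$ is frozen
  for all permutations; the permutation distribution reflects permuted
  responses through the same fitting procedure, not re-tuned model selection.
  The p-value uses the add-one estimator
  $p = (1 + \#\{r_{\text{perm}} \ge r_{\text{obs}}\}) / (1 + B)$.
- **Edge ordering.** Upper triangle, row-major ($i < j$); on-disk formats
  carry node-id labels so files are index-convention-free.
- **Thresholding ties.** Proportional thresholding keeps the top
  $\lfloor dE \rfloor$ positive edges; exact weight ties break
  lexicographically by $(i, j)$, making thresholding (and everything
  downstream) deterministic. Negative FC weights are zeroed before any graph
  construction.
- **Weighted graph conventions.** Path length is $1/w$; weighted clustering
  is Onnela's geometric-mean form on max-normalized weights; weighted
  coreness is the real-valued s-core level; eigenvector centrality is
  computed on the largest connected component.
- **Laplacian edge cases.** Isolated population-graph nodes get identity
  rows, keeping the spectrum inside $[0, 2]$.
- **GCN training.** Explicit backpropagation with Adam; inverted dropout on
  the hidden layer; Glorot-uniform initialization; all randomness flows from
  a single integer seed through `derive_seed(seed, stage)`, so every result
  in the package is exactly reproducible from one seed.
- **Group effect size.** The pipeline default `group_delta = 0.3` was fixed
  as the study condition for the synthetic cohorts so that the planted group
  difference is detectable at the default cohort size (n = 200).

## 5. Limitations

- The permutation test freezes tuned hyperparameters (see above); with very
  aggressive tuning grids this can be slightly anti-conservative.
- The GCN is transductive: it must be retrained to classify new subjects, and
  the population graph must be rebuilt (with `train_idx` excluding them from
  $\sigma$ selection) to avoid leakage.
- Synthetic cohorts are optimistic about real-data noise structure; effect
  sizes do not transfer.
- The s-core (weighted coreness) is a greedy peeling definition; other
  weighted-core definitions in the literature differ.

## 6. Worked example

```{r}
library(taskgcn)
cfg <- run_config(seed = 1, n_subjects = 80, n_nodes = 12,
                  planted_edges = cbind(c(1, 1, 2), c(2, 3, 4)),
                  n_permutations = 20, top_k = 30, n_folds = 5,
                  n_keep = 20, k_class = 3,
                  gcn = list(hidden = 8, K = 3, dropout = 0.3,
                             lr = 0.005, epochs = 80))
manifest <- run_pipeline(cfg, out_dir = tempfile("run"))
str(manifest$checksums)
```
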