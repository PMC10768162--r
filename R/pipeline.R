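# Orchestration: simulate -> decode -> features -> classify, with a manifest
# of every artifact written and deterministic re-runs from a single seed.

#' Default pipeline configuration
#'
#' Nested list of stage configurations.  Every random stage derives its own
#' seed from the global `seed` and the stage name, so one integer reproduces
#' the whole run.
#'
#' @param seed global seed.
#' @param n_subjects,n_nodes cohort size.
#' @param planted_edges,beta,target_r2,group_delta synthetic signal, see
#'   [synthetic_config()].
#' @param n_permutations decoding permutation count.
#' @param top_k screened edge count. @param n_folds decoding folds.
#' @param freq_threshold aggregation threshold.
#' @param density_grid sparsity grid for [optimize_density()].
#' @param n_keep RFE target. @param k_class classification folds.
#' @param gcn list of GCN hyperparameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 200, n_nodes = 30,
                       planted_edges = cbind(c(1, 1, 2, 3, 4),
                                             c(2, 3, 4, 5, 6)),
                       beta = 1, target_r2 = 0.5, group_delta = 0.3,
                       n_permutations = 100, top_k = 200, n_folds = 10,
                       freq_threshold = 0.5,
                       density_grid = seq(0.05, 0.5, by = 0.05),
                       n_keep = 100, k_class = 5,
                       gcn = list(hidden = 16, K = 3, dropout = 0.3,
                                  lr = 0.005, epochs = 200)) {
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_nodes = n_nodes, planted_edges = planted_edges,
                 beta = beta, target_r2 = target_r2,
                 group_delta = group_delta,
                 n_permutations = n_permutations, top_k = top_k,
                 n_folds = n_folds, freq_threshold = freq_threshold,
                 density_grid = density_grid, n_keep = n_keep,
                 k_class = k_class, gcn = gcn),
            class = "run_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: (1) simulate a cohort and write it under `out_dir`; (2) decode the
#' behavioral score from FC edges (cross-validated elastic net + permutation
#' test), writing `decode.json`; (3) build task-pattern features (pattern-node
#' FC plus per-subject graph metrics at the efficiency-optimal density),
#' writing `features.tsv`; (4) classify with the population GCN, writing
#' `results.json`; finally `manifest.json` records the config, seeds, and an
#' md5 checksum of every artifact.
#'
#' @param cfg a [run_config()]. @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)

  say("stage simulate (seed ", cfg$seed, ")")
  scfg <- synthetic_config(n_subjects = cfg$n_subjects, n_nodes = cfg$n_nodes,
                           planted_edges = cfg$planted_edges, beta = cfg$beta,
                           target_r2 = cfg$target_r2,
                           group_delta = cfg$group_delta, seed = cfg$seed)
  cohort <- generate_fc_population(scfg)
  write_cohort(cohort, out_dir)

  say("stage decode")
  X <- cohort_edge_matrix(cohort)
  node_ids <- dimnames(cohort$fc)[[1]]
  perm <- permutation_test(X, cohort$behavior, enet_config(),
                           n_permutations = cfg$n_permutations,
                           n_folds = cfg$n_folds, top_k = cfg$top_k,
                           seed = derive_seed(cfg$seed, "decode"))
  decode_path <- file.path(out_dir, "decode.json")
  write_decode_json(perm$observed, node_ids, decode_path,
                    task_name = "synthetic", permutation = perm,
                    freq_threshold = cfg$freq_threshold)

  say("stage features")
  pattern <- pattern_from_decode(perm$observed, node_ids, "synthetic",
                                 cfg$freq_threshold)
  if (length(pattern$nodes) < 2) stop("stage features: decoded pattern has ",
                                      length(pattern$nodes), " node(s)")
  metrics <- lapply(seq_len(cfg$n_subjects), function(s) {
    C <- cohort$fc[, , s]
    opt <- optimize_density(C, cfg$density_grid, mode = "binary")
    gw <- threshold_graph(C, opt$density, mode = "weighted")
    metric_table(opt$graph, gw)
  })
  feats <- build_features(cohort$fc, pattern, metrics)
  feat_path <- file.path(out_dir, "features.tsv")
  write_features_tsv(feats, feat_path)

  say("stage classify")
  res <- do.call(evaluate_cv,
                 c(list(features = feats, phenotypes = cohort$phenotypes,
                        labels = cohort$labels, k = cfg$k_class,
                        seed = derive_seed(cfg$seed, "classify"),
                        n_keep = cfg$n_keep),
                   cfg$gcn))
  results_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(per_fold = res$per_fold,
         mean_auc = res$mean_auc, sd_auc = res$sd_auc,
         mean_acc = res$mean_acc, sd_acc = res$sd_acc,
         pattern_nodes = pattern$nodes,
         decode_metrics = as.list(perm$observed$metrics),
         permutation_p = perm$p, seed = cfg$seed),
    results_path, auto_unbox = TRUE, digits = NA)

  files <- c(file.path(out_dir, "phenotypes.tsv"),
             file.path(out_dir, "truth.json"),
             decode_path, feat_path, results_path)
  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "planted_edges")],
    planted_edges = apply(as.matrix(cfg$planted_edges), 1, paste,
                          collapse = "-"),
    checksums = as.list(tools::md5sum(files)),
    n_fc_files = cfg$n_subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done")
  invisible(manifest)
}

#' Validate a cohort directory
#'
#' Checks that each FC matrix parses and is symmetric, that FC subjects and
#' phenotype rows align, that no value is missing, and that labels are coded
#' 0/1.  Reporting only: never throws on bad data.
#'
#' @param dir cohort directory with `fc/` and `phenotypes.tsv`.
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(dir) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = check, pass = pass,
                                                detail = detail)
  }
  ph_path <- file.path(dir, "phenotypes.tsv")
  if (!file.exists(ph_path)) {
    add("phenotypes_exists", FALSE, ph_path)
    return(do.call(rbind, checks))
  }
  ph <- utils::read.delim(ph_path)
  add("phenotypes_exists", TRUE)
  add("phenotypes_complete", !anyNA(ph),
      if (anyNA(ph)) paste(sum(is.na(ph)), "missing values") else "")
  if ("label" %in% names(ph)) {
    ok <- all(ph$label %in% c(0, 1))
    add("labels_binary", ok, if (!ok) "labels outside {0,1}" else "")
  }
  fc_files <- list.files(file.path(dir, "fc"), pattern = "\\.tsv$",
                         full.names = TRUE)
  fc_ids <- sub("\\.tsv$", "", basename(fc_files))
  missing_ph <- setdiff(fc_ids, as.character(ph$subject_id))
  add("fc_subjects_in_phenotypes", length(missing_ph) == 0,
      paste(missing_ph, collapse = ", "))
  missing_fc <- setdiff(as.character(ph$subject_id), fc_ids)
  add("phenotype_subjects_have_fc", length(missing_fc) == 0,
      paste(missing_fc, collapse = ", "))
  for (f in fc_files) {
    res <- tryCatch({
      read_fc_tsv(f)
      ""
    }, error = function(e) conditionMessage(e))
    if (nzchar(res)) add("fc_matrix_valid", FALSE,
                         paste0(basename(f), ": ", res))
  }
  if (!any(vapply(checks, function(x) x$check == "fc_matrix_valid",
                  logical(1)))) {
    add("fc_matrix_valid", TRUE, paste(length(fc_files), "files"))
  }
  do.call(rbind, checks)
}
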