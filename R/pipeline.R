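## End-to-end orchestration: a declarative run configuration drives
## simulate -> preprocess -> linear track -> tree track -> neural track
## -> clustering evaluation -> report, with every artifact written in the
## package's own plain-text dialects and all seeds recorded.

#' Default run configuration
#'
#' Returns the full configuration list understood by [run_pipeline()].
#' Any element can be overridden via `...` (top-level names) or by
#' editing the returned list; [run_pipeline()] also accepts a YAML file
#' with the same structure.
#'
#' @param ... top-level overrides, e.g. `seed = 7` or
#'   `preprocess = list(min_per_tissue = 5)` (sub-lists are merged).
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    paths = list(matrix = NULL, annotation = NULL, whitelist = NULL,
                 out_dir = "tissuespec_run"),
    simulate = NULL,  # a synth_config() or list of its arguments
    preprocess = list(min_per_tissue = 10L, drop_labels = "mixed",
                      tpm_threshold = 1, log_offset = 1, organ_map = NULL),
    de = list(p_thresh = 0.01, lfc_thresh = 4, combine = "union"),
    gbm = list(n_folds = 10L, n_reps = 20L, nrounds = 50L,
               k_neighbors = 5L, run_cv = TRUE),
    cnn = list(profile = "desk", top_frac = 0.01, keep_frac = 0.5,
               method = "expected_gradients"),
    evaluate = list(k = NULL, n_runs = 10L, n_null_sets = 100L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("'config' must be a list or a YAML path")
  do.call(default_config, config)
}

#' Run the full tissue-specific gene identification pipeline
#'
#' Executes every stage on one expression matrix: optional simulation,
#' preprocessing (rare-tissue / mixed removal, optional organ-class
#' relabeling for the linear and tree tracks, whitelist + TPM filtering,
#' log2 transform), the three identification tracks, clustering
#' evaluation of the resulting gene sets, the core intersection, and a
#' report. All artifacts are written under `config$paths$out_dir`;
#' `provenance.json` records every parameter and seed.
#'
#' The linear and tree tracks run on organ-class labels when
#' `preprocess$organ_map` is given (tissue labels otherwise); the neural
#' track always uses the finer tissue labels, and the evaluation clusters
#' into `evaluate$k` groups (default: number of tissue labels).
#'
#' @param config a configuration list from [default_config()], a partial
#'   list of overrides, or the path to a YAML file.
#' @return list with `genesets` (limma / lgbm / cnn / core), `de`, `gbm`,
#'   `boruta`, `cnn`, `report`, `matrix`, `annotation`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- .load_config(config)
  out_dir <- cfg$paths$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", out_dir)
  log_msg <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

  ## -- input ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- if (inherits(cfg$simulate, "synth_config")) cfg$simulate
          else do.call(synth_config, cfg$simulate)
    log_msg("simulate", "%d tissues, %d genes, seed %d", sc$n_tissues,
            sc$n_genes, sc$seed)
    sim <- generate_expression(sc)
    mat <- sim$matrix; ann <- sim$annotation; truth <- sim$truth
  } else {
    if (is.null(cfg$paths$matrix) || is.null(cfg$paths$annotation))
      .stopf("config must provide either 'simulate' or paths$matrix + paths$annotation")
    mat <- read_expression_matrix(cfg$paths$matrix)
    ann <- read_sample_annotation(cfg$paths$annotation)
    truth <- NULL
  }

  ## -- preprocess ----------------------------------------------------------
  pp <- cfg$preprocess
  fs <- filter_samples(mat, ann, min_per_tissue = pp$min_per_tissue,
                       drop_labels = pp$drop_labels)
  whitelist <- NULL
  if (!is.null(cfg$paths$whitelist)) {
    if (!file.exists(cfg$paths$whitelist))
      .stopf("whitelist file '%s' does not exist", cfg$paths$whitelist)
    whitelist <- read_geneset(cfg$paths$whitelist, "whitelist")
  }
  tpm <- filter_genes(fs$matrix, whitelist = whitelist,
                      tpm_threshold = pp$tpm_threshold)
  logm <- log2_transform(tpm, offset = pp$log_offset)
  tissue_ann <- fs$annotation
  class_ann <- if (!is.null(pp$organ_map))
    map_to_organs(tissue_ann, unlist(pp$organ_map)) else tissue_ann
  log_msg("preprocess", "%d samples x %d genes retained (%d tissue labels, %d classes)",
          nrow(logm), ncol(logm), length(unique(tissue_ann$tissue)),
          length(unique(class_ann$tissue)))

  ## -- linear track --------------------------------------------------------
  de <- de_track(logm, class_ann, p_thresh = cfg$de$p_thresh,
                 lfc_thresh = cfg$de$lfc_thresh, combine = cfg$de$combine)
  log_msg("de", "%d genes from %d tissue pairs", length(de$geneset),
          nrow(de$counts))

  ## -- tree track ----------------------------------------------------------
  bal <- balance_classes(logm, class_ann, k_neighbors = cfg$gbm$k_neighbors,
                         seed = cfg$seed)
  gbm_cv <- NULL
  if (isTRUE(cfg$gbm$run_cv))
    gbm_cv <- train_gbm_cv(bal$matrix, bal$annotation,
                           n_folds = cfg$gbm$n_folds, seed = cfg$seed,
                           nrounds = cfg$gbm$nrounds)
  boruta <- boruta_filter(bal$matrix, bal$annotation, n_reps = cfg$gbm$n_reps,
                          seed = cfg$seed, nrounds = cfg$gbm$nrounds)
  log_msg("gbm", "%d genes kept by the shadow-feature filter",
          length(boruta$geneset))

  ## -- neural track --------------------------------------------------------
  cnn_cfg <- if (identical(cfg$cnn$profile, "full")) cnn_config_full()
             else cnn_config()
  cnn_cfg$seed <- cfg$seed
  cnn <- cnn_track(logm, tissue_ann, config = cnn_cfg,
                   top_frac = cfg$cnn$top_frac, keep_frac = cfg$cnn$keep_frac,
                   method = cfg$cnn$method)
  log_msg("cnn", "%d genes from %d per-tissue lists", length(cnn$geneset),
          length(cnn$tissue_lists))

  ## -- evaluation ----------------------------------------------------------
  sets <- list(limma = de$geneset, lgbm = boruta$geneset, cnn = cnn$geneset)
  sets <- sets[lengths(sets) > 0]
  report <- evaluate_all(logm, tissue_ann, sets, k = cfg$evaluate$k,
                         n_runs = cfg$evaluate$n_runs,
                         n_null_sets = cfg$evaluate$n_null_sets,
                         seed = cfg$seed)
  core <- if (length(sets) >= 2) core_intersection(sets) else NULL
  log_msg("evaluate", "best set: %s (mean V %.3f)", report$table$set[1],
          report$table$mean_v[1])

  ## -- artifacts -----------------------------------------------------------
  write_expression_matrix(logm, file.path(out_dir, "log2_matrix.tsv"))
  write_sample_annotation(tissue_ann, file.path(out_dir, "annotation.tsv"))
  for (nm in names(sets))
    write_geneset(sets[[nm]], file.path(out_dir, sprintf("geneset_%s.txt", nm)))
  if (!is.null(core)) write_geneset(core, file.path(out_dir, "geneset_core.txt"))
  if (!is.null(gbm_cv))
    write.table(gbm_cv$metrics, file.path(out_dir, "gbm_cv_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cnn$model$history, file.path(out_dir, "cnn_history.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$table, file.path(out_dir, "evaluation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg, gene_set_sizes = lapply(sets, length),
         core_size = if (is.null(core)) 0L else length(core),
         de_counts = de$counts, evaluation = report$table),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)

  invisible(list(genesets = c(sets, list(core = core)), de = de,
                 gbm = gbm_cv, boruta = boruta, cnn = cnn, report = report,
                 matrix = logm, annotation = tissue_ann, truth = truth,
                 out_dir = out_dir))
}

#' Precision / recall of a gene set against planted ground truth
#'
#' @param set candidate gene set.
#' @param truth_set ground-truth gene set (e.g. [truth_geneset()]).
#' @return named vector `precision`, `recall`, `n_set`, `n_truth`.
#' @export
set_recovery <- function(set, truth_set) {
  set <- unique(as.character(set)); truth_set <- unique(as.character(truth_set))
  hit <- length(intersect(set, truth_set))
  c(precision = if (length(set)) hit / length(set) else NA_real_,
    recall = if (length(truth_set)) hit / length(truth_set) else NA_real_,
    n_set = length(set), n_truth = length(truth_set))
}
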