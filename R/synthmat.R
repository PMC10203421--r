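## Synthetic multi-tissue expression generator with planted
## tissue-specific genes and recorded ground truth.

#' Configuration for the synthetic expression generator
#'
#' Describes a multi-tissue bulk RNA-seq experiment on the TPM scale.
#' Expression is generated on the log2 scale as a per-gene baseline
#' (Normal(`baseline_log_mean`, `baseline_log_sd`), drawn once per gene)
#' plus `effect_size` for planted genes in their home tissue plus
#' per-sample Normal(0, `noise_sd`) noise, then exponentiated and scaled
#' so every sample sums to 1e6 (the TPM contract).
#'
#' The default tissue layout mirrors a typical public-database situation:
#' unequal tissue sizes, one rare tissue below a 10-sample cutoff
#' ("seedling") and one heterogeneous "mixed" tissue that preprocessing is
#' expected to discard.
#'
#' @param n_tissues number of tissue labels.
#' @param samples_per_tissue integer vector of per-tissue sample counts
#'   (length `n_tissues`).
#' @param n_genes total number of genes.
#' @param planted_per_tissue planted (truly tissue-specific) genes per tissue.
#' @param effect_size log2-scale mean up-shift of a planted gene in its home
#'   tissue; 0 means no signal.
#' @param baseline_log_mean,baseline_log_sd mean and SD of the per-gene
#'   baseline on the log2 scale.
#' @param noise_sd per-sample log2-scale Gaussian noise SD.
#' @param tissue_names optional character vector of tissue labels.
#' @param seed integer RNG seed for [generate_expression()].
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_tissues = 5L,
                         samples_per_tissue = c(30L, 25L, 20L, 12L, 8L),
                         n_genes = 2000L,
                         planted_per_tissue = 50L,
                         effect_size = 6,
                         baseline_log_mean = 3,
                         baseline_log_sd = 2,
                         noise_sd = 0.3,
                         tissue_names = NULL,
                         seed = 1L) {
  .check_scalar_count(n_tissues, "n_tissues")
  .check_scalar_count(n_genes, "n_genes")
  if (!is.numeric(samples_per_tissue) || length(samples_per_tissue) != n_tissues ||
      any(samples_per_tissue < 1) || any(samples_per_tissue != floor(samples_per_tissue)))
    .stopf("'samples_per_tissue' must be %d positive integers", n_tissues)
  if (!is.numeric(planted_per_tissue) || length(planted_per_tissue) != 1L ||
      planted_per_tissue < 0 || planted_per_tissue != floor(planted_per_tissue))
    .stopf("'planted_per_tissue' must be a single non-negative integer")
  if (planted_per_tissue * n_tissues > n_genes)
    .stopf("'planted_per_tissue' x 'n_tissues' (%d) exceeds 'n_genes' (%d)",
           planted_per_tissue * n_tissues, n_genes)
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    .stopf("'effect_size' must be a single non-negative number")
  if (!is.numeric(noise_sd) || noise_sd < 0) .stopf("'noise_sd' must be non-negative")
  if (!is.numeric(baseline_log_sd) || baseline_log_sd < 0)
    .stopf("'baseline_log_sd' must be non-negative")
  if (is.null(tissue_names)) {
    defaults <- c("leaf", "root", "seed", "seedling", "mixed")
    tissue_names <- if (n_tissues <= length(defaults)) defaults[seq_len(n_tissues)]
                    else c(defaults, paste0("tissue", seq_len(n_tissues - length(defaults))))
  }
  if (length(tissue_names) != n_tissues || anyDuplicated(tissue_names))
    .stopf("'tissue_names' must be %d distinct labels", n_tissues)
  structure(list(
    n_tissues = as.integer(n_tissues),
    samples_per_tissue = as.integer(samples_per_tissue),
    n_genes = as.integer(n_genes),
    planted_per_tissue = as.integer(planted_per_tissue),
    effect_size = effect_size,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd,
    tissue_names = tissue_names,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a synthetic multi-tissue TPM matrix with planted markers
#'
#' Each tissue receives `planted_per_tissue` dedicated genes whose log2
#' mean is elevated by `effect_size` in that tissue only; planted sets are
#' pairwise disjoint. After exponentiation every sample is scaled to sum
#' to 1e6. Because every tissue carries the same amount of planted mass,
#' the within-gene home-vs-other log2 contrast is preserved by the
#' normalization.
#'
#' @param config a [synth_config()].
#' @return list with elements `matrix` (samples x genes TPM matrix,
#'   `expr_scale` attribute `"tpm"`), `annotation` (data.frame
#'   `sample_id`, `tissue`) and `truth` (list `planted`: tissue -> gene
#'   IDs; `effect_size`: named per planted gene).
#' @examples
#' sim <- generate_expression(synth_config(n_tissues = 3,
#'   samples_per_tissue = c(5, 5, 5), n_genes = 100, planted_per_tissue = 5))
#' rowSums(sim$matrix)[1:3]
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "synth_config")) .stopf("'config' must come from synth_config()")
  set.seed(config$seed)
  n_samples <- sum(config$samples_per_tissue)
  tissue <- rep(config$tissue_names, config$samples_per_tissue)
  sample_ids <- sprintf("s%03d_%s", seq_len(n_samples), tissue)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))

  baseline <- rnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd)
  log2x <- matrix(rep(baseline, each = n_samples), n_samples, config$n_genes)

  planted <- vector("list", config$n_tissues)
  names(planted) <- config$tissue_names
  gene_pool <- seq_len(config$n_genes)
  for (t in seq_len(config$n_tissues)) {
    pick <- if (config$planted_per_tissue > 0)
      sort(sample(gene_pool, config$planted_per_tissue)) else integer(0)
    gene_pool <- setdiff(gene_pool, pick)
    planted[[t]] <- gene_ids[pick]
    if (length(pick))
      log2x[tissue == config$tissue_names[t], pick] <-
        log2x[tissue == config$tissue_names[t], pick] + config$effect_size
  }

  if (config$noise_sd > 0)
    log2x <- log2x + matrix(rnorm(length(log2x), 0, config$noise_sd),
                            n_samples, config$n_genes)

  tpm <- 2^log2x
  tpm <- tpm * (1e6 / rowSums(tpm))
  dimnames(tpm) <- list(sample_ids, gene_ids)

  effect <- rep(config$effect_size, config$planted_per_tissue * config$n_tissues)
  names(effect) <- unlist(planted, use.names = FALSE)
  list(
    matrix = .set_scale(tpm, "tpm"),
    annotation = data.frame(sample_id = sample_ids, tissue = tissue,
                            stringsAsFactors = FALSE),
    truth = list(planted = planted, effect_size = effect)
  )
}

#' All planted genes as one ground-truth gene set
#'
#' @param truth the `truth` element of [generate_expression()] output.
#' @return a [geneset()] with provenance `"truth"`.
#' @export
truth_geneset <- function(truth) {
  geneset(unlist(truth$planted, use.names = FALSE), "truth")
}

#' Write a synthetic fixture to disk
#'
#' Emits `matrix.tsv` (first column `sample_id`, one column per gene),
#' `annotation.tsv` (`sample_id`, `tissue`) and one
#' `planted_<tissue>.txt` gene list per tissue, in the dialects read back
#' by [read_expression_matrix()], [read_sample_annotation()] and
#' [read_geneset()].
#'
#' @param matrix,annotation,truth as produced by [generate_expression()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of paths written.
#' @export
write_fixture <- function(matrix, annotation, truth, out_dir) {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", out_dir)
  paths <- c(
    matrix = file.path(out_dir, "matrix.tsv"),
    annotation = file.path(out_dir, "annotation.tsv")
  )
  write_expression_matrix(matrix, paths[["matrix"]])
  write_sample_annotation(annotation, paths[["annotation"]])
  for (t in names(truth$planted)) {
    p <- file.path(out_dir, sprintf("planted_%s.txt", t))
    writeLines(truth$planted[[t]], p)
    paths[[paste0("planted_", t)]] <- p
  }
  invisible(paths)
}
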