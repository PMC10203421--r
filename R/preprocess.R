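## Matrix cleaning: rare-tissue and mixed-tissue removal, organ-class
## relabeling, whitelist + expression-level gene filtering, log transform.

#' Drop rare tissues and unwanted labels
#'
#' Removes every sample whose tissue has fewer than `min_per_tissue`
#' samples or whose label is in `drop_labels`. The gene axis is untouched.
#'
#' @param matrix samples-by-genes expression matrix.
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param min_per_tissue minimum samples a tissue needs to be retained.
#' @param drop_labels tissue labels to discard outright (e.g. `"mixed"`).
#' @return list with filtered `matrix` and `annotation`.
#' @export
filter_samples <- function(matrix, annotation, min_per_tissue = 10L,
                           drop_labels = "mixed") {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  if (min_per_tissue < 1) .stopf("'min_per_tissue' must be >= 1")
  tissue <- .tissue_of(matrix, annotation)
  counts <- table(tissue)
  keep_tissues <- setdiff(names(counts)[counts >= min_per_tissue], drop_labels)
  keep <- tissue %in% keep_tissues
  if (!any(keep)) .stopf("sample filtering removed every sample")
  m <- matrix[keep, , drop = FALSE]
  list(matrix = .set_scale(m, expr_scale(matrix)),
       annotation = annotation[annotation$sample_id %in% rownames(m), , drop = FALSE])
}

#' Relabel tissues as organ classes
#'
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param organ_map named character vector, tissue label -> organ class.
#' @return annotation with `tissue` replaced by the organ class; sample
#'   order preserved.
#' @export
map_to_organs <- function(annotation, organ_map) {
  .check_annotation(annotation)
  unmapped <- setdiff(unique(annotation$tissue), names(organ_map))
  if (length(unmapped))
    .stopf("organ_map does not cover tissue(s): %s", paste(unmapped, collapse = ", "))
  annotation$tissue <- unname(organ_map[annotation$tissue])
  annotation
}

#' Whitelist and expression-level gene filtering
#'
#' Keeps genes in `whitelist` (when given) whose expression exceeds
#' `tpm_threshold` across retained samples; by default a gene passes if
#' its *maximum* TPM is strictly above the threshold, so genes expressed
#' in a single tissue survive (set `stat = "mean"` for a mean-based rule).
#' Idempotent; the sample axis is untouched.
#'
#' @param matrix TPM-scale samples-by-genes matrix.
#' @param whitelist optional character vector of gene IDs to keep.
#' @param tpm_threshold strict lower threshold on the summary statistic.
#' @param stat summary across samples: `"max"` (default) or `"mean"`.
#' @return the filtered matrix.
#' @export
filter_genes <- function(matrix, whitelist = NULL, tpm_threshold = 1,
                         stat = c("max", "mean")) {
  .check_matrix(matrix)
  if (expr_scale(matrix) != "tpm") .stopf("filter_genes() expects a TPM-scale matrix")
  stat <- match.arg(stat)
  keep <- rep(TRUE, ncol(matrix))
  if (!is.null(whitelist)) keep <- colnames(matrix) %in% as.character(whitelist)
  summ <- if (stat == "max") apply(matrix, 2, max) else colMeans(matrix)
  keep <- keep & summ > tpm_threshold
  if (!any(keep)) .stopf("gene filtering removed every gene")
  .set_scale(matrix[, keep, drop = FALSE], "tpm")
}

#' Log2 transform a TPM matrix
#'
#' @param matrix TPM-scale matrix.
#' @param offset pseudo-count added before taking log2 (default 1).
#' @return matrix of `log2(TPM + offset)` values, `expr_scale` `"log2"`.
#' @export
log2_transform <- function(matrix, offset = 1) {
  .check_matrix(matrix)
  if (expr_scale(matrix) != "tpm")
    .stopf("matrix is already on the log2 scale")
  if (offset <= 0 && any(matrix <= 0))
    .stopf("offset must be > 0 when the matrix contains zeros")
  .set_scale(log2(matrix + offset), "log2")
}
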