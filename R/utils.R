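## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    .stopf("'%s' must be a single positive integer", name)
  invisible(as.integer(x))
}

#' Expression-scale flag of a matrix
#'
#' Matrices produced by this package carry an `expr_scale` attribute,
#' either `"tpm"` (non-negative, rows sum to 1e6) or `"log2"`. Matrices
#' without the attribute are treated as TPM.
#'
#' @param x samples-by-genes numeric matrix.
#' @return `"tpm"` or `"log2"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "expr_scale")
  if (is.null(s)) "tpm" else s
}

.set_scale <- function(x, scale) {
  attr(x, "expr_scale") <- scale
  x
}

.check_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) .stopf("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("expression matrix must have sample rownames and gene colnames")
  if (anyDuplicated(rownames(x))) .stopf("duplicate sample IDs in matrix")
  if (anyDuplicated(colnames(x))) .stopf("duplicate gene IDs in matrix")
  if (any(!is.finite(x))) .stopf("expression matrix contains non-finite values")
  invisible(x)
}

.check_annotation <- function(annotation, matrix = NULL) {
  if (!is.data.frame(annotation) || !all(c("sample_id", "tissue") %in% names(annotation)))
    .stopf("annotation must be a data.frame with columns 'sample_id' and 'tissue'")
  if (anyDuplicated(annotation$sample_id)) .stopf("duplicate sample IDs in annotation")
  if (any(!nzchar(annotation$tissue))) .stopf("empty tissue labels in annotation")
  if (!is.null(matrix)) {
    missing <- setdiff(rownames(matrix), annotation$sample_id)
    if (length(missing))
      .stopf("annotation missing matrix sample(s): %s", paste(head(missing, 5), collapse = ", "))
  }
  invisible(annotation)
}

## Tissue labels aligned to the matrix row order.
.tissue_of <- function(matrix, annotation) {
  annotation$tissue[match(rownames(matrix), annotation$sample_id)]
}

#' Construct a provenance-tagged gene set
#'
#' A gene set is a deduplicated character vector of gene IDs carrying a
#' `provenance` attribute recording which track produced it
#' (`"limma"`, `"lgbm"`, `"cnn"`, `"random"`, `"core"`, `"truth"`, ...).
#'
#' @param ids character vector of gene IDs (duplicates and blanks dropped).
#' @param provenance single string naming the producing track.
#' @return character vector of class `"geneset"`.
#' @export
geneset <- function(ids, provenance = "unknown") {
  ids <- unique(as.character(ids[nzchar(ids) & !is.na(ids)]))
  structure(ids, class = "geneset", provenance = provenance)
}

#' @export
print.geneset <- function(x, ...) {
  cat(sprintf("<geneset> %d genes, provenance '%s'\n", length(x), attr(x, "provenance")))
  if (length(x)) cat(" ", paste(head(x, 6), collapse = ", "),
                     if (length(x) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
provenance <- function(x) attr(x, "provenance")

## Stratified fold assignment: within each class, samples are shuffled and
## dealt round-robin into folds.
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

## Stratified train/test split; returns logical "in training set".
.stratified_split <- function(labels, train_frac) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, round(train_frac * length(idx)))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    train[sample(idx)[seq_len(max(1L, n_tr))]] <- TRUE
  }
  train
}
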