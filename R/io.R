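## Readers and writers for the package's plain-text dialects.
## Matrix TSV: header `sample_id` then gene IDs; one row per sample.
## Annotation TSV: columns `sample_id`, `tissue`.
## Gene lists: one ID per line, blank lines ignored.

#' Read a samples-by-genes expression matrix from TSV
#'
#' @param path TSV file whose first column is `sample_id` and remaining
#'   columns are gene IDs.
#' @param scale expression scale to stamp on the result (`"tpm"` or `"log2"`).
#' @return numeric matrix with sample rownames, gene colnames and an
#'   `expr_scale` attribute.
#' @export
read_expression_matrix <- function(path, scale = "tpm") {
  if (!file.exists(path)) .stopf("matrix file '%s' does not exist", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    .stopf("matrix file '%s': first column must be 'sample_id'", path)
  bad <- which(!vapply(df[-1], is.numeric, logical(1)))
  if (length(bad))
    .stopf("matrix file '%s': non-numeric values in column '%s'", path, names(df[-1])[bad[1]])
  m <- as.matrix(df[-1])
  rownames(m) <- df$sample_id
  .check_matrix(m)
  .set_scale(m, match.arg(scale, c("tpm", "log2")))
}

#' @rdname read_expression_matrix
#' @param matrix matrix to write.
#' @export
write_expression_matrix <- function(matrix, path) {
  .check_matrix(matrix)
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' @param path TSV with columns `sample_id` and `tissue`.
#' @return data.frame with columns `sample_id`, `tissue`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) .stopf("annotation file '%s' does not exist", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check_annotation(df)
  df[c("sample_id", "tissue")]
}

#' @rdname read_sample_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_sample_annotation <- function(annotation, path) {
  .check_annotation(annotation)
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a plain-text gene list
#'
#' @param path text file with one gene ID per line; blank lines ignored.
#' @param provenance provenance tag for the resulting [geneset()].
#' @export
read_geneset <- function(path, provenance = "file") {
  if (!file.exists(path)) .stopf("gene list '%s' does not exist", path)
  geneset(trimws(readLines(path)), provenance)
}

#' @rdname read_geneset
#' @param genes character vector or [geneset()] to write.
#' @export
write_geneset <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
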