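## Linear track: two-group moderated-t differential expression on log2
## expression with empirical-Bayes variance shrinkage, BH adjustment,
## strict threshold filtering and the merge across tissue pairs.

## Newton inversion of the trigamma function (used by the log-variance
## moment matching). Solves trigamma(x) = y for x > 0.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks per-gene sample variances toward a pooled prior. The prior
#' degrees of freedom `d0` and prior variance `s0_sq` are estimated by
#' matching the mean and variance of `log(s_sq)` to the moments of a
#' scaled log-F distribution (trigamma inversion); each posterior variance
#' is the df-weighted pool `(d0*s0_sq + d_g*s_sq) / (d0 + d_g)`.
#'
#' @param s_sq per-gene sample variances (>= 0).
#' @param d_g residual degrees of freedom, scalar or per-gene (>= 1).
#' @return list of class `"moderated_variance_fit"` with `d0`, `s0_sq`,
#'   `s_tilde_sq`, `d_g`. `d0` may be `Inf` (all variances shrunk to
#'   `s0_sq`).
#' @export
moderate_variances <- function(s_sq, d_g) {
  if (any(s_sq < 0, na.rm = TRUE)) .stopf("'s_sq' must be non-negative")
  if (any(d_g < 1)) .stopf("'d_g' must be >= 1")
  d_g <- rep_len(d_g, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0
  if (sum(ok) < 2)
    .stopf("variance moderation needs at least 2 genes with positive variance")
  z <- log(s_sq[ok])
  e <- z - digamma(d_g[ok] / 2) + log(d_g[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(d_g[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s_tilde_sq <- if (is.infinite(d0)) rep(s0_sq, length(s_sq))
                else (d0 * s0_sq + d_g * s_sq) / (d0 + d_g)
  structure(list(d0 = d0, s0_sq = s0_sq, s_tilde_sq = s_tilde_sq, d_g = d_g),
            class = "moderated_variance_fit")
}

#' Moderated-t differential expression for one tissue pair
#'
#' For each gene, computes `logFC = mean(A) - mean(B)` on the log2 scale,
#' a pooled two-group variance with `nA + nB - 2` df, the moderated t
#' using the posterior variance from [moderate_variances()] with
#' `d0 + d_g` df, a two-sided p-value, and the BH-adjusted p-value.
#'
#' @param log_matrix log2-scale samples-by-genes matrix.
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param pair character vector of two tissue labels `(A, B)`.
#' @return data.frame of class `"de_table"`: `gene_id`, `logFC`,
#'   `AveExp`, `t`, `P.Value`, `adj.P.Val`, `direction` (filled by
#'   [filter_degs()], initially `"none"`), with attributes `pair` and
#'   `variance_fit`.
#' @export
fit_pairwise_de <- function(log_matrix, annotation, pair) {
  .check_matrix(log_matrix)
  .check_annotation(annotation, log_matrix)
  if (expr_scale(log_matrix) != "log2")
    .stopf("fit_pairwise_de() expects a log2-scale matrix (see log2_transform())")
  if (length(pair) != 2L) .stopf("'pair' must name two tissue labels")
  tissue <- .tissue_of(log_matrix, annotation)
  ia <- which(tissue == pair[1]); ib <- which(tissue == pair[2])
  if (length(ia) < 2 || length(ib) < 2)
    .stopf("tissue pair (%s, %s) needs >= 2 samples per group (have %d, %d)",
           pair[1], pair[2], length(ia), length(ib))
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(log_matrix[ia, , drop = FALSE])
  mb <- colMeans(log_matrix[ib, , drop = FALSE])
  va <- apply(log_matrix[ia, , drop = FALSE], 2, var)
  vb <- apply(log_matrix[ib, , drop = FALSE], 2, var)
  d_g <- na + nb - 2
  s_sq <- ((na - 1) * va + (nb - 1) * vb) / d_g
  fit <- moderate_variances(s_sq, d_g)
  se <- sqrt(fit$s_tilde_sq * (1 / na + 1 / nb))
  logfc <- ma - mb
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  df_total <- fit$d0 + d_g
  p <- 2 * pt(-abs(tstat), df = df_total)
  tab <- data.frame(
    gene_id = colnames(log_matrix),
    logFC = unname(logfc),
    AveExp = unname(colMeans(log_matrix[c(ia, ib), , drop = FALSE])),
    t = unname(tstat),
    P.Value = unname(p),
    adj.P.Val = unname(adjust_bh(p)),
    direction = "none",
    stringsAsFactors = FALSE
  )
  attr(tab, "pair") <- pair
  attr(tab, "variance_fit") <- fit
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated front-end to `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order, clipped to 1.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Threshold a DE table into up/down gene sets
#'
#' Strict inequalities on both thresholds: a gene is "up" when
#' `adj.P.Val < p_thresh` and `logFC > lfc_thresh`, "down" when
#' `adj.P.Val < p_thresh` and `logFC < -lfc_thresh`.
#'
#' @param table a `"de_table"` from [fit_pairwise_de()].
#' @param p_thresh adjusted-p threshold (default 0.01).
#' @param lfc_thresh absolute log2-fold-change threshold (default 4).
#' @return list with `up` and `down` [geneset()]s and the `table` with its
#'   `direction` column filled in.
#' @export
filter_degs <- function(table, p_thresh = 0.01, lfc_thresh = 4) {
  if (p_thresh <= 0 || lfc_thresh <= 0) .stopf("thresholds must be > 0")
  up <- table$adj.P.Val < p_thresh & table$logFC > lfc_thresh
  dn <- table$adj.P.Val < p_thresh & table$logFC < -lfc_thresh
  table$direction <- ifelse(up, "up", ifelse(dn, "down", "none"))
  list(up = geneset(table$gene_id[up], "limma"),
       down = geneset(table$gene_id[dn], "limma"),
       table = table)
}

#' Merge per-pair DEG sets into one tissue-specific gene set
#'
#' @param pair_sets list whose elements are gene sets (or the
#'   `list(up, down)` output of [filter_degs()]).
#' @param combine `"union"` (default) or `"intersection"` across pairs.
#'   With `"intersection"`, each pair contributes the union of its up and
#'   down genes and the pairs are intersected.
#' @return a [geneset()] with provenance `"limma"`.
#' @export
merge_pair_sets <- function(pair_sets, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!length(pair_sets)) .stopf("'pair_sets' must contain at least one set")
  per_pair <- lapply(pair_sets, function(s) {
    if (is.list(s) && !is.null(s$up)) unique(c(s$up, s$down)) else as.character(s)
  })
  ids <- if (combine == "union") unique(unlist(per_pair, use.names = FALSE))
         else Reduce(intersect, per_pair)
  geneset(ids, "limma")
}

#' Enumerate unordered tissue pairs
#'
#' @param labels tissue/organ labels (deduplicated, order preserved).
#' @return list of length-2 character vectors, one per unordered pair.
#' @export
tissue_pairs <- function(labels) {
  labels <- unique(as.character(labels))
  if (length(labels) < 2) .stopf("need >= 2 labels to form pairs")
  cmb <- utils::combn(labels, 2)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Run the full linear track
#'
#' Fits [fit_pairwise_de()] for every tissue pair, applies
#' [filter_degs()] and merges with [merge_pair_sets()].
#'
#' @inheritParams fit_pairwise_de
#' @inheritParams filter_degs
#' @inheritParams merge_pair_sets
#' @return list with `geneset` (provenance `"limma"`), `pair_results`
#'   (per-pair `filter_degs()` output, names `"A.vs.B"`), and `counts`
#'   (data.frame pair / total / up / down).
#' @export
de_track <- function(log_matrix, annotation, p_thresh = 0.01, lfc_thresh = 4,
                     combine = c("union", "intersection")) {
  pairs <- tissue_pairs(.tissue_of(log_matrix, annotation))
  res <- lapply(pairs, function(pr) {
    filter_degs(fit_pairwise_de(log_matrix, annotation, pr),
                p_thresh = p_thresh, lfc_thresh = lfc_thresh)
  })
  names(res) <- vapply(pairs, paste, "", collapse = ".vs.")
  counts <- data.frame(
    pair = names(res),
    total = vapply(res, function(r) length(r$up) + length(r$down), 0L),
    up = vapply(res, function(r) length(r$up), 0L),
    down = vapply(res, function(r) length(r$down), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(geneset = merge_pair_sets(res, combine = combine),
       pair_results = res, counts = counts)
}

#' Write a DE table as TSV
#'
#' @param table a `"de_table"`.
#' @param path output path.
#' @export
write_de_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
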