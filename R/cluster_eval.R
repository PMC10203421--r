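## Validation layer: k-means clustering of samples on candidate gene
## sets, V-measure scoring, a size-matched resampling null and the
## predictive one-tailed t-test, plus the cross-track core intersection.

#' V-measure of a clustering against true classes
#'
#' Conditional-entropy-based scores (natural log; the base cancels):
#' homogeneity `h = 1 - H(C|K)/H(C)`, completeness
#' `c = 1 - H(K|C)/H(K)`, and their harmonic mean `v`. `h = 1` when
#' `H(C) = 0` and `c = 1` when `H(K) = 0`; `v = 0` when `h + c = 0`.
#'
#' @param true_labels vector of true class labels.
#' @param cluster_labels vector of predicted cluster labels (same length).
#' @return list of class `"vmeasure"`: `h`, `c`, `v` and the entropies
#'   `H_C`, `H_C_given_K`, `H_K`, `H_K_given_C`.
#' @export
vmeasure <- function(true_labels, cluster_labels) {
  if (length(true_labels) != length(cluster_labels))
    .stopf("label vectors must have equal length")
  if (!length(true_labels)) .stopf("label vectors must be non-empty")
  n <- length(true_labels)
  ct <- table(true_labels, cluster_labels)  # n_{c,k}
  nc <- rowSums(ct); nk <- colSums(ct)
  plogp <- function(num, den) {
    ok <- num > 0
    sum(num[ok] / n * log(num[ok] / den[ok]))
  }
  H_C <- -sum(ifelse(nc > 0, nc / n * log(nc / n), 0))
  H_K <- -sum(ifelse(nk > 0, nk / n * log(nk / n), 0))
  ## H(C|K) = -sum_{c,k} n_ck/n log(n_ck/n_k)
  H_C_given_K <- -plogp(ct, matrix(nk, nrow(ct), ncol(ct), byrow = TRUE))
  H_K_given_C <- -plogp(ct, matrix(nc, nrow(ct), ncol(ct)))
  h <- if (H_C == 0) 1 else 1 - H_C_given_K / H_C
  c_ <- if (H_K == 0) 1 else 1 - H_K_given_C / H_K
  v <- if (h + c_ > 0) 2 * h * c_ / (h + c_) else 0
  structure(list(h = h, c = c_, v = v, H_C = H_C, H_C_given_K = H_C_given_K,
                 H_K = H_K, H_K_given_C = H_K_given_C),
            class = "vmeasure")
}

## One k-means run (Lloyd) with random initialization; retries with a
## fresh draw when the random centers leave a cluster empty.
.kmeans_once <- function(x, k) {
  for (attempt in 1:10) {
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = k, iter.max = 100,
                              nstart = 1, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  .stopf("k-means failed to produce %d non-empty clusters", k)
}

#' V-measure distribution of k-means on one gene set
#'
#' Restricts the matrix to the gene set's columns (deduplicated), runs
#' Lloyd's k-means `n_runs` times with distinct random initializations,
#' and scores each run against the true tissue labels.
#'
#' @param matrix samples-by-genes matrix (typically log2 scale).
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param geneset character vector / [geneset()] of gene IDs (must all be
#'   matrix columns).
#' @param k number of clusters (default: number of distinct tissues).
#' @param n_runs k-means restarts (default 10).
#' @param seed integer RNG seed.
#' @return numeric vector of `n_runs` V-measure values.
#' @export
cluster_with_geneset <- function(matrix, annotation, geneset, k = NULL,
                                 n_runs = 10L, seed = 1L) {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  ids <- unique(as.character(geneset))
  if (!length(ids)) .stopf("gene set is empty")
  missing <- setdiff(ids, colnames(matrix))
  if (length(missing) == length(ids)) .stopf("no gene of the set is in the matrix")
  ids <- setdiff(ids, missing)
  tissue <- .tissue_of(matrix, annotation)
  if (is.null(k)) k <- length(unique(tissue))
  if (k < 2) .stopf("'k' must be >= 2")
  x <- matrix[, ids, drop = FALSE]
  set.seed(seed)
  vapply(seq_len(n_runs), function(r) vmeasure(tissue, .kmeans_once(x, k))$v, 0)
}

#' Resampling null distribution of mean V-measures
#'
#' Draws `n_sets` uniform random gene subsets of size `set_size` (without
#' replacement within a set), scores each with [cluster_with_geneset()]
#' and records the per-set mean V.
#'
#' @inheritParams cluster_with_geneset
#' @param set_size genes per random set (size-matched to the candidate).
#' @param n_sets number of random sets (default 100).
#' @return list of class `"null_distribution"`: `means` (length
#'   `n_sets`), `mean`, `sd`, `set_size`, `n_sets`, `n_runs`.
#' @export
null_distribution <- function(matrix, annotation, set_size, n_sets = 100L,
                              n_runs = 10L, k = NULL, seed = 1L) {
  .check_matrix(matrix)
  if (set_size > ncol(matrix)) .stopf("'set_size' exceeds the gene count")
  if (n_sets < 2) .stopf("'n_sets' must be >= 2")
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max, n_sets)
  means <- vapply(seq_len(n_sets), function(i) {
    set.seed(draw_seeds[i])
    genes <- sample(colnames(matrix), set_size)
    mean(cluster_with_geneset(matrix, annotation, genes, k = k,
                              n_runs = n_runs, seed = draw_seeds[i] %% 1000L + i))
  }, 0)
  structure(list(means = means, mean = mean(means), sd = sd(means),
                 set_size = as.integer(set_size), n_sets = as.integer(n_sets),
                 n_runs = as.integer(n_runs)),
            class = "null_distribution")
}

#' One-tailed test of a candidate mean V against the resampling null
#'
#' Tests whether the candidate set's mean V-measure is larger than
#' expected for a random gene set of the same size. The statistic is the
#' predictive t
#' `t = (mean(null) - candidate) / (sd(null) * sqrt(1 + 1/n))` with
#' `n - 1` df, whose p-value `P(T <= t)` is small when the candidate lies
#' far above the null and uniform when the candidate is itself a draw
#' from the null. With a degenerate null (`sd = 0`) the p-value is 0, 1
#' or 0.5 for a candidate above, below or equal to the null mean.
#'
#' @param candidate_mean_v mean V-measure of the candidate gene set.
#' @param null a `"null_distribution"`.
#' @return one-tailed p-value.
#' @export
one_tail_test <- function(candidate_mean_v, null) {
  if (!inherits(null, "null_distribution")) .stopf("'null' must come from null_distribution()")
  n <- null$n_sets
  if (null$sd == 0) {
    return(if (candidate_mean_v > null$mean) 0
           else if (candidate_mean_v < null$mean) 1 else 0.5)
  }
  tstat <- (null$mean - candidate_mean_v) / (null$sd * sqrt(1 + 1 / n))
  pt(tstat, df = n - 1)
}

#' Core intersection across tracks
#'
#' @param sets list of >= 2 gene sets.
#' @return a [geneset()] with provenance `"core"`.
#' @export
core_intersection <- function(sets) {
  if (length(sets) < 2) .stopf("need >= 2 sets to intersect")
  geneset(Reduce(intersect, lapply(sets, as.character)), "core")
}

#' Evaluate candidate gene sets by clustering
#'
#' Scores every candidate set and the full gene set with
#' [cluster_with_geneset()], builds a size-matched null for each
#' candidate and reports mean V, the null p-value and a ranking (mean V
#' descending).
#'
#' @inheritParams cluster_with_geneset
#' @param candidate_sets named list of gene sets.
#' @param n_null_sets random sets per null (default 100).
#' @return list of class `"cluster_eval_report"`: `table` (data.frame
#'   set / size / mean_v / p_value / provenance, ranked), `v_distributions`
#'   (list of per-run V vectors), `nulls` (per-candidate
#'   `"null_distribution"`).
#' @export
evaluate_all <- function(matrix, annotation, candidate_sets, k = NULL,
                         n_runs = 10L, n_null_sets = 100L, seed = 1L) {
  if (!length(candidate_sets) || is.null(names(candidate_sets)))
    .stopf("'candidate_sets' must be a non-empty named list")
  if (any(!lengths(candidate_sets))) .stopf("candidate sets must be non-empty")
  sets <- c(candidate_sets, list(full = geneset(colnames(matrix), "full")))
  vdist <- list(); nulls <- list(); rows <- list()
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    vs <- cluster_with_geneset(matrix, annotation, sets[[i]], k = k,
                               n_runs = n_runs, seed = seed + i)
    vdist[[nm]] <- vs
    size <- length(unique(as.character(sets[[i]])))
    nul <- null_distribution(matrix, annotation, set_size = size,
                             n_sets = n_null_sets, n_runs = n_runs, k = k,
                             seed = seed + 1000L + i)
    nulls[[nm]] <- nul
    prov <- attr(sets[[i]], "provenance")
    rows[[nm]] <- data.frame(
      set = nm, size = size, mean_v = mean(vs),
      p_value = one_tail_test(mean(vs), nul),
      provenance = if (is.null(prov)) "unknown" else prov,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$mean_v), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, v_distributions = vdist, nulls = nulls),
            class = "cluster_eval_report")
}

#' @export
print.cluster_eval_report <- function(x, ...) {
  cat("<cluster_eval_report> sets ranked by mean V-measure\n")
  print(x$table, digits = 4)
  invisible(x)
}
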