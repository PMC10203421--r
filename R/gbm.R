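## Tree-ensemble track: SMOTE rebalancing, stratified cross-validated
## gradient-boosted classification (xgboost), total-gain importances,
## and the shadow-feature Z-score filter.

.default_gbm_params <- function(n_classes) {
  list(objective = "multi:softprob", num_class = n_classes,
       max_depth = 4, eta = 0.2, subsample = 0.9,
       colsample_bytree = 0.8, min_child_weight = 1, nthread = 1)
}

.encode_labels <- function(labels) {
  lv <- sort(unique(labels))
  list(levels = lv, y = match(labels, lv) - 1L)
}

.fit_gbm <- function(x, y, n_classes, nrounds, params = NULL) {
  p <- .default_gbm_params(n_classes)
  if (!is.null(params)) p[names(params)] <- params
  xgboost::xgb.train(params = p, data = xgboost::xgb.DMatrix(x, label = y),
                     nrounds = nrounds, verbose = 0)
}

#' SMOTE class rebalancing
#'
#' Brings every class up to the majority-class count by synthesizing
#' minority samples: each synthetic sample is `x_i + u * (x_j - x_i)` with
#' `u ~ U(0, 1)`, where `x_j` is one of the `k_neighbors` nearest
#' same-class neighbors of a randomly chosen minority sample `x_i`.
#' Original rows are preserved unchanged; synthetic rows are appended with
#' IDs `<tissue>_synth<i>`.
#'
#' @param matrix samples-by-genes matrix (any scale).
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param k_neighbors neighbor count (reduced with a warning for classes
#'   smaller than `k_neighbors + 1`).
#' @param seed integer RNG seed.
#' @return list with the augmented `matrix` and `annotation`.
#' @export
balance_classes <- function(matrix, annotation, k_neighbors = 5L, seed = 1L) {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  if (k_neighbors < 1) .stopf("'k_neighbors' must be >= 1")
  set.seed(seed)
  tissue <- .tissue_of(matrix, annotation)
  counts <- table(tissue)
  if (any(counts < 2))
    .stopf("class '%s' has a single sample; cannot synthesize neighbors",
           names(counts)[counts < 2][1])
  target <- max(counts)
  new_rows <- list(); new_ids <- character(0); new_tissue <- character(0)
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    xs <- matrix[tissue == cl, , drop = FALSE]
    k <- k_neighbors
    if (nrow(xs) <= k) {
      k <- nrow(xs) - 1L
      warning(sprintf("class '%s': k_neighbors reduced to %d (class size %d)",
                      cl, k, nrow(xs)), call. = FALSE)
    }
    dmat <- as.matrix(dist(xs))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, function(d) order(d)[seq_len(k)], simplify = FALSE)
    if (is.matrix(nn)) nn <- asplit(nn, 2)  # k = 1 edge shape
    base <- sample(nrow(xs), need, replace = TRUE)
    for (s in seq_len(need)) {
      i <- base[s]
      j <- nn[[i]][sample.int(k, 1)]
      u <- runif(1)
      new_rows[[length(new_rows) + 1L]] <- xs[i, ] + u * (xs[j, ] - xs[i, ])
      new_ids <- c(new_ids, sprintf("%s_synth%d", cl, s))
      new_tissue <- c(new_tissue, cl)
    }
  }
  if (!length(new_rows))
    return(list(matrix = matrix, annotation = annotation))
  add <- do.call(rbind, new_rows)
  rownames(add) <- new_ids
  out <- rbind(matrix, add)
  list(
    matrix = .set_scale(out, expr_scale(matrix)),
    annotation = rbind(annotation[c("sample_id", "tissue")],
                       data.frame(sample_id = new_ids, tissue = new_tissue,
                                  stringsAsFactors = FALSE))
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with marginal-product expected agreement
#' `p_e`. When `p_e == 1` (a degenerate single-cell table) kappa is
#' defined as 0.
#'
#' @param confusion square class-by-class count matrix (rows = truth).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0) || sum(confusion) == 0)
    .stopf("'confusion' must be a square non-negative matrix with positive total")
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

## Macro one-vs-rest AUC from a probability matrix (columns = levels).
.macro_auc <- function(truth, prob, levels) {
  aucs <- vapply(seq_along(levels), function(j) {
    resp <- as.integer(truth == levels[j])
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(resp, prob[, j], quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  }, 0)
  mean(aucs, na.rm = TRUE)
}

.classification_metrics <- function(truth, pred, prob, levels) {
  cm <- table(factor(truth, levels), factor(pred, levels))
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1)
  rec <- tp / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0
  c(accuracy = sum(tp) / sum(cm),
    auc = .macro_auc(truth, prob, levels),
    recall = mean(rec[present]),
    precision = mean(prec[present]),
    f1 = mean(f1[present]),
    kappa = cohens_kappa(cm))
}

#' Stratified cross-validated gradient-boosted classification
#'
#' Runs stratified k-fold cross-validation of a gradient-boosted tree
#' classifier on tissue labels, then fits a final model on a stratified
#' 70/30 train split. Reported metrics per fold: accuracy, macro
#' one-vs-rest AUC, macro recall/precision/F1, Cohen's kappa.
#'
#' @param matrix samples-by-genes matrix.
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param n_folds folds for cross-validation (default 10).
#' @param seed integer RNG seed.
#' @param nrounds boosting rounds.
#' @param params named list overriding the default booster parameters.
#' @param train_frac fraction used to fit the final model (default 0.7).
#' @return list of class `"gbm_cv"`: `model` (xgb.Booster), `metrics`
#'   (data.frame, one row per fold plus `Mean` and `SD`), `levels`,
#'   `holdout` (row indices not used by the final fit).
#' @export
train_gbm_cv <- function(matrix, annotation, n_folds = 10L, seed = 1L,
                         nrounds = 60L, params = NULL, train_frac = 0.7) {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  if (n_folds < 2) .stopf("'n_folds' must be >= 2")
  set.seed(seed)
  enc <- .encode_labels(.tissue_of(matrix, annotation))
  k <- length(enc$levels)
  if (k < 2) .stopf("need >= 2 classes")
  if (min(table(enc$y)) < n_folds)
    warning("some class has fewer samples than folds; folds will miss classes",
            call. = FALSE)
  fold <- .stratified_folds(enc$y, n_folds)
  per_fold <- matrix(NA_real_, n_folds, 6,
                     dimnames = list(NULL, c("accuracy", "auc", "recall",
                                             "precision", "f1", "kappa")))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    bst <- .fit_gbm(matrix[tr, , drop = FALSE], enc$y[tr], k, nrounds, params)
    prob <- predict(bst, xgboost::xgb.DMatrix(matrix[!tr, , drop = FALSE]))
    pred <- enc$levels[max.col(prob)]
    per_fold[f, ] <- .classification_metrics(enc$levels[enc$y[!tr] + 1L],
                                             pred, prob, enc$levels)
  }
  metrics <- as.data.frame(rbind(per_fold,
                                 Mean = colMeans(per_fold),
                                 SD = apply(per_fold, 2, sd)))
  metrics <- cbind(fold = c(seq_len(n_folds) - 1L, "Mean", "SD"), metrics)
  rownames(metrics) <- NULL
  tr <- .stratified_split(enc$y, train_frac)
  final <- .fit_gbm(matrix[tr, , drop = FALSE], enc$y[tr], k, nrounds, params)
  structure(list(model = final, metrics = metrics, levels = enc$levels,
                 holdout = which(!tr)), class = "gbm_cv")
}

#' Total-gain feature importances
#'
#' Per-feature split gain summed over the ensemble, normalized to sum to
#' 1 over used features; features never chosen for a split score 0.
#'
#' @param model an `xgb.Booster` or a `"gbm_cv"` object.
#' @param feature_names optional full feature vector (defaults to the
#'   model's features) so unused features appear with 0.
#' @return named non-negative numeric vector.
#' @export
gain_importance <- function(model, feature_names = NULL) {
  if (inherits(model, "gbm_cv")) model <- model$model
  if (!inherits(model, "xgb.Booster")) .stopf("'model' must be a trained booster")
  imp <- xgboost::xgb.importance(model = model)
  if (is.null(feature_names)) feature_names <- xgboost::getinfo(model, "feature_name")
  if (is.null(feature_names)) feature_names <- imp$Feature
  out <- setNames(numeric(length(feature_names)), feature_names)
  out[imp$Feature] <- imp$Gain
  out
}

#' Information gain of a partition (bits)
#'
#' `Gain(D) = Ent(D) - sum_v (|D_v|/|D|) * Ent(D_v)` with base-2 entropy
#' `Ent(D) = -sum_k p_k log2 p_k`.
#'
#' @param parent_labels labels of the parent set `D`.
#' @param partition list of label vectors, disjoint blocks whose
#'   concatenation is a permutation of `parent_labels`.
#' @return information gain in bits, in `[0, Ent(D)]`.
#' @export
information_gain <- function(parent_labels, partition) {
  if (!length(parent_labels)) .stopf("parent set must be non-empty")
  child <- unlist(partition, use.names = FALSE)
  if (length(child) != length(parent_labels) ||
      !identical(sort(as.character(child)), sort(as.character(parent_labels))))
    .stopf("partition blocks must be disjoint and cover the parent set")
  ent <- function(lab) {
    p <- table(lab) / length(lab)
    -sum(p * log2(p))
  }
  n <- length(parent_labels)
  ent(parent_labels) -
    sum(vapply(partition, function(b) length(b) / n * ent(b), 0)[
      lengths(partition) > 0])
}

#' Shadow-feature Z-score filtering of gene importances
#'
#' For each of `n_reps` repetitions, every real gene column is copied and
#' row-permuted independently ("shadow" features); a gradient-boosted
#' classifier is trained on the concatenated `[real | shadow]` matrix and
#' total-gain importances are recorded. Each feature's Z-score is
#' mean/SD of its importances across repetitions; a real gene is kept iff
#' its Z exceeds the largest shadow Z (`Z_max`). Features with zero SD
#' get Z `+Inf` when their mean importance is positive and `-Inf`
#' otherwise, so never-used features can never be kept.
#'
#' @param matrix samples-by-genes matrix (typically log2 scale, balanced).
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param n_reps independent train repetitions (>= 2; shadows and booster
#'   subsampling are redrawn each time).
#' @param seed integer RNG seed.
#' @param nrounds boosting rounds per repetition.
#' @param params booster parameter overrides; the default uses aggressive
#'   per-node column subsampling so importance mass spreads across
#'   correlated informative genes rather than concentrating on a few.
#' @return list of class `"boruta_result"`: `geneset` (provenance
#'   `"lgbm"`), `z_real`, `z_shadow`, `z_max`, `kept` (logical per gene),
#'   `importances` (reps x features matrix).
#' @export
boruta_filter <- function(matrix, annotation, n_reps = 20L, seed = 1L,
                          nrounds = 50L, params = NULL) {
  .check_matrix(matrix)
  .check_annotation(annotation, matrix)
  if (n_reps < 2) .stopf("'n_reps' must be >= 2 (Z-score SD undefined otherwise)")
  set.seed(seed)
  enc <- .encode_labels(.tissue_of(matrix, annotation))
  k <- length(enc$levels)
  ## canonical (sorted) gene order: greedy tree learners break exact gain
  ## ties by column position, so the kept set is made independent of the
  ## caller's column order by fixing the internal order
  ord <- order(colnames(matrix))
  matrix <- matrix[, ord, drop = FALSE]
  genes <- colnames(matrix)
  p <- ncol(matrix)
  shadow_names <- paste0("shadow_", genes)
  ## per-node feature subsampling spreads split gain across correlated
  ## informative genes instead of concentrating it on a few
  boruta_params <- list(colsample_bynode = 0.1, subsample = 0.8,
                        max_depth = 4, eta = 0.2)
  if (!is.null(params)) boruta_params[names(params)] <- params
  imps <- matrix(0, n_reps, 2 * p, dimnames = list(NULL, c(genes, shadow_names)))
  rep_seeds <- sample.int(2^30, n_reps)
  ## shadow permutations are seeded per (repetition, gene ID) so the kept
  ## set does not depend on gene column order
  gene_hash <- vapply(genes, function(g)
    sum(utf8ToInt(g) * seq_along(utf8ToInt(g))) %% 2^20, 0)
  for (r in seq_len(n_reps)) {
    shadow <- matrix
    for (j in seq_len(p)) {
      set.seed((rep_seeds[r] + gene_hash[j]) %% 2^31)
      shadow[, j] <- shadow[sample.int(nrow(shadow)), j]
    }
    colnames(shadow) <- shadow_names
    x <- cbind(matrix, shadow)
    bst <- .fit_gbm(x, enc$y, k, nrounds,
                    c(boruta_params, list(seed = rep_seeds[r])))
    imps[r, ] <- gain_importance(bst, colnames(x))
  }
  zscore <- function(v) {
    m <- mean(v); s <- sd(v)
    if (s == 0) return(if (m > 0) Inf else -Inf)
    m / s
  }
  z <- apply(imps, 2, zscore)
  z_real <- z[seq_len(p)]
  z_shadow <- z[p + seq_len(p)]
  z_max <- max(z_shadow)
  kept <- z_real > z_max
  structure(list(
    geneset = geneset(genes[kept], "lgbm"),
    z_real = z_real, z_shadow = z_shadow, z_max = z_max, kept = kept,
    importances = imps
  ), class = "boruta_result")
}
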