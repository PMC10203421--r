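test_that("SMOTE balancing reaches the majority count without touching originals", {
  set.seed(10)
  n1 <- 20L; n2 <- 8L
  m <- matrix(rnorm((n1 + n2) * 6, 5, 1), n1 + n2, 6,
              dimnames = list(sprintf("s%02d", 1:(n1 + n2)), paste0("g", 1:6)))
  ann <- data.frame(sample_id = rownames(m),
                    tissue = rep(c("big", "small"), c(n1, n2)),
                    stringsAsFactors = FALSE)
  bal <- balance_classes(m, ann, k_neighbors = 3, seed = 2)
  counts <- table(bal$annotation$tissue)
  expect_equal(unname(counts[["big"]]), n1)
  expect_equal(unname(counts[["small"]]), n1)
  # originals preserved bit for bit
  expect_identical(bal$matrix[rownames(m), ], m[, ])

  # every synthetic row lies on a segment between two minority rows
  synth <- setdiff(rownames(bal$matrix), rownames(m))
  minority <- m[ann$tissue == "small", , drop = FALSE]
  pairs <- t(combn(nrow(minority), 2))
  seg_dist <- function(s) {
    min(apply(pairs, 1, function(ij) {
      a <- minority[ij[1], ]; b <- minority[ij[2], ]
      d <- b - a
      u <- sum((s - a) * d) / sum(d * d)
      if (u < -1e-9 || u > 1 + 1e-9) return(Inf)
      sqrt(sum((s - (a + u * d))^2))
    }))
  }
  res <- vapply(synth, function(id) seg_dist(bal$matrix[id, ]), 0)
  expect_true(all(res < 1e-8))
})

test_that("balancing is the identity on balanced data and rejects singletons", {
  set.seed(11)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  ann <- data.frame(sample_id = rownames(m), tissue = rep(c("a", "b"), each = 5))
  bal <- balance_classes(m, ann, seed = 1)
  expect_identical(bal$matrix, m)
  expect_identical(bal$annotation, ann)

  ann2 <- data.frame(sample_id = rownames(m), tissue = c(rep("a", 9), "b"))
  expect_error(balance_classes(m, ann2, seed = 1), "single sample")

  ann3 <- data.frame(sample_id = rownames(m), tissue = c(rep("a", 7), rep("b", 3)))
  expect_warning(balance_classes(m, ann3, k_neighbors = 5, seed = 1),
                 "k_neighbors reduced")
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohens_kappa(diag(c(5, 3, 2))), 1)
  expect_equal(cohens_kappa(matrix(1, 2, 2)), 0)
  # p_o = 0.7, p_e = 0.5 -> kappa 0.4
  expect_equal(cohens_kappa(matrix(c(40, 20, 10, 30), 2, 2)), 0.4)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "positive total")
})

test_that("information gain matches the entropy definition", {
  # pure split of a balanced binary parent: gain = Ent(D) = 1 bit
  parent <- rep(c("+", "-"), each = 4)
  expect_equal(information_gain(parent, list(rep("+", 4), rep("-", 4))), 1)
  # proportion-preserving split: zero gain
  expect_equal(information_gain(parent,
    list(rep(c("+", "-"), each = 2), rep(c("+", "-"), each = 2))), 0)
  # (3+,1-) / (1+,3-): 1 - H(3/4) = 0.188722 bits
  expect_equal(information_gain(parent,
    list(c("+", "+", "+", "-"), c("+", "-", "-", "-"))),
    0.188722, tolerance = 1e-6)
  expect_error(information_gain(character(0), list()), "non-empty")
  expect_error(information_gain(parent, list(rep("+", 4))), "cover")
})

test_that("information gain agrees with exhaustive enumeration on small sets", {
  ent2 <- function(lab) {
    p <- table(lab) / length(lab)
    -sum(p * log2(p))
  }
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    labels <- sample(c("x", "y"), n, replace = TRUE)
    # every binary split encoded by a subset bitmask
    for (mask in 1:(2^n - 2)) {
      inA <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
      blocks <- list(labels[inA], labels[!inA])
      direct <- ent2(labels) -
        sum(vapply(blocks, function(b) length(b) / n * ent2(b), 0))
      expect_equal(information_gain(labels, blocks), direct, tolerance = 1e-12)
    }
  }
})

test_that("cross-validated boosting separates planted tissues", {
  sim <- fix_small()
  cv <- train_gbm_cv(sim$log2, sim$annotation, n_folds = 5, seed = 3,
                     nrounds = 20)
  mean_row <- cv$metrics[cv$metrics$fold == "Mean", ]
  expect_gte(mean_row$accuracy, 0.95)
  num <- as.matrix(cv$metrics[1:5, c("accuracy", "auc", "recall",
                                     "precision", "f1")])
  expect_true(all(num >= 0 & num <= 1))
  expect_true(all(cv$metrics$kappa >= -1 & cv$metrics$kappa <= 1))
  expect_s3_class(cv, "gbm_cv")
})

test_that("permuted labels drop accuracy to the chance level", {
  sim <- fix_small()
  set.seed(13)
  ann <- sim$annotation
  ann$tissue <- sample(ann$tissue)
  cv <- suppressWarnings(train_gbm_cv(sim$log2, ann, n_folds = 4, seed = 3,
                                      nrounds = 15))
  mean_acc <- cv$metrics[cv$metrics$fold == "Mean", "accuracy"]
  sd_acc <- cv$metrics[cv$metrics$fold == "SD", "accuracy"]
  majority <- max(table(ann$tissue)) / nrow(ann)
  expect_lt(mean_acc, majority + 3 * max(sd_acc, 0.05))
})

test_that("gain importances cover all features and crown a single informative one", {
  set.seed(14)
  n <- 60
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- ifelse(x[, 3] > 0, "a", "b")
  rownames(x) <- paste0("s", 1:n)
  ann <- data.frame(sample_id = rownames(x), tissue = y)
  cv <- suppressWarnings(train_gbm_cv(x, ann, n_folds = 3, seed = 1, nrounds = 10))
  imp <- gain_importance(cv, colnames(x))
  expect_length(imp, 10L)
  expect_true(all(imp >= 0))
  expect_identical(names(which.max(imp)), "g3")
})

test_that("the shadow-feature filter keeps planted genes and drops constants", {
  sim <- fix_small()
  m <- cbind(sim$log2, const = rep(1, nrow(sim$log2)))
  attr(m, "expr_scale") <- "log2"
  br <- boruta_filter(m, sim$annotation, n_reps = 8, seed = 5, nrounds = 30)
  expect_false("const" %in% br$geneset)
  expect_identical(provenance(br$geneset), "lgbm")
  rec <- set_recovery(br$geneset, sim$truth_set)
  expect_gte(rec[["recall"]], 0.9)   # planted markers survive the filter
  expect_lt(length(br$geneset), ncol(m) / 2)
  expect_equal(br$z_max, max(br$z_shadow))
  expect_setequal(as.character(br$geneset),
                  names(br$z_real)[br$z_real > br$z_max])
  expect_error(boruta_filter(m, sim$annotation, n_reps = 1), "n_reps")
})

test_that("the kept set is invariant to gene column order", {
  sim <- fix_small()
  b1 <- boruta_filter(sim$log2, sim$annotation, n_reps = 5, seed = 9,
                      nrounds = 20)
  set.seed(77)
  perm <- sample(ncol(sim$log2))
  m2 <- sim$log2[, perm]
  attr(m2, "expr_scale") <- "log2"
  b2 <- boruta_filter(m2, sim$annotation, n_reps = 5, seed = 9, nrounds = 20)
  expect_setequal(as.character(b1$geneset), as.character(b2$geneset))
})
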