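test_that("variance moderation pools toward the prior and keeps limits", {
  # identical variances: zero log-variance spread implies infinite prior df,
  # so every posterior equals the (bias-corrected) prior
  fit <- moderate_variances(rep(2, 10), d_g = 4)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s_tilde_sq, rep(fit$s0_sq, 10))
  expect_equal(fit$s0_sq, exp(log(2) - digamma(2) + log(2)), tolerance = 1e-10)

  # heterogeneous variances: posterior between observed and prior
  set.seed(1)
  s2 <- 1 / rgamma(200, 3, 3)
  fit <- moderate_variances(s2, d_g = 5)
  expect_true(fit$s0_sq > 0)
  expect_true(all(abs(fit$s_tilde_sq - fit$s0_sq) <= abs(s2 - fit$s0_sq) + 1e-12))
  expect_true(all(fit$s_tilde_sq >= pmin(s2, fit$s0_sq) - 1e-12))
  expect_true(all(fit$s_tilde_sq <= pmax(s2, fit$s0_sq) + 1e-12))

  # the pooling formula itself at imposed d0 = 4, s0^2 = 2
  expect_equal((4 * 2 + 4 * c(1, 4)) / (4 + 4), c(1.5, 3.0))
  expect_error(moderate_variances(c(0, 0, 1), d_g = 2), "positive variance")
})

test_that("moderated statistics reproduce the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 6; g <- 400
  sds <- sqrt(1 / rgamma(g, 2, 2))
  m <- t(vapply(1:(2 * n), function(i) rnorm(g, 5, sds), numeric(g)))
  rownames(m) <- paste0("s", 1:(2 * n)); colnames(m) <- paste0("g", 1:g)
  attr(m, "expr_scale") <- "log2"
  ann <- data.frame(sample_id = rownames(m), tissue = rep(c("A", "B"), each = n))
  tab <- fit_pairwise_de(m, ann, c("A", "B"))

  design <- cbind(A = rep(c(1, 0), each = n), B = rep(c(0, 1), each = n))
  fit <- limma::lmFit(t(m), design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(A - B, levels = design))
  fit <- limma::eBayes(fit)
  vf <- attr(tab, "variance_fit")
  expect_equal(vf$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(vf$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(tab$t, unname(fit$t[, 1]), tolerance = 1e-10)
  expect_equal(tab$P.Value, unname(fit$p.value[, 1]), tolerance = 1e-10)
  expect_equal(tab$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
})

test_that("pairwise DE is antisymmetric in the pair and flags planted genes", {
  sim <- fix_small()
  tab <- fit_pairwise_de(sim$log2, sim$annotation, c("leaf", "root"))
  rev_tab <- fit_pairwise_de(sim$log2, sim$annotation, c("root", "leaf"))
  expect_equal(tab$logFC, -rev_tab$logFC, tolerance = 1e-12)
  expect_equal(tab$adj.P.Val, rev_tab$adj.P.Val, tolerance = 1e-12)

  # planted leaf markers clear the DEG thresholds decisively (the exact
  # contrast varies with the tissue-level compositional shift of TPM)
  leaf_markers <- sim$truth$planted$leaf
  rows <- tab[match(leaf_markers, tab$gene_id), ]
  expect_true(all(rows$logFC > 4))
  expect_true(all(rows$adj.P.Val < 0.01))

  expect_error(fit_pairwise_de(sim$log2, sim$annotation, c("leaf", "absent")),
               ">= 2 samples")
})

test_that("a gene identical in both groups gets logFC 0 and direction none", {
  set.seed(5)
  m <- matrix(rnorm(40, 8, 1), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  m[, 1] <- rep(c(1, 2, 3, 4, 5), 2)   # same five values in group A and B
  attr(m, "expr_scale") <- "log2"
  ann <- data.frame(sample_id = rownames(m), tissue = rep(c("A", "B"), each = 5))
  tab <- fit_pairwise_de(m, ann, c("A", "B"))
  res <- filter_degs(tab)
  expect_equal(tab$logFC[1], 0)
  expect_equal(res$table$direction[1], "none")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.05, 6)), rep(0.05, 6))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DEG thresholds are strict and direction-aware", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    logFC = c(4.0, -5, 4.2, 6),
    AveExp = 1, t = 1, P.Value = 0.001,
    adj.P.Val = c(0.001, 0.009, 0.5, 0.0001),
    direction = "none", stringsAsFactors = FALSE)
  res <- filter_degs(tab, p_thresh = 0.01, lfc_thresh = 4)
  expect_false("a" %in% res$up)      # logFC exactly 4: excluded
  expect_true("b" %in% res$down)
  expect_false("c" %in% c(res$up, res$down))  # adj_p too large
  expect_true("d" %in% res$up)
  expect_length(intersect(res$up, res$down), 0L)

  empty <- filter_degs(tab[0, ])
  expect_length(empty$up, 0L)
  expect_length(empty$down, 0L)
})

test_that("pair sets merge as a deduplicated union (intersection optional)", {
  s1 <- geneset(c("a", "b")); s2 <- geneset(c("b", "c")); s0 <- geneset(character(0))
  expect_setequal(as.character(merge_pair_sets(list(s1, s2))), c("a", "b", "c"))
  expect_setequal(as.character(merge_pair_sets(list(s1, s2, s0))), c("a", "b", "c"))
  d1 <- geneset(c("a", "b")); d2 <- geneset(c("c", "d"))
  expect_length(merge_pair_sets(list(d1, d2)), 4L)
  expect_identical(provenance(merge_pair_sets(list(s1))), "limma")
  expect_setequal(as.character(
    merge_pair_sets(list(s1, s2), combine = "intersection")), "b")
})

test_that("pair enumeration yields all unordered pairs", {
  pairs <- tissue_pairs(c("Leaf", "Seed", "Root", "Seeding"))
  expect_length(pairs, 6L)
  expect_true(all(vapply(pairs, length, 0L) == 2L))
  expect_equal(anyDuplicated(vapply(pairs, function(p) paste(sort(p), collapse = "|"), "")), 0L)
})

test_that("the linear track recovers planted genes on the small fixture", {
  sim <- fix_small()
  res <- de_track(sim$log2, sim$annotation)
  rec <- set_recovery(res$geneset, sim$truth_set)
  expect_gte(rec[["precision"]], 0.9)
  expect_gte(rec[["recall"]], 0.9)
  expect_equal(nrow(res$counts), 3L)
})
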