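test_that("squarify returns the minimal enclosing square side", {
  expect_identical(squarify(21111), 146L)
  expect_identical(squarify(16), 4L)
  expect_identical(squarify(17), 5L)
  expect_identical(squarify(1), 1L)
  n <- 1:100000
  s <- vapply(n, squarify, 0L)
  expect_true(all(s^2 >= n))
  expect_true(all((s - 1)^2 < n))
})

test_that("expression images are row-major with zero padding and invert exactly", {
  set.seed(20)
  m <- matrix(rnorm(3 * 10, 5, 1), 3, 10,
              dimnames = list(paste0("s", 1:3), sprintf("g%02d", 1:10)))
  attr(m, "expr_scale") <- "log2"
  im <- reshape_samples(m)
  expect_equal(im$side, 4L)
  expect_equal(dim(im$images), c(3, 4, 4, 1))
  # gene 5 -> row 2, col 1 (row-major)
  expect_equal(im$map$row[5], 2L)
  expect_equal(im$map$col[5], 1L)
  expect_equal(im$images[2, 2, 1, 1], m[2, 5], ignore_attr = TRUE)
  # 6 trailing pixels are zero
  flat_idx <- cbind(im$map$row, im$map$col)
  for (s in 1:3) {
    img <- im$images[s, , , 1]
    expect_equal(img[flat_idx], unname(m[s, ]))
    img[flat_idx] <- NA
    expect_equal(sum(img == 0, na.rm = TRUE), 6L)
  }
  # permuting gene columns permutes pixels consistently with the map
  perm <- sample(10)
  m2 <- m[, perm]; attr(m2, "expr_scale") <- "log2"
  im2 <- reshape_samples(m2)
  expect_equal(im2$images[1, , , 1][cbind(im2$map$row, im2$map$col)],
               unname(m[1, perm]))
})

test_that("categorical cross-entropy follows the per-sample formula", {
  sc <- tissuespec:::.softmax_ce
  # logits giving probability ~1 on the true class
  r1 <- sc(matrix(c(50, 0, 0), 1, 3), matrix(c(1, 0, 0), 1, 3))
  expect_equal(r1$loss, 0, tolerance = 1e-10)
  # probability exactly 0.5 on the true class -> -ln 0.5
  r2 <- sc(matrix(c(1, 1, -1e6), 1, 3), matrix(c(1, 0, 0), 1, 3))
  expect_equal(r2$loss, 0.693147, tolerance = 1e-5)
  expect_equal(rowSums(r2$prob), 1, tolerance = 1e-12)
})

test_that("backpropagated gradients match numeric differentiation", {
  set.seed(21)
  side <- 6L; n <- 4L; k <- 3L
  cfg <- cnn_config(conv_filters = 2L, dense_width = 5L, batchnorm = TRUE,
                    epochs = 1L, seed = 1L)
  net <- tissuespec:::.build_cnn(side, k, cfg)
  x <- array(rnorm(n * side * side), c(n, side, side, 1))
  y <- tissuespec:::.onehot(c(0L, 1L, 2L, 0L), k)
  loss_of <- function(net) {
    fw <- tissuespec:::.net_forward(net, x, training = TRUE)
    tissuespec:::.softmax_ce(fw$logits, y)$loss
  }
  fw <- tissuespec:::.net_forward(net, x, training = TRUE)
  sc <- tissuespec:::.softmax_ce(fw$logits, y)
  bw <- tissuespec:::.net_backward(net, sc$dlogits, fw$caches)
  eps <- 1e-5
  for (li in seq_along(net$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      theta <- net$layers[[li]][[nm]]
      for (idx in sample(seq_along(theta), min(4, length(theta)))) {
        npl <- net; npl$layers[[li]][[nm]][idx] <- theta[idx] + eps
        nmi <- net; nmi$layers[[li]][[nm]][idx] <- theta[idx] - eps
        num <- (loss_of(npl) - loss_of(nmi)) / (2 * eps)
        expect_equal(g[[nm]][idx], num, tolerance = 1e-4)
      }
    }
  }
  # input gradient too
  fx <- function(xx) {
    fw <- tissuespec:::.net_forward(net, xx, training = TRUE)
    tissuespec:::.softmax_ce(fw$logits, y)$loss
  }
  for (idx in sample(seq_along(x), 4)) {
    xp <- x; xp[idx] <- x[idx] + eps
    xm <- x; xm[idx] <- x[idx] - eps
    expect_equal(bw$dx[idx], (fx(xp) - fx(xm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("the CNN learns the planted fixture and records history", {
  sim <- fix_small()
  im <- reshape_samples(sim$log2)
  cfg <- cnn_config(conv_filters = 8L, dense_width = 32L, epochs = 15L,
                    batch_size = 8L, seed = 2L)
  model <- train_cnn(im, sim$annotation, cfg)
  h <- model$history
  expect_equal(nrow(h), 15L)
  expect_true(all(h$train_loss >= 0))
  expect_gte(tail(h$val_accuracy, 1), 0.9)
  prob <- predict(model, im)
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-8)
  expect_identical(colnames(prob), sort(unique(sim$annotation$tissue)))
})

test_that("gradient-x-input attribution is exact for a linear model", {
  set.seed(22)
  m <- matrix(rnorm(20 * 9, 3, 1), 20, 9,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:9)))
  attr(m, "expr_scale") <- "log2"
  ann <- data.frame(sample_id = rownames(m),
                    tissue = rep(c("a", "b"), each = 10))
  im <- reshape_samples(m)
  cfg <- cnn_config(conv_filters = integer(0), dense_width = NULL,
                    batchnorm = FALSE, epochs = 3L, batch_size = 5L, seed = 3L)
  model <- train_cnn(im, ann, cfg)
  att <- attribute(model, im, ann, method = "gradxinput")
  W <- model$net$layers[[2]]$W  # flatten, dense
  # image pixel (r, c) flattens (column-major over r, c) to index r+(c-1)*side
  flat <- model$map$row + (model$map$col - 1L) * model$side
  for (id in rownames(att)) {
    cls <- match(ann$tissue[ann$sample_id == id], model$levels)
    expect_equal(att[id, ], W[flat, cls] * m[id, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("attribution keeps only correctly predicted samples", {
  sim <- fix_small()
  im <- reshape_samples(sim$log2)
  cfg <- cnn_config(conv_filters = 8L, dense_width = 32L, epochs = 12L,
                    batch_size = 8L, seed = 2L)
  model <- train_cnn(im, sim$annotation, cfg)
  att <- attribute(model, im, sim$annotation, n_draws = 8, seed = 1)
  prob <- predict(model, im)
  pred <- model$levels[max.col(prob)]
  correct_ids <- rownames(prob)[pred == sim$annotation$tissue[
    match(rownames(prob), sim$annotation$sample_id)]]
  expect_setequal(rownames(att), correct_ids)
  expect_equal(ncol(att), ncol(sim$log2))

  # planted genes dominate attribution mass vs random sets of equal size
  truth <- sim$truth_set
  mass <- colSums(abs(att))
  planted_mass <- sum(mass[truth])
  set.seed(30)
  draws <- replicate(100, sum(mass[sample(colnames(att), length(truth))]))
  expect_gte(mean(planted_mass > draws), 0.95)
})

test_that("median aggregation ranks per tissue with deterministic ties", {
  vals <- matrix(0, 4, 6, dimnames = list(paste0("s", 1:4), paste0("g", 1:6)))
  vals[1:2, "g3"] <- 5; vals[3:4, "g5"] <- 2
  att <- structure(vals, tissue = c("x", "x", "y", "y"),
                   class = c("attribution_matrix", "matrix"))
  lists <- aggregate_attributions(att, top_frac = 0.34)  # floor(2.04) = 2
  expect_equal(lists$x[1], "g3")
  expect_equal(lists$y[1], "g5")
  expect_length(lists$x, 2L)

  zero <- structure(matrix(0, 2, 5,
                           dimnames = list(c("a", "b"), paste0("g", 5:1))),
                    tissue = c("x", "x"),
                    class = c("attribution_matrix", "matrix"))
  expect_equal(aggregate_attributions(zero, top_frac = 1)$x,
               paste0("g", 1:5))  # ID-ordered tie break

  one <- structure(matrix(c(3, 1, 2), 1, 3,
                          dimnames = list("a", c("g1", "g2", "g3"))),
                   tissue = "x", class = c("attribution_matrix", "matrix"))
  expect_equal(aggregate_attributions(one, top_frac = 1)$x,
               c("g1", "g3", "g2"))

  # paper-scale arithmetic: 1% of 21,111 genes -> 211 per tissue
  expect_equal(max(1L, floor(0.01 * 21111)), 211)
})

test_that("tissue lists combine by truncation then union or intersection", {
  lists <- list(a = paste0("g", 1:10), b = paste0("g", 11:20))
  expect_length(combine_tissue_lists(lists, keep_frac = 0.5), 10L)
  expect_setequal(as.character(combine_tissue_lists(lists, keep_frac = 1)),
                  paste0("g", 1:20))
  same <- list(a = paste0("g", 1:10), b = paste0("g", 1:10))
  expect_setequal(as.character(combine_tissue_lists(same, keep_frac = 0.5)),
                  paste0("g", 1:5))
  expect_setequal(as.character(
    combine_tissue_lists(list(a = c("g1", "g2"), b = c("g2", "g1")),
                         keep_frac = 1, combine = "intersection")),
    c("g1", "g2"))
  expect_identical(provenance(combine_tissue_lists(lists)), "cnn")
})
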