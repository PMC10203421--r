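## Neural track: expression-to-image reshaping, a compact CNN classifier
## (3x3 conv + ReLU + BatchNorm blocks, 2x2 max pooling, dense softmax
## head, RMSprop on categorical cross-entropy), gradient-based per-gene
## attribution and aggregation into the CNN tissue-specific gene set.

#' Side length of the square image holding n genes
#'
#' Smallest integer `s` with `s^2 >= n_genes`; the remaining
#' `s^2 - n_genes` pixels are zero padding.
#'
#' @param n_genes number of genes (>= 1).
#' @return integer side length.
#' @examples
#' squarify(21111)  # 146
#' @export
squarify <- function(n_genes) {
  .check_scalar_count(n_genes, "n_genes")
  s <- floor(sqrt(n_genes))
  if (s * s < n_genes) s <- s + 1L
  as.integer(s)
}

#' Reshape expression vectors into square single-channel images
#'
#' Genes are laid out row-major in matrix column order; trailing pixels
#' are zero. The returned map inverts the layout exactly, so pixel
#' attributions can be assigned back to genes and padding discarded.
#'
#' @param log_matrix log2-scale samples-by-genes matrix.
#' @return list of class `"expr_images"`: `images` (array
#'   `n_samples x side x side x 1`, sample IDs on the first dimension),
#'   `side`, `gene_ids`, and `map` (data.frame `gene_id`, `row`, `col`).
#' @export
reshape_samples <- function(log_matrix) {
  .check_matrix(log_matrix)
  if (expr_scale(log_matrix) != "log2")
    .stopf("reshape_samples() expects a log2-scale matrix")
  n <- nrow(log_matrix); g <- ncol(log_matrix)
  s <- squarify(g)
  images <- array(0, c(n, s, s, 1))
  idx <- seq_len(g) - 1L
  rows <- idx %/% s + 1L
  cols <- idx %% s + 1L
  for (j in seq_len(g)) images[, rows[j], cols[j], 1] <- log_matrix[, j]
  dimnames(images) <- list(rownames(log_matrix), NULL, NULL, NULL)
  structure(list(images = images, side = s, gene_ids = colnames(log_matrix),
                 map = data.frame(gene_id = colnames(log_matrix),
                                  row = rows, col = cols,
                                  stringsAsFactors = FALSE)),
            class = "expr_images")
}

#' CNN configuration
#'
#' The default is a desk-scale profile (two conv blocks, 20 epochs,
#' learning rate 1e-3) suitable for few-thousand-gene matrices on one
#' CPU. `cnn_config_full()` returns the larger training profile
#' (three 32/64/128-filter blocks, batch 64, 50 epochs, RMSprop learning
#' rate 1e-4, rho 0.9, decay 0.01) appropriate for ~20,000-gene matrices.
#' Kernels are fixed at 3x3.
#'
#' @param conv_filters integer vector: filters per ConvBlock
#'   (conv 3x3 + ReLU + BatchNorm), each followed by 2x2 max pooling.
#'   May be empty for a dense-only network.
#' @param dense_width width of the hidden dense layer (`NULL` to omit).
#' @param batchnorm include BatchNorm in each block.
#' @param learning_rate,rho,decay RMSprop settings; the effective rate at
#'   update `t` is `learning_rate / (1 + decay * t)`.
#' @param batch_size,epochs minibatch size and training epochs.
#' @param split_fraction training fraction of the stratified train/validation
#'   split (default 0.8, i.e. 8:2).
#' @param seed integer RNG seed (initialization, split, batch order).
#' @return list of class `"cnn_config"`.
#' @export
cnn_config <- function(conv_filters = c(8L, 16L), dense_width = 64L,
                       batchnorm = TRUE, learning_rate = 1e-3, rho = 0.9,
                       decay = 0.01, batch_size = 16L, epochs = 20L,
                       split_fraction = 0.8, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    .stopf("'split_fraction' must lie in (0, 1)")
  if (epochs < 1) .stopf("'epochs' must be >= 1")
  structure(list(conv_filters = as.integer(conv_filters),
                 dense_width = if (is.null(dense_width)) NULL else as.integer(dense_width),
                 batchnorm = isTRUE(batchnorm),
                 learning_rate = learning_rate, rho = rho, decay = decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @export
cnn_config_full <- function() {
  cnn_config(conv_filters = c(32L, 64L, 128L), dense_width = 128L,
             learning_rate = 1e-4, decay = 0.01, batch_size = 64L,
             epochs = 50L)
}

## Assemble the layer list for a given image side and class count.
.build_cnn <- function(side, n_classes, config) {
  layers <- list()
  c_in <- 1L; h <- side
  for (f in config$conv_filters) {
    layers <- c(layers, list(.layer_conv(c_in, f)))
    if (config$batchnorm) layers <- c(layers, list(.layer_bn(f)))
    layers <- c(layers, list(list(type = "relu")), list(list(type = "pool")))
    c_in <- f
    h <- h %/% 2L
    if (h < 1) .stopf("image side %d too small for %d pooling stages",
                      side, length(config$conv_filters))
  }
  layers <- c(layers, list(list(type = "flatten")))
  d <- h * h * c_in
  if (length(config$conv_filters) == 0L) d <- side * side
  if (!is.null(config$dense_width)) {
    layers <- c(layers, list(.layer_dense(d, config$dense_width)),
                list(list(type = "relu")))
    d <- config$dense_width
  }
  layers <- c(layers, list(.layer_dense(d, n_classes)))
  list(layers = layers)
}

.onehot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Train the CNN tissue classifier
#'
#' Stratified train/validation split, minibatch RMSprop on the
#' categorical cross-entropy `-sum_i y_i log(p_i)` (natural log), with
#' per-epoch loss and accuracy recorded for both subsets.
#'
#' @param x an `"expr_images"` object from [reshape_samples()].
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param config a [cnn_config()].
#' @return list of class `"cnn_model"`: `net` (layer list), `levels`
#'   (class labels), `history` (data.frame epoch / train_loss /
#'   train_accuracy / val_loss / val_accuracy), `side`, `gene_ids`,
#'   `map`, `config`, `train_ids`, `val_ids`.
#' @export
train_cnn <- function(x, annotation, config = cnn_config()) {
  if (!inherits(x, "expr_images")) .stopf("'x' must come from reshape_samples()")
  .check_annotation(annotation)
  ids <- dimnames(x$images)[[1]]
  tissue <- annotation$tissue[match(ids, annotation$sample_id)]
  if (anyNA(tissue)) .stopf("annotation does not cover all image samples")
  enc <- .encode_labels(tissue)
  k <- length(enc$levels)
  if (k < 2) .stopf("need >= 2 classes")
  if (min(table(enc$y)) < 2) .stopf("every class needs >= 2 samples")
  set.seed(config$seed)
  net <- .build_cnn(x$side, k, config)
  tr <- .stratified_split(enc$y, config$split_fraction)
  xtr <- x$images[tr, , , , drop = FALSE]
  xva <- x$images[!tr, , , , drop = FALSE]
  ytr <- enc$y[tr]; yva <- enc$y[!tr]
  opt <- list(lr = config$learning_rate, rho = config$rho,
              decay = config$decay, cache = list(), t = 0)
  n_tr <- sum(tr)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     train_accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  eval_set <- function(xs, ys) {
    fw <- .net_forward(net, xs, training = FALSE)
    sc <- .softmax_ce(fw$logits, .onehot(ys, k))
    c(loss = sc$loss, acc = mean(max.col(sc$prob) - 1L == ys))
  }
  for (ep in seq_len(config$epochs)) {
    ord <- sample(n_tr)
    batch_losses <- c(); batch_accs <- c()
    for (start in seq(1, n_tr, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      xb <- xtr[bi, , , , drop = FALSE]
      yb <- ytr[bi]
      fw <- .net_forward(net, xb, training = TRUE)
      sc <- .softmax_ce(fw$logits, .onehot(yb, k))
      if (!is.finite(sc$loss))
        .stopf("training diverged (non-finite loss) at epoch %d", ep)
      bw <- .net_backward(net, sc$dlogits, fw$caches)
      net <- .apply_bn_states(net, fw$states)
      st <- .rmsprop_step(net, bw$grads, opt)
      net <- st$model; opt <- st$opt
      batch_losses <- c(batch_losses, sc$loss)
      batch_accs <- c(batch_accs, mean(max.col(sc$prob) - 1L == yb))
    }
    va <- eval_set(xva, yva)
    hist[ep, -1] <- c(mean(batch_losses), mean(batch_accs), va["loss"], va["acc"])
  }
  structure(list(net = net, levels = enc$levels, history = hist,
                 side = x$side, gene_ids = x$gene_ids, map = x$map,
                 config = config, train_ids = ids[tr], val_ids = ids[!tr]),
            class = "cnn_model")
}

#' Class probabilities from a trained CNN
#'
#' @param object a `"cnn_model"`.
#' @param x an `"expr_images"` object (same gene layout as training).
#' @param ... unused.
#' @return samples-by-classes probability matrix (rows sum to 1).
#' @export
predict.cnn_model <- function(object, x, ...) {
  if (!inherits(x, "expr_images")) .stopf("'x' must come from reshape_samples()")
  fw <- .net_forward(object$net, x$images, training = FALSE)
  p <- .softmax(fw$logits)
  dimnames(p) <- list(dimnames(x$images)[[1]], object$levels)
  p
}

## Gradient of the class-c logit w.r.t. the input pixels, eval mode.
## xb: (N, s, s, 1); cls: 0-based class shared by the batch.
.input_gradient <- function(model, xb, cls) {
  fw <- .net_forward(model$net, xb, training = FALSE)
  k <- length(model$levels)
  seed <- matrix(0, dim(xb)[1], k)
  seed[, cls + 1L] <- 1
  .net_backward(model$net, seed, fw$caches)$dx
}

#' Per-gene attribution of CNN predictions
#'
#' For every *correctly predicted* sample, attributes the true-class
#' logit to input pixels and maps pixels back to genes (padding
#' discarded). The default method is expected gradients: attribution =
#' `E_{b, a~U(0,1)}[(x - b) * grad f_c(b + a (x - b))]` over a background
#' of reference images; `"gradxinput"` is the plain `x * grad f_c(x)`
#' fallback (exact for a linear model).
#'
#' @param model a `"cnn_model"`.
#' @param x an `"expr_images"` object to explain.
#' @param annotation data.frame with `sample_id`, `tissue` (true labels).
#' @param method `"expected_gradients"` (default) or `"gradxinput"`.
#' @param background `"expr_images"` used as the reference distribution
#'   (default: `x` itself; typically the training images).
#' @param n_draws background/interpolation draws per sample.
#' @param seed integer RNG seed for the draws.
#' @return matrix of class `"attribution_matrix"`; rows = correctly
#'   predicted samples (IDs as rownames), columns = genes, with a
#'   `tissue` attribute giving each row's true label.
#' @export
attribute <- function(model, x, annotation,
                      method = c("expected_gradients", "gradxinput"),
                      background = NULL, n_draws = 16L, seed = 1L) {
  if (!inherits(model, "cnn_model")) .stopf("'model' must come from train_cnn()")
  if (!inherits(x, "expr_images")) .stopf("'x' must come from reshape_samples()")
  method <- match.arg(method)
  .check_annotation(annotation)
  ids <- dimnames(x$images)[[1]]
  tissue <- annotation$tissue[match(ids, annotation$sample_id)]
  if (anyNA(tissue)) .stopf("annotation does not cover all image samples")
  prob <- predict(model, x)
  pred <- model$levels[max.col(prob)]
  correct <- which(pred == tissue & tissue %in% model$levels)
  if (!length(correct)) .stopf("no correctly predicted samples to attribute")
  set.seed(seed)
  if (is.null(background)) background <- x
  bg <- background$images
  n_bg <- dim(bg)[1]
  s <- model$side
  g <- length(model$gene_ids)
  pix <- cbind(model$map$row, model$map$col)
  out <- matrix(0, length(correct), g,
                dimnames = list(ids[correct], model$gene_ids))
  for (r in seq_along(correct)) {
    i <- correct[r]
    cls <- match(tissue[i], model$levels) - 1L
    xi <- x$images[i, , , 1]
    if (method == "gradxinput") {
      grad <- .input_gradient(model, x$images[i, , , , drop = FALSE], cls)
      attrib <- grad[1, , , 1] * xi
    } else {
      bidx <- sample.int(n_bg, n_draws, replace = TRUE)
      alpha <- runif(n_draws)
      zb <- array(0, c(n_draws, s, s, 1))
      diffs <- array(0, c(n_draws, s, s, 1))
      for (d in seq_len(n_draws)) {
        bd <- bg[bidx[d], , , 1]
        diffs[d, , , 1] <- xi - bd
        zb[d, , , 1] <- bd + alpha[d] * (xi - bd)
      }
      grad <- .input_gradient(model, zb, cls)
      attrib <- apply(diffs * grad, c(2, 3), mean)
    }
    out[r, ] <- attrib[pix]
  }
  structure(out, tissue = tissue[correct], class = c("attribution_matrix", "matrix"))
}

#' Rank genes per tissue by median attribution
#'
#' Computes, within each tissue, the median attribution per gene across
#' that tissue's correctly predicted samples, sorts descending and keeps
#' the top `floor(top_frac * n_genes)` genes (at least 1). Ties are
#' broken by gene ID order. Tissues with no rows are omitted with a
#' warning.
#'
#' @param attr an `"attribution_matrix"` from [attribute()].
#' @param top_frac fraction of genes to keep per tissue (default 0.01).
#' @return named list: tissue -> ranked character vector of gene IDs.
#' @export
aggregate_attributions <- function(attr, top_frac = 0.01) {
  if (top_frac <= 0 || top_frac > 1) .stopf("'top_frac' must lie in (0, 1]")
  tissue <- attr(attr, "tissue")
  g <- ncol(attr)
  n_keep <- max(1L, floor(top_frac * g))
  out <- list()
  for (t in unique(tissue)) {
    rows <- attr[tissue == t, , drop = FALSE]
    med <- apply(rows, 2, median)
    ord <- order(-med, colnames(attr))
    out[[t]] <- colnames(attr)[ord][seq_len(n_keep)]
  }
  out
}

#' Combine per-tissue ranked lists into the CNN gene set
#'
#' Keeps the top `ceil(keep_frac * length)` genes of each tissue's ranked
#' list, then combines across tissues. The default combination is the
#' deduplicated union; `"intersection"` requires a gene to survive the
#' truncation in every tissue.
#'
#' @param lists named list of ranked gene ID vectors (from
#'   [aggregate_attributions()]).
#' @param keep_frac fraction of each list to keep (default 0.5).
#' @param combine `"union"` (default) or `"intersection"`.
#' @return a [geneset()] with provenance `"cnn"`.
#' @export
combine_tissue_lists <- function(lists, keep_frac = 0.5,
                                 combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!length(lists)) .stopf("'lists' must contain at least one ranked list")
  if (keep_frac <= 0 || keep_frac > 1) .stopf("'keep_frac' must lie in (0, 1]")
  trimmed <- lapply(lists, function(l) l[seq_len(ceiling(keep_frac * length(l)))])
  ids <- if (combine == "union") unique(unlist(trimmed, use.names = FALSE))
         else Reduce(intersect, trimmed)
  geneset(ids, "cnn")
}

#' Run the full neural track
#'
#' Reshapes the matrix, trains the CNN, attributes correct predictions
#' and aggregates per-tissue rankings into one gene set.
#'
#' @param log_matrix log2-scale samples-by-genes matrix.
#' @param annotation data.frame with `sample_id`, `tissue`.
#' @param config a [cnn_config()].
#' @param top_frac per-tissue fraction kept by [aggregate_attributions()].
#' @param keep_frac combination fraction for [combine_tissue_lists()].
#' @param method attribution method, see [attribute()].
#' @return list with `geneset` (provenance `"cnn"`), `model`,
#'   `attributions`, `tissue_lists`.
#' @export
cnn_track <- function(log_matrix, annotation, config = cnn_config(),
                      top_frac = 0.01, keep_frac = 0.5,
                      method = "expected_gradients") {
  imgs <- reshape_samples(log_matrix)
  model <- train_cnn(imgs, annotation, config)
  attr_mat <- attribute(model, imgs, annotation, method = method,
                        seed = config$seed)
  lists <- aggregate_attributions(attr_mat, top_frac = top_frac)
  list(geneset = combine_tissue_lists(lists, keep_frac = keep_frac),
       model = model, attributions = attr_mat, tissue_lists = lists)
}
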