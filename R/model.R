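# Classifier construction with exact parameter accounting, the multi-label
# one-versus-all max-entropy loss, and desk-scale training. Since parameter
# accounting does not require pretrained weights, the backbone is represented
# structurally (layer table); the runnable part of the model is a fixed,
# seeded image featurizer followed by a random projection to the backbone's
# penultimate width d and the trainable 8-way dense head -- enough to train
# and evaluate the full pipeline end-to-end on a CPU.

#' Model specification
#'
#' @param arch_name one of [supported_archs()].
#' @param n_classes width of the classification head (default 8).
#' @param head_seed seed initialising the head weights; using the same seed
#'   across architectures gives every model an identically-initialised final
#'   layer.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(arch_name, n_classes = 8L, head_seed = 42L) {
  if (!arch_name %in% supported_archs())
    stop("unknown architecture '", arch_name, "'; see supported_archs()")
  structure(list(arch_name = arch_name, n_classes = as.integer(n_classes),
                 head_seed = as.integer(head_seed)), class = "model_spec")
}

#' Build a classifier with an n-way classification head
#'
#' Assembles the named backbone's parameter-accounting table and replaces
#' the final classification layer with a freshly initialised dense layer of
#' `n_classes` outputs (`d * n_classes + n_classes` parameters, `d` the
#' penultimate width). The returned handle predicts through a deterministic
#' image featurizer, a seeded random projection to width `d`, and the head.
#'
#' @param spec a [model_spec()].
#' @return object of class `fundus_classifier` with elements `arch_name`,
#'   `layers` (data frame: module, params), `d`, `head` (list `W` d x C,
#'   `b` length C) and `n_classes`.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  bb <- arch_backbone(spec$arch_name)
  layers <- rbind(bb$layers,
                  p_fc("head.fc", bb$d, spec$n_classes))
  head <- with_seed(spec$head_seed, list(
    W = matrix(stats::rnorm(bb$d * spec$n_classes, sd = 0.01),
               bb$d, spec$n_classes),
    b = numeric(spec$n_classes)))
  # fixed featurizer projection; seeded from the head seed so two builds of
  # the same spec are identical end to end
  proj <- with_seed(spec$head_seed + 1L, matrix(
    stats::rnorm(bb$d * n_base_features(), sd = 1 / sqrt(n_base_features())),
    bb$d, n_base_features()))
  structure(list(arch_name = spec$arch_name, layers = layers, d = bb$d,
                 head = head, proj = proj, n_classes = spec$n_classes,
                 feat_center = NULL, feat_scale = NULL),
            class = "fundus_classifier")
}

#' @export
print.fundus_classifier <- function(x, ...) {
  cat(sprintf("%s classifier: %d-way head on d=%d, %s trainable parameters\n",
              x$arch_name, x$n_classes, x$d,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the model's layer table (backbone plus head). For every supported
#' architecture the total satisfies the head-swap identity
#' `count(C) = count(1000) - (d*1000 + 1000) + (d*C + C)`.
#'
#' @param model a `fundus_classifier` (or a `model_spec`, which is built
#'   first).
#' @return integer total of trainable parameters.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_spec")) model <- build_classifier(model)
  stopifnot(inherits(model, "fundus_classifier"))
  sum(model$layers$params)
}

## ---- loss ----------------------------------------------------------------

#' Multi-label one-versus-all max-entropy loss
#'
#' For raw scores `yhat` and binary targets `y` of shape (N, C), each record
#' contributes
#' `-(1/C) * sum_i [ y_i * log(sigmoid(yhat_i)) + (1-y_i) * log(1 - sigmoid(yhat_i)) ]`
#' and the batch loss is the mean over records. Computed with the log1p
#' softplus form, numerically stable for |yhat| up to hundreds. At
#' `yhat = 0` the loss equals `log(2)` for any binary target.
#'
#' @param yhat numeric matrix (N x C) of raw (pre-sigmoid) scores.
#' @param y binary matrix of the same shape.
#' @return scalar loss (>= 0).
#' @export
multilabel_loss <- function(yhat, y) {
  yhat <- as.matrix(yhat); y <- as.matrix(y)
  if (!all(dim(yhat) == dim(y))) stop("shape mismatch between yhat and y")
  if (!all(y %in% c(0, 1))) stop("targets y must be binary")
  C <- ncol(y)
  # log(sigmoid(z)) = -softplus(-z); log(1-sigmoid(z)) = -softplus(z)
  softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  per_elem <- y * softplus(-yhat) + (1 - y) * softplus(yhat)
  mean(rowSums(per_elem) / C)
}

## ---- featurizer ----------------------------------------------------------

n_base_features <- function() 64L

# deterministic hand-crafted image descriptor: coarse 4x4 green-channel
# grid, per-channel moments, intensity quantiles and bright/dark fractions
# inside the disc area. Length must equal n_base_features().
fundus_features <- function(image) {
  if (is_gray(image)) image <- array(rep(image, 3), c(dim(image), 3))
  g <- image[, , 2]
  grid <- as.vector(block_mean(g, 4, 4))                        # 16
  gridr <- as.vector(block_mean(image[, , 1], 3, 3))            # 9
  gridb <- as.vector(block_mean(image[, , 3], 3, 3))            # 9
  fg <- g > 20
  gin <- if (any(fg)) g[fg] else 0
  mom <- c(mean(image[, , 1]), mean(g), mean(image[, , 3]),
           stats::sd(image[, , 1]), stats::sd(g), stats::sd(image[, , 3]))  # 6
  qs <- stats::quantile(gin, c(.05, .25, .5, .75, .95), names = FALSE)      # 5
  fr <- c(mean(gin > 200), mean(gin > 160), mean(gin < 60), mean(gin < 30),
          mean(fg))                                                          # 5
  dg <- abs(diff(g)); dgc <- abs(t(diff(t(g))))
  tex <- c(mean(dg), stats::sd(dg), mean(dgc), stats::sd(dgc))               # 4
  ctr <- center_stats(g)                                                     # 10
  out <- c(grid, gridr, gridb, mom, qs, fr, tex, ctr)
  stopifnot(length(out) == n_base_features())
  out
}

block_mean <- function(m, by, bx) {
  h <- nrow(m); w <- ncol(m)
  rb <- floor(seq(0, h, length.out = by + 1))
  cb <- floor(seq(0, w, length.out = bx + 1))
  out <- matrix(0, by, bx)
  for (i in seq_len(by)) for (j in seq_len(bx))
    out[i, j] <- mean(m[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]])
  out
}

center_stats <- function(g) {
  h <- nrow(g); w <- ncol(g)
  d <- sqrt((row(g) - (h + 1) / 2)^2 + (col(g) - (w + 1) / 2)^2) /
    (min(h, w) / 2)
  rings <- list(d <= 0.33, d > 0.33 & d <= 0.66, d > 0.66 & d <= 1)
  rs <- unlist(lapply(rings, function(r) {
    v <- g[r]
    c(mean(v), stats::sd(v), mean(v > 180))
  }))
  c(rs, mean(g[d > 1]))
}

embed_features <- function(model, feats) {
  f <- if (is.null(model$feat_center)) feats
       else sweep(sweep(feats, 2, model$feat_center), 2, model$feat_scale, "/")
  tanh(f %*% t(model$proj))
}

feature_matrix <- function(images) {
  t(vapply(images, fundus_features, numeric(n_base_features())))
}

#' Predict multi-label scores
#'
#' @param object a `fundus_classifier` (fresh or fitted).
#' @param newdata a single image (matrix or RGB array) or a list of images.
#' @param ... unused.
#' @return numeric matrix (records x n_classes) of sigmoid scores in
#'   \[0, 1\], columns named N,D,G,C,A,H,M,O when `n_classes == 8`.
#' @export
predict.fundus_classifier <- function(object, newdata, ...) {
  feats <- if (is.list(newdata)) feature_matrix(newdata)
           else feature_matrix(list(newdata))
  E <- embed_features(object, feats)
  z <- E %*% object$head$W + matrix(object$head$b, nrow(E), object$n_classes,
                                    byrow = TRUE)
  s <- 1 / (1 + exp(-z))
  if (object$n_classes == 8L) colnames(s) <- lv_classes
  s
}

## ---- fitting -------------------------------------------------------------

#' Fit the classification head on a labelled image set
#'
#' Desk-scale training: base features are extracted once, standardised,
#' projected to the backbone's penultimate width, and the dense head is
#' trained by full-batch gradient descent on the multi-label max-entropy
#' loss. Deterministic given `seed` (used for the head's re-initialisation
#' when `reinit = TRUE`; feature extraction and descent are deterministic).
#'
#' @param model a `fundus_classifier` from [build_classifier()].
#' @param images non-empty list of images.
#' @param labels binary label matrix, `length(images)` x `n_classes`.
#' @param epochs number of training epochs (loss is reported once per
#'   epoch).
#' @param lr learning rate (0 freezes the head; the loss trace is then
#'   constant).
#' @param steps_per_epoch gradient steps per epoch.
#' @param seed integer seed.
#' @param reinit re-initialise the head from `seed` before training.
#' @return object of class `fundus_fit`: the trained model plus
#'   `loss_trace` (per-epoch mean loss, evaluated at the end of each epoch).
#' @export
fit_classifier <- function(model, images, labels, epochs = 2, lr = 0.5,
                           steps_per_epoch = 25, seed = 1L, reinit = FALSE) {
  stopifnot(inherits(model, "fundus_classifier"), is.list(images))
  feats <- feature_matrix(images)
  y <- as.matrix(labels)
  if (nrow(feats) == 0L) stop("empty dataset")
  if (nrow(y) != nrow(feats) || ncol(y) != model$n_classes)
    stop("labels must be n x n_classes")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")

  model$feat_center <- colMeans(feats)
  model$feat_scale <- pmax(apply(feats, 2, stats::sd), 1e-8)
  E <- embed_features(model, feats)
  n <- nrow(E); C <- model$n_classes
  W <- model$head$W; b <- model$head$b
  if (reinit) {
    ini <- with_seed(seed, list(
      W = matrix(stats::rnorm(model$d * C, sd = 0.01), model$d, C),
      b = numeric(C)))
    W <- ini$W; b <- ini$b
  }
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (lr > 0) for (s in seq_len(steps_per_epoch)) {
      z <- E %*% W + matrix(b, n, C, byrow = TRUE)
      p <- 1 / (1 + exp(-z))
      gz <- (p - y) / (n * C)
      W <- W - lr * (t(E) %*% gz)
      b <- b - lr * colSums(gz)
    }
    z <- E %*% W + matrix(b, n, C, byrow = TRUE)
    trace[ep] <- multilabel_loss(z, y)
  }
  model$head$W <- W; model$head$b <- b
  structure(c(unclass(model), list(loss_trace = trace, n_train = n,
                                   epochs = epochs, lr = lr)),
            class = c("fundus_fit", "fundus_classifier"))
}

#' @export
print.fundus_fit <- function(x, ...) {
  cat(sprintf("fitted %s head: %d images, %d epochs, final loss %.4f\n",
              x$arch_name, x$n_train, x$epochs, tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
plot.fundus_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "mean loss", ...)
  invisible(x)
}

#' @importFrom utils tail
NULL
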