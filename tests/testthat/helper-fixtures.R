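# Shared fixtures and independent oracles for the test suite. All synthetic
# inputs are generated in code; the Hough params used on generated images set
# nonzero_threshold to 19, the generator's truncated background-noise
# ceiling (background < 20 by construction).

hp_synth <- hough_params(nonzero_threshold = 19)

# plain disc image built directly (independent of the generator) -- RGB
# array with constant disc colour on black
plain_disc <- function(H, W, center, radius, color = c(180, 120, 60)) {
  img <- array(0, c(H, W, 3))
  d <- sqrt((row(img[, , 1]) - 1 - center[1])^2 +
            (col(img[, , 1]) - 1 - center[2])^2)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[d <= radius] <- color[ch]
    img[, , ch] <- pl
  }
  img
}

# ground-truth disc bounding box intersected with the frame (0-based
# half-open), matching the crop-box convention
gt_disc_box <- function(truth, H, W) {
  ctr <- truth$disc_circle$center; R <- truth$disc_circle$radius
  c(row_lo = max(0, floor(ctr[1] - R)), row_hi = min(H, ceiling(ctr[1] + R) + 1),
    col_lo = max(0, floor(ctr[2] - R)), col_hi = min(W, ceiling(ctr[2] + R) + 1))
}

box_iou <- function(b, gt) {
  ri <- max(0, min(b$row_hi, gt["row_hi"]) - max(b$row_lo, gt["row_lo"]))
  ci <- max(0, min(b$col_hi, gt["col_hi"]) - max(b$col_lo, gt["col_lo"]))
  inter <- ri * ci
  a1 <- (b$row_hi - b$row_lo) * (b$col_hi - b$col_lo)
  a2 <- (gt["row_hi"] - gt["row_lo"]) * (gt["col_hi"] - gt["col_lo"])
  unname(inter / (a1 + a2 - inter))
}

# brute-force connected-component labelling by stack-based flood fill;
# deliberately independent of label_components()
flood_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in nb) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] != 0 && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# algebraic (Kasa) circle fit through boundary points; used to check that
# the rendered disc's boundary recovers the specified circle
fit_circle <- function(rows, cols) {
  A <- cbind(2 * rows, 2 * cols, 1)
  b <- rows^2 + cols^2
  sol <- qr.solve(A, b)
  c(row = sol[1], col = sol[2],
    radius = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

disc_boundary_points <- function(img, thr = 19) {
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  fg <- gray > thr
  h <- nrow(fg); w <- ncol(fg)
  interior <- fg[c(1, 1:(h - 1)), ] & fg[c(2:h, h), ] &
              fg[, c(1, 1:(w - 1))] & fg[, c(2:w, w)]
  idx <- which(fg & !interior)
  list(rows = (idx - 1) %% h, cols = (idx - 1) %/% h)
}

# scalar-loop evaluation of the multi-label max-entropy loss (element-wise
# sigmoid cross-entropy oracle)
loss_oracle <- function(yhat, y) {
  n <- nrow(y); C <- ncol(y)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(C)) {
    s <- 1 / (1 + exp(-yhat[i, j]))
    tot <- tot + if (y[i, j] == 1) -log(s) else -log(1 - s)
  }
  tot / (n * C)
}

# scalar-loop confusion-count oracle for the metrics report
metrics_oracle <- function(y_true, y_pred) {
  C <- ncol(y_true); n <- nrow(y_true)
  prec <- rec <- kap <- numeric(C)
  for (cl in seq_len(C)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(n)) {
      t <- y_true[i, cl]; p <- y_pred[i, cl]
      if (t == 1 && p == 1) tp <- tp + 1
      if (t == 0 && p == 1) fp <- fp + 1
      if (t == 1 && p == 0) fn <- fn + 1
      if (t == 0 && p == 0) tn <- tn + 1
    }
    prec[cl] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[cl] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    kap[cl] <- if (abs(1 - pe) < 1e-15) ifelse(po == 1, 1, 0)
               else (po - pe) / (1 - pe)
  }
  P <- mean(prec); R <- mean(rec)
  list(precision = P, recall = R,
       f1 = if (P + R == 0) 0 else 2 * P * R / (P + R),
       kappa = mean(kap))
}

# deterministic labelled mini-dataset of per-eye records built in memory
make_labelled_set <- function(n, seed0, image_size = 96,
                              mix = c(N = 0.3, D = 0.2, G = 0.1, C = 0.1,
                                      A = 0.1, H = 0.1, M = 0.05, O = 0.05)) {
  conds <- withr::with_seed(seed0, sample(names(mix), n, TRUE, mix))
  imgs <- vector("list", n)
  labs <- matrix(0L, n, 8)
  lesions <- list(
    N = list(),
    D = list(exudate = 4, hemorrhage = 3, microaneurysm = 6),
    G = list(cup = 1), C = list(haze = 1), A = list(drusen = 7),
    H = list(flame = 5), M = list(crescent = 1), O = list(patch = 2))
  for (i in seq_len(n)) {
    sp <- random_synth_spec(seed0 * 10000 + i, image_size = image_size,
                            clip_fraction = 0.1,
                            lesion_counts = lesions[[conds[i]]])
    ff <- generate_fundus(sp)
    imgs[[i]] <- ff$image
    labs[i, ] <- as.integer(ff$truth$label)
  }
  list(images = imgs, labels = labs, conditions = conds)
}
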