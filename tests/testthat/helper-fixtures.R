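# Shared fixtures and independent oracles. Oracles are deliberately written
# as literal loops, independent of the vectorized implementations they check.

PHENO_CLASSES <- c("nuclear", "nuclear_excluded", "diffuse")

# k well-separated Gaussian blobs in d dimensions (planted feature structure)
make_blobs <- function(n_per, k, d = 40, sep = 12, seed = 5) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k) * sep / sqrt(d)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * d), n_per), 2, centers[i, ], "+")))
  list(x = x, y = rep(seq_len(k), each = n_per))
}

# harvest labeled ROIs through the real detect+crop path from
# single-phenotype (or mixed) fields
harvest_rois <- function(mix, n_rois, seed0, image_size = 256,
                         max_fields = 60) {
  rois <- list()
  labels <- character(0)
  i <- 0
  while (length(rois) < n_rois && i < max_fields) {
    i <- i + 1
    spec <- synthetic_spec(image_size = image_size, cells_per_field = c(6, 9),
                           transfected_fraction = 0.8, phenotype_mix = mix,
                           seed = seed0 + i)
    g <- generate_field(spec)
    det <- detect_cells(g$field)
    if (nrow(det) == 0) next
    rr <- crop_rois(g$field, det)
    # label each detection with the ground-truth box it overlaps most
    labs <- vapply(seq_len(nrow(det)), function(p) {
      ious <- vapply(seq_len(nrow(g$truth$boxes)),
                     function(t) iou(det[p, ], g$truth$boxes[t, ]), numeric(1))
      g$truth$boxes$label[which.max(ious)]
    }, character(1))
    rois <- c(rois, rr)
    labels <- c(labels, labs)
  }
  keep <- seq_len(min(n_rois, length(rois)))
  list(rois = rois[keep], labels = labels[keep])
}

pure_mix <- function(class) {
  stats::setNames(as.numeric(PHENO_CLASSES == class), PHENO_CLASSES)
}

# ---- independent oracles ----------------------------------------------------

# silhouette: literal double loop over points and clusters
silhouette_oracle <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) sqrt(sum((x[i, ] - x[j, ])^2)), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      other <- which(labels == cl)
      m <- mean(vapply(other, function(j) sqrt(sum((x[i, ] - x[j, ])^2)), numeric(1)))
      if (m < b) b <- m
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# all-points-interpolated AP: explicit per-TP envelope maximum
ap_oracle <- function(tp, n_truth) {
  if (length(tp) == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  total <- 0
  for (i in seq_along(tp)) {
    if (tp[i]) total <- total + max(prec[i:length(tp)]) / n_truth
  }
  total
}

# Pearson r from the covariance / sigma formula, written out
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
  sxy / (sx * sy)
}

# confusion-matrix counts by explicit loop (retained-in-focus orientation)
qc_confusion_oracle <- function(keep, labels) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(keep)) {
    infocus <- labels[i] == "in_focus"
    if (keep[i] && infocus) tp <- tp + 1L
    if (keep[i] && !infocus) fp <- fp + 1L
    if (!keep[i] && !infocus) tn <- tn + 1L
    if (!keep[i] && infocus) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# greedy score-ordered matcher, independently re-written with explicit sets
match_oracle <- function(preds, truths, thr = 0.5) {
  ord <- order(preds$score, decreasing = TRUE)
  available <- seq_len(nrow(truths))
  tp <- logical(nrow(preds))
  for (j in seq_along(ord)) {
    p <- preds[ord[j], ]
    best <- 0; best_t <- NA
    for (t in available) {
      v <- iou(p, truths[t, ])
      if (v > best) { best <- v; best_t <- t }
    }
    if (!is.na(best_t) && best >= thr) {
      tp[j] <- TRUE
      available <- setdiff(available, best_t)
    }
  }
  tp
}

random_boxes <- function(n) {
  data.frame(left = runif(n, 0, 0.7), top = runif(n, 0, 0.7),
             width = runif(n, 0.05, 0.3), height = runif(n, 0.05, 0.3))
}
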