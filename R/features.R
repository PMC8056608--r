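# Per-ROI feature extraction for phenotype discovery.
#
# Two extractor backends behind one handle:
#  * "vgg": the first four convolutional blocks of the VGG-16 architecture
#    (3x3 convs + ReLU + 2x2 max-pools; 64-64 / 128-128 / 256x3 / 512x3
#    channels), followed by adaptive average pooling of the block-4 output to
#    a 4x4 spatial grid over its 512 channels and flattening to 8192
#    features. Weights are either seeded random (He-initialized; fully
#    offline) or loaded from a user-supplied RDS file of pretrained weights.
#    The forward pass is implemented with im2col + BLAS matrix products.
#  * "radial": a weight-free classical profile -- 32 radial mean-intensity
#    bins of the target channel around the nucleus-channel centroid, plus
#    the nucleus-correlated fraction; cheap and discriminative for
#    nuclear/nuclear-excluded/diffuse patterns.

VGG_BLOCKS <- list(
  block1 = c(64, 64),
  block2 = c(128, 128),
  block3 = c(256, 256, 256),
  block4 = c(512, 512, 512)
)

#' Crop detections into classifier-ready ROIs
#'
#' Crops each (optionally padded) detection box out of its source field,
#' clips at the image border, and resizes to the extractor input size.
#' Degenerate boxes (zero area after clipping) are skipped with a warning.
#'
#' @param fields named list of `field_image`s (names = image ids), or a
#'   single field.
#' @param detections data frame with `left,top,width,height` (normalized)
#'   and, when `fields` is a list, an `image` column naming the source field.
#' @param pad extra padding as a fraction of box size (default 0).
#' @param size output side length in pixels (default 64).
#' @return list of `roi` objects: `pixels` (size x size x 3 array), `source`,
#'   `bbox` (the original box row), `id`.
#' @export
crop_rois <- function(fields, detections, pad = 0, size = 64L) {
  if (inherits(fields, "field_image")) {
    fields <- stats::setNames(list(fields), fields$id)
  }
  rois <- list()
  counters <- list()
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    src <- if ("image" %in% names(d)) as.character(d$image) else names(fields)[1]
    field <- fields[[src]]
    if (is.null(field)) stop_phenoscreen("detection ", i, " references unknown field '", src, "'")
    sz <- dim(field$channels)
    l <- (d$left - pad * d$width) * sz[2]
    t <- (d$top - pad * d$height) * sz[1]
    w <- d$width * (1 + 2 * pad) * sz[2]
    h <- d$height * (1 + 2 * pad) * sz[1]
    c1 <- max(1L, floor(l) + 1L); c2 <- min(sz[2], ceiling(l + w))
    r1 <- max(1L, floor(t) + 1L); r2 <- min(sz[1], ceiling(t + h))
    if (r2 <= r1 || c2 <= c1) {
      warning("skipping degenerate ROI ", i, " (zero area after clipping)")
      next
    }
    patch <- field$channels[r1:r2, c1:c2, , drop = FALSE]
    resized <- array(0, c(size, size, dim(patch)[3]))
    for (k in seq_len(dim(patch)[3])) {
      resized[, , k] <- eb_mat(EBImage::resize(EBImage::Image(patch[, , k]),
                                               w = size, h = size))
    }
    counters[[src]] <- (counters[[src]] %||% 0L) + 1L
    rois[[length(rois) + 1L]] <- structure(
      list(pixels = clip01(resized), source = src, bbox = d,
           id = paste0(src, "#", counters[[src]])),
      class = "roi")
  }
  rois
}

he_weights <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k * k * cin, cout))
}

#' Build a feature extractor
#'
#' @param config list; `type` `"vgg"` (default) or `"radial"`;
#'   for `"vgg"`: `weights_source` `"random"` (default; seeded, offline) or
#'   `"pretrained"` (requires `weights_file`, an RDS of the layer weight
#'   list), `seed` (default 1), `input_size` (default 148; 64 gives the
#'   native 4x4 block-4 grid), `pool_grid` (default 4; output length =
#'   `512 * pool_grid^2`).
#' @return an `extractor` handle with a `fingerprint` (architecture, weights
#'   source, seed, input size, feature length).
#' @export
build_extractor <- function(config = list()) {
  cfg <- utils::modifyList(list(type = "vgg", weights_source = "random",
                                seed = 1L, input_size = 148L, pool_grid = 4L,
                                weights_file = NULL, radial_bins = 32L),
                           config)
  if (cfg$type == "radial") {
    n_feat <- cfg$radial_bins + 2L
    fp <- list(arch = "radial_profile", bins = cfg$radial_bins, n_features = n_feat)
    return(structure(list(type = "radial", config = cfg, fingerprint = fp),
                     class = "extractor"))
  }
  if (cfg$type != "vgg") stop_phenoscreen("unknown extractor type '", cfg$type, "'")
  channels <- unlist(VGG_BLOCKS)
  weights <- NULL
  if (cfg$weights_source == "random") {
    weights <- with_seed(as.integer(cfg$seed), {
      cin <- 3L
      ws <- list()
      for (i in seq_along(channels)) {
        cout <- channels[[i]]
        ws[[i]] <- list(W = he_weights(3L, cin, cout), b = numeric(cout))
        cin <- cout
      }
      ws
    })
  } else if (cfg$weights_source == "pretrained") {
    if (is.null(cfg$weights_file) || !file.exists(cfg$weights_file %||% "")) {
      stop_phenoscreen("weights_source='pretrained' needs an existing weights_file ",
                       "(RDS list of per-layer $W ((9*cin) x cout) and $b); ",
                       "export one from a pretrained VGG-16 and pass its path")
    }
    weights <- readRDS(cfg$weights_file)
    if (length(weights) != length(channels)) {
      stop_phenoscreen("weights file has ", length(weights), " layers; expected ",
                       length(channels))
    }
  } else {
    stop_phenoscreen("unknown weights_source '", cfg$weights_source,
                     "'; expected 'random' or 'pretrained'")
  }
  n_feat <- 512L * cfg$pool_grid^2
  fp <- list(arch = "vgg16_blocks1to4", weights_source = cfg$weights_source,
             seed = if (cfg$weights_source == "random") as.integer(cfg$seed) else NA,
             input_size = as.integer(cfg$input_size),
             pool_grid = as.integer(cfg$pool_grid), n_features = n_feat,
             channel_order = c("nucleus", "reporter", "target"))
  structure(list(type = "vgg", config = cfg, weights = weights,
                 layers_per_block = lengths(VGG_BLOCKS), fingerprint = fp),
            class = "extractor")
}

#' @export
print.extractor <- function(x, ...) {
  fp <- x$fingerprint
  if (x$type == "radial") {
    cat("<extractor> radial profile,", fp$bins, "bins ->", fp$n_features, "features\n")
  } else {
    cat("<extractor> VGG-16 blocks 1-4,", fp$weights_source, "weights",
        if (!is.na(fp$seed)) paste0("(seed ", fp$seed, ")") else "",
        "| input", fp$input_size, "-> pool", paste0(fp$pool_grid, "x", fp$pool_grid),
        "->", fp$n_features, "features\n")
  }
  invisible(x)
}

# -- conv-net forward pass (pure R, BLAS-backed) ------------------------------

# im2col for 3x3 same-padding convolution: returns (H*W) x (9*Cin)
im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  j <- 0L
  for (c in seq_len(cin)) {
    for (dx in 0:2) {       # column offset (kernel x)
      for (dy in 0:2) {     # row offset (kernel y)
        j <- j + 1L
        cols[, j] <- as.numeric(xp[dy + seq_len(h), dx + seq_len(w), c])
      }
    }
  }
  cols
}

conv3_relu <- function(x, W, b) {
  d <- dim(x)
  out <- im2col3(x) %*% W
  out <- sweep(out, 2L, b, "+")
  out[out < 0] <- 0
  array(out, c(d[1], d[2], ncol(W)))
}

maxpool2 <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- x[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE]
  b <- x[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), , drop = FALSE]
  cc <- x[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]
  dd <- x[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), , drop = FALSE]
  pmax(a, b, cc, dd)
}

adaptive_avg_pool <- function(x, grid) {
  d <- dim(x)
  out <- array(0, c(grid, grid, d[3]))
  rb <- round(seq(0, d[1], length.out = grid + 1))
  cb <- round(seq(0, d[2], length.out = grid + 1))
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      out[i, j, ] <- apply(x[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], ,
                             drop = FALSE], 3, mean)
    }
  }
  out
}

vgg_forward <- function(extractor, x, upto_layer = Inf) {
  li <- 0L
  for (bi in seq_along(extractor$layers_per_block)) {
    for (l in seq_len(extractor$layers_per_block[[bi]])) {
      li <- li + 1L
      if (li > upto_layer) return(x)
      wl <- extractor$weights[[li]]
      x <- conv3_relu(x, wl$W, wl$b)
    }
    x <- maxpool2(x)
  }
  x
}

roi_to_input <- function(roi, size) {
  px <- roi$pixels
  if (dim(px)[1] != size) {
    out <- array(0, c(size, size, dim(px)[3]))
    for (k in seq_len(dim(px)[3])) {
      out[, , k] <- eb_mat(EBImage::resize(EBImage::Image(px[, , k]),
                                           w = size, h = size))
    }
    px <- out
  }
  px
}

#' Extract per-ROI feature vectors
#'
#' Runs every ROI through the extractor, preserving batch order. ROI channels
#' (nucleus, reporter, target) map directly onto the three extractor input
#' channels, as recorded in the fingerprint.
#'
#' @param rois list of `roi` objects from [crop_rois()], or a list of
#'   3-channel pixel arrays.
#' @param extractor an [build_extractor()] handle.
#' @return numeric matrix, one row per ROI, `fingerprint` attribute attached;
#'   row names are the ROI ids when available.
#' @export
extract_features <- function(rois, extractor) {
  stopifnot(inherits(extractor, "extractor"))
  n <- length(rois)
  nf <- extractor$fingerprint$n_features
  out <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    roi <- rois[[i]]
    px <- if (inherits(roi, "roi")) roi$pixels else roi
    if (extractor$type == "radial") {
      out[i, ] <- radial_profile_features(px, extractor$config$radial_bins)
    } else {
      x <- vgg_forward(extractor,
                       roi_to_input(list(pixels = px), extractor$config$input_size))
      out[i, ] <- as.numeric(adaptive_avg_pool(x, extractor$config$pool_grid))
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    r <- rois[[i]]
    if (inherits(r, "roi")) r$id else paste0("roi", i)
  }, character(1))
  rownames(out) <- make.unique(ids)
  attr(out, "fingerprint") <- extractor$fingerprint
  out
}

# classical weight-free features: radial mean-intensity profile of the target
# channel about the nucleus centroid, normalized, plus the in-nucleus target
# fraction and total intensity
radial_profile_features <- function(px, bins = 32L) {
  nuc <- px[, , 1]; tgt <- px[, , 3]
  h <- nrow(nuc); w <- ncol(nuc)
  wsum <- sum(nuc)
  if (wsum <= 0) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
  } else {
    cy <- sum(row(nuc) * nuc) / wsum
    cx <- sum(col(nuc) * nuc) / wsum
  }
  d <- sqrt((row(tgt) - cy)^2 + (col(tgt) - cx)^2)
  rmax <- max(d)
  bin <- pmin(bins, floor(d / (rmax + 1e-9) * bins) + 1L)
  prof <- vapply(seq_len(bins), function(b) {
    v <- tgt[bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  rng <- max(prof) - min(prof)
  prof_n <- if (rng > 0) (prof - min(prof)) / rng else prof * 0
  nuc_thr <- stats::quantile(nuc, 0.75)
  inside <- nuc >= nuc_thr
  in_frac <- if (sum(tgt) > 0) sum(tgt[inside]) / sum(tgt) else 0
  c(prof_n, in_frac, mean(tgt))
}

#' Montages of convolutional filters and intermediate feature maps
#'
#' Writes a tiled PNG of `count` filters from one convolutional layer and,
#' when an ROI is supplied, a second montage of the corresponding
#' intermediate feature maps.
#'
#' @param extractor a `"vgg"` extractor.
#' @param block block number (1--4).
#' @param layer layer within the block (1-based).
#' @param count number of filters to show (default 16).
#' @param roi optional `roi` whose intermediate maps are montaged.
#' @param out_dir output directory (default tempdir()).
#' @return invisibly, the written file paths.
#' @export
visualize_filters <- function(extractor, block, layer, count = 16L, roi = NULL,
                              out_dir = tempdir()) {
  stopifnot(inherits(extractor, "extractor"), extractor$type == "vgg")
  if (block < 1 || block > length(VGG_BLOCKS)) stop_phenoscreen("block out of range")
  if (layer < 1 || layer > extractor$layers_per_block[[block]]) {
    stop_phenoscreen("layer out of range for block ", block)
  }
  li <- if (block == 1) 0L else sum(extractor$layers_per_block[seq_len(block - 1)])
  li <- li + as.integer(layer)
  wl <- extractor$weights[[li]]
  cout <- ncol(wl$W)
  if (count > cout) {
    stop_phenoscreen("count = ", count, " exceeds the ", cout,
                     " filters of block ", block, " layer ", layer)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cin <- nrow(wl$W) / 9L
  # montage of first-input-channel 3x3 kernels, upsampled
  tile <- 24L
  ncolm <- ceiling(sqrt(count))
  nrowm <- ceiling(count / ncolm)
  mont <- matrix(0, nrowm * tile, ncolm * tile)
  for (f in seq_len(count)) {
    k <- matrix(wl$W[1:9, f], 3, 3)
    k <- (k - min(k)) / (max(k) - min(k) + 1e-12)
    up <- eb_mat(EBImage::resize(EBImage::Image(k), w = tile, h = tile,
                                 filter = "none"))
    r <- (f - 1) %/% ncolm; c <- (f - 1) %% ncolm
    mont[r * tile + 1:tile, c * tile + 1:tile] <- up
  }
  filt_path <- file.path(out_dir, sprintf("filters_b%d_l%d.png", block, layer))
  EBImage::writeImage(EBImage::Image(clip01(mont)), filt_path)
  paths <- filt_path
  if (!is.null(roi)) {
    x <- vgg_forward(extractor,
                     roi_to_input(roi, extractor$config$input_size),
                     upto_layer = li)
    side <- dim(x)[1]
    mont2 <- matrix(0, nrowm * side, ncolm * side)
    for (f in seq_len(count)) {
      fm <- x[, , f]
      rng <- max(fm) - min(fm)
      fm <- if (rng > 0) (fm - min(fm)) / rng else fm * 0
      r <- (f - 1) %/% ncolm; c <- (f - 1) %% ncolm
      mont2[r * side + 1:side, c * side + 1:side] <- fm
    }
    fm_path <- file.path(out_dir, sprintf("feature_maps_b%d_l%d.png", block, layer))
    EBImage::writeImage(EBImage::Image(clip01(mont2)), fm_path)
    paths <- c(paths, fm_path)
  }
  invisible(paths)
}
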