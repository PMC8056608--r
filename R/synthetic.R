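# Synthetic fluorescence-field generator.
#
# Emulates sub-confluent fields of transfected epithelial-like cells imaged in
# three channels (nucleus stain, transfection reporter, target protein) with
# three target-localization phenotypes: nuclear, nuclear-excluded and diffuse.
# Every field carries full ground truth (boxes, phenotype labels, focus label,
# artifact masks) recorded before any degradation, so each downstream stage
# can be benchmarked without real data.

PHENOTYPES <- c("diffuse", "nuclear", "nuclear_excluded")

#' Specification of a synthetic microscopy field
#'
#' Collects every knob of the generator into a validated spec object. The
#' defaults define the package's standard study conditions: 512 px fields,
#' 8--15 cells of radius 14--22 px, 70% transfected (the remaining 30% are
#' nucleus-only distractors), equal phenotype mix, in focus, and mild
#' acquisition noise (base sigma 0.08 scaled by the default multiplier 0.25,
#' i.e. sigma 0.02 on the [0,1] intensity scale); robustness sweeps add
#' whole multiples of the base sigma on top.
#'
#' @param image_size side length in pixels of the (square) field; >= 64.
#' @param cells_per_field integer range `c(min, max)` of cells per field.
#' @param phenotype_mix named proportions over
#'   `c("nuclear", "nuclear_excluded", "diffuse")`; must sum to 1.
#' @param transfected_fraction fraction of cells carrying reporter + target
#'   signal; the rest are nucleus-only distractors.
#' @param blur_sigma Gaussian defocus sigma in pixels (0 = in focus).
#' @param base_noise_sigma base additive-noise sigma in [0,1] intensity units.
#' @param noise_multiplier unitless multiplier >= 0; noise sigma =
#'   `base_noise_sigma * noise_multiplier`.
#' @param artifact_rates named probabilities for `bubble`, `fiber`,
#'   `overexposed` artifacts per field.
#' @param cell_radius range of cell semi-major radius in pixels.
#' @param nucleus_ratio range of nucleus/cell radius ratio (< 1).
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 512,
                           cells_per_field = c(8L, 15L),
                           phenotype_mix = c(nuclear = 1 / 3,
                                             nuclear_excluded = 1 / 3,
                                             diffuse = 1 / 3),
                           transfected_fraction = 0.7,
                           blur_sigma = 0,
                           base_noise_sigma = 0.08,
                           noise_multiplier = 0.25,
                           artifact_rates = c(bubble = 0, fiber = 0, overexposed = 0),
                           cell_radius = c(14, 22),
                           nucleus_ratio = c(0.40, 0.55),
                           seed = 1L) {
  if (!is.numeric(image_size) || image_size < 64) {
    stop_phenoscreen("image_size must be >= 64 (got ", image_size, ")")
  }
  if (length(cells_per_field) == 1L) cells_per_field <- rep(cells_per_field, 2L)
  stopifnot(length(cells_per_field) == 2L, cells_per_field[1] <= cells_per_field[2],
            cells_per_field[1] >= 0)
  if (is.null(names(phenotype_mix)) || !setequal(names(phenotype_mix), PHENOTYPES)) {
    stop_phenoscreen("phenotype_mix must be named over {",
                     paste(sort(PHENOTYPES), collapse = ", "), "}")
  }
  phenotype_mix <- phenotype_mix[sort(PHENOTYPES)]
  if (abs(sum(phenotype_mix) - 1) > 1e-9) {
    stop_phenoscreen("phenotype_mix must sum to 1 (got ", sum(phenotype_mix), ")")
  }
  rates <- c(bubble = 0, fiber = 0, overexposed = 0)
  rates[names(artifact_rates)] <- artifact_rates
  probs <- c(transfected_fraction, rates, phenotype_mix)
  if (any(probs < 0) || any(probs > 1)) {
    stop_phenoscreen("all rates and proportions must lie in [0, 1]")
  }
  stopifnot(blur_sigma >= 0, base_noise_sigma >= 0, noise_multiplier >= 0,
            cell_radius[1] > 0, cell_radius[1] <= cell_radius[2],
            nucleus_ratio[1] > 0, nucleus_ratio[2] < 1)
  structure(list(
    image_size = as.integer(image_size),
    cells_per_field = as.integer(cells_per_field),
    phenotype_mix = phenotype_mix,
    transfected_fraction = transfected_fraction,
    blur_sigma = blur_sigma,
    base_noise_sigma = base_noise_sigma,
    noise_multiplier = noise_multiplier,
    artifact_rates = rates,
    cell_radius = cell_radius,
    nucleus_ratio = nucleus_ratio,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", x$image_size, "px,",
      paste(x$cells_per_field, collapse = "-"), "cells/field,",
      round(100 * x$transfected_fraction), "% transfected\n")
  cat("  phenotype mix:",
      paste(sprintf("%s=%.2f", names(x$phenotype_mix), x$phenotype_mix), collapse = " "), "\n")
  cat("  blur sigma:", x$blur_sigma, " noise sigma:",
      x$base_noise_sigma * x$noise_multiplier, " seed:", x$seed, "\n")
  invisible(x)
}

# channel intensity model (on [0, 1]); backgrounds are flat, signal adds on top
SYNTH_LEVELS <- list(
  background = c(nucleus = 0.25, reporter = 0.22, target = 0.22),
  amplitude  = c(nucleus = 0.55, reporter = 0.40, target = 0.50),
  edge_soft_px = 1.2,  # sigmoid softness of sprite edges, in pixels
  # intracellular granularity (chromatin / vesicular speckle): multiplicative
  # zero-mean texture, smoothed to ~1 px correlation; this is the
  # high-frequency content that defocus destroys and focus QC measures
  tex_amp = c(nucleus = 0.45, reporter = 0.25, target = 0.35),
  tex_scale = 1.5
)

# smoothed multiplicative speckle field (draws from the current RNG stream)
speckle_field <- function(s, amp, scale) {
  t <- matrix(stats::rnorm(s * s), s, s)
  t <- ebimage_blur(t, scale)
  t <- t / max(pop_sd(t), 1e-12)
  pmax(0, 1 + amp * t)
}

# elliptical "distance" of pixel grid to an ellipse (1 on the boundary)
ellipse_dist <- function(nr, nc, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(nc), each = nr), nr) - cx
  y <- matrix(rep(seq_len(nr), nc), nr) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

# soft-edged elliptical fill: ~amp inside, ~0 outside, sigmoid edge
soft_ellipse <- function(nr, nc, cx, cy, a, b, theta, amp, soft_px) {
  d <- ellipse_dist(nr, nc, cx, cy, a, b, theta)
  amp * stats::plogis((1 - d) / (soft_px / mean(c(a, b))))
}

#' Render one synthetic cell sprite
#'
#' Draws a three-channel patch of a single cell: a filled nuclear ellipse in
#' the nucleus channel, a whole-cell fill in the reporter channel, and a
#' target-protein channel whose spatial pattern encodes the localization
#' phenotype -- `nuclear` (signal concentrated inside the nucleus),
#' `nuclear_excluded` (cytosolic signal excluded from the nucleus, the
#' wildtype-like pattern) or `diffuse` (uniform over the whole cell).
#'
#' @param phenotype one of `"nuclear"`, `"nuclear_excluded"`, `"diffuse"`, or
#'   `NA` for a non-transfected distractor (nucleus signal only).
#' @param geometry list with `cell_r` (semi-axes, px), `nucleus_r` (semi-axes,
#'   px; must be smaller than `cell_r`), `theta` (orientation, radians).
#' @param intensity optional jitter multipliers per channel (default 1).
#' @return list with `patch` (s x s x 3 array, channels nucleus/reporter/
#'   target), `nucleus_mask`, `cell_mask` (logical matrices), `center` and
#'   `size`.
#' @export
render_cell <- function(phenotype, geometry, intensity = c(1, 1, 1)) {
  if (!is.na(phenotype) && !phenotype %in% PHENOTYPES) {
    stop_phenoscreen("unknown phenotype label '", phenotype, "'; expected one of ",
                     paste(PHENOTYPES, collapse = ", "), " or NA (distractor)")
  }
  cr <- geometry$cell_r
  nr_ <- geometry$nucleus_r
  theta <- if (is.null(geometry$theta)) 0 else geometry$theta
  if (any(nr_ >= cr)) stop_phenoscreen("nucleus radius must be smaller than cell radius")
  soft <- SYNTH_LEVELS$edge_soft_px
  s <- as.integer(ceiling(2 * (max(cr) + 4 * soft)) + 1L)
  cx <- cy <- (s + 1) / 2
  amp <- SYNTH_LEVELS$amplitude * intensity

  d_cell <- ellipse_dist(s, s, cx, cy, cr[1], cr[2], theta)
  d_nuc <- ellipse_dist(s, s, cx, cy, nr_[1], nr_[2], theta)
  sc <- soft / mean(cr)
  sn <- soft / mean(nr_)
  cell_fill <- stats::plogis((1 - d_cell) / sc)
  nuc_fill <- stats::plogis((1 - d_nuc) / sn)

  ta <- SYNTH_LEVELS$tex_amp
  ts <- SYNTH_LEVELS$tex_scale
  patch <- array(0, c(s, s, 3))
  patch[, , 1] <- amp[["nucleus"]] * nuc_fill * speckle_field(s, ta[["nucleus"]], ts)
  if (!is.na(phenotype)) {
    patch[, , 2] <- amp[["reporter"]] * cell_fill * speckle_field(s, ta[["reporter"]], ts)
    tgt <- switch(phenotype,
      # concentrated well inside the nucleus so edge falloff stays internal
      nuclear = stats::plogis((1 - ellipse_dist(s, s, cx, cy,
                                                0.8 * nr_[1], 0.8 * nr_[2], theta)) / sn),
      # cytosolic: whole-cell fill minus an exclusion zone slightly larger
      # than the nucleus (minor perinuclear rim, no nuclear signal)
      nuclear_excluded = cell_fill *
        stats::plogis((ellipse_dist(s, s, cx, cy,
                                    1.25 * nr_[1], 1.25 * nr_[2], theta) - 1) / sn),
      diffuse = cell_fill
    )
    patch[, , 3] <- amp[["target"]] * tgt * speckle_field(s, ta[["target"]], ts)
  }
  # keep sprite peaks below saturation once composited on the background:
  # overexposure is an explicit artifact, never a side effect of texture
  for (k in 1:3) {
    headroom <- 0.96 - SYNTH_LEVELS$background[k]
    mx <- max(patch[, , k])
    if (mx > headroom) patch[, , k] <- patch[, , k] * (headroom / mx)
  }
  list(patch = patch,
       nucleus_mask = d_nuc <= 1,
       cell_mask = d_cell <= 1,
       center = c(cx, cy),
       size = s)
}

# sample per-cell geometry
sample_geometry <- function(spec) {
  a <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
  ecc <- stats::runif(1, 0.7, 1)
  ratio <- stats::runif(1, spec$nucleus_ratio[1], spec$nucleus_ratio[2])
  list(cell_r = c(a, a * ecc),
       nucleus_r = c(a, a * ecc) * ratio,
       theta = stats::runif(1, 0, pi))
}

#' Generate one synthetic field with ground truth
#'
#' Places cells without nucleus overlap (and with near-disjoint cell bodies,
#' emulating a sub-confluent culture), composes the three channels, records
#' ground truth, then degrades the image: artifacts, Gaussian defocus blur of
#' `blur_sigma`, and additive Gaussian noise of sigma
#' `base_noise_sigma * noise_multiplier` clipped to [0,1]. Ground truth
#' (boxes, labels, masks) is frozen before any degradation.
#'
#' @param spec a [synthetic_spec()].
#' @param id optional field identifier (defaults to `"field_<seed>"`).
#' @return list with `field` (class `field_image`: `channels` H x W x 3 array,
#'   `roles`, `id`) and `truth` (class `ground_truth`: `boxes` data frame of
#'   normalized `left,top,width,height` + `label`, `phenotype_labels`,
#'   `focus_label` (`"in_focus"`/`"blurry"`), `artifact_masks`).
#' @export
generate_field <- function(spec, id = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(id)) id <- paste0("field_", spec$seed)
  sz <- spec$image_size
  bg <- SYNTH_LEVELS$background

  img <- array(0, c(sz, sz, 3))
  for (k in 1:3) img[, , k] <- bg[k]

  placed <- with_seed(derive_seed(spec$seed, "cells"), {
    n <- if (spec$cells_per_field[1] == spec$cells_per_field[2]) {
      spec$cells_per_field[1]
    } else {
      sample(seq(spec$cells_per_field[1], spec$cells_per_field[2]), 1L)
    }
    n_trans <- round(n * spec$transfected_fraction)
    phen <- rep(NA_character_, n)
    if (n_trans > 0) {
      phen[seq_len(n_trans)] <- sample(names(spec$phenotype_mix), n_trans,
                                       replace = TRUE, prob = spec$phenotype_mix)
    }
    cells <- list()
    centers <- matrix(numeric(0), ncol = 2)
    radii <- numeric(0)
    attempts <- 0L
    i <- 1L
    while (i <= n) {
      if (attempts > 400L * max(n, 1L)) {
        stop_phenoscreen("could not place ", n, " cells in a ", sz, "x", sz,
                         " field: density too high")
      }
      attempts <- attempts + 1L
      g <- sample_geometry(spec)
      rmax <- max(g$cell_r)
      margin <- rmax + 4 * SYNTH_LEVELS$edge_soft_px + 1
      if (2 * margin >= sz) next
      cx <- stats::runif(1, margin, sz - margin)
      cy <- stats::runif(1, margin, sz - margin)
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        # nucleus--nucleus non-overlap and ~disjoint cell bodies
        if (any(d < 0.95 * (radii + rmax))) ok <- FALSE
      }
      if (!ok) next
      cells[[i]] <- list(geom = g, cx = cx, cy = cy, phenotype = phen[i],
                         intensity = stats::runif(3, 0.85, 1.15))
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, rmax)
      i <- i + 1L
    }
    cells
  })

  boxes <- data.frame(left = numeric(0), top = numeric(0),
                      width = numeric(0), height = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  sprites <- with_seed(derive_seed(spec$seed, "sprites"),
                       lapply(placed, function(cell)
                         render_cell(cell$phenotype, cell$geom, cell$intensity)))
  for (ci in seq_along(placed)) {
    cell <- placed[[ci]]
    sp <- sprites[[ci]]
    half <- (sp$size - 1) / 2
    r0 <- round(cell$cy) - half; c0 <- round(cell$cx) - half
    rows <- seq(r0, r0 + sp$size - 1); cols <- seq(c0, c0 + sp$size - 1)
    keep_r <- rows >= 1 & rows <= sz; keep_c <- cols >= 1 & cols <= sz
    for (k in 1:3) {
      img[rows[keep_r], cols[keep_c], k] <-
        img[rows[keep_r], cols[keep_c], k] + sp$patch[keep_r, keep_c, k]
    }
    if (!is.na(cell$phenotype)) {
      # tight bounding box of the rotated cell ellipse (+ soft edge)
      a <- cell$geom$cell_r[1]; b <- cell$geom$cell_r[2]; th <- cell$geom$theta
      ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2) + 2 * SYNTH_LEVELS$edge_soft_px
      ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2) + 2 * SYNTH_LEVELS$edge_soft_px
      l <- max(0, (cell$cx - ex) / sz); t <- max(0, (cell$cy - ey) / sz)
      w <- min(1 - l, 2 * ex / sz); h <- min(1 - t, 2 * ey / sz)
      boxes <- rbind(boxes, data.frame(left = l, top = t, width = w, height = h,
                                       label = cell$phenotype,
                                       stringsAsFactors = FALSE))
    }
  }
  img <- clip01(img)

  # artifacts (before blur/noise; masks recorded as ground truth)
  artifact_masks <- list()
  art_seed <- derive_seed(spec$seed, "artifacts")
  for (kind in names(spec$artifact_rates)) {
    p <- spec$artifact_rates[[kind]]
    hit <- with_seed(derive_seed(art_seed, kind), stats::runif(1) < p)
    if (hit) {
      res <- with_seed(derive_seed(art_seed, paste0(kind, "_draw")), {
        if (kind == "overexposed") {
          inject_artifact(img[, , 3], kind)
        } else {
          inject_artifact(img[, , 1], kind)
        }
      })
      if (kind == "overexposed") {
        img[, , 3] <- res$image
      } else {
        # physical aberrations show up in every channel
        for (k in 1:3) {
          chan <- img[, , k]
          chan[res$mask] <- pmax(chan[res$mask], res$image[res$mask])
          img[, , k] <- chan
        }
      }
      artifact_masks[[kind]] <- res$mask
    }
  }

  if (spec$blur_sigma > 0) {
    for (k in 1:3) img[, , k] <- ebimage_blur(img[, , k], spec$blur_sigma)
  }

  sigma <- spec$base_noise_sigma * spec$noise_multiplier
  if (sigma > 0) {
    noise <- with_seed(derive_seed(spec$seed, "noise"),
                       array(stats::rnorm(length(img), 0, sigma), dim(img)))
    img <- clip01(img + noise)
  }

  field <- structure(list(channels = img,
                          roles = c("nucleus", "reporter", "target"),
                          id = id),
                     class = "field_image")
  truth <- structure(list(boxes = boxes,
                          phenotype_labels = boxes$label,
                          focus_label = if (spec$blur_sigma == 0) "in_focus" else "blurry",
                          artifact_masks = artifact_masks,
                          n_cells = length(placed)),
                     class = "ground_truth")
  list(field = field, truth = truth)
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels)
  cat("<field_image>", x$id, ":", d[1], "x", d[2], "px,",
      d[3], "channels (", paste(x$roles, collapse = ", "), ")\n")
  invisible(x)
}

# strip EBImage's Image class back to a plain matrix
eb_mat <- function(x) {
  d <- dim(x)
  matrix(EBImage::imageData(x), d[1], d[2])
}

# EBImage gaussian blur with transposition-safe wrapper (EBImage images are
# x,y; our matrices are row,col -- blur is symmetric so no transpose needed)
ebimage_blur <- function(mat, sigma) {
  eb_mat(EBImage::gblur(EBImage::Image(mat), sigma = sigma))
}

#' Inject an imaging artifact into a single-channel image
#'
#' Adds one of the aberrations that defeat naive focus measures: an air
#' `bubble` (bright high-gradient annulus), a foreign `fiber` (elongated
#' bright streak) or an `overexposed` saturated blob, and returns the
#' artifact mask.
#'
#' @param image numeric matrix on [0,1].
#' @param kind `"bubble"`, `"fiber"` or `"overexposed"`.
#' @return list with `image` (modified) and `mask` (logical matrix covering
#'   the artifact).
#' @export
inject_artifact <- function(image, kind) {
  stopifnot(is.matrix(image))
  nr <- nrow(image); nc <- ncol(image)
  if (!kind %in% c("bubble", "fiber", "overexposed")) {
    stop_phenoscreen("unknown artifact kind '", kind,
                     "'; expected bubble, fiber or overexposed")
  }
  x <- matrix(rep(seq_len(nc), each = nr), nr)
  y <- matrix(rep(seq_len(nr), nc), nr)
  out <- image
  if (kind == "bubble") {
    r <- stats::runif(1, 0.08, 0.18) * min(nr, nc)
    cx <- stats::runif(1, r + 5, nc - r - 5)
    cy <- stats::runif(1, r + 5, nr - r - 5)
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    ring <- exp(-((d - r)^2) / (2 * 1.5^2))   # thin, sharp-edged ring
    out <- clip01(out + 0.7 * ring)
    mask <- abs(d - r) <= 6
  } else if (kind == "fiber") {
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 0.3, 0.7) * nc
    cy <- stats::runif(1, 0.3, 0.7) * nr
    # distance to an infinite line through (cx, cy)
    dline <- abs((x - cx) * sin(theta) - (y - cy) * cos(theta))
    along <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
    len <- stats::runif(1, 0.3, 0.6) * min(nr, nc)
    streak <- exp(-dline^2 / (2 * 1.2^2)) * (abs(along) <= len / 2)
    out <- clip01(out + 0.65 * streak)
    mask <- dline <= 4 & abs(along) <= len / 2 + 2
  } else {
    r <- stats::runif(1, 0.04, 0.08) * min(nr, nc)
    cx <- stats::runif(1, r + 5, nc - r - 5)
    cy <- stats::runif(1, r + 5, nr - r - 5)
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    blob <- d <= r
    out[blob] <- 1.0                          # saturated
    out <- clip01(out + 0.4 * exp(-((d - r)^2) / (2 * 4^2)) * (d > r))
    mask <- blob
  }
  list(image = out, mask = mask)
}

#' Write a synthetic dataset to disk
#'
#' Generates `n_fields` fields (per-field seeds derived from the spec seed),
#' writes each as a multi-page 16-bit TIFF (pages = channels in the fixed
#' order nucleus, reporter, target), plus the ground-truth annotation CSV
#' (`image,tag,left,top,width,height`, normalized coordinates), a phenotype
#' label CSV (`image,roi,label`) and a JSON manifest recording the spec,
#' seed and file list.
#'
#' @param spec a [synthetic_spec()]; `spec$blur_sigma` etc. apply to every
#'   field.
#' @param n_fields number of fields to generate.
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with `fields`, `truths`, and the file paths.
#' @export
generate_dataset <- function(spec, n_fields, dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), is_count(n_fields))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop_phenoscreen("output directory '", dir,
                     "' is non-empty; pass overwrite = TRUE to reuse it")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- vector("list", n_fields)
  truths <- vector("list", n_fields)
  ann <- list()
  lab <- list()
  files <- character(n_fields)
  focus <- character(n_fields)
  for (i in seq_len(n_fields)) {
    fspec <- spec
    fspec$seed <- derive_seed(spec$seed, paste0("field", i))
    id <- sprintf("field_%04d", i)
    g <- generate_field(fspec, id = id)
    fields[[i]] <- g$field
    truths[[i]] <- g$truth
    fname <- paste0(id, ".tif")
    write_field_tiff(g$field, file.path(dir, fname))
    files[i] <- fname
    focus[i] <- g$truth$focus_label
    b <- g$truth$boxes
    if (nrow(b) > 0) {
      ann[[length(ann) + 1L]] <- data.frame(
        image = fname, tag = "cell",
        left = b$left, top = b$top, width = b$width, height = b$height,
        stringsAsFactors = FALSE)
      lab[[length(lab) + 1L]] <- data.frame(
        image = fname, roi = seq_len(nrow(b)), label = b$label,
        stringsAsFactors = FALSE)
    }
  }
  ann_df <- if (length(ann)) do.call(rbind, ann) else
    data.frame(image = character(0), tag = character(0), left = numeric(0),
               top = numeric(0), width = numeric(0), height = numeric(0))
  lab_df <- if (length(lab)) do.call(rbind, lab) else
    data.frame(image = character(0), roi = integer(0), label = character(0))
  ann_path <- file.path(dir, "annotations.csv")
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(ann_df, ann_path, row.names = FALSE)
  utils::write.csv(lab_df, lab_path, row.names = FALSE)
  manifest <- list(spec = unclass(spec), seed = spec$seed, n_fields = n_fields,
                   files = files, focus_labels = focus,
                   channel_order = c("nucleus", "reporter", "target"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fields = fields, truths = truths, dir = dir,
                 annotation_csv = ann_path, label_csv = lab_path,
                 manifest = file.path(dir, "manifest.json")))
}

#' Read/write one field as multi-page 16-bit TIFF
#'
#' @param field a `field_image`.
#' @param path TIFF path.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  pages <- lapply(seq_along(field$roles), function(k) field$channels[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param roles channel roles, in page order.
#' @param id field id (defaults to the file name).
#' @export
read_field_tiff <- function(path, roles = c("nucleus", "reporter", "target"),
                            id = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < length(roles)) {
    stop_phenoscreen("'", path, "' has ", length(pages), " pages; expected ",
                     length(roles))
  }
  arr <- array(0, c(dim(pages[[1]])[1:2], length(roles)))
  for (k in seq_along(roles)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # tolerate RGB-coded pages
    arr[, , k] <- pg
  }
  if (is.null(id)) id <- sub("\\.tiff?$", "", basename(path))
  structure(list(channels = arr, roles = roles, id = id), class = "field_image")
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' @param dir dataset directory containing TIFFs, `annotations.csv` and
#'   (optionally) `manifest.json`.
#' @return list with `fields`, `annotations` (data frame), `labels` (or NULL),
#'   `manifest` (or NULL).
#' @export
read_dataset <- function(dir) {
  ann_path <- file.path(dir, "annotations.csv")
  if (!file.exists(ann_path)) {
    stop_phenoscreen("no annotations.csv in '", dir, "'")
  }
  ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  manifest <- NULL
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath)) manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  tifs <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  fields <- lapply(tifs, read_field_tiff)
  names(fields) <- basename(tifs)
  labels <- NULL
  lpath <- file.path(dir, "labels.csv")
  if (file.exists(lpath)) labels <- utils::read.csv(lpath, stringsAsFactors = FALSE)
  list(fields = fields, annotations = ann, labels = labels, manifest = manifest)
}
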