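# Training-data augmentation: the fixed 14-transform scheme (identity
# included) used to boost detector training sets. Geometric transforms map
# bounding boxes exactly; photometric transforms leave boxes untouched.

#' The registered augmentation transforms
#'
#' Fourteen transforms: identity, three rotations, two flips, one
#' rotation+flip, brightness up/down, contrast up/down, color inversion and
#' two noise levels. 1 source image thus yields exactly 14 training images.
#'
#' @return character vector of the 14 transform ids.
#' @export
augment_transforms <- function() {
  c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v",
    "rot90_flip_h", "brightness_up", "brightness_down", "contrast_up",
    "contrast_down", "invert", "noise_low", "noise_high")
}

rot_cw_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]

apply_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  first <- f(img[, , 1])
  out <- array(0, c(dim(first), dim(img)[3]))
  out[, , 1] <- first
  for (k in seq_len(dim(img)[3])[-1]) out[, , k] <- f(img[, , k])
  out
}

# box maps for the geometric primitives (normalized coords, y down)
box_rot90 <- function(b) data.frame(left = 1 - (b$top + b$height), top = b$left,
                                    width = b$height, height = b$width)
box_flip_h <- function(b) data.frame(left = 1 - (b$left + b$width), top = b$top,
                                     width = b$width, height = b$height)
box_flip_v <- function(b) data.frame(left = b$left, top = 1 - (b$top + b$height),
                                     width = b$width, height = b$height)

#' Apply one augmentation transform to an image and its annotations
#'
#' Geometric transforms (`rot90` is 90 degrees clockwise; `rot180`,
#' `rot270`, `flip_h`, `flip_v`, `rot90_flip_h`) transform both pixels and
#' normalized boxes exactly. Photometric transforms (`brightness_up/down`
#' +-0.15, `contrast_up/down` x1.3 / x0.7 about mid-gray, `invert`,
#' `noise_low/high` Gaussian sigma 0.02 / 0.05, seeded) leave boxes
#' bit-identical. Intensities are clipped to [0,1].
#'
#' @param image numeric matrix or H x W x C array on [0,1].
#' @param annotations data frame with normalized `left,top,width,height`
#'   columns (other columns pass through).
#' @param transform_id one of [augment_transforms()].
#' @param seed seed for the noise transforms (default 0).
#' @return list with `image` and `annotations`.
#' @export
augment_image <- function(image, annotations, transform_id, seed = 0L) {
  ids <- augment_transforms()
  if (!transform_id %in% ids) {
    stop_phenoscreen("unknown transform '", transform_id, "'; valid ids: ",
                     paste(ids, collapse = ", "))
  }
  ann <- annotations
  geo <- function(imgf, boxf) {
    img2 <- apply_channels(image, imgf)
    if (!is.null(ann) && nrow(ann) > 0) {
      nb <- boxf(ann)
      ann[c("left", "top", "width", "height")] <-
        nb[c("left", "top", "width", "height")]
    }
    list(image = img2, annotations = ann)
  }
  photo <- function(f) list(image = apply_channels(image, function(m) clip01(f(m))),
                            annotations = ann)
  switch(transform_id,
    identity = list(image = image, annotations = ann),
    rot90 = geo(rot_cw_mat, box_rot90),
    rot180 = geo(function(m) rot_cw_mat(rot_cw_mat(m)),
                 function(b) box_rot90(box_rot90(b))),
    rot270 = geo(function(m) rot_cw_mat(rot_cw_mat(rot_cw_mat(m))),
                 function(b) box_rot90(box_rot90(box_rot90(b)))),
    flip_h = geo(function(m) m[, ncol(m):1, drop = FALSE], box_flip_h),
    flip_v = geo(function(m) m[nrow(m):1, , drop = FALSE], box_flip_v),
    rot90_flip_h = geo(function(m) rot_cw_mat(m)[, nrow(m):1, drop = FALSE],
                       function(b) box_flip_h(box_rot90(b))),
    brightness_up = photo(function(m) m + 0.15),
    brightness_down = photo(function(m) m - 0.15),
    contrast_up = photo(function(m) (m - 0.5) * 1.3 + 0.5),
    contrast_down = photo(function(m) (m - 0.5) * 0.7 + 0.5),
    invert = photo(function(m) 1 - m),
    noise_low = list(image = add_gaussian_noise(image, 1, 0.02,
                       seed = derive_seed(seed, "noise_low")),
                     annotations = ann),
    noise_high = list(image = add_gaussian_noise(image, 1, 0.05,
                       seed = derive_seed(seed, "noise_high")),
                      annotations = ann)
  )
}

#' Augment a dataset directory by the 14-transform scheme
#'
#' Every image listed in the source `annotations.csv` yields exactly 14
#' output images (identity included), so the output count is 14 x the input
#' count; the output annotation CSV carries the transformed boxes.
#'
#' @param dir source dataset directory (TIFFs + `annotations.csv`).
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param seed seed for the noise transforms.
#' @return invisibly, list with `n_input`, `n_output`, `annotation_csv`.
#' @export
augment_dataset <- function(dir, out_dir, overwrite = FALSE, seed = 0L) {
  ann_path <- file.path(dir, "annotations.csv")
  if (!file.exists(ann_path)) {
    stop_phenoscreen("no annotations.csv in '", dir, "'")
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop_phenoscreen("output directory '", out_dir,
                     "' is non-empty; pass overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  images <- sort(unique(c(ann$image,
                          list.files(dir, pattern = "\\.tiff?$"))))
  out_ann <- list()
  n_out <- 0L
  for (img_name in images) {
    field <- read_field_tiff(file.path(dir, img_name))
    boxes <- ann[ann$image == img_name, , drop = FALSE]
    base <- sub("\\.tiff?$", "", img_name)
    for (tid in augment_transforms()) {
      res <- augment_image(field$channels, boxes, tid,
                           seed = derive_seed(seed, img_name))
      out_name <- paste0(base, "__", tid, ".tif")
      out_field <- structure(list(channels = res$image, roles = field$roles,
                                  id = paste0(base, "__", tid)),
                             class = "field_image")
      write_field_tiff(out_field, file.path(out_dir, out_name))
      n_out <- n_out + 1L
      if (nrow(res$annotations) > 0) {
        a <- res$annotations
        a$image <- out_name
        out_ann[[length(out_ann) + 1L]] <- a
      }
    }
  }
  out_df <- if (length(out_ann)) do.call(rbind, out_ann) else
    ann[0, , drop = FALSE]
  rownames(out_df) <- NULL
  out_csv <- file.path(out_dir, "annotations.csv")
  utils::write.csv(out_df, out_csv, row.names = FALSE)
  invisible(list(n_input = length(images), n_output = n_out,
                 annotation_csv = out_csv))
}
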