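# Focus QC: Laplacian variance, artifact suppression, threshold calibration,
# confusion metrics, SNR, noise injection, batch QC.

test_that("laplacian_variance matches hand-computed values", {
  expect_equal(laplacian_variance(matrix(5, 10, 10)), 0)
  # 4x4 zeros with a single 1 at (row 2, col 2): valid 2x2 responses are
  # {-4, 1, 1, 0} -> population variance 4.25
  img <- matrix(0, 4, 4)
  img[2, 2] <- 1
  expect_equal(laplacian_variance(img), 4.25)
  expect_error(laplacian_variance(matrix(0, 2, 5)), "3x3")
})

test_that("defocus strictly lowers the focus measure", {
  f <- generate_field(synthetic_spec(seed = 12, noise_multiplier = 0))$field
  ch <- f$channels[, , 1]
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = 3))
  expect_lt(laplacian_variance(blurred), laplacian_variance(ch))
})

test_that("bubble dilation removes artifact edges without inventing intensity", {
  const <- matrix(0.4, 64, 64)
  expect_equal(suppress_bubbles(const), const)

  f <- generate_field(synthetic_spec(seed = 5, noise_multiplier = 0))$field
  set.seed(8)
  bub <- inject_artifact(f$channels[, , 1], "bubble")
  sup <- suppress_bubbles(bub$image)
  expect_lt(laplacian_variance(sup), laplacian_variance(bub$image))
  # dilation is a local max filter
  expect_gte(min(sup), min(bub$image))
  expect_equal(max(sup), max(bub$image))
})

test_that("overexposure suppression touches only saturated regions", {
  f <- generate_field(synthetic_spec(seed = 6, noise_multiplier = 0))$field
  ch <- f$channels[, , 3]
  expect_identical(suppress_overexposed(ch), ch)   # nothing saturated

  set.seed(9)
  ove <- inject_artifact(ch, "overexposed")
  sup <- suppress_overexposed(ove$image)
  expect_lt(laplacian_variance(sup), laplacian_variance(ove$image))
  # gradient magnitude inside the artifact drops
  grad_max <- function(img, mask) {
    gx <- img[, -1] - img[, -ncol(img)]
    gy <- img[-1, ] - img[-nrow(img), ]
    max(abs(gx[mask[, -1]]), abs(gy[mask[-1, ]]))
  }
  expect_lt(grad_max(sup, ove$mask), grad_max(ove$image, ove$mask))
})

test_that("suppression is nearly neutral on clean in-focus fields", {
  f <- generate_field(synthetic_spec(seed = 13, noise_multiplier = 0))$field
  ch <- f$channels[, , 1]
  expect_identical(suppress_overexposed(ch), ch)
  v0 <- laplacian_variance(ch)
  v1 <- laplacian_variance(suppress_bubbles(ch))
  expect_lt(abs(v1 - v0) / v0, 0.2)
})

test_that("focus_score reports raw and suppressed measures and decides keep", {
  f <- generate_field(synthetic_spec(seed = 14))$field
  rep0 <- focus_score(f, list(threshold = 1e-9))
  expect_true(rep0$keep)
  expect_s3_class(rep0, "focus_report")

  set.seed(10)
  fb <- f
  fb$channels[, , 1] <- inject_artifact(fb$channels[, , 1], "bubble")$image
  repb <- focus_score(fb, list(threshold = 1e-9))
  expect_gt(repb$raw_variance, repb$focus_measure)

  expect_error(focus_score(f, list(channel = "phase", threshold = 1)), "phase")
})

test_that("threshold calibration maximizes accuracy with strict tie-break", {
  thr <- calibrate_threshold(c(1, 2, 10, 11),
                             c("blurry", "blurry", "in_focus", "in_focus"))
  expect_equal(as.numeric(thr), 10)
  expect_equal(attr(thr, "accuracy"), 1)
  # duplicated observation leaves the cut unchanged
  thr2 <- calibrate_threshold(c(1, 2, 10, 11, 11),
                              c("blurry", "blurry", "in_focus", "in_focus",
                                "in_focus"))
  expect_equal(as.numeric(thr2), 10)
  # degenerate: identical measures across classes
  expect_warning(
    thr3 <- calibrate_threshold(c(5, 5, 5, 5),
                                c("blurry", "in_focus", "blurry", "in_focus")),
    "poorly")
  expect_error(calibrate_threshold(c(1, 2), c("blurry", "blurry")), "both")
})

test_that("qc_metrics follows the retained-in-focus orientation", {
  keep <- c(rep(TRUE, 5), FALSE,            # 6 in-focus: 5 kept, 1 removed
            rep(FALSE, 3), TRUE)            # 4 blurry: 3 removed, 1 kept
  labs <- c(rep("in_focus", 6), rep("blurry", 4))
  m <- qc_metrics(keep, labs)
  expect_equal(unlist(m[c("tp", "fn", "tn", "fp")]),
               c(tp = 5, fn = 1, tn = 3, fp = 1))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 6)

  perfect <- qc_metrics(labs == "in_focus", labs)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall), c(1, 1, 1))

  all_kept <- qc_metrics(rep(TRUE, 10), labs)
  expect_equal(all_kept$recall, 1)
  expect_equal(all_kept$precision, 6 / 10)

  expect_error(qc_metrics(logical(0), character(0)), "empty")
})

test_that("qc_metrics agrees with a brute-force confusion matrix", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    keep <- sample(c(TRUE, FALSE), n, replace = TRUE)
    labs <- sample(c("in_focus", "blurry"), n, replace = TRUE)
    m <- qc_metrics(keep, labs)
    o <- qc_confusion_oracle(keep, labs)
    expect_identical(unlist(m[c("tp", "fp", "tn", "fn")]),
                     unlist(o)[c("tp", "fp", "tn", "fn")])
  }
})

test_that("SNR follows the mean-over-population-sd convention", {
  s <- compute_snr(matrix(c(1, 3, 1, 3), 2))
  expect_equal(s$mean_pixel, 2)
  expect_equal(s$std_pixel, 1)
  expect_equal(s$snr, 2)
  expect_warning(sc <- compute_snr(matrix(0.5, 3, 3)), "constant")
  expect_equal(sc$snr, Inf)
  # scale invariance
  set.seed(3)
  img <- matrix(runif(100, 0.1, 0.9), 10)
  expect_equal(compute_snr(3.7 * img)$snr, compute_snr(img)$snr)
})

test_that("noise injection is controlled and seeded", {
  img <- matrix(0.5, 40, 40)
  expect_identical(add_gaussian_noise(img, 0, seed = 1), img)
  expect_identical(add_gaussian_noise(img, 2, seed = 5),
                   add_gaussian_noise(img, 2, seed = 5))
  expect_error(add_gaussian_noise(img, -1), ">= 0")

  f <- generate_field(synthetic_spec(seed = 15))$field
  snr <- vapply(1:3, function(m)
    compute_snr(add_gaussian_noise(f$channels[, , 3], m, 0.08, seed = 2))$snr,
    numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("batch QC keeps exactly the sharp fields once calibrated", {
  sharp <- lapply(1:5, function(i)
    generate_field(synthetic_spec(seed = 30 + i))$field)
  blurred <- lapply(1:5, function(i)
    generate_field(synthetic_spec(seed = 40 + i, blur_sigma = 8))$field)
  fields <- c(sharp, blurred)
  thr <- calibrate_threshold(fields, rep(c("in_focus", "blurry"), each = 5))
  res <- qc_batch(fields, list(threshold = as.numeric(thr)))
  expect_equal(nrow(res$report), 10)
  expect_identical(vapply(res$kept, function(f) f$id, character(1)),
                   vapply(sharp, function(f) f$id, character(1)))
  expect_error(qc_batch(fields, list()), "threshold")
})
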