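# Synthetic-field generator: rendering contracts, determinism, ground truth
# bookkeeping, artifacts, dataset I/O.

test_that("rendered sprites honor the localization contracts", {
  set.seed(101)
  geom <- list(cell_r = c(18, 14), nucleus_r = c(9, 7), theta = 0.5)
  for (i in 1:3) {
    sp <- render_cell("nuclear", geom)
    frac <- sum(sp$patch[, , 3][sp$nucleus_mask]) / sum(sp$patch[, , 3])
    expect_gte(frac, 0.8)

    sp <- render_cell("nuclear_excluded", geom)
    frac <- sum(sp$patch[, , 3][sp$nucleus_mask]) / sum(sp$patch[, , 3])
    expect_lte(frac, 0.2)

    sp <- render_cell("diffuse", geom)
    frac <- sum(sp$patch[, , 3][sp$nucleus_mask]) / sum(sp$patch[, , 3])
    area_ratio <- sum(sp$nucleus_mask) / sum(sp$cell_mask)
    expect_lt(abs(frac - area_ratio), 0.1)
  }
  # distractor: nucleus only
  sp <- render_cell(NA, geom)
  expect_equal(sum(sp$patch[, , 2]), 0)
  expect_equal(sum(sp$patch[, , 3]), 0)
  expect_gt(sum(sp$patch[, , 1]), 0)
})

test_that("unknown phenotype and bad geometry are rejected by name", {
  geom <- list(cell_r = c(18, 14), nucleus_r = c(9, 7), theta = 0)
  expect_error(render_cell("membrane", geom), "membrane")
  expect_error(render_cell("nuclear", list(cell_r = c(8, 8), nucleus_r = c(9, 9))),
               "nucleus radius")
})

test_that("field generation is deterministic and records truth correctly", {
  spec <- synthetic_spec(seed = 7)
  g1 <- generate_field(spec)
  g2 <- generate_field(spec)
  expect_identical(g1$field$channels, g2$field$channels)
  expect_identical(g1$truth$boxes, g2$truth$boxes)
  b <- g1$truth$boxes
  expect_equal(length(g1$truth$phenotype_labels), nrow(b))
  expect_true(all(b$left >= 0 & b$top >= 0 &
                  b$left + b$width <= 1 & b$top + b$height <= 1))
})

test_that("transfected_fraction controls the annotated box count exactly", {
  spec <- synthetic_spec(cells_per_field = c(20L, 20L),
                         transfected_fraction = 0.5, seed = 3)
  g <- generate_field(spec)
  expect_equal(g$truth$n_cells, 20)
  expect_equal(nrow(g$truth$boxes), 10)  # round(20 * 0.5)

  g0 <- generate_field(synthetic_spec(cells_per_field = c(0L, 0L), seed = 3))
  expect_equal(nrow(g0$truth$boxes), 0)
  expect_equal(g0$truth$n_cells, 0)
})

test_that("unplaceable densities raise an error naming the density", {
  spec <- synthetic_spec(image_size = 96, cells_per_field = c(120L, 120L),
                         seed = 1)
  expect_error(generate_field(spec), "density")
})

test_that("phenotype labels are multinomial draws from the configured mix", {
  mix <- c(nuclear = 0.1, nuclear_excluded = 0.45, diffuse = 0.45)
  labs <- character(0)
  i <- 0
  while (length(labs) < 1000) {
    i <- i + 1
    spec <- synthetic_spec(image_size = 192, cells_per_field = c(8L, 8L),
                           transfected_fraction = 1, phenotype_mix = mix,
                           seed = 5000 + i)
    labs <- c(labs, generate_field(spec)$truth$phenotype_labels)
  }
  labs <- labs[1:1000]
  n_nuc <- sum(labs == "nuclear")
  expect_lt(abs(n_nuc - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})

test_that("artifacts behave per contract", {
  bg <- matrix(0.3, 200, 200)
  set.seed(4)
  bub <- inject_artifact(bg, "bubble")
  expect_gt(laplacian_variance(bub$image), laplacian_variance(bg))
  expect_gt(sum(bub$mask), 0)

  ove <- inject_artifact(bg, "overexposed")
  expect_gte(mean(ove$image[ove$mask] == 1), 0.95)

  fib <- inject_artifact(bg, "fiber")
  for (res in list(bub, ove, fib)) {
    expect_gt(sum(res$mask), 0)
    expect_identical(dim(res$mask), dim(bg))
  }
  expect_error(inject_artifact(bg, "scratchy"), "unknown artifact")
})

test_that("dataset round-trips through TIFF + CSV with labels conserved", {
  dir <- file.path(tempdir(), "ds_roundtrip")
  unlink(dir, recursive = TRUE)
  spec <- synthetic_spec(image_size = 192, cells_per_field = c(5L, 7L), seed = 21)
  ds <- generate_dataset(spec, 3, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 3)
  expect_true(file.exists(file.path(dir, "manifest.json")))

  back <- read_dataset(dir)
  expect_length(back$fields, 3)
  # boxes in the CSV equal the in-memory ground truth
  for (i in 1:3) {
    mem <- ds$truths[[i]]$boxes
    csv <- back$annotations[back$annotations$image == sprintf("field_%04d.tif", i), ]
    expect_equal(nrow(csv), nrow(mem))
    if (nrow(mem)) {
      expect_equal(csv$left, mem$left, tolerance = 1e-12)
      expect_equal(csv$height, mem$height, tolerance = 1e-12)
    }
  }
  # label conservation
  mem_labs <- sort(unlist(lapply(ds$truths, function(t) t$phenotype_labels)))
  expect_equal(sort(back$labels$label), mem_labs)
  # pixel round-trip within 16-bit quantization (absolute)
  expect_lt(max(abs(back$fields[[1]]$channels - ds$fields[[1]]$channels)),
            1.01 / 65535)
  # refusal to clobber
  expect_error(generate_dataset(spec, 1, dir), "overwrite")
})

test_that("laplacian variance is non-increasing in defocus blur", {
  lv <- vapply(c(0, 1, 2, 4, 8), function(b) {
    f <- generate_field(synthetic_spec(seed = 7, blur_sigma = b))$field
    laplacian_variance(f$channels[, , 1])
  }, numeric(1))
  expect_true(all(diff(lv) <= 1e-6))
  expect_gt(lv[1], lv[5])   # and strictly separates the extremes
})

test_that("background-only SNR decreases monotonically with the multiplier", {
  snr <- vapply(c(0.5, 1, 2, 3), function(m) {
    spec <- synthetic_spec(cells_per_field = c(0L, 0L), noise_multiplier = m,
                           seed = 9)
    compute_snr(generate_field(spec)$field$channels[, , 3])$snr
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})
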