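# Detection: IoU geometry, greedy matching, precision/recall, average
# precision (with envelope oracle), the reference detector, noise sweep.

test_that("iou matches hand geometry", {
  b <- bbox(0.2, 0.3, 0.2, 0.2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(bbox(0, 0, 0.1, 0.1), bbox(0.5, 0.5, 0.1, 0.1)), 0)
  # pixel boxes (0,0,2,2) and (1,1,2,2) on a 10x10 grid
  a <- bbox(0, 0, 0.2, 0.2)
  c <- bbox(0.1, 0.1, 0.2, 0.2)
  expect_equal(iou(a, c), 1 / 7, tolerance = 1e-12)
  expect_error(bbox(0.9, 0, 0.3, 0.1), "invalid")
})

test_that("greedy matching awards the truth to the higher-scored prediction", {
  truths <- data.frame(left = 0.4, top = 0.4, width = 0.2, height = 0.2)
  preds <- data.frame(score = c(0.9, 0.7),
                      left = c(0.41, 0.39), top = c(0.4, 0.41),
                      width = 0.2, height = 0.2)
  m <- match_detections(preds, truths)
  expect_identical(m$tp, c(TRUE, FALSE))
  expect_equal(m$unmatched_truth, 0)

  m0 <- match_detections(preds[0, ], truths)
  expect_length(m0$tp, 0)
  expect_equal(m0$unmatched_truth, 1)
})

test_that("matching agrees with an independent greedy oracle", {
  set.seed(123)
  for (i in 1:200) {
    np <- sample(1:8, 1); nt <- sample(1:6, 1)
    preds <- cbind(score = sample(seq(0.1, 0.99, 0.01), np), random_boxes(np))
    truths <- random_boxes(nt)
    m <- match_detections(preds, truths)
    # compare in ranked order against the set-based oracle
    o <- match_oracle(preds, truths)
    expect_identical(m$tp, o)
  }
})

test_that("precision_recall arithmetic and degenerate warnings", {
  pr <- precision_recall(c(rep(TRUE, 5), FALSE), 6)
  expect_equal(unname(pr), c(5 / 6, 5 / 6))
  expect_equal(unname(precision_recall(rep(TRUE, 4), 4)), c(1, 1))
  expect_warning(pr0 <- precision_recall(logical(0), 0))
  expect_equal(unname(pr0), c(0, 0))
})

test_that("average precision reproduces hand-worked PR envelopes", {
  expect_equal(average_precision(TRUE, 1), 1)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * (2 / 3))
  # trailing false positives after full recall leave the envelope unchanged
  expect_equal(average_precision(c(TRUE, TRUE, FALSE, FALSE), 2),
               average_precision(c(TRUE, TRUE), 2))
  expect_error(average_precision(c(TRUE), 0), "n_truth")
})

test_that("average precision equals the brute-force envelope oracle", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(1:25, 1)
    tp <- sample(c(TRUE, FALSE), n, replace = TRUE)
    n_truth <- max(1, sum(tp) + sample(0:4, 1))
    expect_equal(average_precision(tp, n_truth), ap_oracle(tp, n_truth),
                 tolerance = 1e-12)
  }
})

test_that("the reference detector finds transfected cells and only those", {
  # distractors only -> nothing detected
  spec0 <- synthetic_spec(transfected_fraction = 0, seed = 70,
                          noise_multiplier = 0)
  g0 <- generate_field(spec0)
  expect_equal(nrow(detect_cells(g0$field)), 0)

  # easy field: every truth box matched at IoU >= 0.5
  spec <- synthetic_spec(cells_per_field = c(10L, 10L),
                         transfected_fraction = 1, seed = 71,
                         noise_multiplier = 0)
  g <- generate_field(spec)
  det <- detect_cells(g$field)
  expect_equal(nrow(det), 10)
  m <- evaluate_detections(list(det), list(g$truth$boxes))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # determinism
  expect_identical(det, detect_cells(g$field))
  expect_error(detect_cells(structure(list(channels = g$field$channels[, , 1:2],
                                           roles = c("nucleus", "reporter"),
                                           id = "x"), class = "field_image")),
               "target")
})

test_that("recall does not improve with added noise", {
  gs <- lapply(1:4, function(i) generate_field(synthetic_spec(seed = 80 + i)))
  fields <- lapply(gs, `[[`, "field")
  truths <- lapply(gs, function(g) g$truth$boxes)
  eval_at <- function(mult) {
    noisy <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      f$channels <- add_gaussian_noise(f$channels, mult, 0.13,
                                       seed = derive_seed(1, paste0("nf", i)))
      f
    })
    evaluate_detections(lapply(noisy, detect_cells), truths)
  }
  expect_lte(eval_at(3)$recall, eval_at(1)$recall)
})

test_that("the multiplier-0 sweep row equals the clean evaluation", {
  gs <- lapply(1:3, function(i) generate_field(synthetic_spec(seed = 90 + i)))
  fields <- lapply(gs, `[[`, "field")
  truths <- lapply(gs, function(g) g$truth$boxes)
  sw <- noise_sweep(fields, truths, multipliers = c(0, 2), seed = 4)
  clean <- evaluate_detections(lapply(fields, detect_cells), truths)
  expect_equal(sw$recall[1], clean$recall)
  expect_equal(sw$precision[1], clean$precision)
  expect_equal(sw$average_precision[1], clean$average_precision)
  expect_lt(sw$mean_snr[2], sw$mean_snr[1])
  expect_error(noise_sweep(fields, truths, multipliers = numeric(0)),
               "multipliers")
})
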