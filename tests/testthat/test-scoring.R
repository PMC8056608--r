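# Scoring: classifier training/evaluation, per-variant distributions,
# Pearson correlation + p-value, LOF correlation (incl. the end-to-end
# synthetic study).

test_that("the classifier separates planted classes on held-out data", {
  b <- make_blobs(120, 3, d = 20, sep = 14, seed = 50)
  labels <- c("alpha", "beta", "gamma")[b$y]
  m <- train_classifier(b$x, labels, seed = 6)
  expect_s3_class(m, "phenotype_model")
  rep <- evaluate_classifier(m)
  expect_gte(rep$accuracy, 0.95)
  expect_equal(sum(rep$confusion), length(m$holdout_ids))
  # per-class metrics equal the confusion-matrix arithmetic
  cm <- rep$confusion
  expect_equal(rep$per_class$precision, unname(diag(cm) / pmax(colSums(cm), 1)))
  expect_equal(rep$per_class$recall, unname(diag(cm) / pmax(rowSums(cm), 1)))
  expect_equal(rep$per_class$n, unname(as.integer(rowSums(cm))))

  # identical data + seed -> identical split and coefficients
  m2 <- train_classifier(b$x, labels, seed = 6)
  expect_identical(m$holdout_ids, m2$holdout_ids)
  expect_equal(stats::coef(m$fit), stats::coef(m2$fit))
})

test_that("training guards: class floor advisory, degenerate classes", {
  b <- make_blobs(40, 2, d = 10, sep = 12, seed = 51)
  labels <- c("a", "b")[b$y]
  expect_warning(train_classifier(b$x, labels, seed = 1), "100")
  expect_error(suppressWarnings(train_classifier(b$x, rep("a", 80), seed = 1)),
               "2 classes")
})

test_that("classification is argmax with coherent probabilities", {
  b <- make_blobs(120, 3, d = 20, sep = 14, seed = 52)
  labels <- c("alpha", "beta", "gamma")[b$y]
  m <- train_classifier(b$x, labels, seed = 2)
  pred <- classify_rois(m, b$x)
  probs <- as.matrix(pred[, m$classes])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_identical(pred$label, m$classes[apply(probs, 1, which.max)])

  # fingerprint mismatch is refused
  m$fingerprint <- list(arch = "radial_profile", n_features = 20)
  feats <- b$x
  attr(feats, "fingerprint") <- list(arch = "other", n_features = 20)
  expect_error(classify_rois(m, feats), "fingerprint")

  # holdout disjointness is enforced by id
  m2 <- train_classifier(b$x, labels, seed = 2)
  expect_error(evaluate_classifier(m2, b$x[1:5, ], labels[1:5],
                                   ids = m2$train_ids[1:5]),
               "overlap")
})

test_that("variant scores are empirical label distributions", {
  labs <- c(rep("nuclear", 6), rep("nuclear_excluded", 2), rep("diffuse", 2))
  s <- score_variant("V1", labs)
  expect_equal(s$nuclear_fraction, 0.6)
  expect_equal(s$frac_nuclear, 0.6)
  expect_equal(s$frac_nuclear_excluded, 0.2)
  expect_equal(s$frac_diffuse, 0.2)
  expect_equal(s$n_cells, 10)

  s1 <- score_variant("V2", rep("diffuse", 5))
  expect_equal(s1$frac_diffuse, 1)
  expect_equal(s1$nuclear_fraction, 0)

  set.seed(1)
  for (i in 1:20) {
    labs <- sample(c("nuclear", "nuclear_excluded", "diffuse"), 30, TRUE)
    s <- score_variant("x", labs)
    expect_equal(s$frac_nuclear + s$frac_nuclear_excluded + s$frac_diffuse, 1,
                 tolerance = 1e-9)
  }
  expect_error(score_variant("V", character(0)), "no labeled")
})

test_that("pearson matches hand values and the covariance oracle", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 2, 4)), 9 / sqrt(84), tolerance = 1e-12)
  expect_error(pearson(x, c(2, 2, 2)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "n >= 3")

  set.seed(60)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.3 * a
    expect_equal(pearson(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("the t-transform p-value reproduces printed and derived values", {
  # 13 paired samples (wildtype + 12 variants) at r = 0.759
  expect_equal(round(pearson_pvalue(0.759, 13), 3), 0.003)
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(9 / sqrt(84), 3), 0.121, tolerance = 1e-3)
  expect_warning(p1 <- pearson_pvalue(1, 5), "reported as 0")
  expect_equal(p1, 0)
})

test_that("LOF correlation joins by exact id and reports mismatches", {
  nuc_counts <- c(2, 3, 6, 8, 10)
  scores <- do.call(rbind, lapply(1:5, function(i)
    score_variant(paste0("V", i), rep(c("nuclear", "diffuse"),
                                      c(nuc_counts[i], 12 - nuc_counts[i])))))
  lof <- data.frame(variant = c(paste0("V", 1:5), "GHOST"),
                    lof_score = c(1:5 / 5, 9))
  expect_message(res <- correlate_lof(scores, lof), "GHOST")
  expect_equal(res$n, 5)
  expect_gt(res$r, 0.95)   # nuclear fraction rises with lof here
  # permutation invariance
  res2 <- suppressMessages(correlate_lof(scores[5:1, ], lof))
  expect_equal(res2$r, res$r)
  expect_error(suppressMessages(
    correlate_lof(scores[1:2, ], lof[1:2, ])), "fewer than 3")
  expect_error(correlate_lof(scores, rbind(lof, lof[1, ])), "duplicate")
})

test_that("the end-to-end synthetic study recovers the planted LOF trend", {
  # 8 variants x 150 cells: generator -> detection -> crops -> radial
  # features -> classifier -> per-variant nuclear fraction -> correlation
  ex <- build_extractor(list(type = "radial"))
  train <- list(rois = list(), labels = character(0))
  for (cl in PHENO_CLASSES) {
    h <- harvest_rois(pure_mix(cl), 110, match(cl, PHENO_CLASSES) * 10000)
    train$rois <- c(train$rois, h$rois)
    train$labels <- c(train$labels, rep(cl, length(h$rois)))
  }
  feats <- extract_features(train$rois, ex)
  model <- train_classifier(feats, train$labels, seed = 2)
  expect_gte(evaluate_classifier(model)$accuracy, 0.9)

  lof <- seq(0.05, 0.85, length.out = 8)
  variants <- paste0("V", 1:8)
  scores <- list()
  for (j in 1:8) {
    p_nuc <- 0.08 + 0.8 * lof[j]
    mix <- c(nuclear = p_nuc, nuclear_excluded = (1 - p_nuc) * 0.6,
             diffuse = (1 - p_nuc) * 0.4)
    labs <- character(0)
    i <- 0
    while (length(labs) < 150 && i < 40) {
      i <- i + 1
      g <- generate_field(synthetic_spec(image_size = 256,
                                         cells_per_field = c(6L, 9L),
                                         transfected_fraction = 0.8,
                                         phenotype_mix = mix,
                                         seed = j * 1000 + i))
      det <- detect_cells(g$field)
      if (nrow(det) == 0) next
      labs <- c(labs,
                classify_rois(model,
                              extract_features(crop_rois(g$field, det), ex))$label)
    }
    scores[[j]] <- score_variant(variants[j], labs[seq_len(min(150, length(labs)))])
  }
  res <- correlate_lof(do.call(rbind, scores),
                       data.frame(variant = variants, lof_score = lof))
  expect_gt(res$r, 0.9)
  expect_lt(res$p, 0.01)
  # class-distribution conservation
  total <- sum(vapply(scores, function(s) s$n_cells, numeric(1)))
  per_class <- Reduce(`+`, lapply(scores, function(s)
    s$n_cells * c(s$frac_nuclear, s$frac_nuclear_excluded, s$frac_diffuse)))
  expect_equal(sum(per_class), total)
})
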