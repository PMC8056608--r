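# Supervised phenotype scoring: train a classifier on human-labeled
# exemplar classes, score every detected cell, aggregate per-variant
# localization distributions, and correlate the nuclear fraction with
# orthogonal loss-of-function (LOF) scores.

#' Train the reference phenotype classifier
#'
#' A linear discriminative classifier on the discovery-module feature
#' vectors: features are standardized, projected onto at most
#' `pca_components` principal components and fit with multinomial logistic
#' regression. A stratified held-out split (default 80/20, seeded) is
#' reserved for evaluation. Classes with fewer than 100 examples trigger an
#' advisory warning (the recommended training floor). The backend is
#' pluggable: any object with a `predict(model, features)` method returning
#' class probabilities can stand in.
#'
#' @param features numeric matrix, one row per labeled ROI.
#' @param labels character class labels (>= 2 classes, none empty).
#' @param config list; `holdout_frac` (default 0.2), `pca_components`
#'   (default 64), `maxit` (default 500).
#' @param seed integer seed for the split.
#' @return object of class `phenotype_model`: the fitted pipeline, class
#'   levels, train/holdout indices and the feature fingerprint.
#' @export
train_classifier <- function(features, labels, config = list(), seed = 1L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop_phenoscreen("training needs >= 2 classes")
  if (any(tab == 0)) stop_phenoscreen("empty class in training labels")
  if (any(tab < 100)) {
    warning("classes below the recommended 100-example floor: ",
            paste(sprintf("%s (%d)", names(tab)[tab < 100], tab[tab < 100]),
                  collapse = ", "))
  }
  cfg <- utils::modifyList(list(holdout_frac = 0.2, pca_components = 64L,
                                maxit = 500L), config)
  classes <- sort(names(tab))
  ids <- rownames(x) %||% paste0("roi", seq_len(nrow(x)))
  rownames(x) <- ids
  holdout <- with_seed(derive_seed(seed, "split"), {
    sel <- logical(nrow(x))
    for (cl in classes) {
      idx <- which(labels == cl)
      nh <- floor(length(idx) * cfg$holdout_frac)
      if (nh > 0) sel[sample(idx, nh)] <- TRUE
    }
    sel
  })
  xtr <- x[!holdout, , drop = FALSE]
  ytr <- labels[!holdout]
  ctr <- colMeans(xtr)
  sds <- apply(xtr, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(sweep(xtr, 2, ctr), 2, sds, "/")
  p <- min(cfg$pca_components, nrow(z) - 1L, ncol(z))
  pca <- stats::prcomp(z, center = FALSE, rank. = p)
  ztr <- pca$x
  df <- data.frame(.y = factor(ytr, levels = classes), ztr)
  fit <- with_seed(derive_seed(seed, "fit"),
    nnet::multinom(.y ~ ., data = df, maxit = cfg$maxit, trace = FALSE,
                   MaxNWts = 100000))
  structure(list(fit = fit, classes = classes, center = ctr, scale = sds,
                 rotation = pca$rotation,
                 train_ids = ids[!holdout], holdout_ids = ids[holdout],
                 holdout = list(features = x[holdout, , drop = FALSE],
                                labels = labels[holdout]),
                 fingerprint = attr(features, "fingerprint"),
                 seed = as.integer(seed)),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat("<phenotype_model>", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), ");",
      length(x$train_ids), "training /", length(x$holdout_ids), "holdout ROIs\n")
  invisible(x)
}

model_probs <- function(model, features) {
  z <- sweep(sweep(as.matrix(features), 2, model$center), 2, model$scale, "/")
  zp <- z %*% model$rotation
  pr <- stats::predict(model$fit, newdata = data.frame(zp), type = "probs")
  if (is.null(dim(pr))) {   # two classes or single row
    if (length(model$classes) == 2L && length(pr) == nrow(zp)) {
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- model$classes
    } else {
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    }
  }
  pr[, model$classes, drop = FALSE]
}

#' Classify ROIs into phenotype classes
#'
#' Predicts class probabilities for each feature row and assigns the argmax
#' label; exact probability ties break toward the alphabetically first
#' class. Refuses to classify features produced under a different extractor
#' fingerprint than the model was trained on.
#'
#' @param model a `phenotype_model`.
#' @param features numeric matrix of ROI features.
#' @param check_fingerprint verify the extractor fingerprint (default TRUE
#'   when both sides carry one).
#' @return data frame: `roi`, `label`, one probability column per class.
#' @export
classify_rois <- function(model, features, check_fingerprint = TRUE) {
  stopifnot(inherits(model, "phenotype_model"))
  fp_m <- model$fingerprint
  fp_f <- attr(features, "fingerprint")
  if (check_fingerprint && !is.null(fp_m) && !is.null(fp_f) &&
      !identical(fp_m, fp_f)) {
    stop_phenoscreen("feature fingerprint does not match the model's training ",
                     "fingerprint; re-extract with the same extractor")
  }
  pr <- model_probs(model, features)
  # argmax with alphabetical tie-break: classes are already sorted, and
  # which.max returns the first maximum
  lab <- model$classes[apply(pr, 1, which.max)]
  out <- data.frame(roi = rownames(features) %||% paste0("roi", seq_len(nrow(pr))),
                    label = lab, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pr))
}

#' Evaluate the classifier on held-out ROIs
#'
#' Computes the confusion matrix and per-class precision/recall on a holdout
#' set that must be disjoint (by ROI id) from the training set; by default
#' the model's own reserved split is used.
#'
#' @param model a `phenotype_model`.
#' @param features,labels,ids optional explicit holdout (defaults to the
#'   model's reserved split).
#' @return object of class `classifier_report`: `confusion` (rows = truth),
#'   `per_class` data frame (`class, n, precision, recall`), `accuracy`.
#' @export
evaluate_classifier <- function(model, features = NULL, labels = NULL, ids = NULL) {
  stopifnot(inherits(model, "phenotype_model"))
  if (is.null(features)) {
    features <- model$holdout$features
    labels <- model$holdout$labels
    ids <- model$holdout_ids
  }
  if (!is.null(ids) && any(ids %in% model$train_ids)) {
    stop_phenoscreen("holdout overlaps the training set: ",
                     paste(utils::head(intersect(ids, model$train_ids), 3), collapse = ", "))
  }
  pred <- classify_rois(model, features, check_fingerprint = FALSE)$label
  truth <- factor(as.character(labels), levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  cm <- table(truth = truth, predicted = pred)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  structure(list(confusion = cm,
                 per_class = data.frame(class = model$classes,
                                        n = as.integer(rowSums(cm)),
                                        precision = as.numeric(prec),
                                        recall = as.numeric(rec)),
                 accuracy = sum(diag(cm)) / sum(cm)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> accuracy =", round(x$accuracy, 3), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Per-variant phenotype score
#'
#' Empirical distribution of phenotype labels among a variant's cells, with
#' the nuclear fraction extracted as the headline scalar.
#'
#' @param variant variant identifier.
#' @param labels character phenotype labels of the variant's cells (>= 1).
#' @param label_set the full class set (default: the phenotype classes
#'   observed plus the canonical three).
#' @return one-row data frame of class `variant_score`: `variant`, `n_cells`,
#'   one `frac_*` column per class, `nuclear_fraction`.
#' @export
score_variant <- function(variant, labels,
                          label_set = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop_phenoscreen("no labeled cells for variant ", variant)
  label_set <- label_set %||% sort(unique(c(labels, PHENOTYPES)))
  tab <- table(factor(labels, levels = label_set))
  dist <- as.numeric(tab) / length(labels)
  out <- data.frame(variant = as.character(variant), n_cells = length(labels),
                    stringsAsFactors = FALSE)
  for (i in seq_along(label_set)) out[[paste0("frac_", label_set[i])]] <- dist[i]
  out$nuclear_fraction <- if ("nuclear" %in% label_set) {
    dist[match("nuclear", label_set)]
  } else {
    NA_real_
  }
  structure(out, class = c("variant_score", "data.frame"))
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return sample correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_phenoscreen("pearson needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_phenoscreen("pearson undefined for zero-variance input")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Exact t transform: `t = r * sqrt(n-2) / sqrt(1-r^2)` referred to a
#' t distribution with `n - 2` degrees of freedom, two-sided. `|r| = 1`
#' yields a 0 sentinel with a warning.
#'
#' @param r correlation coefficient.
#' @param n paired-sample count, >= 3.
#' @return two-sided p-value.
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    warning("|r| = 1: p-value reported as 0")
    return(0)
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Correlate per-variant nuclear fractions with LOF scores
#'
#' Inner-joins the variant scores with the LOF table on variant id (exact,
#' case-sensitive; mismatches are reported, never silently dropped), then
#' computes the Pearson correlation, its two-sided p-value and the
#' ordinary-least-squares best-fit line of LOF on nuclear fraction.
#'
#' @param scores a data frame of [score_variant()] rows (or rbind thereof).
#' @param lof data frame with columns `variant`, `lof_score` (unique ids).
#' @param csv optional path: writes the joined pairs.
#' @return object of class `correlation_result`: `r`, `p`, `n`, `slope`,
#'   `intercept`, `pairs` (joined data frame), `unmatched`.
#' @export
correlate_lof <- function(scores, lof, csv = NULL) {
  stopifnot(all(c("variant", "nuclear_fraction") %in% names(scores)),
            all(c("variant", "lof_score") %in% names(lof)))
  if (anyDuplicated(lof$variant)) stop_phenoscreen("duplicate variant ids in LOF table")
  joined <- merge(scores[, c("variant", "n_cells", "nuclear_fraction")],
                  lof[, c("variant", "lof_score")], by = "variant")
  unmatched <- list(scores = setdiff(scores$variant, joined$variant),
                    lof = setdiff(lof$variant, joined$variant))
  if (length(unmatched$scores) || length(unmatched$lof)) {
    message("correlate_lof: unmatched variants dropped by the join -- scores: {",
            paste(unmatched$scores, collapse = ", "), "}, lof: {",
            paste(unmatched$lof, collapse = ", "), "}")
  }
  if (nrow(joined) < 3) {
    stop_phenoscreen("fewer than 3 joined variants (got ", nrow(joined),
                     "); missing: ",
                     paste(c(unmatched$scores, unmatched$lof), collapse = ", "))
  }
  r <- pearson(joined$nuclear_fraction, joined$lof_score)
  p <- pearson_pvalue(r, nrow(joined))
  fit <- stats::lm(lof_score ~ nuclear_fraction, data = joined)
  if (!is.null(csv)) utils::write.csv(joined, csv, row.names = FALSE)
  structure(list(r = r, p = p, n = nrow(joined),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pairs = joined, unmatched = unmatched),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.4g, n = %d (LOF = %.3f + %.3f x nuclear_fraction)\n",
              x$r, x$p, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Scatter plot of the LOF correlation with the best-fit line
#'
#' @param x a `correlation_result`.
#' @param ... passed to [plot()].
#' @export
plot.correlation_result <- function(x, ...) {
  graphics::plot(x$pairs$nuclear_fraction, x$pairs$lof_score,
                 xlab = "nuclear fraction", ylab = "LOF score",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue", lwd = 2)
  graphics::text(x$pairs$nuclear_fraction, x$pairs$lof_score,
                 labels = x$pairs$variant, pos = 3, cex = 0.7)
  invisible(x)
}
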