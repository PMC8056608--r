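# Unsupervised phenotype discovery: dimensionality reduction of per-ROI
# feature maps, removal of a small noise cluster, silhouette-guided choice of
# the subcluster count, spectral subclustering, and centroid exemplars for
# human labeling.

#' Reduce feature maps for clustering and visualization
#'
#' PCA pre-reduction to `min(500, n-1, F)` components, then UMAP to 30
#' dimensions for clustering and (a separate run with the same
#' hyperparameters) to 2 dimensions for visualization. UMAP uses
#' n_neighbors = min(100, n-1), min_dist = 0.1 and the Chebyshev distance
#' metric; the Chebyshev k-nearest-neighbor graph is computed exactly and
#' passed to the UMAP optimizer. Deterministic given `seed`.
#'
#' @param features numeric matrix, one row per ROI.
#' @param config list; `n_components` (default 30), `n_neighbors` (default
#'   100, clamped to n-1 with a warning), `min_dist` (default 0.1),
#'   `pca_components` (default 500).
#' @param seed integer seed.
#' @return object of class `reduced_embedding`: `coords30` (n x 30),
#'   `coords2` (n x 2), `ids`, plus `noise` / `subcluster` slots filled by
#'   the later stages (NULL here).
#' @export
reduce_features <- function(features, config = list(), seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3) stop_phenoscreen("reduce_features needs at least 3 rows (got ", n, ")")
  cfg <- utils::modifyList(list(n_components = 30L, n_neighbors = 100L,
                                min_dist = 0.1, pca_components = 500L), config)
  k <- min(cfg$n_neighbors, n - 1L)
  if (k < cfg$n_neighbors) {
    warning("n_neighbors clamped to ", k, " (n = ", n, ")")
  }
  p <- min(cfg$pca_components, n - 1L, ncol(x))
  centered <- scale(x, center = TRUE, scale = FALSE)
  pca <- stats::prcomp(centered, center = FALSE, rank. = p)
  scores <- pca$x
  # exact Chebyshev kNN, fed to UMAP as precomputed neighbors
  d <- as.matrix(stats::dist(scores, method = "maximum"))
  nn_idx <- t(apply(d, 1, function(r) order(r)[seq_len(k + 1L)]))
  nn_dist <- t(vapply(seq_len(n), function(i) d[i, nn_idx[i, ]], numeric(k + 1L)))
  # guarantee self is the first neighbor (order() breaks ties by index)
  for (i in seq_len(n)) {
    if (nn_idx[i, 1] != i) {
      j <- match(i, nn_idx[i, ])
      if (!is.na(j)) {
        nn_idx[i, j] <- nn_idx[i, 1]; nn_dist[i, j] <- nn_dist[i, 1]
      }
      nn_idx[i, 1] <- i; nn_dist[i, 1] <- 0
    }
  }
  run_umap <- function(ncomp, tag) {
    with_seed(derive_seed(seed, tag),
      uwot::umap(scores, n_components = ncomp, min_dist = cfg$min_dist,
                 nn_method = list(idx = nn_idx, dist = nn_dist),
                 init = "spca", n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE))
  }
  ncomp30 <- min(cfg$n_components, max(2L, n - 2L), p)
  if (ncomp30 < cfg$n_components) {
    warning("embedding dimensionality capped at ", ncomp30,
            " (input rank limits the reduction)")
  }
  coords30 <- run_umap(ncomp30, "umap30")
  coords2 <- run_umap(2L, "umap2")
  ids <- rownames(x) %||% paste0("roi", seq_len(n))
  structure(list(coords30 = coords30, coords2 = coords2, ids = ids,
                 noise = NULL, subcluster = NULL,
                 fingerprint = attr(features, "fingerprint"),
                 seed = as.integer(seed)),
            class = "reduced_embedding")
}

#' @export
print.reduced_embedding <- function(x, ...) {
  cat("<reduced_embedding>", nrow(x$coords30), "points,",
      ncol(x$coords30), "clustering dims + 2 visualization dims\n")
  if (!is.null(x$noise)) cat("  noise points:", sum(x$noise), "\n")
  if (!is.null(x$subcluster)) {
    cat("  subclusters:", paste(table(x$subcluster), collapse = "/"), "\n")
  }
  invisible(x)
}

# -- spectral clustering (Ng-Jordan-Weiss on a symmetrized kNN graph) ---------

spectral_cluster <- function(coords, k, n_neighbors = 10L, seed = 1L) {
  x <- as.matrix(coords)
  n <- nrow(x)
  if (k < 2 || k > n - 1) stop_phenoscreen("k must lie in [2, n-1] (k=", k, ", n=", n, ")")
  kn <- min(n_neighbors, n - 1L)
  nn <- FNN::get.knn(x, k = kn)
  a <- matrix(0, n, n)
  # local-scale Gaussian weights on the kNN graph, symmetrized by max
  sigma <- pmax(nn$nn.dist[, kn], 1e-12)
  for (i in seq_len(n)) {
    j <- nn$nn.index[i, ]
    w <- exp(-nn$nn.dist[i, ]^2 / (sigma[i] * sigma[j]))
    a[i, j] <- pmax(a[i, j], w)
    a[j, i] <- pmax(a[j, i], w)
  }
  dg <- pmax(rowSums(a), 1e-12)
  dis <- 1 / sqrt(dg)
  lsym <- diag(n) - (dis * a) * rep(dis, each = n)
  ev <- eigen(lsym, symmetric = TRUE)
  vec <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(vec^2))
  vec <- vec / pmax(rn, 1e-12)
  km <- with_seed(derive_seed(seed, "spectral_kmeans"),
                  stats::kmeans(vec, centers = k, nstart = 10L, iter.max = 100L))
  relabel_by_size(km$cluster)
}

# remap integer labels so cluster 1 is the largest (ties: first occurrence)
relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), match(names(tab), unique(as.character(labels))))]
  as.integer(factor(as.character(labels), levels = ord))
}

#' Split off the noise cluster
#'
#' Clusters the 30-dim embedding into two groups with spectral clustering.
#' The smaller group is the noise candidate; it is discarded automatically
#' only when its fraction is below `noise_max_frac` (default 0.2) --
#' otherwise both groups are retained with a warning so a human can review
#' the split.
#'
#' @param embedding a `reduced_embedding`.
#' @param config list; `noise_max_frac` (default 0.2), `n_neighbors`
#'   (default 10).
#' @param seed integer seed.
#' @return the embedding with `noise` (logical; TRUE = flagged noise and
#'   discarded) and attribute-like fields `noise_candidate` (logical) and
#'   `noise_discarded` (flag).
#' @export
split_noise_cluster <- function(embedding, config = list(), seed = 1L) {
  stopifnot(inherits(embedding, "reduced_embedding"))
  n <- nrow(embedding$coords30)
  if (n < 4) stop_phenoscreen("split_noise_cluster needs at least 4 points")
  cfg <- utils::modifyList(list(noise_max_frac = 0.2, n_neighbors = 10L), config)
  lab <- spectral_cluster(embedding$coords30, 2L, cfg$n_neighbors, seed)
  small <- lab == 2L     # labels are size-ordered; 2 is the smaller group
  frac <- mean(small)
  discard <- frac < cfg$noise_max_frac
  if (!discard) {
    warning("candidate noise cluster holds ", round(100 * frac, 1),
            "% of ROIs (>= ", 100 * cfg$noise_max_frac,
            "%); nothing discarded -- review the split manually")
    embedding$noise <- rep(FALSE, n)
  } else {
    embedding$noise <- small
  }
  embedding$noise_candidate <- small
  embedding$noise_discarded <- discard
  embedding
}

#' Mean silhouette coefficient of a partition
#'
#' Per-point silhouette `s = (b - a) / max(a, b)` with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster; points in singleton clusters score 0. Euclidean distance.
#'
#' @param coords numeric matrix of coordinates.
#' @param labels cluster labels (>= 2 distinct, each non-empty).
#' @return mean silhouette in [-1, 1].
#' @export
mean_silhouette <- function(coords, labels) {
  x <- as.matrix(coords)
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop_phenoscreen("mean_silhouette needs >= 2 clusters")
  d <- as.matrix(stats::dist(x))
  sizes <- tabulate(labels)
  s <- numeric(n)
  # mean distance of each point to each cluster, via one matrix product
  memb <- outer(labels, ks, "==") * 1
  sums <- d %*% memb
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min(sums[i, -ci] / sizes[-ci])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Subcluster the retained embedding
#'
#' Spectral clustering of the 30-dim coordinates with nearest-neighbors
#' affinity into `k` groups; labels are remapped to descending cluster size.
#'
#' @param coords numeric matrix (retained rows of `coords30`).
#' @param k number of clusters, `2 <= k <= n-1`.
#' @param n_neighbors affinity-graph neighbors (default 10).
#' @param seed integer seed.
#' @return integer labels in `1..k`.
#' @export
subcluster <- function(coords, k, n_neighbors = 10L, seed = 1L) {
  spectral_cluster(coords, k, n_neighbors, seed)
}

#' Silhouette sweep over candidate subcluster counts
#'
#' Runs [subcluster()] for each `k` and records the mean silhouette of the
#' partition on the same coordinates; the chosen k is the argmax (ties go to
#' the smaller k).
#'
#' @param coords numeric matrix (retained rows of `coords30`).
#' @param k_range candidate cluster counts (subset of `[2, n-1]`).
#' @param n_neighbors affinity-graph neighbors.
#' @param seed integer seed.
#' @return object of class `cluster_sweep`: data frame `k, mean_silhouette`,
#'   plus `chosen_k` and `labels` (the partition at `chosen_k`).
#' @export
silhouette_sweep <- function(coords, k_range = 2:8, n_neighbors = 10L, seed = 1L) {
  if (length(k_range) == 0) stop_phenoscreen("empty k_range")
  n <- nrow(as.matrix(coords))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop_phenoscreen("k_range must lie within [2, n-1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  labs <- list()
  sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    labs[[i]] <- subcluster(coords, k_range[i], n_neighbors, seed)
    sil[i] <- mean_silhouette(coords, labs[[i]])
  }
  best <- which(sil >= max(sil) - 1e-12)[1]   # ties -> smaller k
  structure(list(table = data.frame(k = k_range, mean_silhouette = sil),
                 chosen_k = k_range[best], labels = labs[[best]]),
            class = "cluster_sweep")
}

#' @export
print.cluster_sweep <- function(x, ...) {
  cat("<cluster_sweep> chosen k =", x$chosen_k, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Centroid exemplars per subcluster
#'
#' For each subcluster: the centroid is the mean of the 30-dim coordinates;
#' the `n_neighbors` retained points nearest to it (Euclidean, ascending)
#' are the exemplars handed to a human for class labeling. Optionally writes
#' a per-cluster montage image and a CSV of exemplar ids.
#'
#' @param embedding a `reduced_embedding` with `subcluster` filled (or pass
#'   `labels`).
#' @param rois optional list of `roi` objects aligned with the retained
#'   rows, used for montages.
#' @param n_neighbors exemplars per cluster (default 20); clusters smaller
#'   than this return all members with a warning.
#' @param labels optional explicit labels (overrides `embedding$subcluster`).
#' @param out_dir optional output directory for montages + CSV.
#' @return list per cluster: `ids`, `index` (row indices), `distance`
#'   (ascending).
#' @export
centroid_exemplars <- function(embedding, rois = NULL, n_neighbors = 20L,
                               labels = NULL, out_dir = NULL) {
  stopifnot(inherits(embedding, "reduced_embedding"))
  labels <- labels %||% embedding$subcluster
  if (is.null(labels)) stop_phenoscreen("no subcluster labels on the embedding")
  retained <- if (is.null(embedding$noise)) rep(TRUE, nrow(embedding$coords30)) else !embedding$noise
  coords <- embedding$coords30[retained, , drop = FALSE]
  ids <- embedding$ids[retained]
  stopifnot(length(labels) == nrow(coords))
  out <- list()
  rows <- list()
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    cen <- colMeans(coords[idx, , drop = FALSE])
    dd <- sqrt(colSums((t(coords[idx, , drop = FALSE]) - cen)^2))
    ord <- order(dd)
    take <- min(n_neighbors, length(idx))
    if (length(idx) < n_neighbors) {
      warning("cluster ", k, " has only ", length(idx),
              " members (< ", n_neighbors, "); returning all")
    }
    sel <- ord[seq_len(take)]
    out[[as.character(k)]] <- list(ids = ids[idx[sel]], index = idx[sel],
                                   distance = dd[sel])
    rows[[length(rows) + 1L]] <- data.frame(cluster = k, roi = ids[idx[sel]],
                                            distance = dd[sel])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "exemplars.csv"), row.names = FALSE)
    if (!is.null(rois)) {
      for (k in names(out)) {
        sel <- out[[k]]$index
        tiles <- lapply(rois[sel], function(r) r$pixels[, , 3])
        side <- nrow(tiles[[1]])
        ncolm <- ceiling(sqrt(length(tiles)))
        nrowm <- ceiling(length(tiles) / ncolm)
        mont <- matrix(0, nrowm * side, ncolm * side)
        for (i in seq_along(tiles)) {
          r <- (i - 1) %/% ncolm; c <- (i - 1) %% ncolm
          t_ <- tiles[[i]]
          rng <- max(t_) - min(t_)
          if (rng > 0) t_ <- (t_ - min(t_)) / rng
          mont[r * side + 1:side, c * side + 1:side] <- t_
        }
        EBImage::writeImage(EBImage::Image(mont),
                            file.path(out_dir, sprintf("exemplars_cluster%s.png", k)))
      }
    }
  }
  out
}

#' Embedding export
#'
#' Writes the per-ROI embedding CSV
#' (`roi,source_image,umap1,umap2,noise,subcluster`).
#'
#' @param embedding a `reduced_embedding`.
#' @param path output CSV path.
#' @param sources optional source-image ids aligned with the embedding rows.
#' @export
write_embedding_csv <- function(embedding, path, sources = NULL) {
  n <- nrow(embedding$coords30)
  noise <- embedding$noise %||% rep(FALSE, n)
  sub <- rep(NA_integer_, n)
  if (!is.null(embedding$subcluster)) sub[!noise] <- embedding$subcluster
  df <- data.frame(roi = embedding$ids,
                   source_image = sources %||% NA_character_,
                   umap1 = embedding$coords2[, 1], umap2 = embedding$coords2[, 2],
                   noise = noise, subcluster = sub)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
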