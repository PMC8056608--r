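# Pipeline orchestration: configuration, stage sequencing, logging and the
# run manifest. All cross-stage communication is file-based (TIFF/CSV/JSON)
# so any stage can be re-run or substituted by an external tool.

#' Default pipeline configuration
#'
#' @return nested list of stage configs with every default filled in.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    input = NULL,                    # dataset directory (TIFFs + annotations.csv)
    out = "phenoscreen_out",
    channels = list(nucleus = 1L, reporter = 2L, target = 3L),
    synthetic = NULL,                # optional synthetic_spec args + n_fields
    qc = list(channel = "nucleus", threshold = NA_real_),
    detect = list(min_area = 60, max_area = 6000, pad_frac = 0.15,
                  reporter_min_frac = 0.3, iou_threshold = 0.5),
    rois = list(size = 64L, pad = 0),
    discover = list(extractor = "radial", kmin = 2L, kmax = 8L,
                    n_neighbors = 10L, noise_max_frac = 0.2),
    score = list(labels_csv = NULL, variants_csv = NULL, lof_csv = NULL)
  )
}

#' Load a pipeline configuration file
#'
#' Reads YAML or JSON, fills defaults, and rejects unknown keys. An empty
#' file yields the full default configuration with a warning.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a `pipeline_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_phenoscreen("config file '", path, "' not found")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_phenoscreen("cannot parse '", path, "': ",
                                                  conditionMessage(e)))
  }
  if (is.null(raw) || length(raw) == 0) {
    warning("empty config file: using full defaults")
    raw <- list()
  }
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop_phenoscreen("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in c("channels", "qc", "detect", "rois", "discover", "score")) {
    if (!is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(bad)) {
        stop_phenoscreen("unknown keys in config section '", sec, "': ",
                         paste(bad, collapse = ", "))
      }
    }
  }
  cfg <- utils::modifyList(def, raw)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a config list.
#' @return character vector of issues; empty iff the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "seed must be a single integer")
  need(!is.null(config$channels) &&
         all(c("nucleus", "reporter", "target") %in% names(config$channels)),
       "channels must map the roles nucleus, reporter, target")
  if (!is.null(config$synthetic)) {
    pm <- config$synthetic$phenotype_mix
    if (!is.null(pm) && abs(sum(unlist(pm)) - 1) > 1e-9) {
      issues <- c(issues, "synthetic$phenotype_mix does not sum to 1")
    }
    for (f in c("transfected_fraction")) {
      v <- config$synthetic[[f]]
      if (!is.null(v) && (v < 0 || v > 1)) {
        issues <- c(issues, paste0("synthetic$", f, " must lie in [0,1]"))
      }
    }
  }
  if (is.null(config$input) && is.null(config$synthetic)) {
    issues <- c(issues, "either input (dataset directory) or synthetic must be set")
  }
  d <- config$detect
  if (!is.null(d) && !is.null(d$iou_threshold) &&
      (d$iou_threshold <= 0 || d$iou_threshold > 1)) {
    issues <- c(issues, "detect$iou_threshold must lie in (0,1]")
  }
  issues
}

log_line <- function(...) message("[phenoscreen] ", ...)

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full pipeline
#'
#' Stages run in order: (optional) synthetic generation, image quality
#' control, cell detection, ROI extraction + feature extraction, phenotype
#' discovery -- or classification + per-variant scoring when training labels
#' are supplied -- and LOF correlation when an LOF table is supplied. Every
#' stage writes its outputs under `config$out` and the run manifest records
#' the config, per-stage files with MD5 hashes, discarded-item counts and
#' timestamps. A stage failure halts the run naming the stage.
#'
#' @param config a `pipeline_config` (see [load_config()],
#'   [default_config()]).
#' @return the run manifest (list, class `run_manifest`), invisibly written
#'   to `<out>/run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues)) {
    stop_phenoscreen("invalid config:\n  - ", paste(issues, collapse = "\n  - "))
  }
  out_root <- config$out
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(),
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   versions = list(phenoscreen = as.character(utils::packageVersion("phenoscreen")),
                                   R = paste(R.version$major, R.version$minor, sep = ".")))
  run_stage <- function(name, fun) {
    log_line("stage: ", name)
    tryCatch(fun(), error = function(e) {
      stop_phenoscreen("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  input_dir <- config$input
  if (is.null(input_dir)) {
    input_dir <- file.path(out_root, "synthetic")
    run_stage("synthetic", function() {
      sargs <- config$synthetic
      n_fields <- sargs$n_fields %||% 10L
      sargs$n_fields <- NULL
      sargs$seed <- sargs$seed %||% derive_seed(config$seed, "synthetic")
      spec <- do.call(synthetic_spec, sargs)
      generate_dataset(spec, n_fields, input_dir, overwrite = TRUE)
    })
    manifest$stages$synthetic <- list(dir = input_dir,
                                      hashes = hash_files(list.files(input_dir, full.names = TRUE)))
  }

  ds <- read_dataset(input_dir)
  fields <- ds$fields

  # -- QC ---------------------------------------------------------------------
  qc_dir <- file.path(out_root, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  qc_res <- run_stage("qc", function() {
    qcfg <- config$qc
    if (is.null(qcfg$threshold) || is.na(qcfg$threshold)) {
      labs <- ds$manifest$focus_labels
      if (is.null(labs)) {
        stop_phenoscreen("no qc$threshold configured and the dataset manifest ",
                         "carries no focus labels to calibrate on")
      }
      if (length(unique(labs)) < 2L) {
        # single-class calibration set: keep everything (or nothing) rather
        # than guessing a cut from one class
        qcfg$threshold <- if (unique(labs) == "in_focus") 0 else Inf
        log_line("focus labels are single-class; threshold set to ",
                 qcfg$threshold)
      } else {
        thr <- calibrate_threshold(fields, labs, qcfg)
        log_line("calibrated focus threshold: ", signif(thr, 5))
        qcfg$threshold <- as.numeric(thr)
      }
    }
    qc_batch(fields, qcfg, report_csv = file.path(qc_dir, "qc_report.csv"))
  })
  log_line("QC removed ", length(fields) - length(qc_res$kept), " of ",
           length(fields), " fields")
  manifest$stages$qc <- list(report = file.path(qc_dir, "qc_report.csv"),
                             kept = length(qc_res$kept),
                             removed = length(fields) - length(qc_res$kept),
                             threshold = qc_res$report$threshold[1],
                             hashes = hash_files(file.path(qc_dir, "qc_report.csv")))
  kept_fields <- qc_res$kept

  # -- detection --------------------------------------------------------------
  det_dir <- file.path(out_root, "detect")
  dir.create(det_dir, showWarnings = FALSE)
  det_csv <- file.path(det_dir, "detections.csv")
  detections <- run_stage("detect", function() {
    rows <- list()
    for (f in kept_fields) {
      det <- detect_cells(f, config$detect)
      if (nrow(det)) {
        det$image <- paste0(f$id, ".tif")
        rows[[length(rows) + 1L]] <- det
      }
    }
    all <- if (length(rows)) do.call(rbind, rows) else
      data.frame(score = numeric(0), left = numeric(0), top = numeric(0),
                 width = numeric(0), height = numeric(0), image = character(0))
    utils::write.csv(all, det_csv, row.names = FALSE)
    all
  })
  log_line(nrow(detections), " detections across ", length(kept_fields), " fields")
  manifest$stages$detect <- list(csv = det_csv, n = nrow(detections),
                                 hashes = hash_files(det_csv))

  # -- ROI extraction + features ---------------------------------------------
  feat_dir <- file.path(out_root, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  feat_csv <- file.path(feat_dir, "features.csv")
  ext_cfg <- if (identical(config$discover$extractor, "vgg")) {
    list(type = "vgg", weights_source = "random",
         seed = derive_seed(config$seed, "extractor"))
  } else {
    list(type = "radial")
  }
  extraction <- run_stage("extract", function() {
    named <- stats::setNames(kept_fields,
                             vapply(kept_fields, function(f) paste0(f$id, ".tif"),
                                    character(1)))
    rois <- crop_rois(named, detections, pad = config$rois$pad,
                      size = config$rois$size)
    extractor <- build_extractor(ext_cfg)
    feats <- extract_features(rois, extractor)
    df <- data.frame(roi = rownames(feats),
                     source_image = vapply(rois, function(r) r$source, character(1)))
    utils::write.csv(cbind(df, as.data.frame(unname(feats))), feat_csv,
                     row.names = FALSE)
    list(rois = rois, features = feats)
  })
  manifest$stages$extract <- list(csv = feat_csv,
                                  n_rois = length(extraction$rois),
                                  fingerprint = attr(extraction$features, "fingerprint"),
                                  hashes = hash_files(feat_csv))

  labels_csv <- config$score$labels_csv
  if (is.null(labels_csv)) {
    # -- discovery ------------------------------------------------------------
    disc_dir <- file.path(out_root, "discovery")
    dir.create(disc_dir, showWarnings = FALSE)
    disc <- run_stage("discover", function() {
      emb <- reduce_features(extraction$features,
                             seed = derive_seed(config$seed, "umap"))
      emb <- split_noise_cluster(emb,
                                 list(noise_max_frac = config$discover$noise_max_frac,
                                      n_neighbors = config$discover$n_neighbors),
                                 seed = derive_seed(config$seed, "noise_split"))
      retained <- !emb$noise
      coords <- emb$coords30[retained, , drop = FALSE]
      kmax <- min(config$discover$kmax, nrow(coords) - 1L)
      sweep <- silhouette_sweep(coords, config$discover$kmin:kmax,
                                n_neighbors = config$discover$n_neighbors,
                                seed = derive_seed(config$seed, "sweep"))
      emb$subcluster <- sweep$labels
      write_embedding_csv(emb, file.path(disc_dir, "embedding.csv"),
                          sources = vapply(extraction$rois, function(r) r$source,
                                           character(1)))
      centroid_exemplars(emb, rois = extraction$rois[retained],
                         labels = sweep$labels, out_dir = disc_dir)
      utils::write.csv(sweep$table, file.path(disc_dir, "silhouette_sweep.csv"),
                       row.names = FALSE)
      list(embedding = emb, sweep = sweep)
    })
    log_line("discovery: ", sum(disc$embedding$noise), " noise ROIs discarded, ",
             "chosen k = ", disc$sweep$chosen_k)
    manifest$stages$discover <- list(
      dir = disc_dir, chosen_k = disc$sweep$chosen_k,
      n_noise = sum(disc$embedding$noise),
      hashes = hash_files(list.files(disc_dir, full.names = TRUE, pattern = "\\.csv$")))
  } else {
    # -- classification + scoring --------------------------------------------
    score_dir <- file.path(out_root, "scoring")
    dir.create(score_dir, showWarnings = FALSE)
    scored <- run_stage("score", function() {
      lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
      idx <- match(lab$roi, rownames(extraction$features))
      if (anyNA(idx)) {
        stop_phenoscreen("label CSV references unknown ROI ids: ",
                         paste(utils::head(lab$roi[is.na(idx)], 3), collapse = ", "))
      }
      model <- train_classifier(extraction$features[idx, , drop = FALSE],
                                lab$label, seed = derive_seed(config$seed, "clf"))
      pred <- classify_rois(model, extraction$features)
      variant_of <- rep("all", nrow(pred))
      if (!is.null(config$score$variants_csv)) {
        vmap <- utils::read.csv(config$score$variants_csv, stringsAsFactors = FALSE)
        src <- vapply(extraction$rois, function(r) r$source, character(1))
        variant_of <- vmap$variant[match(src, vmap$image)]
      }
      parts <- split(pred$label, variant_of)
      scores <- do.call(rbind, Map(score_variant, names(parts), parts))
      utils::write.csv(scores, file.path(score_dir, "scores.csv"), row.names = FALSE)
      utils::write.csv(pred, file.path(score_dir, "classifications.csv"),
                       row.names = FALSE)
      res <- list(model = model, scores = scores)
      if (!is.null(config$score$lof_csv)) {
        lof <- utils::read.csv(config$score$lof_csv, stringsAsFactors = FALSE)
        corr <- correlate_lof(scores, lof,
                              csv = file.path(score_dir, "lof_pairs.csv"))
        jsonlite::write_json(list(r = corr$r, p = corr$p, n = corr$n,
                                  slope = corr$slope, intercept = corr$intercept),
                             file.path(score_dir, "correlation.json"),
                             auto_unbox = TRUE, digits = NA)
        res$correlation <- corr
      }
      res
    })
    manifest$stages$score <- list(
      dir = score_dir,
      n_variants = nrow(scored$scores),
      hashes = hash_files(list.files(score_dir, full.names = TRUE)))
    if (!is.null(scored$correlation)) {
      manifest$stages$score$r <- scored$correlation$r
      manifest$stages$score$p <- scored$correlation$p
    }
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_root, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", length(x$stages), "stages:",
      paste(names(x$stages), collapse = " -> "), "\n")
  invisible(x)
}
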