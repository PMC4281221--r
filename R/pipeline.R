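#' Full pipeline configuration
#'
#' Either a synthetic [scene_spec()] or paths to real inputs
#' (multispectral + panchromatic rasters, ground-truth GeoJSON) must be
#' provided — exactly one of the two.  All stage parameters default to
#' the published rule-set values.
#'
#' @param scene a [scene_spec()] for synthetic mode, or `NULL`.
#' @param ms_path,pan_path,truth_path real-data inputs (GeoTIFF pair and
#'   ground-truth points), or `NULL`.
#' @param pan_weights simulated-pan weights for pan-sharpening.
#' @param ann an [ann_config()].
#' @param landscape_seg,animal_seg the two [seg_params()] rows.
#' @param landscape_cfg a [landscape_rules()].
#' @param animal_cfg an [animal_rules()].
#' @param n_animal_samples,n_landscape_samples training-sample sizes.
#' @param match_tol_m detection-to-truth matching tolerance (meters).
#' @param out_dir optional directory for intermediate artifacts.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, ms_path = NULL, pan_path = NULL,
                            truth_path = NULL,
                            pan_weights = c(0.1, 0.3, 0.4, 0.2),
                            ann = ann_config(),
                            landscape_seg = landscape_seg_params(),
                            animal_seg = animal_seg_params(),
                            landscape_cfg = landscape_rules(),
                            animal_cfg = animal_rules(),
                            n_animal_samples = 150,
                            n_landscape_samples = 50,
                            match_tol_m = 2.0, out_dir = NULL, seed = 1L) {
  synthetic <- !is.null(scene)
  real <- !is.null(ms_path) || !is.null(pan_path)
  if (synthetic == real) {
    stop("provide exactly one of: a scene spec, or ms/pan paths")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the hybrid detection pipeline end to end
#'
#' Executes, in order: scene simulation (or raster loading),
#' Gram-Schmidt pan-sharpening, training-sample extraction, spectral
#' separability audit (classes flagged as poorly separable from the
#' animal class are merged with it, mirroring the animals+shadow merged
#' class), neural-network training and per-pixel classification, 3 x 3
#' low-pass smoothing and landscape segmentation/classification, the
#' object-based animal refinement, and (when ground truth is available)
#' detection matching and error rates.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `detections`
#'   (`detection_set`), `counts` / `report` (accuracy, synthetic mode),
#'   `separability`, `model`, `manifest` (per-stage counts and echoed
#'   settings).  Intermediate artifacts are written to `out_dir` when
#'   set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(seed = config$seed, mode = if (config$synthetic)
    "synthetic" else "real")

  if (config$synthetic) {
    scn <- stage("simulate", generate_scene(config$scene))
    ms <- scn$ms; pan <- scn$pan; truth <- scn$truth
    manifest$true_animals <- nrow(truth$animals)
  } else {
    ms <- stage("load", read_geotiff(config$ms_path))
    pan <- stage("load", read_geotiff(config$pan_path))
    truth <- if (!is.null(config$truth_path)) {
      list(animals = read_geojson_points(config$truth_path))
    }
  }

  sharp <- stage("pansharpen",
                 gram_schmidt_pansharpen(ms, pan, config$pan_weights))

  if (config$synthetic && nrow(truth$animals) == 0) {
    ## nothing to detect and no animal class to train: empty result
    det <- empty_detection_set(sharp$cell_size_m, sharp$origin)
    counts <- match_detections(det, truth, config$match_tol_m)
    report <- error_rates(counts)
    manifest$detections <- 0L
    return(structure(list(detections = det, counts = counts,
                          report = report, separability = NULL,
                          model = NULL, manifest = manifest),
                     class = "pipeline_result"))
  }

  if (config$synthetic) {
    n_animal <- config$n_animal_samples
    avail <- sum(vapply(truth$footprints, nrow, integer(1)))
    if (avail < n_animal) {
      warning("only ", avail, " animal pixels available; reducing the ",
              "animal sample size from ", n_animal)
      n_animal <- avail
    }
    samples <- stage("samples",
                     sample_training_points(truth, sharp, n_animal,
                                            config$n_landscape_samples,
                                            seed = config$seed))
  } else {
    stop("real-data mode requires a training-sample GeoJSON; use the ",
         "module functions directly")
  }

  stats <- stage("separability", class_stats(sharp, samples))
  sep <- stage("separability", separability_matrix(stats))
  ## merge classes that are poorly separable from the animal class
  merged_into_animal <- character(0)
  for (p in sep$merge_recommendations) {
    if ("animal" %in% p) {
      other <- setdiff(p, "animal")
      samples$class[samples$class %in% other] <- "animal"
      merged_into_animal <- c(merged_into_animal, other)
    }
  }
  manifest$merged_into_animal <- merged_into_animal
  warn_pairs <- sep$flags[sep$flags$class_a == "animal" |
                            sep$flags$class_b == "animal", ]
  if (any(warn_pairs$flag == "intermediate")) {
    warning("animal class has intermediate separability from some ",
            "landscape classes; pixel stage may under- or over-detect")
  }

  cfg_ann <- config$ann
  cfg_ann$seed <- config$seed
  model <- stage("train", train_ann(sharp, samples, cfg_ann))
  manifest$ann_converged <- model$converged
  manifest$ann_test_accuracy <- attr(model$test_report, "overall")
  cls <- stage("classify", classify_pixels(sharp, model))
  manifest$candidate_px <-
    sum(cls$labels == cls$class_table[["animal"]])

  smooth <- stage("lowpass", lowpass_3x3(sharp))
  lseg <- stage("segment_landscape",
                multiresolution_segment(smooth, config$landscape_seg))
  lseg <- stage("classify_landscape",
                classify_landscape(lseg, config$landscape_cfg))
  manifest$landscape_segments <- nrow(lseg$features)
  manifest$landscape_classes <- table(lseg$features$class)

  det <- stage("refine",
               refine_animals(cls, lseg, sharp, config$animal_seg,
                              config$animal_cfg))
  manifest$stage_counts <- det$audit
  manifest$detections <- nrow(det$detections)

  counts <- report <- NULL
  if (!is.null(truth)) {
    counts <- stage("assess",
                    match_detections(det, truth, config$match_tol_m))
    report <- error_rates(counts)
    manifest$count_error_pct <- report$count_error_pct
    manifest$omission_pct <- report$omission_pct
    manifest$commission_pct <- report$commission_pct
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_geotiff(sharp, file.path(config$out_dir, "sharpened.tif"))
    write_detections_geojson(det,
                             file.path(config$out_dir, "detections.geojson"))
    if (!is.null(report)) {
      write.csv(report, file.path(config$out_dir, "accuracy.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest_to_json(manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  structure(list(detections = det, counts = counts, report = report,
                 separability = sep, model = model, manifest = manifest),
            class = "pipeline_result")
}

manifest_to_json <- function(m) {
  m$landscape_classes <- as.list(m$landscape_classes)
  m
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  detections:", nrow(x$detections$detections), "\n")
  if (!is.null(x$report)) {
    cat(sprintf("  count error %.1f%%, omission %.1f%%, commission %.1f%%\n",
                x$report$count_error_pct, x$report$omission_pct,
                x$report$commission_pct))
  }
  invisible(x)
}

#' Read a sectioned key = value pipeline configuration file
#'
#' Plain-text configuration: `key = value` lines, `[section]` headers
#' (`scene`, `ann`, `landscape_seg`, `animal_seg`, `landscape_rules`,
#' `animal_rules`, `pipeline`), `#` comments.  Vector values are
#' comma-separated.  Every rule threshold appears under its field name
#' with its published default.
#'
#' @param path config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- "pipeline"
  vals <- list(pipeline = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (is.null(vals[[section]])) vals[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      raw <- trimws(paste(kv[-1], collapse = "="))
      parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      vals[[section]][[key]] <- if (!anyNA(num)) num else parts
    }
  }
  build <- function(fn, sec) do.call(fn, vals[[sec]] %||% list())
  p <- vals$pipeline
  pipeline_config(
    scene = if (!is.null(vals$scene)) build(scene_spec, "scene"),
    ms_path = p$ms_path, pan_path = p$pan_path, truth_path = p$truth_path,
    pan_weights = p$pan_weights %||% c(0.1, 0.3, 0.4, 0.2),
    ann = build(ann_config, "ann"),
    landscape_seg = if (!is.null(vals$landscape_seg))
      build(seg_params, "landscape_seg") else landscape_seg_params(),
    animal_seg = if (!is.null(vals$animal_seg))
      build(seg_params, "animal_seg") else animal_seg_params(),
    landscape_cfg = build(landscape_rules, "landscape_rules"),
    animal_cfg = build(animal_rules, "animal_rules"),
    n_animal_samples = p$n_animal_samples %||% 150,
    n_landscape_samples = p$n_landscape_samples %||% 50,
    match_tol_m = p$match_tol_m %||% 2.0,
    out_dir = p$out_dir, seed = as.integer(p$seed %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
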