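#' Rule thresholds for landscape masking (Step A)
#'
#' Objects are classified as surroundings (vegetation, water, shadow)
#' only when they exceed a minimum size, so animal-sized objects are
#' never masked.
#'
#' @param ndvi_min NDVI threshold for vegetation (default 0.6).
#' @param min_landscape_area_px minimum object size, pixels (default 20).
#' @param shadow_brightness_max brightness ceiling for shadow (315).
#' @param shadow_vegetation_radius_m a shadow object must have vegetation
#'   within this distance (default 1 m).
#' @param blue_ratio_min_water blue-ratio floor for water (default 0.18).
#' @return A list of class `landscape_rules`.
#' @export
landscape_rules <- function(ndvi_min = 0.6, min_landscape_area_px = 20,
                            shadow_brightness_max = 315,
                            shadow_vegetation_radius_m = 1.0,
                            blue_ratio_min_water = 0.18) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg, is.finite, logical(1))))
  structure(cfg, class = "landscape_rules")
}

#' Rule thresholds for animal refinement (Step B)
#'
#' @param max_animal_px upper object size for one animal, pixels
#'   (default 10 = 2.5 m^2 at 0.5 m); larger candidate objects are split
#'   at local brightness minima.
#' @param centroid_buffer_m buffer radius around detection centroids
#'   (default 0.5 m, the cell size); intersecting buffers merge.
#' @param herd_max_nn_dist_m detections farther than this from every
#'   other detection are discarded (default 10 m).
#' @param brightness_max hard brightness ceiling (default 315).
#' @param brightness_soft_max detections with brightness in
#'   (`brightness_max`, `brightness_soft_max`\] survive only with high
#'   local color contrast (default 325).
#' @param max_diff_min_soft max-difference floor for the soft brightness
#'   band (default 1.45).
#' @param watershed_tolerance_dn minima shallower than this are merged
#'   before splitting oversized objects (default 25 DN, about twice the
#'   per-pixel brightness noise of 11-bit imagery, so splits happen only
#'   at real brightness ridges, not at noise minima).
#' @param iterative_herd_filter re-apply the isolation rule until stable
#'   instead of a single pass against the pre-filter set.
#' @return A list of class `animal_rules`.
#' @export
animal_rules <- function(max_animal_px = 10, centroid_buffer_m = 0.5,
                         herd_max_nn_dist_m = 10.0, brightness_max = 315,
                         brightness_soft_max = 325, max_diff_min_soft = 1.45,
                         watershed_tolerance_dn = 25,
                         iterative_herd_filter = FALSE) {
  structure(as.list(environment()), class = "animal_rules")
}

#' Classify landscape segments (Step A)
#'
#' Applies the landscape rule set to a segmented image, in the fixed
#' order vegetation, water, shadow (shadow needs vegetation labels
#' first):
#' \itemize{
#'   \item vegetation: NDVI >= `ndvi_min` and area >= the size floor;
#'   \item water: blue ratio >= `blue_ratio_min_water` and area floor;
#'   \item shadow: brightness <= `shadow_brightness_max`, area floor,
#'     and vegetation within `shadow_vegetation_radius_m`;
#'   \item everything else: open.
#' }
#'
#' @param segments a `segment_layer` with computed features.
#' @param config a [landscape_rules()].
#' @return The `segment_layer` with a `class` column added to its
#'   features (`vegetation`, `water`, `shadow`, `open`).
#' @export
classify_landscape <- function(segments, config = landscape_rules()) {
  f <- segments$features
  if (is.null(f) || !nrow(f)) stop("segment features missing")
  big <- f$area_px >= config$min_landscape_area_px
  cls <- rep("open", nrow(f))
  cls[big & f$ndvi >= config$ndvi_min] <- "vegetation"
  cls[cls == "open" & big &
        f$blue_ratio >= config$blue_ratio_min_water] <- "water"
  shadow_cand <- cls == "open" & big &
    f$brightness <= config$shadow_brightness_max
  if (any(shadow_cand) && any(cls == "vegetation")) {
    dveg <- dist_to_mask(segments$segment_ids,
                         f$id[cls == "vegetation"]) * segments$cell_size_m
    mind <- segment_min_dist(segments$segment_ids, dveg, nrow(f))
    cls[shadow_cand & mind <= config$shadow_vegetation_radius_m] <- "shadow"
  }
  segments$features$class <- cls
  segments
}

## per-pixel euclidean distance (in px) to the nearest pixel of the given
## segment ids
dist_to_mask <- function(ids, mask_ids) {
  m <- matrix(1, nrow(ids), ncol(ids))
  m[ids %in% mask_ids] <- 0
  d <- EBImage::distmap(m)
  matrix(d, nrow(ids), ncol(ids))
}

segment_min_dist <- function(ids, distmat, k) {
  inm <- ids > 0
  v <- tapply(distmat[inm], ids[inm], min)
  out <- rep(Inf, k)
  out[as.integer(names(v))] <- v
  out
}

#' Clip pixel candidates to open terrain (Step B, first move)
#'
#' Candidate animal pixels that fall on landscape segments classified as
#' vegetation, shadow or water are relabeled to that landscape class;
#' everything else is unchanged.
#'
#' @param class_raster a [class_raster()] from [classify_pixels()].
#' @param landscape a [classify_landscape()] output on the same grid.
#' @param candidate_class name of the candidate class (default
#'   `"animal"`).
#' @return The clipped [class_raster()].
#' @export
clip_candidates <- function(class_raster, landscape,
                            candidate_class = "animal") {
  stopifnot(inherits(class_raster, "class_raster"))
  if (!all(dim(class_raster$labels) == dim(landscape$segment_ids))) {
    stop("grid mismatch between class raster and landscape segmentation")
  }
  tab <- class_raster$class_table
  cand_id <- tab[[candidate_class]]
  if (is.null(cand_id)) stop("candidate class not in class table")
  for (lc in c("vegetation", "shadow", "water")) {
    if (!lc %in% names(tab)) tab[lc] <- max(tab) + 1L
  }
  seg_class <- landscape$features$class
  lab <- class_raster$labels
  px_class <- matrix("", nrow(lab), ncol(lab))
  inm <- landscape$segment_ids > 0
  px_class[inm] <- seg_class[landscape$segment_ids[inm]]
  for (lc in c("vegetation", "shadow", "water")) {
    hit <- lab == cand_id & px_class == lc
    lab[hit] <- tab[[lc]]
  }
  class_raster(lab, tab, class_raster$cell_size_m, class_raster$origin)
}

#' Split oversized candidate objects (Step B)
#'
#' Candidate objects larger than `max_animal_px` are split into
#' sub-objects by marker-based watershed on their per-pixel brightness
#' surface (markers are the regional brightness minima, after merging
#' minima shallower than `watershed_tolerance_dn`).  Objects at or below
#' the size cap, and oversized objects with no interior brightness
#' minimum (which cannot be split), pass through unchanged; the latter
#' are kept and flagged rather than dropped.
#'
#' @param segments candidate `segment_layer` with features.
#' @param raster the [mb_raster()] the candidates live on.
#' @param config an [animal_rules()].
#' @return A `segment_layer` with updated ids/features and a logical
#'   `oversized_unsplit` feature column.
#' @export
split_oversized <- function(segments, raster, config = animal_rules()) {
  f <- segments$features
  if (is.null(f) || !nrow(f)) return(segments)
  ids <- segments$segment_ids
  bright <- apply(raster$bands, c(1, 2), mean)
  over <- f$id[f$area_px > config$max_animal_px]
  next_id <- max(ids)
  for (sid in over) {
    pix <- which(ids == sid, arr.ind = TRUE)
    rr <- range(pix[, 1]); cr <- range(pix[, 2])
    sub <- matrix(0, diff(rr) + 1, diff(cr) + 1)
    loc <- cbind(pix[, 1] - rr[1] + 1, pix[, 2] - cr[1] + 1)
    bvals <- bright[pix]
    sub[loc] <- max(bvals) - bvals + 1  # minima -> peaks, outside = 0
    ws <- EBImage::watershed(EBImage::as.Image(sub),
                             tolerance = config$watershed_tolerance_dn,
                             ext = 1)
    wl <- matrix(EBImage::imageData(ws), nrow(sub), ncol(sub))
    parts <- wl[loc]
    if (length(unique(parts[parts > 0])) > 1) {
      ## unlabeled plateau pixels (rare) join part 1
      parts[parts == 0] <- 1
      newids <- ifelse(parts == 1, sid, next_id + parts - 1)
      next_id <- max(next_id, max(newids))
      ids[pix] <- newids
    }
  }
  ## compact relabel and recompute features
  relab <- sort(unique(ids[ids > 0]))
  ids[ids > 0] <- match(ids[ids > 0], relab)
  out <- structure(list(segment_ids = ids,
                        cell_size_m = segments$cell_size_m,
                        origin = segments$origin, features = NULL,
                        params = segments$params),
                   class = "segment_layer")
  out <- compute_features(raster, out)
  out$features$oversized_unsplit <-
    out$features$area_px > config$max_animal_px
  out
}

#' Detection sets
#'
#' A `detection_set` holds the per-animal objects surviving the rule
#' engine: centroids (map meters), pixel footprints, object features and
#' an audit trail of the rules each detection passed.
#'
#' @param segments a candidate `segment_layer` with features.
#' @param drop optional logical vector of segments to exclude.
#' @return A list of class `detection_set` with a `detections` data
#'   frame, a `pixels` list and an `audit` list of per-stage counts.
#' @export
detections_from_segments <- function(segments, drop = NULL) {
  f <- segments$features
  if (is.null(f) || !nrow(f)) {
    return(empty_detection_set(segments$cell_size_m, segments$origin))
  }
  keep <- if (is.null(drop)) rep(TRUE, nrow(f)) else !drop
  f <- f[keep, , drop = FALSE]
  nb <- grep("^mean_", names(f), value = TRUE)
  det <- data.frame(id = seq_len(nrow(f)), x = f$x, y = f$y,
                    area_px = f$area_px, brightness = f$brightness,
                    max_diff = f$max_diff,
                    oversized = if (!is.null(f$oversized_unsplit))
                      f$oversized_unsplit else FALSE,
                    admitted_by = "", stringsAsFactors = FALSE)
  det[nb] <- f[nb]
  structure(list(detections = det,
                 pixels = segment_pixels(segments$segment_ids, f$id),
                 cell_size_m = segments$cell_size_m,
                 origin = segments$origin,
                 audit = list(initial = nrow(det))),
            class = "detection_set")
}

empty_detection_set <- function(cell_size_m = 0.5, origin = c(0, 0)) {
  structure(list(detections = data.frame(id = integer(0), x = numeric(0),
                                         y = numeric(0),
                                         area_px = integer(0),
                                         brightness = numeric(0),
                                         max_diff = numeric(0),
                                         oversized = logical(0),
                                         admitted_by = character(0)),
                 pixels = list(), cell_size_m = cell_size_m,
                 origin = origin, audit = list(initial = 0L)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d detection(s)\n", nrow(x$detections)))
  if (length(x$audit)) {
    cat("  stage counts:",
        paste(names(x$audit), unlist(x$audit), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Merge detections whose centroid buffers intersect (Step B)
#'
#' Disks of radius `centroid_buffer_m` around the centroids are unioned
#' transitively: groups of detections with pairwise centroid distances
#' below twice the buffer radius collapse to a single detection at the
#' area-weighted mean centroid with the merged footprint; band means are
#' combined area-weighted, and brightness/max-difference recomputed.
#'
#' @param det a `detection_set`.
#' @param config an [animal_rules()].
#' @return The merged `detection_set`.
#' @export
merge_centroid_buffers <- function(det, config = animal_rules()) {
  d <- det$detections
  if (nrow(d) < 2) {
    det$audit$buffer_merge <- nrow(d)
    return(det)
  }
  thr <- 2 * config$centroid_buffer_m
  comp <- dist_components(d$x, d$y, thr, strict = TRUE)
  nb <- grep("^mean_", names(d), value = TRUE)
  rows <- lapply(split(seq_len(nrow(d)), comp), function(idx) {
    w <- d$area_px[idx] / sum(d$area_px[idx])
    r <- d[idx[1], , drop = FALSE]
    r$x <- sum(w * d$x[idx]); r$y <- sum(w * d$y[idx])
    r$area_px <- sum(d$area_px[idx])
    for (b in nb) r[[b]] <- sum(w * d[[b]][idx])
    if (length(nb)) {
      bm <- unlist(r[nb])
      r$brightness <- mean(bm)
      r$max_diff <- if (r$brightness > 0)
        (max(bm) - min(bm)) / r$brightness else 0
    } else {
      r$brightness <- sum(w * d$brightness[idx])
    }
    r$oversized <- any(d$oversized[idx])
    r
  })
  merged <- do.call(rbind, rows)
  merged$id <- seq_len(nrow(merged))
  pixels <- lapply(split(seq_len(nrow(d)), comp), function(idx) {
    do.call(rbind, det$pixels[idx])
  })
  det$detections <- merged
  det$pixels <- unname(pixels)
  det$audit$buffer_merge <- nrow(merged)
  det
}

## 8-connected component labels of a logical mask (integer matrix,
## 0 outside the mask, components numbered 1..K in raster order)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  parent <- seq_along(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + sh[1]; c2 <- c + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    a <- which(ok)[nb > 0]; b <- nb[nb > 0]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labs <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  out[idx] <- labs
  out
}

## connected components of the "distance < thr" (or <= thr) graph
dist_components <- function(x, y, thr, strict = FALSE) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  A <- if (strict) D < thr else D <= thr
  comp <- integer(n); cur <- 0
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1
    queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (comp[j] > 0) next
      comp[j] <- cur
      queue <- c(queue, which(A[j, ] & comp == 0))
    }
  }
  comp
}

#' Remove isolated detections (Step B herd rule)
#'
#' Large migratory savannah ungulates occur in herds, so a detection
#' whose nearest neighbor is farther than `herd_max_nn_dist_m` (10 m) is
#' discarded.  Distances are centroid-to-centroid, computed in a single
#' pass against the pre-filter detection set; a lone detection (no
#' neighbor at all) is treated as infinitely isolated and removed.  Set
#' `config$iterative_herd_filter` to re-apply the rule until stable.
#'
#' @param det a `detection_set`.
#' @param config an [animal_rules()].
#' @return The filtered `detection_set`.
#' @export
herd_filter <- function(det, config = animal_rules()) {
  repeat {
    d <- det$detections
    n <- nrow(d)
    if (n == 0) break
    if (n == 1) {
      det <- subset_detections(det, logical(1))
      break
    }
    D <- as.matrix(dist(cbind(d$x, d$y)))
    diag(D) <- Inf
    nn <- apply(D, 1, min)
    keep <- nn <= config$herd_max_nn_dist_m
    det <- subset_detections(det, keep)
    if (!config$iterative_herd_filter || all(keep)) break
  }
  det$audit$herd_filter <- nrow(det$detections)
  det
}

subset_detections <- function(det, keep) {
  det$detections <- det$detections[keep, , drop = FALSE]
  if (nrow(det$detections)) {
    det$detections$id <- seq_len(nrow(det$detections))
  }
  det$pixels <- det$pixels[keep]
  det
}

#' Brightness gate (Step B layer-value rule)
#'
#' Keeps a detection if its brightness is below `brightness_max` (315),
#' or if brightness lies in the closed band
#' \[`brightness_max`, `brightness_soft_max`\] (315-325) *and* its
#' max-difference exceeds `max_diff_min_soft` (1.45) — animals whose
#' objects absorbed some bright surrounding pixels still show strong
#' local color contrast.  The audit trail records which branch admitted
#' each detection.
#'
#' @param det a `detection_set`.
#' @param config an [animal_rules()].
#' @return The filtered `detection_set`.
#' @export
brightness_gate <- function(det, config = animal_rules()) {
  d <- det$detections
  dark <- d$brightness < config$brightness_max
  soft <- d$brightness >= config$brightness_max &
    d$brightness <= config$brightness_soft_max &
    d$max_diff > config$max_diff_min_soft
  det$detections$admitted_by[dark] <- "brightness"
  det$detections$admitted_by[soft & !dark] <- "soft_band_max_diff"
  det <- subset_detections(det, dark | soft)
  det$audit$brightness_gate <- nrow(det$detections)
  det
}

#' Refine pixel candidates into animal detections (Step B)
#'
#' The full object-based refinement: clip candidates to open terrain,
#' segment the surviving candidate mask at the animal segmentation
#' parameters (the mask acts as a thematic constraint), compute object
#' features, drop objects adjacent to vegetation, split oversized
#' objects at brightness minima, merge intersecting centroid buffers,
#' apply the herd-isolation rule and the brightness gate.  Every stage
#' count is recorded in the audit trail.
#'
#' @param class_raster pixel classification ([classify_pixels()]).
#' @param landscape classified landscape segmentation
#'   ([classify_landscape()]).
#' @param raster the pan-sharpened [mb_raster()].
#' @param seg_params animal-object [seg_params()] (default
#'   [animal_seg_params()]).
#' @param config an [animal_rules()].
#' @param candidate_class candidate class name (default `"animal"`).
#' @return A `detection_set`.
#' @export
refine_animals <- function(class_raster, landscape, raster,
                           seg_params = animal_seg_params(),
                           config = animal_rules(),
                           candidate_class = "animal") {
  clipped <- clip_candidates(class_raster, landscape, candidate_class)
  cand <- clipped$labels == clipped$class_table[[candidate_class]]
  audit <- list(candidate_px = sum(cand))
  if (!any(cand)) {
    out <- empty_detection_set(raster$cell_size_m, raster$origin)
    out$audit <- c(audit, out$audit)
    return(out)
  }
  ## thematic polygons: 8-connected components of the candidate mask (an
  ## animal and its attached shadow image as one polygon)
  comp <- label_components8(cand)
  them <- matrix(NA_integer_, nrow(cand), ncol(cand))
  them[cand] <- comp[cand]
  aseg <- multiresolution_segment(raster, seg_params, thematic = them)
  audit$candidate_subobjects <- nrow(aseg$features)
  ## objects are the thematic polygons: union the sub-segments of each
  ## polygon into one object, as when segmenting with a thematic layer
  aseg$segment_ids <- them
  aseg$segment_ids[!cand] <- 0L
  aseg <- compute_features(raster, aseg)
  audit$candidate_objects <- nrow(aseg$features)

  ## exclusion: objects next to vegetated areas (sharing a 4-connectivity
  ## boundary with vegetation, or centroid within one cell of it)
  veg_ids <- landscape$features$id[landscape$features$class == "vegetation"]
  if (length(veg_ids)) {
    dveg <- dist_to_mask(landscape$segment_ids, veg_ids)
    mind <- segment_min_dist(aseg$segment_ids, dveg, nrow(aseg$features))
    crow <- map_to_row(aseg, aseg$features$y)
    ccol <- map_to_col(aseg, aseg$features$x)
    cdist <- dveg[cbind(pmin(pmax(crow, 1), nrow(dveg)),
                        pmin(pmax(ccol, 1), ncol(dveg)))]
    near_veg <- mind <= 1 | cdist <= 1
    keep_ids <- aseg$features$id[!near_veg]
    ids <- aseg$segment_ids
    ids[!(ids %in% keep_ids)] <- 0L
    if (length(keep_ids)) ids[ids > 0] <- match(ids[ids > 0], sort(keep_ids))
    aseg$segment_ids <- ids
    aseg <- compute_features(raster, aseg)
  }
  audit$not_near_vegetation <- nrow(aseg$features)
  if (!nrow(aseg$features)) {
    out <- empty_detection_set(raster$cell_size_m, raster$origin)
    out$audit <- c(audit, out$audit)
    return(out)
  }

  aseg <- split_oversized(aseg, raster, config)
  audit$after_split <- nrow(aseg$features)
  det <- detections_from_segments(aseg)
  det$audit <- audit
  det <- merge_centroid_buffers(det, config)
  det <- herd_filter(det, config)
  det <- brightness_gate(det, config)
  det
}

#' Export detections as GeoJSON points
#'
#' @param det a `detection_set`.
#' @param path output path.
#' @export
write_detections_geojson <- function(det, path) {
  d <- det$detections
  write_geojson_points(point_set(d$x, d$y, id = d$id, area_px = d$area_px,
                                 brightness = d$brightness,
                                 max_diff = d$max_diff,
                                 admitted_by = d$admitted_by), path)
}
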