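#' Segmentation parameters
#'
#' Parameters of the multi-resolution region-merging segmentation.  The
#' defaults carry the two parameter rows used by the pipeline: landscape
#' objects (`scale 20`, layer weights `1,1,1,2` over B,G,R,NIR,
#' shape/color `0.2/0.8`, compactness/smoothness `0.5/0.5`) and animal
#' objects (`scale 6`, weights `1,1,1,1`, `0.1/0.9`, `0.5/0.5`).
#'
#' @param scale scale parameter; merging stops once the cheapest merge
#'   would increase heterogeneity by at least `scale^2`.
#' @param layer_weights non-negative per-band color weights.
#' @param shape_weight weight of the shape term in \[0, 1\] (color gets
#'   `1 - shape_weight`).
#' @param compactness_weight weight of compactness vs smoothness.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(scale, layer_weights = c(1, 1, 1, 1),
                       shape_weight = 0.2, compactness_weight = 0.5) {
  stopifnot(scale > 0, all(layer_weights >= 0),
            shape_weight >= 0, shape_weight <= 1,
            compactness_weight >= 0, compactness_weight <= 1)
  structure(list(scale = scale, layer_weights = layer_weights,
                 shape_weight = shape_weight,
                 compactness_weight = compactness_weight),
            class = "seg_params")
}

#' @rdname seg_params
#' @export
landscape_seg_params <- function() {
  seg_params(scale = 20, layer_weights = c(1, 1, 1, 2),
             shape_weight = 0.2, compactness_weight = 0.5)
}

#' @rdname seg_params
#' @export
animal_seg_params <- function() {
  seg_params(scale = 6, layer_weights = c(1, 1, 1, 1),
             shape_weight = 0.1, compactness_weight = 0.5)
}

#' Multi-resolution region-merging segmentation
#'
#' Bottom-up pairwise region merging under the combined color/shape
#' heterogeneity criterion: a merge of regions 1 and 2 costs
#' \deqn{f = (1-w_s)\sum_b w_b (n_m \sigma_{b,m} - n_1 \sigma_{b,1} -
#'   n_2 \sigma_{b,2}) + w_s \, \Delta h_{shape}}
#' where the shape term mixes compactness (perimeter / sqrt(area)) and
#' smoothness (perimeter / bounding-box perimeter), each n-weighted.
#' Merging proceeds by local mutual best fitting while the cost is below
#' `scale^2`, with ties broken toward the smallest region id, so the
#' partition is deterministic.  An optional thematic layer constrains
#' merges: regions never grow across thematic boundaries, and pixels
#' with thematic value `NA` are excluded (segment id 0).
#'
#' @param raster an [mb_raster()].
#' @param params a [seg_params()].
#' @param thematic optional integer matrix (same grid) of thematic
#'   labels, `NA` = excluded.
#' @param features compute object features on completion (default TRUE).
#' @return A `segment_layer`: list with `segment_ids` (integer matrix,
#'   0 = excluded), `cell_size_m`, `origin`, and (if requested) a
#'   `features` data frame from [compute_features()].
#' @export
multiresolution_segment <- function(raster, params, thematic = NULL,
                                    features = TRUE) {
  stopifnot(inherits(raster, "mb_raster"), inherits(params, "seg_params"))
  d <- dim(raster$bands)
  stopifnot(length(params$layer_weights) == d[3])
  if (is.null(thematic)) {
    thematic <- matrix(0L, d[1], d[2])
  } else {
    stopifnot(all(dim(thematic) == d[1:2]))
    thematic <- matrix(as.integer(thematic), d[1], d[2])
  }
  thematic[is.na(thematic)] <- -1L
  ids <- segment_mrs_cpp(as.numeric(raster$bands), as.integer(d),
                         as.numeric(params$layer_weights), params$scale,
                         params$shape_weight, params$compactness_weight,
                         thematic)
  seg <- structure(list(segment_ids = ids, cell_size_m = raster$cell_size_m,
                        origin = raster$origin, features = NULL,
                        params = params),
                   class = "segment_layer")
  if (features) seg <- compute_features(raster, seg)
  seg
}

#' @export
print.segment_layer <- function(x, ...) {
  k <- max(x$segment_ids)
  cat(sprintf("<segment_layer> %d x %d px, %d segment(s)\n",
              nrow(x$segment_ids), ncol(x$segment_ids), k))
  invisible(x)
}

#' Object features of a segmentation
#'
#' Per segment: per-band mean DNs; `brightness` (arithmetic mean of the
#' band means); `ndvi` = (NIR - red)/(NIR + red) of the band means (0
#' when NIR + red = 0); `blue_ratio` = blue / (blue + green + red + NIR);
#' `max_diff` = (max band mean - min band mean) / brightness (0 when
#' brightness is 0) — a normalized local color contrast; pixel and
#' square-meter area; area-weighted centroid in map meters; and the
#' 4-connectivity neighbor list.
#'
#' @param raster the [mb_raster()] the segmentation partitions.
#' @param segments a `segment_layer`.
#' @return The `segment_layer` with `features` (data frame, one row per
#'   segment id) and `neighbors` (list of integer vectors) filled.
#' @export
compute_features <- function(raster, segments) {
  stopifnot(inherits(segments, "segment_layer"))
  ids <- segments$segment_ids
  d <- dim(raster$bands)
  stopifnot(all(dim(ids) == d[1:2]))
  inmask <- ids > 0
  id_v <- ids[inmask]
  if (!length(id_v)) {
    segments$features <- data.frame()
    segments$neighbors <- list()
    return(segments)
  }
  k <- max(id_v)
  area <- tabulate(id_v, nbins = k)
  bm <- matrix(0, k, d[3])
  for (b in seq_len(d[3])) {
    v <- raster$bands[, , b][inmask]
    bm[, b] <- rowsum(v, id_v, reorder = TRUE)[, 1] / area[area > 0]
  }
  rr <- row(ids)[inmask]; cc <- col(ids)[inmask]
  cx <- rowsum(px_center_x(segments, cc), id_v)[, 1] / area[area > 0]
  cy <- rowsum(px_center_y(segments, rr), id_v)[, 1] / area[area > 0]
  brightness <- rowMeans(bm)
  nir <- bm[, min(4, d[3])]; red <- bm[, min(3, d[3])]
  ndvi <- ifelse(nir + red == 0, 0, (nir - red) / (nir + red))
  tot <- rowSums(bm)
  blue_ratio <- ifelse(tot == 0, 0, bm[, 1] / tot)
  spread <- apply(bm, 1, max) - apply(bm, 1, min)
  max_diff <- ifelse(brightness == 0, 0, spread / brightness)
  feats <- data.frame(id = seq_len(k), area_px = area,
                      area_m2 = area * segments$cell_size_m^2,
                      brightness = brightness, ndvi = ndvi,
                      blue_ratio = blue_ratio, max_diff = max_diff,
                      x = cx, y = cy)
  colnames(bm) <- paste0("mean_", raster$band_names)
  feats <- cbind(feats, bm)
  segments$features <- feats
  segments$neighbors <- segment_neighbors(ids, k)
  segments
}

## 4-connectivity adjacency between positive segment ids
segment_neighbors <- function(ids, k = max(ids)) {
  pr <- cbind(as.vector(ids[-nrow(ids), ]), as.vector(ids[-1, ]))
  pc <- cbind(as.vector(ids[, -ncol(ids)]), as.vector(ids[, -1]))
  p <- rbind(pr, pc)
  p <- p[p[, 1] != p[, 2] & p[, 1] > 0 & p[, 2] > 0, , drop = FALSE]
  p <- unique(rbind(p, p[, 2:1]))
  out <- rep(list(integer(0)), k)
  if (nrow(p)) {
    sp <- split(p[, 2], p[, 1])
    out[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  out
}

## pixel index sets per segment (list of n x 2 [row, col] matrices)
segment_pixels <- function(ids, which_ids) {
  idx <- which(ids > 0)
  sp <- split(idx, ids[idx])
  lapply(as.character(which_ids), function(i) {
    lin <- sp[[i]]
    cbind((lin - 1) %% nrow(ids) + 1, (lin - 1) %/% nrow(ids) + 1)
  })
}
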