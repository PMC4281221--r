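#' Multiband raster objects
#'
#' A lightweight in-memory raster: a `row x col x band` array of digital
#' numbers (DNs) with a square-pixel, axis-aligned georeference.  Pixel
#' `(r, c)` (0-based in map arithmetic, 1-based for R indexing) covers the
#' half-open map square starting at the raster origin, which is the map
#' coordinate of the *outer corner* of the first pixel; row index increases
#' southward.
#'
#' @param bands numeric array `nrow x ncol x nband`, or a matrix for a
#'   single band.
#' @param cell_size_m positive cell size in meters per pixel side.
#' @param origin numeric length-2, map `(x, y)` of the outer corner of
#'   pixel (1, 1).
#' @param band_names character vector, one per band.  The canonical order
#'   for 4-band imagery is `c("blue", "green", "red", "nir")`.
#' @param nodata optional sentinel value.
#' @param dn_range length-2 radiometric range; defaults to 11-bit
#'   `c(0, 2047)` as delivered for the sensor class modeled here.
#' @return An object of class `mb_raster`.
#' @export
mb_raster <- function(bands, cell_size_m, origin = c(0, 0),
                      band_names = NULL, nodata = NULL,
                      dn_range = c(0, 2047)) {
  if (is.matrix(bands)) bands <- array(bands, c(dim(bands), 1L))
  stopifnot(is.array(bands), length(dim(bands)) == 3L)
  if (dim(bands)[3] < 1L) stop("raster must have at least one band")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L ||
      cell_size_m <= 0) {
    stop("cell_size_m must be a positive scalar")
  }
  if (is.null(band_names)) {
    band_names <- if (dim(bands)[3] == 4L) c("blue", "green", "red", "nir")
                  else paste0("band", seq_len(dim(bands)[3]))
  }
  stopifnot(length(band_names) == dim(bands)[3])
  structure(list(bands = bands, cell_size_m = as.numeric(cell_size_m),
                 origin = as.numeric(origin), band_names = band_names,
                 nodata = nodata, dn_range = as.numeric(dn_range)),
            class = "mb_raster")
}

#' @export
print.mb_raster <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf("<mb_raster> %d x %d pixels, %d band(s) [%s], %.3g m/px\n",
              d[1], d[2], d[3], paste(x$band_names, collapse = ","),
              x$cell_size_m))
  cat(sprintf("  origin (%.2f, %.2f), DN range [%g, %g]\n",
              x$origin[1], x$origin[2], x$dn_range[1], x$dn_range[2]))
  invisible(x)
}

#' @export
dim.mb_raster <- function(x) dim(x$bands)

n_bands <- function(r) dim(r$bands)[3]

#' Per-pixel class labels
#'
#' Integer class labels on the same grid convention as [mb_raster()].
#'
#' @param labels integer matrix of labels (0 = unlabeled is permitted).
#' @param class_table named integer vector mapping class name -> label.
#' @param cell_size_m,origin georeference, as for [mb_raster()].
#' @return An object of class `class_raster`.
#' @export
class_raster <- function(labels, class_table, cell_size_m, origin = c(0, 0)) {
  stopifnot(is.matrix(labels))
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(present %in% class_table)) {
    stop("labels present in grid but missing from class_table")
  }
  structure(list(labels = labels, class_table = class_table,
                 cell_size_m = as.numeric(cell_size_m),
                 origin = as.numeric(origin)),
            class = "class_raster")
}

#' @export
print.class_raster <- function(x, ...) {
  cat(sprintf("<class_raster> %d x %d, classes: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(names(x$class_table), collapse = ", ")))
  invisible(x)
}

#' Labeled point sets
#'
#' @param x,y map coordinates (meters).
#' @param ... further per-point attribute vectors (e.g. `class`, `id`,
#'   `split`), recycled to length of `x`.
#' @return A `data.frame` with class `point_set`.
#' @export
point_set <- function(x, y, ...) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), ...,
                   stringsAsFactors = FALSE)
  if (!is.null(df$id) && anyDuplicated(df$id)) stop("point ids must be unique")
  class(df) <- c("point_set", "data.frame")
  df
}

## map <-> pixel helpers (pixel centers; r, c are 1-based R indices)
px_center_x <- function(r, c) r$origin[1] + (c - 0.5) * r$cell_size_m
px_center_y <- function(r, rw) r$origin[2] - (rw - 0.5) * r$cell_size_m
map_to_col <- function(r, x) floor((x - r$origin[1]) / r$cell_size_m) + 1L
map_to_row <- function(r, y) floor((r$origin[2] - y) / r$cell_size_m) + 1L

#' Read a georeferenced TIFF raster
#'
#' Reads a single- or multi-band TIFF together with its ESRI world-file
#' sidecar (`.tfw`), which carries the affine georeference.  Only
#' axis-aligned, square-pixel geotransforms are supported; a rotated or
#' rectangular-pixel world file is rejected.  Integer rasters written by
#' [write_geotiff()] round-trip bit-identically.
#'
#' @param path file path of the `.tif`.
#' @param dn_range radiometric range recorded on the returned raster.
#' @return An [mb_raster()].
#' @export
read_geotiff <- function(path, dn_range = c(0, 2047)) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] < 1L) stop("raster has 0 bands")
  meta <- read_world_file(path)
  if (meta$rot != 0) stop("unsupported geotransform: rotated pixels")
  if (abs(meta$sx + meta$sy) > 1e-9 * abs(meta$sx)) {
    stop("unsupported geotransform: non-square pixels")
  }
  att <- read_raster_sidecar(path)
  ## 16-bit files may come back as raw integers (as.is honored) or as
  ## [0,1] doubles depending on the photometric layout; float32 files
  ## always need the stored scale undone
  bands <- if (att$bits == 16 && is.integer(img)) img + 0
           else img * att$scale
  mb_raster(bands, cell_size_m = meta$sx,
            origin = c(meta$x0, meta$y0),
            band_names = att$band_names, nodata = att$nodata,
            dn_range = if (is.null(att$dn_range)) dn_range else att$dn_range)
}

#' Write a georeferenced TIFF raster
#'
#' DN grids with all-integer values in \[0, 65535\] are stored as 16-bit
#' unsigned samples (lossless round trip); anything else is stored as
#' 32-bit float.  The georeference goes into an ESRI world file (`.tfw`)
#' and band names / nodata into a small JSON sidecar (`.aux.json`).
#'
#' @param raster an [mb_raster()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(raster, path) {
  stopifnot(inherits(raster, "mb_raster"))
  b <- raster$bands
  intish <- all(is.finite(b)) && all(b == round(b)) && min(b) >= 0 &&
    max(b) <= 65535
  if (intish) {
    tiff::writeTIFF(b / 65535, path, bits.per.sample = 16L)
    scale <- 65535; bits <- 16L
  } else {
    ## float32 storage: keep magnitudes well inside float range
    tiff::writeTIFF(b / 65536, path, bits.per.sample = 32L)
    scale <- 65536; bits <- 32L
  }
  write_world_file(path, raster$cell_size_m, raster$origin)
  sidecar <- list(band_names = raster$band_names, scale = scale,
                  bits = bits, nodata = raster$nodata,
                  dn_range = raster$dn_range)
  jsonlite::write_json(sidecar, paste0(path, ".aux.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

world_path <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)

write_world_file <- function(path, cell, origin) {
  ## world file lines: sx, rot, rot, -sy, x-center(1,1), y-center(1,1)
  lines <- formatC(c(cell, 0, 0, -cell,
                     origin[1] + cell / 2, origin[2] - cell / 2),
                   format = "fg", digits = 12)
  writeLines(lines, world_path(path))
}

read_world_file <- function(path) {
  wf <- world_path(path)
  if (!file.exists(wf)) stop("missing world file: ", wf)
  v <- as.numeric(readLines(wf))
  list(sx = v[1], rot = abs(v[2]) + abs(v[3]), sy = v[4],
       x0 = v[5] - v[1] / 2, y0 = v[6] - v[4] / 2)
}

read_raster_sidecar <- function(path) {
  sc <- paste0(path, ".aux.json")
  if (!file.exists(sc)) {
    return(list(band_names = NULL, scale = 1, bits = 16L, nodata = NULL,
                dn_range = NULL))
  }
  j <- jsonlite::read_json(sc, simplifyVector = TRUE)
  list(band_names = j$band_names, scale = j$scale,
       bits = j$bits %||% 16L, nodata = j$nodata, dn_range = j$dn_range)
}

#' 3 x 3 low-pass (mean) smoothing
#'
#' Convolves every band with the uniform 3 x 3 mean kernel.  Borders use
#' reflect (edge-repeat) padding, so output dimensions equal input
#' dimensions and a constant band passes through unchanged.
#'
#' @param raster an [mb_raster()].
#' @return The smoothed [mb_raster()].
#' @export
lowpass_3x3 <- function(raster) {
  stopifnot(inherits(raster, "mb_raster"))
  out <- raster
  for (k in seq_len(n_bands(raster))) {
    out$bands[, , k] <- mean3x3(raster$bands[, , k])
  }
  out
}

mean3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # reflect pad by 1
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
  }
  acc / 9
}

#' Cubic-convolution resampling
#'
#' Resamples every band to a new cell size with Keys' cubic-convolution
#' kernel (a = -0.5), evaluated at the pixel centers of the target grid.
#' The output covers the same map extent; border support outside the
#' source grid uses edge replication.  Cubic convolution reproduces
#' constants exactly and linear ramps exactly away from the replicated
#' border.
#'
#' @param raster an [mb_raster()].
#' @param target_cell_size_m positive target cell size in meters.
#' @return The resampled [mb_raster()].
#' @export
resample_cubic <- function(raster, target_cell_size_m) {
  stopifnot(inherits(raster, "mb_raster"), target_cell_size_m > 0)
  d <- dim(raster$bands)
  nr_out <- round(d[1] * raster$cell_size_m / target_cell_size_m)
  nc_out <- round(d[2] * raster$cell_size_m / target_cell_size_m)
  if (nr_out < 1 || nc_out < 1) stop("degenerate output size")
  Wr <- keys_weights(d[1], nr_out, raster$cell_size_m, target_cell_size_m)
  Wc <- keys_weights(d[2], nc_out, raster$cell_size_m, target_cell_size_m)
  out <- array(0, c(nr_out, nc_out, d[3]))
  for (k in seq_len(d[3])) {
    out[, , k] <- Wr %*% raster$bands[, , k] %*% t(Wc)
  }
  mb_raster(out, cell_size_m = target_cell_size_m, origin = raster$origin,
            band_names = raster$band_names, nodata = raster$nodata,
            dn_range = raster$dn_range)
}

keys_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  ifelse(at <= 1, (a + 2) * at^3 - (a + 3) * at^2 + 1,
         ifelse(at < 2, a * at^3 - 5 * a * at^2 + 8 * a * at - 4 * a, 0))
}

## dense n_out x n_in interpolation weight matrix for one axis
keys_weights <- function(n_in, n_out, s_in, s_out) {
  W <- matrix(0, n_out, n_in)
  centers <- ((seq_len(n_out) - 0.5) * s_out) / s_in - 0.5  # 0-based src idx
  base <- floor(centers)
  for (j in -1:2) {
    idx <- base + j
    w <- keys_kernel(centers - idx)
    idx <- pmin(pmax(idx, 0), n_in - 1)  # replicate edges
    W[cbind(seq_len(n_out), idx + 1)] <-
      W[cbind(seq_len(n_out), idx + 1)] + w
  }
  W
}

## exact block-mean aggregation (used to build 2 m bands from 0.5 m scenes)
aggregate_mean <- function(raster, factor) {
  d <- dim(raster$bands)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  out <- array(0, c(nr, nc, d[3]))
  for (k in seq_len(d[3])) {
    m <- raster$bands[, , k]
    m <- matrix(colMeans(matrix(m, factor)), nr, ncol(m))   # rows
    m <- t(matrix(colMeans(matrix(t(m), factor)), nc, nr))  # cols
    out[, , k] <- m
  }
  mb_raster(out, cell_size_m = raster$cell_size_m * factor,
            origin = raster$origin, band_names = raster$band_names,
            nodata = raster$nodata, dn_range = raster$dn_range)
}

#' Read / write point and polygon layers as GeoJSON
#'
#' Minimal GeoJSON support for the vector layers the pipeline uses:
#' labeled sample points, ground-truth animal locations and detection
#' centroids.  Per-feature properties become data-frame columns.
#'
#' @param path GeoJSON file path.
#' @return For `read_geojson_points()`, a [point_set()].
#' @export
read_geojson_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path)
  feats <- j$features
  if (length(feats) == 0) return(point_set(numeric(0), numeric(0)))
  xy <- t(vapply(feats, function(f) {
    as.numeric(unlist(f$geometry$coordinates)[1:2])
  }, numeric(2)))
  props <- lapply(feats, function(f) f$properties)
  keys <- unique(unlist(lapply(props, names)))
  df <- point_set(xy[, 1], xy[, 2])
  for (k in keys) {
    df[[k]] <- sapply(props, function(p) {
      v <- p[[k]]
      if (is.null(v)) NA else v
    })
  }
  df
}

#' @rdname read_geojson_points
#' @param points a [point_set()] (or plain data frame with `x`, `y`).
#' @export
write_geojson_points <- function(points, path) {
  cols <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, cols, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
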