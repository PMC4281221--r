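## Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

## a small but complete synthetic scene plus its pan-sharpened image
small_scene <- function() {
  if (is.null(.fixture_env$scene)) {
    spec <- scene_spec(extent_m = c(120, 120), n_herds = 1,
                       animals_per_herd = c(24, 30), tree_density = 6,
                       water_fraction = 0.05, seed = 421)
    scn <- generate_scene(spec)
    scn$spec <- spec
    scn$sharp <- gram_schmidt_pansharpen(scn$ms, scn$pan)
    .fixture_env$scene <- scn
  }
  .fixture_env$scene
}

## a hand-buildable detection set (bare structure, documented fields)
make_detections <- function(x, y, area_px = rep(5L, length(x)),
                            brightness = rep(200, length(x)),
                            max_diff = rep(0.5, length(x)),
                            cell = 0.5) {
  structure(list(
    detections = data.frame(id = seq_along(x), x = x, y = y,
                            area_px = as.integer(area_px),
                            brightness = brightness, max_diff = max_diff,
                            oversized = rep(FALSE, length(x)),
                            admitted_by = rep("", length(x)),
                            stringsAsFactors = FALSE),
    pixels = replicate(length(x), cbind(1L, 1L), simplify = FALSE),
    cell_size_m = cell, origin = c(0, 100), audit = list()),
    class = "detection_set")
}

## segment layer built from an explicit id matrix and a feature table
make_segment_layer <- function(ids, features, cell = 0.5) {
  structure(list(segment_ids = ids, cell_size_m = cell,
                 origin = c(0, nrow(ids) * cell), features = features,
                 params = NULL),
            class = "segment_layer")
}

## a landscape layer with a vegetation block (cols 1-5), an unlabeled
## strip, and candidate shadow blocks at controlled distances
landscape_fixture <- function() {
  ids <- matrix(4L, 20, 30)                 # big open background
  ids[1:10, 1:5] <- 1L                      # vegetation, 50 px
  ids[1:10, 7:9] <- 2L                      # dark block, 1.0 m from veg
  ids[1:10, 11:13] <- 3L                    # dark block, 3.0 m from veg
  f <- data.frame(id = 1:4,
                  area_px = c(50, 30, 30, 490),
                  brightness = c(200, 300, 300, 500),
                  ndvi = c(0.7, 0.1, 0.1, 0.1),
                  blue_ratio = c(0.1, 0.15, 0.15, 0.15),
                  max_diff = 0.5,
                  x = 0, y = 0)
  make_segment_layer(ids, f)
}

## Gaussian 1-D class stats helper for JM tests
gauss_stats <- function(mu, var, n = 100) {
  herdspot:::new_class_stats("g", n, mu, matrix(var, 1, 1))
}

## numerical-integration Bhattacharyya oracle for 1-D Gaussians
jm_numeric_1d <- function(mu1, sd1, mu2, sd2) {
  bc <- integrate(function(x) {
    sqrt(dnorm(x, mu1, sd1) * dnorm(x, mu2, sd2))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  2 * (1 - bc)
}
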