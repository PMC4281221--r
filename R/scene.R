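## Synthetic savannah scene generator.
##
## Emulates the imaging situation the detection pipeline is built for: an
## 11-bit 4-band (blue, green, red, NIR) multispectral image at 2 m, a
## co-registered panchromatic band at 0.5 m, and ground truth for herds of
## large ungulates rendered as elongated dark blobs (3-4 pixels long,
## 1-2 pixels wide at 0.5 m) with attached shadows, placed in open terrain.

SCENE_CLASSES <- c(trees = 1L, grassland = 2L, bare_soil = 3L, sand = 4L,
                   water = 5L, shadow = 6L, animal = 7L)

## Default class spectra (band means and standard deviations, 11-bit DNs).
## Calibrated so that the animal class overlaps tree shadow in feature
## space (JM < 1.40) while separating cleanly (JM > 1.90) from every
## sunlit landscape class, and so that the object-rule thresholds
## (NDVI 0.6, blue ratio 0.18, brightness 315) fall on the intended side
## of every class.
default_class_spectra <- function() {
  list(
    trees     = list(mean = c(170, 260, 170, 1000), sd = c(18, 22, 20, 45)),
    grassland = list(mean = c(280, 430, 510, 630),  sd = c(20, 25, 28, 30)),
    bare_soil = list(mean = c(320, 470, 545, 610),  sd = c(22, 26, 28, 30)),
    sand      = list(mean = c(440, 630, 730, 810),  sd = c(25, 28, 30, 32)),
    water     = list(mean = c(360, 310, 230, 110),  sd = c(15, 15, 14, 12)),
    shadow    = list(mean = c(95, 138, 152, 228),   sd = c(14, 16, 16, 22)),
    animal    = list(mean = c(108, 146, 158, 232),  sd = c(20, 22, 22, 26))
  )
}

#' Specification of a synthetic savannah scene
#'
#' Bundles every tunable of the scene generator with defaults describing a
#' 250 m x 250 m open-savannah tile during ungulate migration: mostly dry
#' grassland with bare-soil and sand patches, scattered tree crowns with
#' cast shadows, an optional water body, and a small number of herds whose
#' animals are 1.5-2 m long and at most 1 m wide (3-4 x 1-2 pixels at
#' 0.5 m).
#'
#' @param extent_m width/height of the square scene in meters.
#' @param ms_cell_m,pan_cell_m multispectral / panchromatic cell sizes.
#' @param class_spectra per-class band means and standard deviations.
#' @param n_herds number of herds.
#' @param animals_per_herd inclusive integer range; herd sizes are drawn
#'   uniformly from it.
#' @param herd_spread_m standard deviation (m) of animal offsets from the
#'   herd center (Thomas-process-style cluster) for a reference herd of
#'   50 animals; the spread of each herd scales with the square root of
#'   its size, so within-herd packing density stays constant across herd
#'   sizes (large aggregations occupy more ground rather than packing
#'   tighter).
#' @param herd_anisotropy at least 1; stretches clusters along a random herd
#'   axis to approximate animals moving in lines.
#' @param animal_length_px,animal_width_px inclusive ranges at 0.5 m.
#' @param min_animal_spacing_m minimum distance between animal centroids.
#' @param shadow_offset_px integer (row, col) shift of tree shadows.
#' @param tree_density trees per hectare.
#' @param water_fraction fraction of the scene covered by water.
#' @param pan_weights band weights of the simulated panchromatic response.
#' @param seed integer RNG seed; the scene is a pure function of the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(extent_m = c(250, 250), ms_cell_m = 2, pan_cell_m = 0.5,
                       class_spectra = default_class_spectra(),
                       n_herds = 2, animals_per_herd = c(30, 100),
                       herd_spread_m = 12, herd_anisotropy = 1.5,
                       animal_length_px = c(3, 4), animal_width_px = c(1, 2),
                       min_animal_spacing_m = 2.5,
                       shadow_offset_px = c(3, 3),
                       tree_density = 5, water_fraction = 0.03,
                       pan_weights = c(0.1, 0.3, 0.4, 0.2),
                       seed = 1L) {
  stopifnot(water_fraction >= 0, water_fraction <= 1,
            tree_density >= 0, n_herds >= 0,
            all(animal_length_px >= 3), all(animal_length_px <= 4),
            all(animal_width_px >= 1), all(animal_width_px <= 2),
            abs(sum(pan_weights) - 1) < 1e-9, herd_anisotropy >= 1)
  for (cs in class_spectra) {
    stopifnot(all(cs$mean >= 0), all(cs$mean <= 2047))
  }
  structure(as.list(environment()), class = "scene_spec")
}

#' Generate a synthetic scene
#'
#' Paints the landscape as contiguous patches, places herds as clustered
#' point processes in open terrain (every animal is within 8 m of another
#' member of its herd, so within-herd nearest-neighbor distances never
#' exceed 10 m), renders each animal as an elongated blob at a uniformly
#' random orientation with an attached darker shadow, adds per-class
#' Gaussian DN noise, and derives the panchromatic band (weighted band
#' mean at 0.5 m) and the multispectral image (4 x 4 block aggregation to
#' 2 m).  Deterministic given `spec` (which includes the seed).
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `ms` (4-band 2 m [mb_raster()]), `pan`
#'   (1-band 0.5 m [mb_raster()]), and `truth`: a list with `animals`
#'   (a [point_set()] with `id`, `herd`), `footprints` (list of n x 2
#'   pixel index matrices on the pan grid), and `class_map` (0.5 m
#'   [class_raster()] of the true scene).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  s <- spec$pan_cell_m
  nr <- round(spec$extent_m[2] / s); nc <- round(spec$extent_m[1] / s)
  agg <- round(spec$ms_cell_m / spec$pan_cell_m)
  stopifnot(nr %% agg == 0, nc %% agg == 0)
  cls <- matrix(SCENE_CLASSES[["grassland"]], nr, nc)

  paint_ellipse <- function(cls, cr, cc, a, b, theta, value, over) {
    rr <- max(1, floor(cr - a - b)):min(nr, ceiling(cr + a + b))
    cc2 <- max(1, floor(cc - a - b)):min(nc, ceiling(cc + a + b))
    if (!length(rr) || !length(cc2)) return(cls)
    g <- expand.grid(r = rr, c = cc2)
    u <- (g$c - cc) * cos(theta) + (g$r - cr) * sin(theta)
    v <- -(g$c - cc) * sin(theta) + (g$r - cr) * cos(theta)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    idx <- cbind(g$r[inside], g$c[inside])
    ok <- cls[idx] %in% over
    cls[idx[ok, , drop = FALSE]] <- value
    cls
  }
  open_ids <- SCENE_CLASSES[c("grassland", "bare_soil", "sand")]

  for (i in seq_len(6)) {  # bare-soil patches
    cls <- paint_ellipse(cls, runif(1, 1, nr), runif(1, 1, nc),
                         runif(1, 10, 40) / s, runif(1, 8, 30) / s,
                         runif(1, 0, pi), SCENE_CLASSES[["bare_soil"]],
                         SCENE_CLASSES[["grassland"]])
  }
  for (i in seq_len(4)) {  # sand patches
    cls <- paint_ellipse(cls, runif(1, 1, nr), runif(1, 1, nc),
                         runif(1, 5, 25) / s, runif(1, 4, 18) / s,
                         runif(1, 0, pi), SCENE_CLASSES[["sand"]], open_ids)
  }
  if (spec$water_fraction > 0) {
    area_px <- spec$water_fraction * nr * nc
    asp <- runif(1, 0.4, 0.8)
    a <- sqrt(area_px / (pi * asp))
    cls <- paint_ellipse(cls, runif(1, a, nr - a), runif(1, a, nc - a),
                         a, a * asp, runif(1, 0, pi),
                         SCENE_CLASSES[["water"]], open_ids)
  }
  n_trees <- round(spec$tree_density * prod(spec$extent_m) / 1e4)
  off <- spec$shadow_offset_px
  for (i in seq_len(n_trees)) {
    cr <- runif(1, 5, nr - 5); cc <- runif(1, 5, nc - 5)
    r_px <- runif(1, 2, 3.5) / s
    cls <- paint_ellipse(cls, cr, cc, r_px, r_px, 0,
                         SCENE_CLASSES[["trees"]], open_ids)
    cls <- paint_ellipse(cls, cr + off[1], cc + off[2], r_px, r_px, 0,
                         SCENE_CLASSES[["shadow"]], open_ids)
  }

  ## ---- herds and animals ----
  herd_sizes <- if (spec$n_herds > 0) {
    sample_range(spec$animals_per_herd, spec$n_herds)
  } else integer(0)
  placed_r <- numeric(0); placed_c <- numeric(0)
  herd_of <- integer(0); footprints <- list()
  is_open <- function(idx) all(cls[idx] %in% open_ids)
  spread_px <- spec$herd_spread_m / s
  spacing_px <- spec$min_animal_spacing_m / s
  soff <- sign(off); if (all(soff == 0)) soff <- c(1, 1)

  for (h in seq_len(spec$n_herds)) {
    ## herd center: an open disc, away from the image edge
    ok <- FALSE
    for (try in seq_len(500)) {
      hr <- runif(1, 40, nr - 40); hc <- runif(1, 40, nc - 40)
      d6 <- 6 / s
      rr <- round(hr + c(-d6, 0, d6, 0, 0)); cc2 <- round(hc + c(0, -d6, 0, d6, 0))
      if (all(rr >= 1 & rr <= nr & cc2 >= 1 & cc2 <= nc) &&
          is_open(cbind(rr, cc2))) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible placement: no open ground for herd center")
    theta_h <- runif(1, 0, 2 * pi)
    spread_px_h <- spread_px * sqrt(herd_sizes[h] / 50)
    n_placed_h <- 0
    for (a in seq_len(herd_sizes[h])) {
      done <- FALSE
      for (try in seq_len(400)) {
        if (n_placed_h == 0 || try <= 250) {
          u <- rnorm(1, 0, spread_px_h * spec$herd_anisotropy)
          v <- rnorm(1, 0, spread_px_h / spec$herd_anisotropy)
          ar <- hr + u * sin(theta_h) + v * cos(theta_h)
          ac <- hc + u * cos(theta_h) - v * sin(theta_h)
        } else {
          ## densification fallback: hang off an existing herd member
          j <- sample(which(herd_of == h), 1)
          d <- runif(1, spacing_px * 1.2, 8 / s); ang <- runif(1, 0, 2 * pi)
          ar <- placed_r[j] + d * sin(ang); ac <- placed_c[j] + d * cos(ang)
        }
        if (ar < 4 || ar > nr - 4 || ac < 4 || ac > nc - 4) next
        ## herd cohesion: within 8 m of an existing member (=> NN <= 10 m)
        if (n_placed_h > 0) {
          dmin <- min(sqrt((placed_r[herd_of == h] - ar)^2 +
                           (placed_c[herd_of == h] - ac)^2))
          if (dmin > 8 / s) next
        }
        if (length(placed_r)) {
          dall <- min(sqrt((placed_r - ar)^2 + (placed_c - ac)^2))
          if (dall < spacing_px) next
        }
        fp <- animal_footprint(ar, ac, runif(1, 0, 2 * pi),
                               sample_range(spec$animal_length_px),
                               sample_range(spec$animal_width_px))
        if (any(fp[, 1] < 1 | fp[, 1] > nr | fp[, 2] < 1 | fp[, 2] > nc)) next
        if (!is_open(fp)) next
        sh <- cbind(fp[, 1] + soff[1], fp[, 2] + soff[2])
        sh <- sh[sh[, 1] >= 1 & sh[, 1] <= nr & sh[, 2] >= 1 & sh[, 2] <= nc,
                 , drop = FALSE]
        cls[fp] <- SCENE_CLASSES[["animal"]]
        keep <- cls[sh] %in% open_ids
        cls[sh[keep, , drop = FALSE]] <- SCENE_CLASSES[["shadow"]]
        placed_r <- c(placed_r, mean(fp[, 1])); placed_c <- c(placed_c, mean(fp[, 2]))
        herd_of <- c(herd_of, h)
        footprints[[length(footprints) + 1L]] <- fp
        n_placed_h <- n_placed_h + 1
        done <- TRUE
        break
      }
      if (!done) stop("infeasible placement: could not place animal ",
                      a, " of herd ", h)
    }
  }

  ## ---- radiometry ----
  spectra <- spec$class_spectra[names(SCENE_CLASSES)]
  mu <- t(vapply(spectra, `[[`, numeric(4), "mean"))
  sg <- t(vapply(spectra, `[[`, numeric(4), "sd"))
  hi <- array(0, c(nr, nc, 4))
  ci <- as.integer(cls)
  for (k in 1:4) {
    hi[, , k] <- matrix(pmin(2047, pmax(0, round(
      mu[ci, k] + rnorm(nr * nc) * sg[ci, k]))), nr, nc)
  }
  pan_dn <- matrix(0, nr, nc)
  for (k in 1:4) pan_dn <- pan_dn + spec$pan_weights[k] * hi[, , k]
  pan_dn <- pmin(2047, pmax(0, round(pan_dn + rnorm(nr * nc, 0, 2))))
  hi_r <- mb_raster(hi, cell_size_m = s)
  ms <- aggregate_mean(hi_r, agg)
  ms$bands <- round(ms$bands)
  pan <- mb_raster(array(pan_dn, c(nr, nc, 1)), cell_size_m = s,
                   band_names = "pan")

  centers_x <- (placed_c - 0.5) * s
  centers_y <- spec$extent_m[2] - (placed_r - 0.5) * s + 0
  animals <- point_set(centers_x, centers_y + 0,
                       id = seq_along(centers_x), herd = herd_of)
  ## origin convention: origin = (0, extent_north); y decreases southward
  ms$origin <- pan$origin <- c(0, spec$extent_m[2])
  truth <- list(animals = animals, footprints = footprints,
                class_map = class_raster(cls, SCENE_CLASSES, s,
                                         origin = c(0, spec$extent_m[2])))
  list(ms = ms, pan = pan, truth = truth)
}

## uniform integer draw from an inclusive range (safe for lo == hi)
sample_range <- function(range, n = 1) {
  v <- range[1]:range[2]
  v[sample.int(length(v), n, replace = TRUE)]
}

## digital line of exactly len pixels, widened to wid by a parallel line
animal_footprint <- function(cr, cc, theta, len, wid) {
  dx <- cos(theta); dy <- sin(theta)
  t <- seq_len(len) - (len + 1) / 2
  if (abs(dx) >= abs(dy)) {
    c0 <- round(cc + t * sign(dx))
    r0 <- round(cr + (c0 - cc) * dy / dx)
    perp <- c(1, 0)  # thicken across rows
  } else {
    r0 <- round(cr + t * sign(dy))
    c0 <- round(cc + (r0 - cr) * dx / dy)
    perp <- c(0, 1)
  }
  fp <- cbind(r0, c0)
  if (wid == 2) fp <- rbind(fp, cbind(r0 + perp[1], c0 + perp[2]))
  unique(fp)
}

#' Sample labeled training/testing points from a synthetic scene
#'
#' Draws pixel samples on the pan-resolution grid: `n_animal` pixels from
#' animal footprints and `n_per_landscape` pixels from every landscape
#' class present (trees, grassland, bare soil, sand, water, shadow).  A
#' disjoint 20\% test split is flagged per class, so the default
#' `n_animal = 150` yields 120 training and 30 testing animal samples.
#'
#' @param truth the `truth` element of [generate_scene()].
#' @param ms_sharp the raster samples will be read from (georeference
#'   only; used to express points in map coordinates).
#' @param n_animal number of animal-class pixel samples (> 0).
#' @param n_per_landscape pixel samples per landscape class.
#' @param seed RNG seed for sampling and the split.
#' @return A [point_set()] with columns `class`, `split` (train/test).
#' @export
sample_training_points <- function(truth, ms_sharp, n_animal = 150,
                                   n_per_landscape = 50, seed = 1L) {
  if (n_animal <= 0 || length(truth$footprints) == 0) {
    stop("insufficient animals for training-sample selection")
  }
  fp_all <- do.call(rbind, truth$footprints)
  if (nrow(fp_all) < n_animal) {
    stop("insufficient animal pixels: ", nrow(fp_all), " < ", n_animal)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  cm <- truth$class_map
  pick <- function(idx_mat, n, cname) {
    take <- idx_mat[sample(nrow(idx_mat), n), , drop = FALSE]
    n_test <- floor(0.2 * n)
    split <- rep("train", n)
    split[sample(n, n_test)] <- "test"
    data.frame(r = take[, 1], c = take[, 2], class = cname, split = split,
               stringsAsFactors = FALSE)
  }
  out <- list(pick(fp_all, n_animal, "animal"))
  for (cn in setdiff(names(SCENE_CLASSES), "animal")) {
    idx <- which(cm$labels == SCENE_CLASSES[[cn]], arr.ind = TRUE)
    if (nrow(idx) >= n_per_landscape) {
      out[[length(out) + 1L]] <- pick(idx, n_per_landscape, cn)
    }
  }
  df <- do.call(rbind, out)
  ps <- point_set(px_center_x(ms_sharp, df$c), px_center_y(ms_sharp, df$r),
                  class = df$class, split = df$split,
                  id = seq_len(nrow(df)))
  ps
}
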