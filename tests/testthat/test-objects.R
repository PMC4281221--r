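test_that("degenerate inputs give degenerate partitions", {
  cst <- mb_raster(array(5, c(6, 6, 4)), 2)
  expect_equal(max(multiresolution_segment(cst, seg_params(1),
                                           features = FALSE)$segment_ids), 1)
  ## two constant halves separated by a huge DN gap stay two segments
  h <- matrix(rep(c(0, 1000), each = 18), 6, 6)
  r <- mb_raster(array(rep(h, 4), c(6, 6, 4)), 1)
  seg <- multiresolution_segment(r, seg_params(3))
  expect_equal(max(seg$segment_ids), 2)
  expect_equal(length(unique(as.vector(seg$segment_ids[, 1:3]))), 1)
  expect_equal(length(unique(as.vector(seg$segment_ids[, 4:6]))), 1)
})

test_that("region merging matches the brute-force oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- if (seed %% 2) 6 else 8
    r <- mb_raster(array(round(runif(n * n * 4, 0, 40)), c(n, n, 4)), 0.5)
    for (sc in c(2, 4)) {
      p <- seg_params(sc, c(1, 1, 1, 2), 0.2, 0.5)
      got <- multiresolution_segment(r, p, features = FALSE)$segment_ids
      want <- oracle_segment(r, p)
      expect_identical(got, want)
    }
  }
  ## thematic layers constrain merging and exclude masked pixels
  set.seed(99)
  r <- mb_raster(array(round(runif(64 * 4, 0, 30)), c(8, 8, 4)), 0.5)
  them <- matrix(NA_integer_, 8, 8)
  them[2:7, 2:4] <- 1L
  them[2:5, 6:7] <- 2L
  p <- seg_params(4, shape_weight = 0.1)
  got <- multiresolution_segment(r, p, thematic = them,
                                 features = FALSE)$segment_ids
  expect_identical(got, oracle_segment(r, p, thematic = them))
  expect_true(all(got[is.na(them)] == 0))
  expect_false(any(got[them == 1 & !is.na(them)] %in%
                     got[them == 2 & !is.na(them)]))
})

test_that("segmentation is a partition and scale is monotone", {
  set.seed(17)
  r <- mb_raster(array(round(runif(20 * 20 * 4, 0, 60)), c(20, 20, 4)), 0.5)
  counts <- vapply(c(1, 2, 4, 8, 16), function(sc) {
    ids <- multiresolution_segment(r, seg_params(sc),
                                   features = FALSE)$segment_ids
    expect_true(all(ids >= 1))  # every pixel belongs to one segment
    max(ids)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("object features follow the published formulas", {
  ## one segment with band means (90, 180, 200, 800)
  b <- array(rep(c(90, 180, 200, 800), each = 4), c(2, 2, 4))
  r <- mb_raster(b, 0.5)
  seg <- make_segment_layer(matrix(1L, 2, 2), NULL)
  f <- compute_features(r, seg)$features
  expect_equal(f$ndvi, 0.6)
  expect_equal(f$blue_ratio, 90 / 1270, tolerance = 1e-12)
  expect_equal(f$brightness, 317.5)
  expect_equal(f$max_diff, (800 - 90) / 317.5, tolerance = 1e-12)
  expect_equal(f$area_px, 4)
  expect_equal(f$area_m2, 1)

  ## equal bands: neutral indices
  b2 <- array(100, c(2, 2, 4))
  f2 <- compute_features(mb_raster(b2, 0.5),
                         make_segment_layer(matrix(1L, 2, 2), NULL))$features
  expect_equal(f2$brightness, 100)
  expect_equal(f2$blue_ratio, 0.25)
  expect_equal(f2$max_diff, 0)
  expect_equal(f2$ndvi, 0)
})

test_that("features equal direct recomputation from raw pixels", {
  set.seed(23)
  r <- mb_raster(array(runif(12 * 12 * 4, 0, 500), c(12, 12, 4)), 0.5,
                 origin = c(0, 6))
  seg <- multiresolution_segment(r, seg_params(6))
  f <- seg$features
  expect_equal(sum(f$area_px), 144)  # area conserved
  for (sid in f$id) {
    pick <- seg$segment_ids == sid
    bm <- vapply(1:4, function(k) mean(r$bands[, , k][pick]), numeric(1))
    expect_equal(unlist(f[f$id == sid, paste0("mean_", r$band_names)],
                        use.names = FALSE), bm)
    expect_equal(f$brightness[f$id == sid], mean(bm))
    expect_equal(f$x[f$id == sid], mean((col(pick)[pick] - 0.5) * 0.5))
    expect_equal(f$y[f$id == sid], mean(6 - (row(pick)[pick] - 0.5) * 0.5))
  }
  ## neighbor lists are symmetric 4-adjacency
  nb <- seg$neighbors
  for (i in seq_along(nb)) for (j in nb[[i]]) {
    expect_true(i %in% nb[[j]])
  }
})
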