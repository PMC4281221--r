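test_that("geotiff round trip is lossless for integer DNs", {
  dir <- withr::local_tempdir()
  b <- array(sample(0:2047, 10 * 8 * 4, replace = TRUE), c(10, 8, 4))
  r <- mb_raster(b, cell_size_m = 2, origin = c(100, 500))
  p <- file.path(dir, "ms.tif")
  write_geotiff(r, p)
  r2 <- read_geotiff(p)
  expect_identical(r2$bands, b + 0)  # numeric storage
  expect_equal(r2$cell_size_m, 2)
  expect_equal(r2$origin, c(100, 500))
  expect_equal(r2$band_names, c("blue", "green", "red", "nir"))

  pan <- mb_raster(matrix(round(runif(16, 0, 2047)), 4, 4),
                   cell_size_m = 0.5, nodata = 0)
  p2 <- file.path(dir, "pan.tif")
  write_geotiff(pan, p2)
  pan2 <- read_geotiff(p2)
  expect_identical(pan2$bands, pan$bands)
  expect_equal(pan2$cell_size_m, 0.5)
  expect_equal(pan2$nodata, 0)
})

test_that("real-valued rasters round trip within float32 precision", {
  dir <- withr::local_tempdir()
  b <- array(runif(6 * 6 * 2, 0, 2047), c(6, 6, 2))
  r <- mb_raster(b, 0.5, band_names = c("a", "b"))
  p <- file.path(dir, "f.tif")
  write_geotiff(r, p)
  r2 <- read_geotiff(p)
  expect_lt(max(abs(r2$bands - b)), 1e-3)
})

test_that("degenerate rasters and geotransforms are rejected", {
  expect_error(mb_raster(array(0, c(3, 3, 0)), 1), "at least one band")
  expect_error(mb_raster(matrix(1, 2, 2), -1), "positive")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rot.tif")
  write_geotiff(mb_raster(matrix(1:4, 2, 2), 1), p)
  writeLines(c("1", "0.3", "0.3", "-1", "0.5", "-0.5"),
             sub("\\.tif$", ".tfw", p))
  expect_error(read_geotiff(p), "unsupported geotransform")
  expect_error(read_geotiff(file.path(dir, "nope.tif")), "not found")
})

test_that("3x3 low-pass matches a naive sliding-window mean", {
  cst <- mb_raster(matrix(7, 5, 5), 1)
  expect_equal(lowpass_3x3(cst)$bands, cst$bands)
  expect_equal(mean(lowpass_3x3(cst)$bands), 7)

  spike <- matrix(0, 7, 7); spike[4, 4] <- 9
  sm <- lowpass_3x3(mb_raster(spike, 1))$bands[, , 1]
  expect_equal(sm[3:5, 3:5], matrix(1, 3, 3))
  expect_equal(sum(sm), 9)

  set.seed(5)
  m <- matrix(runif(16 * 16, 0, 100), 16, 16)
  naive <- matrix(0, 16, 16)
  pad <- m[c(1, 1:16, 16), c(1, 1:16, 16)]
  for (i in 1:16) for (j in 1:16) {
    naive[i, j] <- mean(pad[i:(i + 2), j:(j + 2)])
  }
  expect_equal(lowpass_3x3(mb_raster(m, 1))$bands[, , 1], naive,
               tolerance = 1e-12)
})

test_that("cubic convolution reproduces constants and interior ramps", {
  cst <- mb_raster(array(42, c(8, 8, 2)), 2)
  out <- resample_cubic(cst, 0.5)
  expect_equal(dim(out$bands)[1:2], c(32, 32))
  expect_equal(max(abs(out$bands - 42)), 0, tolerance = 1e-12)

  ## identity resampling: coincident centers give equal values
  set.seed(9)
  r <- mb_raster(matrix(runif(64, 0, 100), 8, 8), 2)
  same <- resample_cubic(r, 2)
  expect_equal(same$bands, r$bands, tolerance = 1e-12)

  ## linear ramp reproduced exactly away from replicated borders
  ramp <- outer(seq_len(12), seq_len(12),
                function(r, c) 3 + 2 * c + 5 * r)
  rr <- mb_raster(ramp, 2)
  up <- resample_cubic(rr, 1)$bands[, , 1]
  src_r <- ((seq_len(24) - 0.5) * 1) / 2 + 0.5  # 1-based source coords
  expected <- outer(src_r, src_r, function(r, c) 3 + 2 * c + 5 * r)
  interior <- 5:20
  expect_equal(up[interior, interior], expected[interior, interior],
               tolerance = 1e-9)

  ## commutes with adding a constant
  shifted <- r; shifted$bands <- r$bands + 13.5
  expect_equal(resample_cubic(shifted, 0.5)$bands,
               resample_cubic(r, 0.5)$bands + 13.5, tolerance = 1e-9)
})

test_that("geojson point layers round trip with attributes", {
  dir <- withr::local_tempdir()
  ps <- point_set(c(1.5, 2.5, 9), c(10, 20, 30),
                  class = c("animal", "water", "animal"),
                  id = 1:3)
  p <- file.path(dir, "pts.geojson")
  write_geojson_points(ps, p)
  ps2 <- read_geojson_points(p)
  expect_equal(ps2$x, ps$x)
  expect_equal(ps2$y, ps$y)
  expect_equal(ps2$class, ps$class)
  expect_error(point_set(c(1, NA), c(1, 2)), "finite")
  expect_error(point_set(1:2, 1:2, id = c(1, 1)), "unique")
})
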