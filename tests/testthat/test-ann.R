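## toy two-class raster: class "dark" around DN 120, class "bright" at 800
toy_samples <- function(n_per = 60, seed = 1) {
  set.seed(seed)
  b <- array(0, c(20, 20, 4))
  dark <- matrix(rnorm(200 * 4, 120, 15), 200, 4)
  bright <- matrix(rnorm(200 * 4, 800, 25), 200, 4)
  vals <- rbind(dark, bright)
  for (k in 1:4) b[, , k] <- matrix(vals[, k], 20, 20)
  r <- mb_raster(b, 1, origin = c(0, 20))
  ## values fill column-major, so columns 1-10 hold the dark class
  rows <- sample(1:20, 2 * n_per, TRUE)
  cols <- c(sample(1:10, n_per, TRUE), sample(11:20, n_per, TRUE))
  lab <- rep(c("dark", "bright"), each = n_per)
  ps <- point_set(cols - 0.5, 20 - rows + 0.5, class = lab,
                  split = rep(c("train", "test"), length.out = 2 * n_per))
  list(raster = r, samples = ps)
}

test_that("training separates linearly separable classes and is
           deterministic", {
  fx <- toy_samples()
  m1 <- train_ann(fx$raster, fx$samples, ann_config(seed = 3))
  expect_gte(attr(m1$test_report, "overall"), 0.95)
  m2 <- train_ann(fx$raster, fx$samples, ann_config(seed = 3))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  m3 <- train_ann(fx$raster, fx$samples, ann_config(seed = 4))
  expect_false(identical(m1$W1, m3$W1))

  one <- fx$samples
  one$class <- "dark"
  expect_error(train_ann(fx$raster, one), "two classes")
})

test_that("the configured training-rate band is enforced", {
  expect_error(ann_config(learning_rate = 0.2), "0.01, 0.05")
  expect_silent(ann_config(learning_rate = 0.2, allow_any_rate = TRUE))
  expect_error(ann_config(momentum = 1.2))
})

test_that("prediction is a pure per-pixel function", {
  fx <- toy_samples()
  m <- train_ann(fx$raster, fx$samples, ann_config(seed = 3))
  cst <- mb_raster(array(120, c(5, 7, 4)), 1)
  cr <- classify_pixels(cst, m)
  expect_equal(length(unique(as.vector(cr$labels))), 1)
  expect_equal(names(cr$class_table)[cr$class_table == cr$labels[1, 1]],
               "dark")
  expect_error(classify_pixels(mb_raster(matrix(1, 2, 2), 1), m),
               "band count")
})

test_that("subclass splitting follows the BIC choice", {
  set.seed(12)
  b <- array(0, c(30, 30, 4))
  ## bimodal class: half the samples near 100, half near 900
  v <- rbind(matrix(rnorm(450 * 4, 100, 10), 450, 4),
             matrix(rnorm(450 * 4, 900, 10), 450, 4))
  for (k in 1:4) b[, , k] <- matrix(v[, k], 30, 30)
  r <- mb_raster(b, 1, origin = c(0, 30))
  rows <- sample(1:30, 80, TRUE)
  cols <- sample(1:30, 80, TRUE)
  ps <- point_set(cols - 0.5, 30 - rows + 0.5, class = "mix")
  out <- subclass_split(r, ps, "mix", max_k = 3)
  expect_equal(sort(unique(out$class)), c("mix.1", "mix.2"))

  ## unimodal class stays whole
  set.seed(13)
  b2 <- array(rnorm(900 * 4, 500, 20), c(30, 30, 4))
  r2 <- mb_raster(b2, 1, origin = c(0, 30))
  ps2 <- point_set(sample(1:30, 60, TRUE) - 0.5,
                   sample(1:30, 60, TRUE) - 0.5, class = "uni")
  out2 <- subclass_split(r2, ps2, "uni", max_k = 3)
  expect_equal(unique(out2$class), "uni")

  expect_warning(subclass_split(r2, ps2[1:6, ], "uni"), "too few")
})

test_that("models serialize to versioned JSON and predict identically", {
  fx <- toy_samples()
  m <- train_ann(fx$raster, fx$samples, ann_config(seed = 3))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.json")
  write_ann_model(m, p)
  m2 <- read_ann_model(p)
  expect_equal(m2$W1, m$W1)
  expect_equal(m2$parent_map, m$parent_map)
  c1 <- classify_pixels(fx$raster, m)
  c2 <- classify_pixels(fx$raster, m2)
  expect_identical(c1$labels, c2$labels)
  writeLines("{}", p)
  expect_error(read_ann_model(p), "not a model file")
})

test_that("subclass labels collapse to parents at prediction time", {
  fx <- toy_samples()
  s <- fx$samples
  dark <- s$class == "dark"
  s$class[dark] <- paste0("dark.", rep(1:2, length.out = sum(dark)))
  m <- train_ann(fx$raster, s, ann_config(seed = 3))
  cr <- classify_pixels(mb_raster(array(120, c(3, 3, 4)), 1), m)
  expect_true("dark" %in% names(cr$class_table))
  expect_false(any(grepl("dark\\.", names(cr$class_table))))
})
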