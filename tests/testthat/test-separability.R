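test_that("class statistics match hand-computed values", {
  b <- array(0, c(3, 3, 2))
  b[, , 1] <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, 3)
  b[, , 2] <- matrix(c(2, 4, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  r <- mb_raster(b, 1, origin = c(0, 3), band_names = c("a", "b"))
  ## class u: pixels (1,1),(2,1),(3,1); class v: (1,3),(2,3),(3,3)
  ps <- point_set(x = c(0.5, 0.5, 0.5, 2.5, 2.5, 2.5),
                  y = c(2.5, 1.5, 0.5, 2.5, 1.5, 0.5),
                  class = rep(c("u", "v"), each = 3))
  st <- class_stats(r, ps, min_n = 3)
  u <- st[[which(vapply(st, `[[`, "", "class_name") == "u")]]
  expect_equal(u$mean, c(20, 3))
  expect_equal(u$cov[1, 1], 100)  # var of 10,20,30
  expect_equal(u$cov[2, 2], 1)    # var of 2,4,3
  expect_equal(u$cov[1, 2], 5)

  ## constant region: zero covariance, ridge-regularized to stay PD
  ps2 <- point_set(rep(0.5, 5), seq(2.9, 2.5, by = -0.1),
                   class = rep("c", 5))
  st2 <- class_stats(r, ps2, min_n = 5)
  expect_equal(st2[[1]]$mean, c(10, 2))
  expect_true(all(eigen(st2[[1]]$cov)$values > 0))

  out <- point_set(10, 10, class = "far")
  expect_error(class_stats(r, out, min_n = 1), "outside")
  expect_error(class_stats(r, ps, min_n = 4), "minimum sample count")
})

test_that("JM distance matches closed forms and saturates at 2", {
  g <- function(mu, v) gauss_stats(mu, v)
  expect_equal(jm_distance(g(0, 1), g(0, 1)), 0, tolerance = 1e-12)
  ## equal unit variances, means 0 and 2: B = 0.5
  expect_equal(jm_distance(g(0, 1), g(2, 1)), 2 * (1 - exp(-0.5)),
               tolerance = 1e-12)
  expect_equal(jm_distance(g(0, 1), g(1000, 1)), 2, tolerance = 1e-9)
  ## symmetry and monotonicity in mean separation
  seps <- seq(0, 10, by = 0.5)
  jm <- vapply(seps, function(s) jm_distance(g(0, 2), g(s, 2)), numeric(1))
  expect_true(all(diff(jm) >= 0))
  expect_true(all(jm >= 0 & jm <= 2))
  expect_equal(jm_distance(g(3, 2), g(0, 5)), jm_distance(g(0, 5), g(3, 2)))
})

test_that("JM agrees with numerical integration of the Bhattacharyya
           coefficient", {
  cases <- list(c(0, 1, 1, 1), c(0, 1, 3, 2), c(-2, 0.5, 2, 3),
                c(5, 2, 5, 0.3), c(0, 1, 0.2, 1))
  for (cs in cases) {
    ours <- jm_distance(gauss_stats(cs[1], cs[2]^2),
                        gauss_stats(cs[3], cs[4]^2))
    oracle <- jm_numeric_1d(cs[1], cs[2], cs[3], cs[4])
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("separability matrix flags pairs and recommends merges", {
  s <- list(gauss_stats(0, 1), gauss_stats(0, 1), gauss_stats(0, 1))
  s[[1]]$class_name <- "a"; s[[2]]$class_name <- "b"; s[[3]]$class_name <- "c"
  rep0 <- separability_matrix(s)
  expect_true(all(rep0$jm[upper.tri(rep0$jm)] == 0))
  expect_true(all(rep0$flags$flag == "poor"))
  expect_equal(length(rep0$merge_recommendations), 3)
  expect_equal(rep0$jm, t(rep0$jm))
  expect_true(all(diag(rep0$jm) == 0))
  expect_error(separability_matrix(s[1]), "length")
})

test_that("the synthetic scene reproduces the published separability
           structure", {
  scn <- small_scene()
  samp <- sample_training_points(scn$truth, scn$sharp, n_animal = 120,
                                 n_per_landscape = 40, seed = 2)
  st <- class_stats(scn$sharp, samp)
  sep <- separability_matrix(st)
  expect_lt(sep$jm["animal", "shadow"], 1.40)   # poor: merge them
  others <- setdiff(colnames(sep$jm), c("animal", "shadow"))
  expect_true(all(sep$jm["animal", others] >= 1.90))
  fl <- sep$flags
  expect_equal(fl$flag[fl$class_a == "animal" & fl$class_b == "shadow"],
               "poor")
  expect_true(any(vapply(sep$merge_recommendations,
                         function(p) setequal(p, c("animal", "shadow")),
                         logical(1))))
})
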