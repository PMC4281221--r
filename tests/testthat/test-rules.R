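test_that("landscape rules fire exactly at the published thresholds", {
  seg <- classify_landscape(landscape_fixture())
  cls <- seg$features$class
  expect_equal(cls[1], "vegetation")  # ndvi 0.7, 50 px
  expect_equal(cls[2], "shadow")      # brightness 300, veg at 1.0 m
  expect_equal(cls[3], "open")        # same but veg 3 m away
  expect_equal(cls[4], "open")

  ## small objects are protected by the size floor
  seg2 <- landscape_fixture()
  seg2$features$area_px[1] <- 8       # ndvi 0.7 but only 8 px
  cls2 <- classify_landscape(seg2)$features$class
  expect_equal(cls2[1], "open")
  expect_equal(cls2[2], "open")       # no vegetation left to anchor shadow

  ## water: blue ratio at threshold, before the shadow rule
  seg3 <- landscape_fixture()
  seg3$features$blue_ratio[2] <- 0.18
  expect_equal(classify_landscape(seg3)$features$class[2], "water")
  seg3$features$blue_ratio[2] <- 0.179
  expect_equal(classify_landscape(seg3)$features$class[2], "shadow")

  ## vegetation requires both ndvi and area
  seg4 <- landscape_fixture()
  seg4$features$ndvi[1] <- 0.59
  expect_equal(classify_landscape(seg4)$features$class[1], "open")
})

test_that("candidates are clipped to open terrain", {
  seg <- classify_landscape(landscape_fixture())
  tab <- c(animal = 1L, grassland = 2L)
  lab <- matrix(2L, 20, 30)
  lab[5, 3] <- 1L    # on vegetation
  lab[5, 8] <- 1L    # on shadow
  lab[5, 20] <- 1L   # on open ground
  cr <- class_raster(lab, tab, 0.5, origin = c(0, 10))
  out <- clip_candidates(cr, seg)
  expect_equal(out$labels[5, 3], out$class_table[["vegetation"]])
  expect_equal(out$labels[5, 8], out$class_table[["shadow"]])
  expect_equal(out$labels[5, 20], 1L)
  ## empty candidate mask: unchanged
  cr0 <- class_raster(matrix(2L, 20, 30), tab, 0.5)
  expect_equal(clip_candidates(cr0, seg)$labels, cr0$labels)
  expect_error(clip_candidates(class_raster(matrix(2L, 5, 5), tab, 0.5),
                               seg), "grid mismatch")
})

test_that("oversized objects split at brightness valleys only", {
  profile <- c(200, 160, 120, 160, 200, 240, 240, 200, 160, 120, 160, 200)
  r <- mb_raster(array(rep(profile, 4), c(1, 12, 4)), 0.5)
  seg <- compute_features(r, make_segment_layer(matrix(1L, 1, 12), NULL))
  out <- split_oversized(seg, r, animal_rules())
  expect_equal(max(out$segment_ids), 2)
  expect_equal(as.integer(table(out$segment_ids)), c(6, 6))

  ## a flat oversized strip cannot be split: kept and flagged
  rf <- mb_raster(array(200, c(1, 12, 4)), 0.5)
  segf <- compute_features(rf, make_segment_layer(matrix(1L, 1, 12), NULL))
  outf <- split_oversized(segf, rf, animal_rules())
  expect_equal(max(outf$segment_ids), 1)
  expect_true(outf$features$oversized_unsplit)

  ## objects at or below 10 px pass through untouched
  r8 <- mb_raster(array(rep(profile[1:8], 4), c(1, 8, 4)), 0.5)
  seg8 <- compute_features(r8, make_segment_layer(matrix(1L, 1, 8), NULL))
  out8 <- split_oversized(seg8, r8, animal_rules())
  expect_equal(out8$segment_ids, seg8$segment_ids)
})

test_that("intersecting centroid buffers merge transitively", {
  cfg <- animal_rules()
  two <- merge_centroid_buffers(make_detections(c(0, 0.9), c(0, 0)), cfg)
  expect_equal(nrow(two$detections), 1)
  apart <- merge_centroid_buffers(make_detections(c(0, 1.2), c(0, 0)), cfg)
  expect_equal(nrow(apart$detections), 2)
  chain <- merge_centroid_buffers(
    make_detections(c(0, 0.9, 1.8), c(0, 0, 0),
                    area_px = c(4, 4, 8)), cfg)
  expect_equal(nrow(chain$detections), 1)
  ## area-weighted centroid of the chain
  expect_equal(chain$detections$x, (0 * 4 + 0.9 * 4 + 1.8 * 8) / 16)
  expect_equal(chain$detections$area_px, 16L)
})

test_that("the herd rule removes isolated detections", {
  cfg <- animal_rules()
  ## two mutual supporters 8 m apart, one straggler 15 m away from all
  d <- make_detections(c(0, 8, 40), c(0, 0, 0))
  out <- herd_filter(d, cfg)
  expect_equal(out$detections$x, c(0, 8))
  ## a lone detection is infinitely isolated
  lone <- herd_filter(make_detections(5, 5), cfg)
  expect_equal(nrow(lone$detections), 0)
  ## single pass: removing the straggler does not cascade
  line <- make_detections(c(0, 9, 18, 40), c(0, 0, 0, 0))
  expect_equal(nrow(herd_filter(line, cfg)$detections), 3)
  ## iterative variant re-checks until stable
  cfg2 <- animal_rules(iterative_herd_filter = TRUE)
  chain <- make_detections(c(0, 9, 19.5, 40), c(0, 0, 0, 0))
  expect_equal(nrow(herd_filter(chain, cfg2)$detections), 2)
})

test_that("the brightness gate admits via either branch", {
  cfg <- animal_rules()
  d <- make_detections(1:4, rep(0, 4),
                       brightness = c(300, 320, 320, 330),
                       max_diff = c(0.5, 1.6, 1.2, 1.6))
  out <- brightness_gate(d, cfg)
  expect_equal(out$detections$brightness, c(300, 320))
  expect_equal(out$detections$admitted_by,
               c("brightness", "soft_band_max_diff"))
  ## closed interval at both soft-band ends
  d2 <- make_detections(1:2, c(0, 0), brightness = c(315, 325),
                        max_diff = c(1.5, 1.5))
  expect_equal(nrow(brightness_gate(d2, cfg)$detections), 2)
})

test_that("rule stages are idempotent", {
  cfg <- animal_rules()
  d <- make_detections(c(0, 0.9, 5, 40), c(0, 0, 0, 0),
                       brightness = c(300, 310, 320, 200),
                       max_diff = c(0.5, 0.6, 1.6, 0.2))
  m1 <- merge_centroid_buffers(d, cfg)
  expect_equal(merge_centroid_buffers(m1, cfg)$detections$x,
               m1$detections$x)
  h1 <- herd_filter(m1, cfg)
  expect_equal(herd_filter(h1, cfg)$detections, h1$detections)
  g1 <- brightness_gate(h1, cfg)
  expect_equal(brightness_gate(g1, cfg)$detections, g1$detections)
})

test_that("refinement of an empty candidate field is empty", {
  seg <- classify_landscape(landscape_fixture())
  tab <- c(animal = 1L, grassland = 2L)
  cr <- class_raster(matrix(2L, 20, 30), tab, 0.5, origin = c(0, 10))
  r <- mb_raster(array(500, c(20, 30, 4)), 0.5, origin = c(0, 10))
  det <- refine_animals(cr, seg, r)
  expect_equal(nrow(det$detections), 0)
  expect_equal(det$audit$candidate_px, 0)
})
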