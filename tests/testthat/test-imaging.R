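test_that("rolling-ball background subtraction removes smooth background", {
  # constant image -> zero
  flat <- matrix(7, 40, 40)
  expect_equal(max(abs(as.matrix(subtract_background(flat, 10)))), 0)

  # a blob smaller than the ball survives within 5% of its peak
  img <- blob_image(41, 41, 21, 21, sigma = 2, peak = 100, background = 50)
  out <- as.matrix(subtract_background(img, radius = 10))
  expect_gt(max(out), 95)
  # matches the naive morphological-opening oracle
  oracle <- img - oracle_opening(img, 10)
  expect_lt(max(abs(out - pmax(oracle, 0))), 1e-3)

  # linear ramp + blob: residual background below 10% of the blob peak
  ramp <- matrix(rep(seq(0, 30, length.out = 41), 41), 41, 41)
  img2 <- ramp + blob_image(41, 41, 21, 21, sigma = 2, peak = 100)
  out2 <- as.matrix(subtract_background(img2, radius = 10))
  border <- out2[c(1:3, 39:41), ]
  expect_lt(max(border), 10)

  expect_error(subtract_background(flat, -1), "> 0")
})

test_that("difference-of-Gaussians is linear and scale-selective", {
  flat <- matrix(3, 50, 50)
  expect_lt(max(abs(as.matrix(enhance_dog(flat, 2, 4)))), 1e-8)

  img <- blob_image(51, 51, 26, 26, sigma = 3, peak = 10)
  dog <- as.matrix(enhance_dog(img, 3, 6))
  peak_at <- which(dog == max(dog), arr.ind = TRUE)
  expect_equal(unname(peak_at[1, ]), c(26, 26))

  # linearity: dog(a * I) = a * dog(I)
  expect_equal(as.matrix(enhance_dog(3.7 * img, 2, 5)),
               3.7 * as.matrix(enhance_dog(img, 2, 5)), tolerance = 1e-10)

  expect_error(enhance_dog(img, 4, 2), "smaller")
})

test_that("IsoData threshold lands at its histogram fixed point", {
  # two-level image: threshold between the levels, mask = bright pixels
  img <- matrix(10, 30, 30)
  img[1:10, 1:10] <- 100
  t <- threshold_isodata(img)
  expect_gt(t, 10); expect_lt(t, 100)
  expect_equal(sum(img > t), 100L)

  # fixed-point property within one bin on arbitrary images
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(c(rnorm(400, 10, 2), rnorm(100, 30, 3)), 25, 20)
    t <- threshold_isodata(x)
    fp <- (mean(x[x <= t]) + mean(x[x > t])) / 2
    bin_w <- (max(x) - min(x)) / 256
    expect_lt(abs(t - fp), 1.5 * bin_w)
    # mask pixel count equals a brute-force count above the threshold
    expect_equal(sum(x > t), sum(as.vector(x) > t))
  }

  # shift equivariance: adding a constant shifts T, mask unchanged
  t0 <- threshold_isodata(img)
  t5 <- threshold_isodata(img + 5)
  expect_equal(t5 - t0, 5, tolerance = 1e-9)
  expect_equal(img > t0, (img + 5) > t5)

  expect_error(threshold_isodata(matrix(1, 5, 5)), "constant")
})

test_that("watershed separates touching nuclei without inventing pixels", {
  # two disjoint discs -> 2 labels
  m1 <- disc_image(60, 60, rbind(c(20, 20), c(20, 45)), radius = 8) > 0
  lab1 <- separate_watershed(m1, h = 1)
  expect_equal(max(lab1), 2L)

  # overlapping discs, centres 1.5 radii apart -> still 2 labels
  m2 <- disc_image(60, 60, rbind(c(30, 24), c(30, 36)), radius = 8) > 0
  lab2 <- separate_watershed(m2, h = 1)
  expect_equal(max(lab2), 2L)
  # labelled pixels exactly cover the mask
  expect_equal(lab2 > 0, m2)

  # empty mask -> empty labelling, not an error
  expect_equal(max(separate_watershed(matrix(FALSE, 10, 10))), 0)
})

test_that("nucleus extraction converts to calibrated chip coordinates", {
  geom <- small_geometry(40, 40, pixel_size = 1)
  lab <- matrix(0L, 40, 40)
  lab[11:15, 11:15] <- 1L   # 5x5 square, rows 11..15, cols 11..15
  rec <- extract_nuclei(lab, geom, detection_params(min_area = 1, max_area = 100,
                                                    pixel_size = 1))
  expect_equal(nrow(rec), 1L)
  # centroid row/col 13 -> pixel centre 12.5; y = y_min + 12.5
  expect_equal(rec$x_um, 12.5)
  expect_equal(rec$y_um, geom$y_min + 12.5)
  expect_equal(rec$area_um2, 25)
  expect_equal(rec$region, "sprout")

  # area gate removes small labels
  lab[30, 30] <- 2L
  rec2 <- extract_nuclei(lab, geom, detection_params(min_area = 5, max_area = 100,
                                                     pixel_size = 1))
  expect_equal(nrow(rec2), 1L)

  expect_error(extract_nuclei(lab, list(pixel_size = NULL)), "pixel_size")
})

test_that("detection is deterministic and intensity-scale invariant", {
  geom <- chip_geometry()
  ph <- sample_phenotype("sunitinib_control", geom, seed = 21)
  img <- render_image(ph, geom, seed = 21)
  det1 <- detect_nuclei(img)
  det2 <- detect_nuclei(img)
  expect_identical(det1, det2)
  expect_gt(nrow(det1), 10)

  scaled <- img; scaled$pixels <- img$pixels * 4.2
  det3 <- detect_nuclei(scaled)
  expect_equal(nrow(det3), nrow(det1))
  expect_equal(det3$x_um, det1$x_um, tolerance = 1e-8)

  # a blank noisy image yields no records after the area gate
  sproutscreen:::with_seed(9, {
    blank <- matrix(100 + rnorm(200 * 200, 0, 3), 200, 200)
  })
  det0 <- detect_nuclei(blank, geometry = small_geometry(200, 200, 0.65))
  expect_equal(nrow(det0), 0L)
})

test_that("translating the image translates the detected centroids", {
  geom <- small_geometry(120, 120, pixel_size = 1)
  base <- matrix(0, 120, 120)
  centers <- rbind(c(40, 40), c(60, 80), c(90, 55))
  for (i in 1:3) base <- base + blob_image(120, 120, centers[i, 1],
                                           centers[i, 2], sigma = 3, peak = 200)
  base <- base + 50
  dp <- detection_params(rolling_ball_radius = 15, dog_sigma_small = 3,
                         dog_sigma_large = 4.8, min_area = 5, max_area = 500)
  d1 <- detect_nuclei(base, dp, geom)
  shifted <- matrix(0, 120, 120)
  shifted[11:120, 6:120] <- base[1:110, 1:115]
  shifted[shifted == 0] <- 50
  d2 <- detect_nuclei(shifted, dp, geom)
  expect_equal(nrow(d1), 3L)
  expect_equal(nrow(d2), 3L)
  expect_equal(sort(d2$y_um), sort(d1$y_um) + 10, tolerance = 0.1)
  expect_equal(sort(d2$x_um), sort(d1$x_um) + 5, tolerance = 0.1)
})

test_that("detection recovers rendered nuclei and their sprouting distance", {
  geom <- chip_geometry()
  pp <- phenotype_params(vessel_nuclei_mean = 50, sprout_nuclei_base = 40)
  for (s in 1:2) {
    ph <- sample_phenotype("vehicle", geom, pp, seed = s + 100)
    img <- render_image(ph, geom, seed = s + 100)
    det <- detect_nuclei(img)
    m <- match_nuclei(img$truth, det, radius_um = 2 * geom$pixel_size)
    expect_gt(m$f1, 0.95)
    d10_true <- d10(img$truth$y_um[img$truth$region == "sprout"])
    d10_det <- d10(det$y_um[det$region == "sprout"])
    expect_lt(abs(d10_true - d10_det), 5)
  }
})
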