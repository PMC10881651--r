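test_that("layouts respect plate composition and duplicate placement", {
  lay <- generate_layout(n_plates = 1, n_compounds = 24, seed = 7)
  expect_equal(nrow(lay), 64L)
  counts <- table(lay$role)
  expect_equal(counts[["vehicle"]], 8L)
  expect_equal(counts[["sunitinib_control"]], 4L)
  expect_equal(counts[["unstimulated"]], 4L)
  expect_equal(counts[["sample"]], 48L)
  per_compound <- table(stats::na.omit(lay$compound_id))
  expect_true(all(per_compound == 2L))
  expect_equal(length(per_compound), 24L)

  # duplicates land on distinct plates when plates are available
  lay2 <- generate_layout(n_plates = 2, n_compounds = 48, seed = 1)
  plates_per_compound <- tapply(lay2$plate_id, lay2$compound_id,
                                function(p) length(unique(p)))
  expect_true(all(plates_per_compound == 2L))

  # deterministic in the seed
  expect_identical(generate_layout(3, 60, seed = 11),
                   generate_layout(3, 60, seed = 11))
  expect_false(identical(generate_layout(3, 60, seed = 11),
                         generate_layout(3, 60, seed = 12)))
})

test_that("layout capacity errors name the required plate count", {
  expect_error(generate_layout(n_plates = 1, n_compounds = 30, seed = 1),
               "at least 2 plates")
})

test_that("phenotype generator honours its calibration anchors", {
  geom <- chip_geometry()
  # zero-CV degenerate cases
  ph <- sample_phenotype("vehicle", geom, phenotype_params(vehicle_cv = 0),
                         seed = 99)
  expect_equal(ph$true_d10, 352.1)
  ph0 <- sample_phenotype("sample", geom, phenotype_params(vehicle_cv = 0),
                          inhibition_effect = 0, toxicity_class = 1, seed = 3)
  expect_equal(ph0$true_d10, 0)
  expect_equal(sum(ph0$nuclei$region == "sprout"), 0L)

  # ground-truth D10 from positions equals the drawn true_d10 exactly
  for (s in 1:5) {
    p <- sample_phenotype("vehicle", geom, seed = s)
    expect_equal(d10(p$nuclei$y_um[p$nuclei$region == "sprout"]), p$true_d10,
                 tolerance = 1e-10)
  }

  # Monte-Carlo: median within 2% of 352.1, CV within 15% (relative) of 12.1%
  draws <- vapply(1:10000, function(s) {
    sproutscreen:::with_seed(s, {
      lp <- list(meanlog = log(352.1), sdlog = sqrt(log(1 + 0.121^2)))
      exp(stats::rnorm(1, lp$meanlog, lp$sdlog))
    })
  }, numeric(1))
  expect_lt(abs(stats::median(draws) - 352.1) / 352.1, 0.02)
  cv <- stats::sd(draws) / mean(draws)
  expect_lt(abs(cv - 0.121) / 0.121, 0.15)

  expect_error(sample_phenotype("weird"), "role")
})

test_that("full Monte-Carlo vehicle draws through sample_phenotype match the anchors", {
  geom <- chip_geometry()
  d <- vapply(1:2000, function(s) {
    sample_phenotype("vehicle", geom, seed = s)$true_d10
  }, numeric(1))
  expect_lt(abs(stats::median(d) - 352.1) / 352.1, 0.02)
  expect_lt(abs(stats::sd(d) / mean(d) - 0.121) / 0.121, 0.15)
})

test_that("expected sprouting distance decreases with planted inhibition", {
  geom <- chip_geometry()
  pp <- phenotype_params()
  mean_d10 <- vapply(c(1, 0.7, 0.4, 0.1), function(eff) {
    mean(vapply(1:300, function(s) {
      sample_phenotype("sample", geom, pp, inhibition_effect = eff,
                       toxicity_class = 1, seed = s)$true_d10
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d10) < 0))
})

test_that("replicate coupling induces the configured correlation", {
  geom <- chip_geometry()
  pp <- phenotype_params()
  pairs <- t(vapply(1:400, function(i) {
    zc <- sproutscreen:::with_seed(i, stats::rnorm(1))
    c(sample_phenotype("sample", geom, pp, inhibition_effect = 0.5,
                       toxicity_class = 1, z_compound = zc, seed = 2 * i)$true_d10,
      sample_phenotype("sample", geom, pp, inhibition_effect = 0.5,
                       toxicity_class = 1, z_compound = zc, seed = 2 * i + 1)$true_d10)
  }, numeric(2)))
  r <- stats::cor(log(pairs[, 1]), log(pairs[, 2]))
  expect_gt(r, 0.7)
  expect_lt(r, 0.95)
})

test_that("nuclei are placed without physical interpenetration", {
  geom <- chip_geometry()
  for (s in 1:3) {
    nuc <- sample_phenotype("vehicle", geom, seed = s)$nuclei
    d <- as.matrix(stats::dist(cbind(nuc$x_um, nuc$y_um)))
    diag(d) <- Inf
    expect_gt(min(d), 0.9 * phenotype_params()$min_separation)
  }
})

test_that("rendered rasters are faithful to the phenotype and deterministic", {
  geom <- small_geometry(80, 80)
  # no nuclei, no noise -> constant background
  empty <- list(nuclei = tibble::tibble(x_um = numeric(), y_um = numeric(),
                                        region = character()))
  rp0 <- render_params(poisson_noise = FALSE, read_noise_sd = 0,
                       gradient_amplitude = 0)
  img0 <- render_image(empty, geom, rp0, seed = 1)
  expect_equal(max(img0$pixels) - min(img0$pixels), 0)

  # 20 well-separated nuclei, zero noise -> exactly 20 connected components
  set.seed(42)
  grid_pos <- expand.grid(x = seq(8, 72, by = 16), y = seq(4, 68, by = 16))
  pick <- grid_pos[sample(nrow(grid_pos), 20), ]
  ph <- list(nuclei = tibble::tibble(x_um = pick$x, y_um = pick$y,
                                     region = "sprout"))
  img <- render_image(ph, geom, render_params(poisson_noise = FALSE,
                                              read_noise_sd = 0,
                                              gradient_amplitude = 0,
                                              diameter_jitter = 0,
                                              nucleus_diameter = 6),
                      seed = 1)
  cc <- EBImage::bwlabel(img$pixels > 0.5 * max(img$pixels))
  expect_equal(max(cc), 20L)

  # determinism: same phenotype + seed -> bit-identical raster
  imga <- render_image(ph, geom, render_params(), seed = 5)
  imgb <- render_image(ph, geom, render_params(), seed = 5)
  expect_identical(imga$pixels, imgb$pixels)
  imgc <- render_image(ph, geom, render_params(), seed = 6)
  expect_false(identical(imga$pixels, imgc$pixels))

  # out-of-bounds nuclei are a geometry error
  bad <- list(nuclei = tibble::tibble(x_um = 1e5, y_um = 0, region = "sprout"))
  expect_error(render_image(bad, geom), "bounds")
})

test_that("TIFF round trip preserves the raster to 16-bit precision", {
  geom <- small_geometry(40, 40)
  ph <- list(nuclei = tibble::tibble(x_um = 20, y_um = 20, region = "sprout"))
  img <- render_image(ph, geom, render_params(), seed = 1)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_chip_tiff(img, path)
  back <- read_chip_tiff(path, geom)
  expect_lt(max(abs(back$pixels - img$pixels)), 1.01)
})

test_that("dose series and simulated dose-response follow the 4PL", {
  s <- dilution_series(top = 10000, fold = 4, n = 8)
  expect_equal(s, c(10000, 2500, 625, 156.25, 39.0625, 9.765625,
                    2.44140625, 0.6103515625))

  # midpoint identity and asymptotes at zero noise
  expect_equal(pl4(100, ic50 = 100, hill = 1, top = 80, bottom = 20), 50)
  expect_equal(pl4(1e-9, 100, 1, 80, 20), 80, tolerance = 1e-6)
  expect_equal(pl4(1e12, 100, 1, 80, 20), 20, tolerance = 1e-6)

  ds <- simulate_dose_response(ic50 = 100, noise_cv = 0, seed = 1)
  at_mid <- ds$response[abs(ds$concentration_nM - 100) < 1e-9]
  expect_equal(length(unique(ds$concentration_nM)), 8L)
  expect_equal(nrow(ds), 16L)

  expect_error(simulate_dose_response(series = c(-1, 1, 10, 100)), "> 0")
  expect_error(simulate_dose_response(series = c(1, 10, 100)), "4 distinct")

  # planted nuclei-count decay shows up at the top dose
  dd <- simulate_dose_response(count_decay = 0.5, seed = 2)
  per <- tapply(dd$vessel_nuclei_count, dd$concentration_nM, mean)
  expect_lt(per[["10000"]], per[["0.6103515625"]])
})
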