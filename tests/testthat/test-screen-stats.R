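test_that("d10 averages the ten furthest nuclei with defined degenerate cases", {
  expect_equal(d10(1:20), mean(11:20))
  expect_equal(d10(numeric()), 0)
  expect_equal(d10(c(10, 20, 30)), 20)

  # property: equals the naive sort-based oracle on random inputs
  set.seed(4)
  for (i in 1:200) {
    y <- runif(sample(0:30, 1), 0, 500)
    expect_equal(d10(y), oracle_d10(y))
  }
})

test_that("plate statistics use median and raw MAD of vehicle chips", {
  m <- tibble::tibble(
    chip_id = paste0("c", 1:6), plate_id = "P01",
    role = c(rep("vehicle", 4), "sample", "sample"),
    d10_um = c(300, 350, 400, 350, 100, 90),
    qc_score = 4)
  ps <- plate_stats(m)
  expect_equal(ps$vehicle_median_d10, 350)
  expect_equal(ps$vehicle_mad_d10, 25)
  expect_equal(ps$n_vehicle, 4L)
  expect_equal(ps$basis, "plate")

  # all-equal vehicles are flagged degenerate
  m2 <- m; m2$d10_um[1:4] <- 350
  expect_true(plate_stats(m2)$degenerate)

  # a plate below the vehicle minimum falls back to pooled statistics
  m3 <- dplyr::bind_rows(
    m,
    tibble::tibble(chip_id = "x1", plate_id = "P02", role = "vehicle",
                   d10_um = 500, qc_score = 4))
  ps3 <- plate_stats(m3, min_vehicle = 4)
  expect_equal(ps3$basis[ps3$plate_id == "P02"], "pooled")
  expect_equal(ps3$vehicle_median_d10[ps3$plate_id == "P02"],
               stats::median(c(300, 350, 400, 350, 500)))

  expect_error(plate_stats(m |> dplyr::mutate(qc_score = 1)), "vehicle")
})

test_that("robust Z* matches direct arithmetic and its invariances", {
  expect_equal(robust_z(350, 350, 25), 0)
  expect_equal(robust_z(300, 350, 25), -2)

  set.seed(7)
  for (i in 1:200) {
    d <- runif(1, 0, 600); med <- runif(1, 100, 500); mad <- runif(1, 5, 60)
    expect_equal(robust_z(d, med, mad), oracle_robust_z(d, med, mad))
    # scale invariance
    k <- runif(1, 0.1, 10)
    expect_equal(robust_z(k * d, k * med, k * mad), robust_z(d, med, mad),
                 tolerance = 1e-12)
  }
  expect_error(robust_z(1, 0, 0), "MAD")
})

test_that("inhibition classes reproduce the reported score mapping", {
  expect_equal(as.character(classify_inhibition(-17.9)), "high")
  expect_equal(as.character(classify_inhibition(-11.9)), "moderate")
  expect_equal(as.character(classify_inhibition(c(-7.2, -5.9, -4.9))),
               rep("mild", 3))
  expect_equal(as.character(classify_inhibition(0)), "none")
  # boundary convention: exact boundaries take the more severe class
  expect_equal(as.character(classify_inhibition(c(-3, -9, -15))),
               c("mild", "moderate", "high"))
  # monotone severity
  z <- sort(runif(100, -30, 5))
  cls <- classify_inhibition(z)
  expect_true(all(diff(as.integer(cls)) <= 0))
  # oracle agreement
  set.seed(2)
  for (zz in runif(300, -25, 5)) {
    expect_equal(as.character(classify_inhibition(zz)), oracle_classify(zz))
  }
  expect_error(classify_inhibition(NA_real_), "finite")
})

test_that("Z-prime factor behaves as a separation index", {
  # groups with sample means 352.1 / 62.2 and sample SDs 42.6 / 12.4
  a0 <- 352.1 + 42.6 * c(-1, 0, 1)
  b0 <- 62.2 + 12.4 * c(-1, 0, 1)
  expect_equal(z_prime(a0, b0), 1 - 3 * (42.6 + 12.4) / (352.1 - 62.2))
  expect_equal(z_prime(a0, b0), 0.4308, tolerance = 1e-4)
  # zero spread -> exactly 1
  expect_equal(z_prime(c(10, 10), c(50, 50)), 1)
  # symmetry and oracle agreement on random groups
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(8, 350, 40); b <- rnorm(4, 60, 12)
    expect_equal(z_prime(a, b), oracle_z_prime(a, b))
    expect_equal(z_prime(a, b), z_prime(b, a))
    expect_lte(z_prime(a, b), 1)
  }
  # separation grows -> Z' grows at fixed spreads
  a <- c(340, 350, 360)
  expect_gt(z_prime(a + 200, c(50, 60, 70)), z_prime(a, c(50, 60, 70)))
  expect_error(z_prime(c(1, 1), c(1, 1)), "equal")
})

test_that("control CV is percent sd over mean", {
  expect_equal(control_cv(c(100, 100, 100)), 0)
  expect_equal(control_cv(c(90, 100, 110)), 10)
  set.seed(3)
  x <- rlnorm(10000, log(352.1), sqrt(log(1 + 0.121^2)))
  expect_lt(abs(control_cv(x) - 12.1), 1)
  expect_error(control_cv(c(-5, 5)), "mean")
})

test_that("replicate Spearman matches the rank-then-Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(replicate_spearman(x, x)$spearman, 1)
  expect_equal(replicate_spearman(x, -x)$spearman, -1)
  # hand-listed pairs with a tie
  a <- c(-5, -2, -2, 0, 3); b <- c(-4, -1, -3, 1, 2)
  expect_equal(replicate_spearman(a, b)$spearman, oracle_spearman(a, b))
  # dropped incomplete pairs are counted
  r <- replicate_spearman(c(a, NA), c(b, 1))
  expect_equal(r$n_dropped, 1L)
  expect_equal(r$n_pairs, 5L)
  expect_error(replicate_spearman(1:2, 2:1), "3 complete")
})

test_that("integrity concordance partitions duplicate pairs", {
  r <- integrity_concordance(c(4, 2, 1), c(3, 2, 3))
  expect_equal(unlist(r[1, 1:3]), c(same_pct = 100 / 3, adjacent_pct = 100 / 3,
                                    discordant_pct = 100 / 3))
  all_same <- integrity_concordance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(all_same$same_pct, 100)
  set.seed(5)
  for (i in 1:100) {
    s1 <- sample(1:4, 20, TRUE); s2 <- sample(1:4, 20, TRUE)
    r <- integrity_concordance(s1, s2)
    expect_equal(r$same_pct + r$adjacent_pct + r$discordant_pct, 100)
    expect_equal(unname(unlist(r[1, 1:3])), unname(oracle_concordance(s1, s2)))
  }
})

test_that("score_chips joins plate statistics and flags exclusions", {
  set.seed(8)
  m <- tibble::tibble(
    chip_id = paste0("c", 1:12), plate_id = "P01",
    role = c(rep("vehicle", 6), rep("sample", 6)),
    compound_id = c(rep(NA, 6), paste0("C", rep(1:3, each = 2))),
    replicate = c(rep(NA, 6), rep(1:2, 3)),
    d10_um = c(340, 350, 360, 345, 355, 350, 100, 110, 300, 310, 352, 348),
    qc_score = c(rep(4, 11), 1), integrity_score = 4)
  s <- score_chips(m)
  expect_equal(s$z_star[s$chip_id == "c1"],
               (340 - 350) / stats::median(abs(c(340, 350, 360, 345, 355, 350) - 350)))
  expect_true(s$qc_excluded[s$chip_id == "c12"])
  expect_false(any(s$qc_excluded[1:11]))
})
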