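test_that("kinetic_extent follows first-order saturation", {
  expect_equal(kinetic_extent(log(2), 1, dmax = 100), 50)
  expect_equal(kinetic_extent(0, 8), 0)
  expect_equal(kinetic_extent(1000, 8, dmax = 80), 80, tolerance = 1e-9)
  # monotone non-decreasing in t
  t <- seq(0, 8, by = 0.25)
  expect_true(all(diff(kinetic_extent(0.3, t, 80)) >= 0))
  expect_equal(kinetic_extent(0.5, 0), 0)
  expect_error(kinetic_extent(-1, 1), class = "deamid_validation_error")
  expect_error(kinetic_extent(1, 1, dmax = 0), class = "deamid_validation_error")
})

test_that("generation is bitwise deterministic for a fixed spec", {
  spec <- synthetic_spec(n_molecules = 3, seed = 11)
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a, b)
  c2 <- generate_synthetic(synthetic_spec(n_molecules = 3, seed = 12))
  expect_false(identical(a$chains$sequence, c2$chains$sequence))
})

test_that("generated data respect kinetics, LOQ and coverage conventions", {
  sim <- small_world(6)
  tc <- sim$timecourse; truth <- sim$truth
  # noiseless extents: zero at t0, non-decreasing in t
  expect_true(all(truth$noiseless_pct_t0 == 0))
  nl <- as.matrix(truth[, paste0("noiseless_", c("pct_1wk", "pct_2wk",
                                                 "pct_4wk", "pct_8wk"))])
  expect_true(all(cbind(truth$noiseless_pct_t0, nl[, -4]) <= nl + 1e-12))
  # LOQ censoring: no measured value in (0, 0.1)
  meas <- unlist(tc[, c("pct_t0", "pct_1wk", "pct_2wk", "pct_4wk", "pct_8wk")])
  meas <- meas[!is.na(meas)]
  expect_true(all(meas == 0 | meas >= 0.1))
  expect_true(all(meas <= 100))
  # uncovered sites carry no extents
  uncov <- tc[!tc$covered, c("pct_t0", "pct_8wk")]
  expect_true(all(is.na(unlist(uncov))))
  # zero-rate sites never deamidate (noiselessly)
  zero <- truth$true_k < 1e-12
  if (any(zero)) expect_true(all(nl[zero, ] == 0))
  # chains and time course use the io dialects
  expect_silent(deamidr:::validate_timecourse(tc))
  # active sites accumulate more deamidation than inactive ones
  lab <- label_sites(tc)
  expect_gt(mean(tc$pct_8wk[lab$label == "active"], na.rm = TRUE),
            mean(tc$pct_8wk[lab$label == "inactive"], na.rm = TRUE))
})

test_that("labeler reproduces ground truth on noiseless time courses", {
  sim <- generate_synthetic(synthetic_spec(n_molecules = 6, seed = 3,
                                           noise_sd = 0, missingness = 0))
  lab <- label_sites(sim$timecourse)
  tr <- sim$truth
  # increments of the noiseless kinetics, distance from the 1% threshold
  d1 <- tr$noiseless_pct_1wk - tr$noiseless_pct_t0
  d2 <- tr$noiseless_pct_2wk - tr$noiseless_pct_1wk
  outside_band <- abs(d1 - 1) > 0.15 & abs(d2 - 1) > 0.15
  expect_gt(mean(outside_band), 0.9)
  expect_equal(lab$label[outside_band], tr$true_label[outside_band])
})

test_that("unreachable target fractions raise a generation error", {
  spec <- synthetic_spec(n_molecules = 4, seed = 1,
                         target_active_fraction = 0.9)
  expect_error(generate_synthetic(spec), "unreachable",
               class = "deamid_generation_error")
})
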