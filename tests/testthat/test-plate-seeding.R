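test_that("occupancy pmf matches the Poisson closed form and normalises", {
  expect_equal(occupancy_pmf(occupancy_model(0), 0), 1.0)
  expect_equal(occupancy_pmf(occupancy_model(1.44), 0), exp(-1.44))
  expect_equal(occupancy_pmf(occupancy_model(1.44), 0), 0.2369,
               tolerance = 1e-3)
  expect_equal(occupancy_pmf(occupancy_model(2), 1), 2 * exp(-2))
  # normalisation at the truncation point used internally
  for (lam in c(0.5, 1.44, 3, 10)) {
    k <- 0:ceiling(lam + 20 * sqrt(lam) + 30)
    expect_lt(abs(1 - sum(occupancy_pmf(occupancy_model(lam), k))), 1e-12)
  }
  expect_error(occupancy_pmf(occupancy_model(1), -1), "non-negative")
  expect_error(occupancy_model(-0.1), "range")
})

test_that("blank-fraction target inverts to the published cell density", {
  # 24.3% blanks in 60 uL wells -> 23.58 CFU/mL, the density quoted as 24
  d <- density_for_blank_fraction(0.243, plate_spec(384, 60))
  expect_equal(d, -log(0.243) / 0.060)
  expect_equal(round(d), 24)
  expect_equal(density_for_blank_fraction(exp(-1), plate_spec(96, 1000)), 1)
  expect_equal(density_for_blank_fraction(0.5, plate_spec(384, 60)),
               11.55, tolerance = 1e-3)
  # round trip: exp(-density * V) recovers the target for any p0
  for (p0 in c(0.01, 0.243, 0.5, 0.9, 0.99)) {
    d <- density_for_blank_fraction(p0, plate_spec(384, 60))
    expect_equal(exp(-d * 0.060), p0)
  }
  expect_error(density_for_blank_fraction(0), "range")
  expect_error(density_for_blank_fraction(1), "range")
})

test_that("lambda calibration matches the exact binomial interval", {
  expect_equal(calibrate_lambda(96, 384)$lambda, -log(0.25))
  expect_equal(calibrate_lambda(384, 384)$lambda, 0)
  m <- calibrate_lambda(100, 384)
  expect_equal(m$lambda, -log(100 / 384), tolerance = 1e-6)
  expect_lt(m$ci[1], m$lambda)
  expect_gt(m$ci[2], m$lambda)
  # independent Clopper-Pearson oracle through the beta quantiles
  cp_lo <- qbeta(0.025, 100, 384 - 100 + 1)
  cp_hi <- qbeta(0.975, 100 + 1, 384 - 100)
  expect_equal(m$ci, c(-log(cp_hi), -log(cp_lo)), tolerance = 1e-9)
  expect_error(calibrate_lambda(0, 384), "unidentifiable")
  expect_error(calibrate_lambda(400, 384), "exceed")
})

test_that("calibration CI covers the generating lambda at nominal rate", {
  set.seed(71)
  lam <- 1.44
  n <- 384
  covered <- replicate(1000, {
    blanks <- rbinom(1, n, exp(-lam))
    if (blanks == 0) return(NA)
    ci <- calibrate_lambda(blanks, n)$ci
    ci[1] <= lam && lam <= ci[2]
  })
  expect_gte(mean(covered, na.rm = TRUE), 0.93)
})

test_that("dilution acceptance band is inclusive and configurable", {
  expect_true(dilution_acceptable(0.27))
  expect_true(all(dilution_acceptable(c(0.24, 0.30))))
  expect_false(any(dilution_acceptable(c(0.10, 0.31))))
  expect_true(dilution_acceptable(0.5, band = c(0.4, 0.6)))
  expect_error(dilution_acceptable(1.2), "\\[0, 1\\]")
})

test_that("purity given growth matches the closed form and is monotone", {
  expect_equal(purity_given_growth(5, abundance_profile(1)), 1.0)
  expect_equal(purity_given_growth(1.44, abundance_profile(c(0.5, 0.5))),
               0.655, tolerance = 1e-3)
  # truncated series vs independent closed form, several lambdas/profiles
  profiles <- list(c(1), c(0.5, 0.5), c(0.9, 0.1), rep(0.1, 10),
                   c(0.4, 0.3, 0.2, 0.1))
  for (lam in c(0.5, 1.44, 3)) {
    for (p in profiles) {
      expect_equal(purity_given_growth(lam, abundance_profile(p)),
                   purity_closed_form(lam, p), tolerance = 1e-10)
    }
  }
  # limit lambda -> 0+: single-cell wells dominate, purity -> 1
  expect_gt(purity_given_growth(1e-6, abundance_profile(c(0.5, 0.5))),
            1 - 1e-5)
  # monotone decreasing in lambda for a fixed multi-strain profile
  lams <- seq(0.2, 4, by = 0.2)
  pur <- vapply(lams,
                function(l) purity_given_growth(l, abundance_profile(c(0.6, 0.3, 0.1))),
                numeric(1))
  expect_true(all(diff(pur) < 0))
  expect_error(purity_given_growth(0, abundance_profile(c(0.5, 0.5))),
               "undefined")
})

test_that("abundance profiles validate and normalise", {
  expect_error(abundance_profile(c(0.5, 0.6)), "sum to 1")
  p <- abundance_profile(c(2, 2), normalise = TRUE)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  expect_error(abundance_profile(c(-0.1, 1.1)), "non-negative")
})

test_that("dilution series decompose greedily and multiply back exactly", {
  p <- plan_dilution_series(2.4e6, 24, max_step = 10)
  expect_equal(p$dilution_steps, rep(10, 5))
  expect_equal(plan_dilution_series(24, 24)$dilution_steps, numeric(0))
  p2 <- plan_dilution_series(240, 24, max_step = 5)
  expect_equal(p2$dilution_steps, c(5, 2))
  # product check across awkward ratios
  for (ratio in c(1.5, 7, 10, 123.4, 1e4, 3.7e5)) {
    pl <- plan_dilution_series(24 * ratio, 24)
    expect_equal(prod(pl$dilution_steps), ratio, tolerance = 1e-9)
    expect_true(all(pl$dilution_steps <= 10 + 1e-12))
  }
  expect_error(plan_dilution_series(10, 24), "upward")
  # plate-aware plan records lambda and expected blanks
  p3 <- plan_dilution_series(2.4e6, 24, plate = plate_spec(384, 60))
  expect_equal(p3$lambda, 1.44)
  expect_equal(p3$target_blank_fraction, exp(-1.44))
})
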