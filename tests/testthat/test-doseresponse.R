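test_that("dilution ladders reproduce the plate designs and their display values", {
  nine <- build_dilution_ladder(10e-6, 4, 9)
  expect_length(nine, 9)
  expect_equal(min(nine), 10e-6 / 4^8)
  expect_equal(format_concentration(min(nine)), "153 pM")

  five <- build_dilution_ladder(10e-6, 4, 5)
  expect_equal(min(five), 39.0625e-9)
  expect_equal(format_concentration(min(five)), "39.1 nM")

  single <- build_dilution_ladder(2e-6, 2, 1)
  expect_equal(as.numeric(single), 2e-6)

  # consecutive points differ by exactly the fold ratio
  for (fold in c(2, 3.16, 4, 10)) {
    lad <- build_dilution_ladder(1e-5, fold, 7)
    expect_equal(lad[-7] / lad[-1], rep(fold, 6))
  }

  expect_error(build_dilution_ladder(-1e-6, 4, 9), "positive")
  expect_error(build_dilution_ladder(1e-6, 0.5, 9), "ratio")
  expect_error(build_dilution_ladder(1e-6, 4, 0), "whole number")
})

test_that("TGI follows the baseline-adjusted growth-inhibition formula", {
  plate <- list(baseline_wells = c(990, 1010), untreated_wells = c(8900, 9100))
  expect_equal(compute_tgi(9000, plate), 0)     # indistinguishable from untreated
  expect_equal(compute_tgi(1000, plate), 1)     # stasis at seeding level
  b1 <- list(baseline_wells = 1000, untreated_wells = 9000)
  expect_equal(compute_tgi(5000, b1), 0.5)
  expect_equal(compute_tgi(500, b1), 1.0625)    # cytotoxic: > 1 retained
  expect_equal(compute_tgi(10000, b1), -0.125)  # stimulation: < 0 retained
  expect_error(
    compute_tgi(500, list(baseline_wells = 9000, untreated_wells = 1000)),
    "degenerate")
})

test_that("the 4PL fitter recovers noiseless generating parameters to 0.1%", {
  lad <- build_dilution_ladder(10e-6, 4, 9)
  cases <- list(pl4(0, 1, 10e-9, 1),
                pl4(0, 1, 8.2e-9, 1.2),
                pl4(0.05, 0.95, 150e-9, 1.8))
  for (truth in cases) {
    fit <- fit_4pl(lad, predict_4pl(truth, lad))
    expect_equal(fit$censored, "exact")
    expect_lt(abs(fit$ic50 - truth$ic50) / truth$ic50, 1e-3)
    expect_lt(abs(fit$hill - truth$hill) / truth$hill, 1e-2)
    expect_lt(abs(fit$upper - truth$upper), 1e-3)
  }
})

test_that("flat and right-shifted curves are reported as censored bounds, not IC50s", {
  lad <- build_dilution_ladder(10e-6, 4, 9)
  flat <- fit_4pl(lad, rep(0, 9))
  expect_equal(flat$censored, "greater_than_top")
  expect_equal(flat$ic50, 10e-6)  # bound equals the top tested dose
  # true IC50 100x above the top dose
  truth <- pl4(0, 1, 1e-3, 1)
  shifted <- fit_4pl(lad, predict_4pl(truth, lad))
  expect_equal(shifted$censored, "greater_than_top")
  expect_error(fit_4pl(lad[1:3], c(1, 0.5, 0)), "insufficient")
})

test_that("predict_4pl hits its analytic anchor points", {
  f <- pl4(0, 1, 3e-8, 2.7)
  expect_equal(predict_4pl(f, 3e-8), 0.5)               # inflection midpoint
  expect_equal(predict_4pl(pl4(0.2, 0.8, 1e-8, 1), 1e-8), 0.5)
  expect_equal(predict_4pl(pl4(0, 1, 10e-9, 1), 40e-9), 0.8)
  expect_equal(predict_4pl(f, 1), 1, tolerance = 1e-6)  # asymptote
  expect_error(predict_4pl(f, 0), "positive")
  # monotone non-decreasing in dose for h > 0, U >= L
  d <- 10^seq(-12, -4, length.out = 50)
  expect_true(all(diff(predict_4pl(f, d)) >= 0))
})

test_that("round-trip recovery holds over random generating curves", {
  lad <- build_dilution_ladder(10e-6, 4, 9)
  set.seed(11)
  for (i in 1:15) {
    truth <- pl4(runif(1, 0, 0.15), runif(1, 0.75, 1),
                 10^runif(1, -8.5, -6.5), runif(1, 0.6, 3))
    fit <- fit_4pl(lad, predict_4pl(truth, lad))
    expect_lt(abs(fit$ic50 - truth$ic50) / truth$ic50, 1e-3)
  }
})

test_that("the fit agrees with an independent nonlinear least-squares fit", {
  skip_if_not_installed("minpack.lm")
  lad <- build_dilution_ladder(10e-6, 4, 9)
  truth <- pl4(0, 1, 25e-9, 1.4)
  set.seed(3)
  y <- predict_4pl(truth, lad) + rnorm(9, 0, 0.03)
  fit <- fit_4pl(lad, y)
  df <- data.frame(logd = log10(as.numeric(lad)), y = y)
  ref <- minpack.lm::nlsLM(
    y ~ L + (U - L) / (1 + 10^(h * (m - logd))), data = df,
    start = list(L = 0, U = 1, m = -7.5, h = 1))
  expect_equal(fit$ic50, 10^coef(ref)[["m"]], tolerance = 0.02)
  expect_equal(fit$hill, coef(ref)[["h"]], tolerance = 0.05)
})
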