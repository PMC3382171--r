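test_that("Bliss expectation follows independence algebra", {
  expect_equal(bliss_expected(0, 0), 0)
  expect_equal(bliss_expected(1, 0.3), 1)      # full inhibition dominates
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_error(bliss_expected(NA, 0.2), "finite")
  # symmetry, bounds, monotonicity over a grid
  g <- seq(0, 1, by = 0.1)
  M <- outer(g, g, bliss_expected)
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(apply(M, 1, diff) >= -1e-12))
  # inputs outside [0,1] are clipped before combination
  expect_equal(bliss_expected(1.4, -0.2), 1)
})

test_that("ΔBLISS surfaces recover analytic interior excess", {
  # edges (0, 0.2, 0.4) x (0, 0.3, 0.5); interior = Bliss value + 0.1
  ea <- c(0, 0.2, 0.4); eb <- c(0, 0.3, 0.5)
  obs <- outer(ea, eb, function(a, b) a + b - a * b)
  obs[2:3, 2:3] <- obs[2:3, 2:3] + 0.1
  surf <- delta_bliss_surface(obs, c(0, 1e-9, 4e-9), c(0, 1e-9, 4e-9))
  expect_equal(unname(surf$delta[2:3, 2:3]), matrix(0.1, 2, 2))
  expect_equal(unname(surf$delta[1, ]), rep(0, 3))
  expect_equal(unname(surf$delta[, 1]), rep(0, 3))
})

test_that("ΔBLISS is zero under exact additivity and one under full rescue", {
  doses <- build_dilution_ladder(1e-6, 4, 5)
  add <- simulate_combination(pl4(0, 1, 5e-8, 1), pl4(0, 1, 2e-7, 1.2),
                              "bliss", doses_a = doses, doses_b = doses)
  surf <- delta_bliss_surface(add$observed, add$doses_a, add$doses_b)
  expect_equal(max(abs(surf$delta)), 0)

  resc <- simulate_combination(flat_4pl(), flat_4pl(), "rescue",
                               rescue_params = full_4pl(),
                               doses_a = doses, doses_b = doses)
  surf2 <- delta_bliss_surface(resc$observed, resc$doses_a, resc$doses_b)
  expect_equal(max(surf2$delta), 1)
})

test_that("ΔBLISS is invariant to swapping the two drugs", {
  doses <- build_dilution_ladder(1e-6, 4, 4)
  set.seed(5)
  sim <- simulate_combination(pl4(0, 0.7, 5e-8, 1), pl4(0, 0.9, 2e-7, 1.5),
                              "rescue", rescue_params = pl4(0, 1, 1e-8, 1),
                              doses_a = doses, doses_b = doses,
                              gate_a = 1e-8, gate_b = 1e-8)
  s1 <- delta_bliss_surface(sim$observed, sim$doses_a, sim$doses_b)
  s2 <- delta_bliss_surface(t(sim$observed), sim$doses_b, sim$doses_a)
  expect_equal(unname(s1$delta), unname(t(s2$delta)))
  expect_true(all(s1$delta >= 0 & s1$delta <= 1))
  expect_true(all(s1$excess >= -1))
})

test_that("mean ΔBLISS vanishes as noise shrinks on a Bliss-additive surface", {
  doses <- build_dilution_ladder(1e-6, 4, 5)
  means <- vapply(c(0.1, 0.02, 0), function(cv) {
    sim <- simulate_combination(pl4(0, 0.8, 5e-8, 1), pl4(0, 0.8, 5e-8, 1),
                                "bliss", doses_a = doses, doses_b = doses,
                                noise_cv = cv, seed = 42)
    mean(delta_bliss_surface(sim$observed, sim$doses_a, sim$doses_b)$delta)
  }, 0)
  expect_true(all(diff(means) <= 0))
  expect_equal(means[3], 0)
})

test_that("surfaces without single-agent edges are rejected", {
  expect_error(delta_bliss_surface(matrix(0.5, 3, 3),
                                   c(1e-9, 4e-9, 1.6e-8),
                                   c(0, 1e-9, 4e-9)),
               "zero-dose")
})

test_that("the synergy window reports exclusive dose bounds below the qualifying block", {
  # 5 non-zero doses each way; delta = 1 only on the top-right 2x2 block
  da <- c(0, sort(as.numeric(build_dilution_ladder(1e-5, 4, 5))))
  delta <- matrix(0, 6, 6)
  delta[5:6, 5:6] <- 1
  obs <- delta  # edges 0 => expected 0 => delta equals observed
  surf <- delta_bliss_surface(obs, da, da)
  expect_equal(unname(surf$delta), unname(delta))
  win <- max_synergy_window(surf)
  # bound = third dose of the descending ladder (first below the block)
  expect_false(win$empty)
  expect_equal(win$min_dose_a, da[4])
  expect_equal(win$min_dose_b, da[4])
  # all-zero surface has no window
  empty <- max_synergy_window(delta_bliss_surface(matrix(0, 6, 6), da, da))
  expect_true(empty$empty)
})

test_that("the window matches simulation truth for a gated rescue surface", {
  doses <- build_dilution_ladder(1e-5, 4, 6)   # 10 uM ... ~9.8 nM
  asc <- sort(as.numeric(doses))
  gate <- asc[3]  # rescue only above the third ascending dose
  sim <- simulate_combination(flat_4pl(), flat_4pl(), "rescue",
                              rescue_params = full_4pl(),
                              doses_a = doses, doses_b = doses,
                              gate_a = gate, gate_b = gate)
  surf <- delta_bliss_surface(sim$observed, sim$doses_a, sim$doses_b)
  win <- max_synergy_window(surf)
  expect_equal(win$min_dose_a, gate)
  expect_equal(win$min_dose_b, gate)
})

test_that("the antagonism model leaves a negative signed excess", {
  doses <- build_dilution_ladder(1e-6, 4, 5)
  sim <- simulate_combination(pl4(0, 0.8, 5e-8, 1), pl4(0, 0.8, 5e-8, 1),
                              "antagonism", doses_a = doses, doses_b = doses)
  surf <- delta_bliss_surface(sim$observed, sim$doses_a, sim$doses_b)
  expect_lt(min(surf$excess), 0)
  expect_error(simulate_combination(flat_4pl(), flat_4pl(), "loewe",
                                    doses_a = doses, doses_b = doses),
               "unknown interaction model")
})
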