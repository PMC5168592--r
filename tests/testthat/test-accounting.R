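test_that("OD to dry weight conversion is linear through 330", {
  expect_equal(od_to_dry_weight(1), 330)
  expect_equal(od_to_dry_weight(c(0, 0.5)), c(0, 165))
  expect_error(od_to_dry_weight(-0.1), "non-negative")
})

test_that("carbon recovery modes count the right pools", {
  # a perfectly closed hand-built run: glucose -> 2 acetate + 2 CO2 + cells
  # with cell carbon absorbing the remaining glucose carbon
  glu <- c(0, 10)
  ac <- c(0, 16)  # 1.6 mol/mol -> 4.8 C of 6
  cells_c <- 6 * 10 - 2 * 16 - 16 # mmol C: glucose minus acetate minus CO2
  cells_mg <- c(5, 5 + cells_c * 12.011 / 0.5)
  run <- fermentation_run(c(0, 10), cells_mg, glu, lactate = c(0, 0),
                          acetate = ac, h2 = 2 * ac,
                          co2_mode = "acetate_stoichiometric",
                          phases = c(t0 = 0, t1 = 0, t2 = 10, t3 = 10))
  expect_equal(carbon_recovery(run, "to_t2", "C1"), 100)
  # C2 adds only non-negative terms
  expect_gte(carbon_recovery(run, "to_t2", "C2"),
             carbon_recovery(run, "to_t2", "C1"))
  expect_error(carbon_recovery(run, c(0, 0.0)), "duration")
})

test_that("specific rates recover a constant q under exponential growth", {
  # X(t) = X0 e^(mu t), product flux qc * X => delta P * mu / delta X = qc
  mu <- 0.3; x0 <- 20; qc <- 0.05 # mmol per mg per h scaled below
  tt <- seq(0, 10, by = 0.5)
  X <- x0 * exp(mu * tt)
  P <- qc / mu * (X - x0) # integral of qc * X dt
  run <- fermentation_run(tt, X, glucose_consumed = P, lactate = 0 * tt,
                          acetate = 0 * tt, h2 = P,
                          co2_mode = "acetate_stoichiometric",
                          phases = c(t0 = 0, t1 = 1, t2 = 9, t3 = 10))
  q <- specific_rates(run, "growth")
  expect_equal(unname(q["q_H2"]), qc * 1000, tolerance = 1e-10)
  expect_equal(unname(q["q_glucose"]), qc * 1000, tolerance = 1e-10)
  # and the volumetric rate factorises as q times log-mean biomass
  Q <- volumetric_rates(run, "growth")
  expect_equal(unname(Q["QH2"]),
               unname(q["q_H2"]) * log_mean_biomass(run, "growth") / 1000)
})

test_that("log-mean biomass handles the constant-biomass limit", {
  run <- fermentation_run(c(0, 5), c(100, 100), c(0, 2), c(0, 0), c(0, 1),
                          h2 = c(0, 2), co2_mode = "acetate_stoichiometric",
                          phases = c(t0 = 0, t1 = 0, t2 = 5, t3 = 5))
  expect_equal(log_mean_biomass(run, c(0, 5)), 100)
  expect_equal(unname(specific_rates(run, c(0, 5))["q_H2"]), (2 / 5) / 0.1)
})

test_that("volumetric rates are plain window slopes", {
  run <- serum_bottle_runs()$control
  expect_equal(unname(volumetric_rates(run, 14.5)["Qcells"]),
               (108.2 - 4.8) / 14.5)
  # no change over a window gives zero
  flat <- fermentation_run(c(0, 1, 2), c(10, 20, 20), c(0, 1, 1), c(0, 0, 0),
                           c(0, 0.5, 0.5), h2 = c(0, 1, 1),
                           co2_mode = "acetate_stoichiometric",
                           phases = c(t0 = 0, t1 = 0, t2 = 1, t3 = 2))
  expect_equal(unname(volumetric_rates(flat, c(1, 2))), c(0, 0, 0))
})

test_that("molar yields are ratios to glucose with sane errors", {
  run <- serum_bottle_runs()$control
  y <- molar_yields(run, 14.5)
  expect_equal(unname(y["h2_per_acetate"]), 9.3 / 5.4)
  expect_equal(unname(y["acetate_per_glu"]), 5.4 / 3.8)
  expect_equal(unname(y["cells_per_glu"]), (108.2 - 4.8) / 3.8)
  flat <- fermentation_run(c(0, 2), c(10, 10), c(0, 0), c(0, 0), c(0, 0),
                           h2 = c(0, 0), co2_mode = "acetate_stoichiometric",
                           phases = c(t0 = 0, t1 = 0, t2 = 2, t3 = 2))
  expect_error(molar_yields(flat, c(0, 2)), "no glucose")
})

test_that("thiosulfate yield regression: exact line, restriction, scaling", {
  # two exact points
  fit <- yield_on_thiosulfate(c(0, 1), c(0, 1), limited_range_max = 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  # points above the limited range are excluded from the fit
  pts <- thiosulfate_yield_points()
  fit_all <- yield_on_thiosulfate(pts$thiosulfate, pts$max_cells)
  expect_equal(fit_all$n, 4)
  # scale equivariance: scaling cells scales the slope
  fit_scaled <- yield_on_thiosulfate(pts$thiosulfate, 2 * pts$max_cells)
  expect_equal(fit_scaled$slope, 2 * fit_all$slope)
  expect_error(yield_on_thiosulfate(c(0.2, 0.3), c(1, 2)), "at least 2")
  expect_error(yield_on_thiosulfate(c(0.01, 0.01), c(1, 2)), "variance")
})

test_that("noisy known-slope points are recovered within 2 SE", {
  set.seed(2024)
  x <- rep(c(0, 0.01, 0.02, 0.03, 0.04, 0.06), 2)
  y <- 50 + 3000 * x + rnorm(length(x), 0, 10)
  fit <- yield_on_thiosulfate(x, y)
  expect_lt(abs(fit$slope - 3000), 2 * fit$slope_se)
})

test_that("sulfur budget arithmetic follows the elemental cell formula", {
  prof <- stoichiometry_profile()
  expect_equal(prof$formula_mass,
               12.011 + 1.6 * 1.008 + 0.6 * 15.999 + 0.2 * 14.007 +
                 0.005 * 32.06)
  sb <- sulfur_budget(128, 1, 0)
  expect_equal(sb$S_YE, 0.07)
  expect_equal(sb$S_thiosulfate, 0)
  expect_equal(sb$S_cells, 0.005 * 128 / prof$formula_mass)
  expect_equal(sb$S_cells, 0.0244, tolerance = 2e-3)
  zero <- sulfur_budget(0, 1, 0.06)
  expect_equal(zero$S_cells, 0)
  expect_equal(zero$incorporation_ratio, 0)
})

test_that("detoxification capacity is 4 H2 per thiosulfate", {
  expect_equal(thiosulfate_detox_capacity(0.15), 0.6)
  expect_equal(thiosulfate_detox_capacity(0), 0)
  expect_equal(thiosulfate_detox_capacity(1), 4)
})

test_that("yield_report bundles every layer consistently", {
  run <- thiosulfate_runs()[["0.12"]]
  rep <- yield_report(run, "to_t2")
  expect_s3_class(rep, "yield_report")
  expect_equal(unname(rep$recovery["C1"]), carbon_recovery(run, "to_t2", "C1"))
  expect_equal(rep$yields, molar_yields(run, "to_t2"))
  expect_equal(rep$volumetric, volumetric_rates(run, "to_t2"))
  expect_output(print(rep), "C recovery")
})
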