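# Regression of the derived columns of the packaged study tables: every
# printed ratio, recovery and rate should be reproduced from the raw columns
# within the expect_printed tolerance (printed inputs are rounded means).

test_that("serum-bottle derived columns recompute from raw columns", {
  runs <- serum_bottle_runs()
  # printed: condition/time -> (H2/acet, C-recovery, Qcells, Qglu, QH2)
  printed <- list(
    control = list(`14.5` = c(1.71, 96.2, 7.14, 0.26, 0.64),
                   `22` = c(2.10, 91.4, 6.98, 0.32, 0.97)),
    thiosulfate = list(`14.5` = c(1.80, 94.5, 16.96, 1.06, 2.74),
                       `22` = c(1.97, 93.0, 6.92, 0.79, 2.15)),
    Na2S = list(`14.5` = c(1.81, 89.3, 17.92, 1.41, 3.51),
                `22` = c(1.79, 94.4, 10.43, 0.93, 2.49))
  )
  for (cond in names(printed)) {
    run <- runs[[cond]]
    for (tchr in names(printed[[cond]])) {
      tend <- as.numeric(tchr)
      exp_v <- printed[[cond]][[tchr]]
      expect_printed(molar_yields(run, tend)[["h2_per_acetate"]],
                     exp_v[1], 2)
      expect_printed(carbon_recovery(run, tend, "C1"), exp_v[2], 1)
      rates <- volumetric_rates(run, tend)
      expect_printed(rates[["Qcells"]], exp_v[3], 2)
      expect_printed(rates[["Qglu"]], exp_v[4], 2)
      expect_printed(rates[["QH2"]], exp_v[5], 2)
    }
  }
})

test_that("hydrogen partial-pressure runs reproduce printed yield shifts", {
  runs <- ph2_runs()
  # acetate/glu and lactate/glu at t3: the catabolic shift with pH2
  expect_printed(molar_yields(runs[["7.1"]], "full")[["acetate_per_glu"]],
                 1.3, 1)
  expect_printed(molar_yields(runs[["7.1"]], "full")[["lactate_per_glu"]],
                 0.5, 1)
  expect_printed(molar_yields(runs[["606.9"]], "full")[["acetate_per_glu"]],
                 1.0, 1)
  expect_printed(molar_yields(runs[["606.9"]], "full")[["lactate_per_glu"]],
                 0.8, 1)
  # H2/CO2 ~ 2 and CO2/acetate ~ 1 where H2 was measurable
  y <- molar_yields(runs[["71.4"]], "to_t2")
  expect_printed(y[["h2_per_acetate"]] / (y[["co2_per_acetate"]]), 2.15, 1)
  expect_printed(y[["co2_per_acetate"]], 0.89, 1)
  # C recovery at t2, measured CO2
  expect_printed(carbon_recovery(runs[["7.1"]], "to_t2", "C1"), 91.2, 1)
  expect_printed(carbon_recovery(runs[["178.5"]], "to_t2", "C1"), 90.1, 1)
})

test_that("thiosulfate-run derived columns recompute from raw columns", {
  runs <- thiosulfate_runs()
  # printed t2-window values: thio -> (C1, acet/glu, lac/glu, H2/glu,
  #                                    q_glucose, q_H2)
  printed <- list(
    "0" = c(54.9, 0.7, 0.3, 1.4, 8.9, 13.4),
    "0.01" = c(70.4, 0.8, 0.5, 1.6, 12.0, 20.4),
    "0.03" = c(74.6, 1.1, 0.3, 2.1, 13.1, 27.7),
    "0.06" = c(78.1, 1.0, 0.5, 1.9, 14.8, 28.7),
    "0.12" = c(79.2, 1.1, 0.4, 2.1, 18.5, 40.4),
    "0.18" = c(81.5, 1.0, 0.5, 1.9, 18.8, 36.3),
    "0.24" = c(84.3, 1.0, 0.5, 2.0, 17.9, 36.6)
  )
  for (th in names(printed)) {
    run <- runs[[th]]
    exp_v <- printed[[th]]
    expect_printed(carbon_recovery(run, "to_t2", "C1"), exp_v[1], 1)
    y <- molar_yields(run, "to_t2")
    expect_printed(y[["acetate_per_glu"]], exp_v[2], 1)
    expect_printed(y[["lactate_per_glu"]], exp_v[3], 1)
    expect_printed(y[["h2_per_glu"]], exp_v[4], 1)
    q <- specific_rates(run, "growth")
    expect_printed(q[["q_glucose"]], exp_v[5], 1)
    expect_printed(q[["q_H2"]], exp_v[6], 1)
  }
  # cells/glu (g/mol) where the printed ratio matches the produced-biomass
  # convention (the 0 and 0.01 rows reflect replicate-level averaging that
  # printed raw means cannot reproduce)
  for (th in c("0.06", "0.12", "0.24")) {
    expect_printed(molar_yields(runs[[th]], "to_t2")[["cells_per_glu"]],
                   c("0.06" = 8.5, "0.12" = 8.9, "0.24" = 9.6)[[th]], 1)
  }
  # C2 recoveries where alanine and EPS were assayed
  expect_printed(carbon_recovery(runs[["0"]], "to_t2", "C2"), 87.2, 1)
  expect_printed(carbon_recovery(runs[["0.12"]], "to_t2", "C2"), 92.2, 1)
  expect_printed(carbon_recovery(runs[["0.24"]], "to_t2", "C2"), 95.8, 1)
})

test_that("sulfur budgets of the two reported conditions match the table", {
  cond <- sulfur_budget_conditions()
  b1 <- sulfur_budget(cond$cells[1], cond$yeast_extract[1],
                      cond$thiosulfate[1])
  b2 <- sulfur_budget(cond$cells[2], cond$yeast_extract[2],
                      cond$thiosulfate[2])
  expect_equal(b1$S_thiosulfate, 0)
  expect_equal(b2$S_thiosulfate, 0.12)
  expect_printed(b1$S_cells, 0.025, 3)
  expect_printed(b2$S_cells, 0.068, 3)
  expect_equal(round(b1$incorporation_ratio), 35)
  expect_equal(round(b2$incorporation_ratio), 36)
})

test_that("all packaged fixtures satisfy run invariants and round-trip", {
  dir <- file.path(tempdir(), "fermgas-fixture-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- emit_fixture_tables(dir)
  expect_length(paths, 18)
  for (p in paths) {
    run <- load_run(p)
    expect_s3_class(run, "fermentation_run")
    expect_true(all(diff(run$data$time_h) > 0))
    expect_true(all(diff(run$data$glucose_consumed) >= -1e-9))
  }
  # a specific provenance spot check
  thio06 <- load_run(file.path(dir, "thio_0.06.csv"))
  expect_equal(thio06$data$cells[3], 353.5)
  expect_equal(thio06$thiosulfate, 0.06)
})
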