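cfg <- headspace_config()

const_production <- function(time_h, q_h2, q_co2) {
  production_series(time_h, rep(q_h2, length(time_h)),
                    rep(q_co2, length(time_h)), config = cfg)
}

test_that("pure carrier flushes the headspace to 100 % nitrogen", {
  tt <- seq(0, 8, by = 1 / 30)
  prod <- const_production(tt, 0, 0)
  out <- simulate_headspace(prod, n2_flow_policy = 30, config = cfg,
                            initial_fractions = c(n2 = 60, h2 = 25, co2 = 15))
  expect_equal(tail(out$p_n2, 1), 100, tolerance = 1e-6)
  expect_equal(tail(out$p_h2, 1), 0, tolerance = 1e-6)
})

test_that("outlet fractions equal flow fractions at steady state", {
  tt <- seq(0, 8, by = 1 / 30)
  # Q_N2 = 57, Q_H2 = 3 at headspace temperature -> 5 % hydrogen
  q_ref <- 57 / ((273 + cfg$T_head) / (273 + cfg$T_ref))
  out <- simulate_headspace(const_production(tt, 3, 0), q_ref, cfg)
  expect_equal(tail(out$p_h2, 1), 5, tolerance = 1e-6)
  expect_equal(tail(out$p_n2, 1), 95, tolerance = 1e-6)
})

test_that("fractions close to 100 % at every step", {
  tt <- seq(0, 6, by = 1 / 30)
  prod <- production_series(tt, Q_H2 = 2 + sin(tt) + 1,
                            Q_CO2 = 1.5 + 0.5 * cos(tt), config = cfg)
  out <- simulate_headspace(prod, n2_flow_policy = 35, config = cfg)
  expect_lt(max(abs(attr(out, "closure_residual"))), 1e-6)
})

test_that("a step in production relaxes with the residence-time constant", {
  dt <- 1 / 120
  tt <- seq(0, 10, by = dt)
  q_n2_head <- 45; q_h2_0 <- 1; q_h2_1 <- 3
  t_step <- 4
  qh2 <- ifelse(tt < t_step, q_h2_0, q_h2_1)
  prod <- production_series(tt, qh2, rep(0, length(tt)), config = cfg)
  q_ref <- q_n2_head / ((273 + cfg$T_head) / (273 + cfg$T_ref))
  out <- simulate_headspace(prod, q_ref, cfg, sample_times_h = tt)
  V <- cfg$V_HR - cfg$V_Steam
  qt <- q_n2_head + q_h2_1
  tau_min <- V / qt
  p_inf <- 100 * q_h2_1 / qt
  p_0 <- 100 * q_h2_0 / (q_n2_head + q_h2_0)
  after <- tt > t_step
  analytic <- p_inf + (p_0 - p_inf) *
    exp(-(tt[after] - t_step) * 60 / tau_min)
  expect_equal(out$p_h2[after], analytic, tolerance = 1e-3)
})

test_that("vented + held gas equals produced + initial inventory", {
  tt <- seq(0, 8, by = 1 / 30)
  prod <- production_series(tt, Q_H2 = 1 + tt / 4, Q_CO2 = 0.5 + tt / 8,
                            config = cfg)
  out <- simulate_headspace(prod, n2_flow_policy = 40, config = cfg)
  bal <- attr(out, "balance")
  n <- nrow(bal)
  for (sp in c("n2", "h2", "co2")) {
    vented <- bal[[paste0("out_", sp)]][n]
    held <- bal[[paste0("held_", sp)]][n] - bal[[paste0("held_", sp)]][1]
    produced <- bal[[paste0("in_", sp)]][n]
    expect_equal(vented + held, produced, tolerance = 1e-6)
  }
})

test_that("forward-then-inverse round trip recovers piecewise-constant rates", {
  set.seed(42)
  dt <- 1 / 120
  tt <- seq(0, 12, by = dt)
  V <- cfg$V_HR - cfg$V_Steam
  for (rep in 1:3) {
    breaks <- c(0, sort(runif(2, 2, 9)), Inf)
    lv_h2 <- runif(3, 0.5, 4)
    lv_co2 <- runif(3, 0.5, 3)
    seg <- findInterval(tt, breaks)
    prod <- production_series(tt, lv_h2[seg], lv_co2[seg], config = cfg)
    out <- simulate_headspace(prod, n2_flow_policy = 40, config = cfg)
    rec <- reconstruct_production(out, cfg)
    qt_min <- 40 * (273 + cfg$T_head) / (273 + cfg$T_ref) # carrier alone
    res_h <- V / qt_min / 60 # residence time in hours, upper bound
    settled <- rep(TRUE, length(tt))
    for (b in breaks[is.finite(breaks)]) {
      # also drop the two samples before the break: the central difference
      # there already spans the discontinuity
      settled <- settled & !(tt >= b - 2 * dt & tt < b + res_h)
    }
    expect_lt(max(abs(rec$Q_H2[settled] - lv_h2[seg][settled]) /
                    lv_h2[seg][settled]), 0.01)
    expect_lt(max(abs(rec$Q_CO2[settled] - lv_co2[seg][settled]) /
                    lv_co2[seg][settled]), 0.01)
  }
})

test_that("algebraic inversion at steady state matches hand values", {
  # p_H2 = p_CO2 = 5 %, Q_N2 = 54 at headspace T -> Q_H2 = Q_CO2 = 3
  tt <- seq(0, 1, by = 1 / 60)
  n <- length(tt)
  q_ref <- 54 / ((273 + cfg$T_head) / (273 + cfg$T_ref))
  out <- outlet_gas_series(tt, p_n2 = rep(90, n), p_h2 = rep(5, n),
                           p_co2 = rep(5, n), q_n2_ref = rep(q_ref, n))
  rec <- reconstruct_production(out, cfg)
  expect_equal(rec$Q_H2, rep(3, n), tolerance = 1e-9)
  expect_equal(rec$Q_CO2, rep(3, n), tolerance = 1e-9)
})

test_that("zero hydrogen signal yields zero cumulative hydrogen", {
  tt <- seq(0, 2, by = 1 / 60)
  n <- length(tt)
  out <- outlet_gas_series(tt, rep(95, n), rep(0, n), rep(5, n),
                           q_n2_ref = rep(30, n))
  rec <- reconstruct_production(out, cfg)
  expect_true(all(rec$cum_H2 == 0))
  expect_true(all(diff(rec$cum_CO2) >= 0))
})

test_that("degenerate inputs are rejected", {
  tt <- seq(0, 1, by = 0.1)
  n <- length(tt)
  expect_error(outlet_gas_series(tt, rep(50, n), rep(10, n), rep(10, n),
                                 rep(10, n)), "sum to 100")
  expect_error(outlet_gas_series(rev(tt), rep(90, n), rep(5, n), rep(5, n),
                                 rep(10, n)), "increasing")
  ok <- outlet_gas_series(tt, c(rep(90, n - 1), 0), c(rep(5, n - 1), 95),
                          rep(5, n), rep(10, n))
  expect_error(reconstruct_production(ok, cfg), "singular")
  prod <- const_production(tt, 0, 0)
  expect_error(simulate_headspace(prod, n2_flow_policy = 0, config = cfg),
               "identically zero")
})

test_that("closed-loop control pins outlet hydrogen to the setpoint", {
  tt <- seq(0, 20, by = 1 / 30)
  # slowly varying production: logistic ramp from ~0.2 to ~4 mL/min
  qh2 <- 4 / (1 + exp(-(tt - 8) / 2.5))
  prod <- production_series(tt, qh2, qh2 / 2, config = cfg)
  out <- simulate_headspace(prod, n2_flow_policy = "setpoint", config = cfg)
  active <- !attr(out, "empty_trigger") & out$time_h > 2
  expect_gt(sum(active), 50)
  expect_lt(max(abs(out$p_h2[active] - cfg$h2_setpoint)), 0.5)
})

test_that("dissolved CO2 correction adds the carbonate inventory", {
  tt <- seq(0, 4, by = 1 / 30)
  prod <- const_production(tt, 3, 1.5)
  out <- simulate_headspace(prod, n2_flow_policy = 40, config = cfg)
  out$pH <- 7
  rec <- reconstruct_production(out, cfg)
  corr <- total_co2_production(rec, out, cfg)
  n <- nrow(corr)
  inv <- total_dissolved_co2(tail(out$p_co2, 1) / 100 * cfg$P_total, 7,
                             cfg$liquid_volume) / cfg$liquid_volume
  expect_equal(corr$cum_CO2_total[n], corr$cum_CO2[n] + inv)
  # continuous mode starts at zero correction
  corr2 <- total_co2_production(rec, out, cfg, mode = "continuous")
  expect_equal(corr2$cum_CO2_total[1], corr2$cum_CO2[1])
  expect_gt(corr2$cum_CO2_total[n], corr2$cum_CO2[n])
})
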