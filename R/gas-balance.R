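# Headspace gas mass balance of a nitrogen-sparged, isobaric bioreactor.
#
# For each gaseous species X in {N2, CO2, H2}, with pure inlet streams
# (p_X = 100 %), the outlet fraction obeys
#
#   dp_X^out/dt = [Q_X * 100 - Q_T^out * p_X^out] / (V_HR - V_Steam)
#
# with Q_T^out = Q_N2 + Q_CO2 + Q_H2 and fractions summing to 100 %.
# Flows are at headspace temperature; volumes in mL; internal time in min.

.rate_fun <- function(time_h, values) {
  t_min <- .hours_to_min(time_h)
  if (length(t_min) == 1L) return(function(t) rep(values, length(t)))
  stats::approxfun(t_min, values, rule = 2)
}

#' Simulate the outlet gas composition of a sparged headspace
#'
#' Integrates the three-species headspace mass balance forward in time from
#' known biological production flows, under a carrier-gas policy. Policies:
#' a single number or a vector aligned to `production$time_h` (carrier flow at
#' the meter reference temperature, mL min^-1), a function of time in hours
#' returning such a flow, or `"setpoint"` for the closed loop in which the
#' steady-state feedforward law of [control_n2_flow()] is applied through a
#' first-order actuator with time constant `control_tau_min` (the plant-style
#' 5 % outlet-H2 regulation, floored at the initial carrier flow).
#'
#' @param production a [production_series()] (or data.frame with `time_h`,
#'   `Q_H2`, `Q_CO2`): biological flows at headspace temperature, mL min^-1.
#'   The time grid must be finer than the headspace residence time
#'   `(V_HR - V_Steam)/Q_T` for the interpolation to be faithful.
#' @param n2_flow_policy carrier-flow policy, see Details above.
#' @param config a [headspace_config()].
#' @param initial_fractions named vector of starting outlet fractions in
#'   percent (`n2`, `h2`, `co2`); defaults to pure nitrogen.
#' @param sample_times_h output grid, hours; defaults to the production grid.
#' @param control_tau_min actuator smoothing time constant, minutes
#'   (setpoint policy only).
#' @param rtol,atol integrator tolerances passed to [deSolve::ode()].
#' @return An [outlet_gas_series()] with the temperature-uncorrected carrier
#'   record in `q_n2_ref`; attribute `balance` holds a data.frame of
#'   cumulative produced and vented volumes (mL at headspace temperature) per
#'   species plus the headspace inventory, for conservation checks, and
#'   attribute `empty_trigger` flags samples where the carrier demand fell
#'   below the emptying threshold.
#' @examples
#' prod <- production_series(seq(0, 10, 0.05), Q_H2 = rep(3, 201),
#'                           Q_CO2 = rep(1.5, 201))
#' out <- simulate_headspace(prod, n2_flow_policy = "setpoint")
#' tail(out$p_h2, 1) # ~5 % once the controller has settled
#' @export
simulate_headspace <- function(production, n2_flow_policy = "setpoint",
                               config = headspace_config(),
                               initial_fractions = c(n2 = 100, h2 = 0, co2 = 0),
                               sample_times_h = production$time_h,
                               control_tau_min = 5,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(c("time_h", "Q_H2", "Q_CO2") %in% names(production)))
  .assert_increasing(production$time_h, "production$time_h")
  .assert_nonneg(production$Q_H2, "Q_H2")
  .assert_nonneg(production$Q_CO2, "Q_CO2")
  if (abs(sum(initial_fractions) - 100) > 1e-6) {
    .stopf("'initial_fractions' must sum to 100 %%")
  }

  V <- config$V_HR - config$V_Steam
  qh2_f <- .rate_fun(production$time_h, production$Q_H2)
  qco2_f <- .rate_fun(production$time_h, production$Q_CO2)
  closed_loop <- identical(n2_flow_policy, "setpoint")
  floor_head <- correct_flow_to_headspace(config$initial_n2_flow, config)

  if (closed_loop) {
    qn2_f <- NULL
  } else if (is.function(n2_flow_policy)) {
    qn2_f <- function(t) correct_flow_to_headspace(
      n2_flow_policy(.min_to_hours(t)), config)
  } else if (is.numeric(n2_flow_policy)) {
    .assert_nonneg(n2_flow_policy, "n2_flow_policy")
    qn2_f <- .rate_fun(
      if (length(n2_flow_policy) == 1L) production$time_h[1] else production$time_h,
      correct_flow_to_headspace(n2_flow_policy, config))
  } else {
    .stopf("'n2_flow_policy' must be \"setpoint\", a numeric or a function")
  }

  if (!closed_loop) {
    if (max(qn2_f(.hours_to_min(production$time_h))) <= 0 &&
        max(production$Q_H2 + production$Q_CO2) <= 0) {
      .stopf("total gas flow is identically zero: steady state undefined")
    }
  }

  deriv <- function(t, y, parms) {
    qh2 <- qh2_f(t); qco2 <- qco2_f(t)
    if (closed_loop) {
      qn2 <- y[["qn2"]]
      target <- as.numeric(control_n2_flow(qh2, qco2, config,
                                           floor_flow = floor_head))
      dqn2 <- (target - qn2) / control_tau_min
    } else {
      qn2 <- qn2_f(t)
      dqn2 <- NULL
    }
    qt <- qn2 + qh2 + qco2
    dp_n2 <- (qn2 * 100 - qt * y[["p_n2"]]) / V
    dp_h2 <- (qh2 * 100 - qt * y[["p_h2"]]) / V
    dp_co2 <- (qco2 * 100 - qt * y[["p_co2"]]) / V
    # cumulative vented volume per species and cumulative inputs (mL at head T)
    list(c(dp_n2, dp_h2, dp_co2, dqn2,
           qt * y[["p_n2"]] / 100, qt * y[["p_h2"]] / 100,
           qt * y[["p_co2"]] / 100, qn2, qh2, qco2),
         qn2_now = qn2)
  }

  y0 <- c(p_n2 = unname(initial_fractions["n2"]),
          p_h2 = unname(initial_fractions["h2"]),
          p_co2 = unname(initial_fractions["co2"]))
  if (closed_loop) y0 <- c(y0, qn2 = floor_head)
  y0 <- c(y0, out_n2 = 0, out_h2 = 0, out_co2 = 0,
          in_n2 = 0, in_h2 = 0, in_co2 = 0)

  times <- .hours_to_min(sort(unique(sample_times_h)))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)

  qn2_head <- if (closed_loop) sol$qn2 else qn2_f(times)
  q_n2_ref <- qn2_head / ((273 + config$T_head) / (273 + config$T_ref))
  # renormalise the tiny integrator closure residual before validation
  total <- sol$p_n2 + sol$p_h2 + sol$p_co2
  out <- outlet_gas_series(
    time_h = .min_to_hours(times),
    p_n2 = pmax(sol$p_n2, 0), p_h2 = pmax(sol$p_h2, 0),
    p_co2 = pmax(sol$p_co2, 0), q_n2_ref = q_n2_ref, tol = 0.5)
  attr(out, "closure_residual") <- total - 100
  attr(out, "balance") <- data.frame(
    time_h = .min_to_hours(times),
    out_n2 = sol$out_n2, out_h2 = sol$out_h2, out_co2 = sol$out_co2,
    in_n2 = sol$in_n2, in_h2 = sol$in_h2, in_co2 = sol$in_co2,
    held_n2 = V * sol$p_n2 / 100, held_h2 = V * sol$p_h2 / 100,
    held_co2 = V * sol$p_co2 / 100)
  attr(out, "empty_trigger") <-
    qn2_head < correct_flow_to_headspace(config$empty_trigger_flow, config)
  out
}

#' Reconstruct biological gas production from an outlet gas record
#'
#' Inverts the headspace mass balance per time step. With the
#' temperature-corrected carrier flow known, the nitrogen balance yields the
#' total outlet flow `Q_T = (100 * Q_N2 - V * dp_N2/dt) / p_N2`, after which
#' the H2 and CO2 balances give `Q_X = (V * dp_X/dt + Q_T * p_X) / 100`.
#' Time derivatives are estimated by central finite differences; where
#' `|dp/dt| * V / Q_T` falls below `min_deriv_frac` (in percentage points,
#' default 0.001) the derivative term is dropped (quasi-steady-state step).
#' The default only removes numerically negligible derivative terms, keeping
#' the round-trip error of genuine transients below 1 %; raise it towards
#' 0.1 on noisy, coarsely sampled records to trade bias for variance. Negative reconstructed flows, which arise from
#' measurement noise, are clipped to zero before integration; the raw values
#' are kept in `Q_H2_raw`/`Q_CO2_raw` for diagnostics. Volumetric flows are
#' converted to molar flows by the ideal-gas law at headspace temperature and
#' total pressure, then integrated to cumulative mmol per litre of culture.
#'
#' @param outlet an [outlet_gas_series()].
#' @param config a [headspace_config()].
#' @param min_deriv_frac quasi-steady-state threshold on
#'   `|dp/dt| * V / Q_T`, percentage points.
#' @return A [production_series()] with diagnostic columns `Q_H2_raw`,
#'   `Q_CO2_raw` and `Q_T` appended.
#' @export
reconstruct_production <- function(outlet, config = headspace_config(),
                                   min_deriv_frac = 0.001) {
  stopifnot(inherits(outlet, "data.frame"),
            all(c("time_h", "p_n2", "p_h2", "p_co2", "q_n2_ref")
                %in% names(outlet)))
  .assert_increasing(outlet$time_h, "time_h")
  if (any(outlet$p_n2 <= 0)) {
    .stopf("p_n2 reaches 0: the nitrogen-balance inversion is singular")
  }
  V <- config$V_HR - config$V_Steam
  qn2 <- correct_flow_to_headspace(outlet$q_n2_ref, config)
  t_min <- .hours_to_min(outlet$time_h)

  d_n2 <- V * .grad(t_min, outlet$p_n2)
  d_h2 <- V * .grad(t_min, outlet$p_h2)
  d_co2 <- V * .grad(t_min, outlet$p_co2)
  # quasi-steady-state throughput estimate used only for the drop criterion
  qt_qss <- 100 * qn2 / outlet$p_n2
  small <- function(d) abs(d) / qt_qss < min_deriv_frac
  d_n2[small(d_n2)] <- 0
  d_h2[small(d_h2)] <- 0
  d_co2[small(d_co2)] <- 0

  q_t <- (100 * qn2 - d_n2) / outlet$p_n2
  q_h2_raw <- (d_h2 + q_t * outlet$p_h2) / 100
  q_co2_raw <- (d_co2 + q_t * outlet$p_co2) / 100

  prod <- production_series(outlet$time_h,
                            Q_H2 = pmax(q_h2_raw, 0),
                            Q_CO2 = pmax(q_co2_raw, 0),
                            config = config)
  prod$Q_H2_raw <- q_h2_raw
  prod$Q_CO2_raw <- q_co2_raw
  prod$Q_T <- q_t
  prod
}

#' Total CO2 production including the dissolved inventory
#'
#' Cumulative gas-phase CO2 leaves part of the produced CO2 behind as
#' dissolved carbonate species. This correction adds the liquid-phase
#' inventory, computed by [total_dissolved_co2()] from the headspace CO2
#' fraction and the pH record, either once at the end of the run (default) or
#' continuously at every sample.
#'
#' @param production a [production_series()] from [reconstruct_production()].
#' @param outlet the matching [outlet_gas_series()]; its `p_co2` and `pH`
#'   columns supply the equilibrium state.
#' @param config a [headspace_config()].
#' @param constants a [carbonate_constants()].
#' @param mode `"end"` (correct the final cumulative value only) or
#'   `"continuous"` (add the instantaneous inventory change at every sample).
#' @return The production series with `cum_CO2_total` (mmol per litre)
#'   appended.
#' @export
total_co2_production <- function(production, outlet,
                                 config = headspace_config(),
                                 constants = carbonate_constants(),
                                 mode = c("end", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(nrow(production) == nrow(outlet))
  if (all(is.na(outlet$pH))) {
    .stopf("the outlet record carries no pH: dissolved CO2 is undefined")
  }
  inv <- vapply(seq_len(nrow(outlet)), function(i) {
    total_dissolved_co2(outlet$p_co2[i] / 100 * config$P_total, outlet$pH[i],
                        config$liquid_volume, constants)
  }, numeric(1)) / config$liquid_volume # mmol per litre of culture
  production$cum_CO2_total <- production$cum_CO2
  n <- nrow(production)
  if (mode == "end") {
    production$cum_CO2_total[n] <- production$cum_CO2[n] + inv[n]
  } else {
    production$cum_CO2_total <- production$cum_CO2 + (inv - inv[1])
  }
  production
}
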