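# Synthetic batch fermentations with the stoichiometric structure the
# accounting layer assumes: sulfur-limited logistic growth, glucose routed to
# acetate/lactate/alanine/EPS/cell pathways in fixed fractions, 2 H2 and
# 1 CO2 per acetate, gas production vented through the simulated headspace
# under the 5 % outlet-H2 control loop, and multiplicative measurement noise.

#' Configuration of a synthetic fermentation run
#'
#' Defaults describe the bioreactor study conditions: glucose 60 mmol L^-1,
#' yeast extract 1 g L^-1, thiosulfate 0.06 mmol L^-1, a cell yield on
#' thiosulfate of 3617 mg mmol^-1 with the sulfur of 1 g L^-1 yeast extract
#' equivalent to 0.03 mmol L^-1 thiosulfate, and a product split per mole of
#' glucose of roughly 1 acetate : 0.44 lactate : 2 H2 : 1 CO2 with small
#' alanine and EPS branches and a cell yield of 9 g mol^-1.
#'
#' Pathway fractions `f_*` are fractions of consumed glucose molecules routed
#' to each branch (glucose -> 2 acetate + 2 CO2 + 4 H2; -> 2 lactate;
#' -> 2 alanine; -> 1 EPS glucose equivalent). The cell branch is derived
#' from `cells_per_glu` (about 144 g cells per mol glucose at 100 % routing,
#' given 50 % cell carbon content); all fractions must sum to at most 1,
#' any remainder being unmeasured carbon. Under sulfur limitation
#' (thiosulfate below `eps_shift_threshold`) carbon shifts from the acetate
#' branch to EPS by up to `eps_shift_max`, emulating the stress response.
#'
#' @param mu_max maximum specific growth rate, h^-1.
#' @param yield_cells_per_thiosulfate true cell yield on thiosulfate,
#'   mg mmol^-1.
#' @param ye_sulfur_equiv thiosulfate equivalent of the sulfur in 1 g of
#'   yeast extract, mmol g^-1.
#' @param glucose_0,thiosulfate_0 initial glucose and thiosulfate, mmol L^-1.
#' @param yeast_extract yeast extract, g L^-1.
#' @param x0 inoculum, mg L^-1.
#' @param cells_per_glu cell yield on glucose, g mol^-1.
#' @param f_acetate,f_lactate,f_alanine,f_eps pathway fractions (see above).
#' @param eps_shift_threshold,eps_shift_max sulfur-limitation EPS up-shift.
#' @param maintenance maintenance glucose consumption, mmol per mg cells per
#'   hour.
#' @param noise_cv relative (multiplicative Gaussian) measurement noise.
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @param sample_interval sampling interval, h (default 2 min, the off-gas
#'   analysis cadence).
#' @param t_end run length, h.
#' @param ideal if TRUE, enforce exact carbon closure: no maintenance, no
#'   alanine/EPS branches, acetate absorbing all non-cell, non-lactate
#'   carbon, and no noise. Useful as a conservation oracle.
#' @param config a [headspace_config()] for the gas phase.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(mu_max = 0.35,
                              yield_cells_per_thiosulfate = 3617,
                              ye_sulfur_equiv = 0.03,
                              glucose_0 = 60, thiosulfate_0 = 0.06,
                              yeast_extract = 1, x0 = 25,
                              cells_per_glu = 9,
                              f_acetate = 0.50, f_lactate = 0.22,
                              f_alanine = 0.045, f_eps = 0.07,
                              eps_shift_threshold = 0.06,
                              eps_shift_max = 0.18,
                              maintenance = 5e-4,
                              noise_cv = 0.05, seed = 1L,
                              sample_interval = 1 / 30, t_end = 30,
                              ideal = FALSE,
                              config = headspace_config()) {
  if (mu_max <= 0) .stopf("'mu_max' must be positive")
  .assert_nonneg(c(glucose_0, thiosulfate_0, yeast_extract, noise_cv,
                   maintenance), "concentrations and rates")
  if (x0 <= 0) .stopf("'x0' must be positive")
  # mg of cells supported by 1 mmol of glucose routed entirely to biomass
  # (6 carbons at 50 % cell carbon content)
  mg_cells_per_mmol_glu <- 6 * .ATOMIC_MASS[["C"]] / 0.5
  f_cells <- cells_per_glu / mg_cells_per_mmol_glu
  if (ideal) {
    f_alanine <- 0
    f_eps <- 0
    eps_shift_max <- 0
    maintenance <- 0
    noise_cv <- 0
    f_acetate <- 1 - f_cells - f_lactate
  }
  fr <- c(cells = f_cells, acetate = f_acetate, lactate = f_lactate,
          alanine = f_alanine, eps = f_eps)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12) {
    .stopf("pathway fractions are infeasible (sum %.3f with cells %.3f)",
           sum(fr), f_cells)
  }
  structure(
    list(mu_max = mu_max,
         yield_cells_per_thiosulfate = yield_cells_per_thiosulfate,
         ye_sulfur_equiv = ye_sulfur_equiv, glucose_0 = glucose_0,
         thiosulfate_0 = thiosulfate_0, yeast_extract = yeast_extract,
         x0 = x0, cells_per_glu = cells_per_glu, fractions = fr,
         eps_shift_threshold = eps_shift_threshold,
         eps_shift_max = eps_shift_max, maintenance = maintenance,
         noise_cv = noise_cv, seed = as.integer(seed),
         sample_interval = sample_interval, t_end = t_end, ideal = ideal,
         headspace = config),
    class = "simulation_config"
  )
}

# Effective pathway fractions after the sulfur-limitation EPS up-shift.
.effective_fractions <- function(cfg) {
  fr <- cfg$fractions
  if (cfg$eps_shift_max > 0 && cfg$thiosulfate_0 < cfg$eps_shift_threshold) {
    shift <- cfg$eps_shift_max *
      (1 - cfg$thiosulfate_0 / cfg$eps_shift_threshold)
    shift <- min(shift, fr[["acetate"]])
    fr[["eps"]] <- fr[["eps"]] + shift
    fr[["acetate"]] <- fr[["acetate"]] - shift
  }
  fr
}

#' Simulate a synthetic batch fermentation run
#'
#' Integrates logistic growth toward the sulfur-set biomass ceiling
#' `x0 + Y_X/Thio * (thiosulfate_0 + ye_sulfur_equiv * yeast_extract)`,
#' couples glucose consumption to growth (plus a maintenance term) and
#' products to glucose through the pathway fractions, then routes the H2 and
#' CO2 production through [simulate_headspace()] under the closed-loop 5 %
#' outlet-H2 controller. Both the noiseless truth and a noisy measured
#' channel (multiplicative Gaussian, truncated at zero, fixed seed) are
#' returned. Growth and consumption stop if glucose runs out, and the run is
#' flagged.
#'
#' @param cfg a [simulation_config()].
#' @param include_gas integrate the headspace gas phase (set FALSE to skip
#'   the ODE when only the liquid-phase accounting is needed).
#' @return An object of class `synthetic_run`: list with `run` (measured
#'   [fermentation_run()]), `truth_run` (noiseless), `production` (true
#'   [production_series()]), `outlet` (measured [outlet_gas_series()], when
#'   `include_gas`), `params` (the config plus derived true quantities) and
#'   `glucose_exhausted`.
#' @examples
#' sr <- simulate_run(simulation_config(noise_cv = 0, seed = 7,
#'                                      sample_interval = 0.2),
#'                    include_gas = FALSE)
#' molar_yields(sr$truth_run, "full")[["h2_per_acetate"]] # exactly 2
#' @export
simulate_run <- function(cfg = simulation_config(), include_gas = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  fr <- .effective_fractions(cfg)
  x_max <- cfg$x0 + cfg$yield_cells_per_thiosulfate *
    (cfg$thiosulfate_0 + cfg$ye_sulfur_equiv * cfg$yeast_extract)
  # mmol glucose per mg cells (inverse of the biomass routing capacity)
  glu_per_cells <- 1 / (6 * .ATOMIC_MASS[["C"]] / 0.5 * fr[["cells"]])

  deriv <- function(t, y, parms) {
    exhausted <- y[["glu"]] >= cfg$glucose_0
    dx <- if (exhausted) 0 else cfg$mu_max * y[["X"]] * (1 - y[["X"]] / x_max)
    dglu <- if (exhausted) 0 else
      dx * glu_per_cells + cfg$maintenance * y[["X"]]
    list(c(dx, dglu))
  }
  times <- seq(0, cfg$t_end, by = cfg$sample_interval)
  sol <- as.data.frame(deSolve::ode(
    y = c(X = cfg$x0, glu = 0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = 1e-8, atol = 1e-10))
  glu <- pmin(sol$glu, cfg$glucose_0)
  exhausted <- any(sol$glu >= cfg$glucose_0 - 1e-9)

  acetate <- 2 * fr[["acetate"]] * glu
  lactate <- 2 * fr[["lactate"]] * glu
  alanine <- 2 * fr[["alanine"]] * glu
  eps <- fr[["eps"]] * glu
  h2 <- 2 * acetate
  co2 <- acetate

  phases <- c(
    t0 = 0,
    t1 = times[which(sol$X >= 1.2 * cfg$x0)[1]],
    t2 = times[which(sol$X >= 0.995 * max(sol$X))[1]],
    t3 = cfg$t_end)
  if (is.na(phases["t1"]) || phases["t1"] >= phases["t2"]) {
    phases["t1"] <- times[2]
  }

  truth_run <- fermentation_run(
    time_h = times, cells = sol$X, glucose_consumed = glu,
    lactate = lactate, acetate = acetate, h2 = h2, co2 = co2,
    alanine = alanine, eps_glucose_equiv = eps,
    thiosulfate = cfg$thiosulfate_0, yeast_extract = cfg$yeast_extract,
    phases = phases, co2_mode = "measured", label = "synthetic truth")

  # gas production: mmol L^-1 h^-1 -> mL min^-1 at headspace conditions
  hs <- cfg$headspace
  ml_per_mmol <- .R_GAS * .C_TO_K(hs$T_head) * 1000 / hs$P_total
  rate_to_flow <- function(conc) {
    .grad(times, conc) * hs$liquid_volume / 60 * ml_per_mmol
  }
  production <- production_series(
    time_h = times, Q_H2 = pmax(rate_to_flow(h2), 0),
    Q_CO2 = pmax(rate_to_flow(co2), 0), config = hs)

  noisy <- function(x) {
    if (cfg$noise_cv <= 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, cfg$noise_cv)), 0)
  }
  measured_glu <- if (cfg$noise_cv > 0) cummax(noisy(glu)) else glu
  run <- fermentation_run(
    time_h = times, cells = noisy(sol$X), glucose_consumed = measured_glu,
    lactate = noisy(lactate), acetate = noisy(acetate), h2 = noisy(h2),
    co2 = noisy(co2), alanine = noisy(alanine),
    eps_glucose_equiv = noisy(eps), thiosulfate = cfg$thiosulfate_0,
    yeast_extract = cfg$yeast_extract, phases = phases,
    co2_mode = "measured", label = "synthetic measured")

  outlet <- NULL
  if (include_gas) {
    outlet <- simulate_headspace(production, n2_flow_policy = "setpoint",
                                 config = hs)
    if (cfg$noise_cv > 0) {
      p_h2 <- pmin(pmax(noisy(outlet$p_h2), 0), 100)
      p_co2 <- pmin(pmax(noisy(outlet$p_co2), 0), 100 - p_h2)
      outlet <- outlet_gas_series(outlet$time_h, 100 - p_h2 - p_co2,
                                  p_h2, p_co2, outlet$q_n2_ref,
                                  pH = outlet$pH, tol = 0.5)
    }
  }

  structure(
    list(run = run, truth_run = truth_run, production = production,
         outlet = outlet,
         params = list(config = cfg, x_max = x_max,
                       fractions_effective = fr),
         glucose_exhausted = exhausted),
    class = "synthetic_run"
  )
}

#' @export
print.synthetic_run <- function(x, ...) {
  cfg <- x$params$config
  cat(sprintf("Synthetic run: thiosulfate %g mmol/L, glucose %g mmol/L, seed %d\n",
              cfg$thiosulfate_0, cfg$glucose_0, cfg$seed))
  cat(sprintf("  biomass ceiling %0.1f mg/L, reached %0.1f mg/L%s\n",
              x$params$x_max, max(x$truth_run$data$cells),
              if (x$glucose_exhausted) " (glucose exhausted)" else ""))
  invisible(x)
}

#' Sweep initial thiosulfate and recover the cell yield
#'
#' Runs one synthetic batch per thiosulfate level, reads the measured cell
#' concentration at the end of the growth phase (the t2 marker, the
#' convention of the study tables) as the maximum biomass of each run, and
#' fits [yield_on_thiosulfate()]. This is the parameter-recovery experiment
#' validating the regression against a generator with known truth.
#'
#' @param thiosulfate_levels initial thiosulfate levels, mmol L^-1.
#' @param cfg a template [simulation_config()]; its seed is offset per level.
#' @param limited_range_max passed to [yield_on_thiosulfate()].
#' @return A [yield_on_thiosulfate()] result, with attribute `points`.
#' @export
recover_yield_from_sweep <- function(thiosulfate_levels = c(0, 0.01, 0.03, 0.06),
                                     cfg = simulation_config(),
                                     limited_range_max = 0.06) {
  max_cells <- vapply(seq_along(thiosulfate_levels), function(i) {
    cfg_i <- cfg
    cfg_i$thiosulfate_0 <- thiosulfate_levels[i]
    cfg_i$seed <- cfg$seed + i
    sr <- simulate_run(cfg_i, include_gas = FALSE)
    .run_at(sr$run, "cells", sr$run$phases["t2"])
  }, numeric(1))
  fit <- yield_on_thiosulfate(thiosulfate_levels, max_cells,
                              limited_range_max)
  attr(fit, "points") <- data.frame(thiosulfate = thiosulfate_levels,
                                    max_cells = max_cells)
  fit
}
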