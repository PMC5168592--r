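#' Headspace configuration for a sparged batch bioreactor
#'
#' Fixed reactor geometry, temperatures and control settings used by the gas
#' mass-balance model. Defaults describe a 2.3 L double-jacket vessel with a
#' 1.5 L working volume sparged with nitrogen carrier gas: 960 mL headspace of
#' which 320 mL is water vapour, headspace at 69 degrees C (median during a
#' run), culture at 80 degrees C, mass-flow meter referenced to 20 degrees C,
#' atmospheric pressure, a 5 % setpoint on the outlet hydrogen fraction, and
#' reactor emptying triggered when the regulated carrier flow falls below
#' 15 mL min^-1.
#'
#' @param V_HR headspace volume, mL.
#' @param V_Steam water-vapour volume inside the headspace, mL. The model
#'   integrates over the dry-gas volume `V_HR - V_Steam`.
#' @param T_head headspace temperature, degrees Celsius.
#' @param T_ref mass-flow-meter reference temperature, degrees Celsius.
#' @param T_liquid culture temperature, degrees Celsius.
#' @param P_total total pressure, bar.
#' @param h2_setpoint target outlet hydrogen fraction, percent.
#' @param empty_trigger_flow carrier flow (mL min^-1, at `T_ref`) below which
#'   the process triggers reactor emptying.
#' @param initial_n2_flow initial carrier flow (mL min^-1, at `T_ref`), also
#'   the floor of the controller.
#' @param liquid_volume working liquid volume, L; used to express cumulative
#'   gas production per litre of culture.
#' @return An object of class `headspace_config`.
#' @examples
#' cfg <- headspace_config()
#' cfg$V_HR - cfg$V_Steam # dry headspace volume driving the dynamics
#' @export
headspace_config <- function(V_HR = 960, V_Steam = 320, T_head = 69,
                             T_ref = 20, T_liquid = 80, P_total = 1,
                             h2_setpoint = 5, empty_trigger_flow = 15,
                             initial_n2_flow = 10, liquid_volume = 1.5) {
  if (V_HR <= 0 || V_Steam <= 0 || V_Steam >= V_HR) {
    .stopf("require 0 < V_Steam < V_HR (got V_Steam = %g, V_HR = %g)",
           V_Steam, V_HR)
  }
  if (P_total <= 0) .stopf("'P_total' must be positive")
  if (h2_setpoint <= 0 || h2_setpoint >= 100) {
    .stopf("'h2_setpoint' must lie strictly between 0 and 100 %%")
  }
  if (empty_trigger_flow <= 0 || initial_n2_flow <= 0 || liquid_volume <= 0) {
    .stopf("flows and liquid volume must be positive")
  }
  structure(
    list(V_HR = V_HR, V_Steam = V_Steam, T_head = T_head, T_ref = T_ref,
         T_liquid = T_liquid, P_total = P_total, h2_setpoint = h2_setpoint,
         empty_trigger_flow = empty_trigger_flow,
         initial_n2_flow = initial_n2_flow, liquid_volume = liquid_volume),
    class = "headspace_config"
  )
}

#' @export
print.headspace_config <- function(x, ...) {
  cat("Headspace configuration\n")
  cat(sprintf("  dry headspace volume : %g mL (V_HR %g - V_Steam %g)\n",
              x$V_HR - x$V_Steam, x$V_HR, x$V_Steam))
  cat(sprintf("  temperatures         : head %g C, liquid %g C, meter ref %g C\n",
              x$T_head, x$T_liquid, x$T_ref))
  cat(sprintf("  pressure             : %g bar, working volume %g L\n",
              x$P_total, x$liquid_volume))
  cat(sprintf("  H2 setpoint          : %g %%, emptying below %g mL/min, initial N2 %g mL/min\n",
              x$h2_setpoint, x$empty_trigger_flow, x$initial_n2_flow))
  invisible(x)
}

#' Correct a carrier-gas flow from meter reference to headspace temperature
#'
#' Mass-flow meters report volumetric flow at a reference temperature; inside
#' the headspace the same molar flow occupies a larger volume. The isobaric
#' ideal-gas correction is `flow * (273 + T_head) / (273 + T_ref)`.
#'
#' @param flow_at_ref flow at the meter reference temperature, mL min^-1.
#' @param config a [headspace_config()].
#' @return Flow at headspace temperature, mL min^-1.
#' @examples
#' correct_flow_to_headspace(50) # 50 * 342/293 = 58.36 mL/min
#' @export
correct_flow_to_headspace <- function(flow_at_ref, config = headspace_config()) {
  .assert_nonneg(flow_at_ref, "flow_at_ref")
  flow_at_ref * (273 + config$T_head) / (273 + config$T_ref)
}

#' Water-vapour volume of the headspace from the Antoine equation
#'
#' Diagnostic estimate of the vapour fraction of the headspace: the Antoine
#' saturation pressure of water at `T` divided by the total pressure, times
#' the headspace volume. The pipeline default keeps the fixed
#' `V_Steam = 320` mL of [headspace_config()]; this function exists to make
#' the sensitivity of the dry volume to the vapour model inspectable (standard
#' Antoine constants give about 286 mL at 69 degrees C rather than 320 mL).
#'
#' @param T temperature, degrees Celsius; must lie in (0, 100).
#' @param config a [headspace_config()] supplying `V_HR` and `P_total`.
#' @param A,B,C Antoine constants for water with pressure in mmHg and
#'   temperature in degrees Celsius (defaults: Antoine's 1888 parameterisation
#'   for the 1-100 degree range).
#' @return Vapour volume, mL.
#' @examples
#' steam_volume_antoine(69) # ~286 mL
#' @export
steam_volume_antoine <- function(T, config = headspace_config(),
                                 A = 8.07131, B = 1730.63, C = 233.426) {
  if (!is.finite(T) || T <= 0 || T >= 100) {
    .stopf("'T' must lie strictly between 0 and 100 degrees C")
  }
  p_sat_mmHg <- 10^(A - B / (C + T))
  p_sat_bar <- p_sat_mmHg * 1.01325 / 760
  frac <- pmin(p_sat_bar / config$P_total, 1)
  frac * config$V_HR
}

#' Carrier-gas flow achieving the outlet hydrogen setpoint
#'
#' Steady-state feedforward control law: at steady state the outlet fractions
#' equal the flow fractions, so holding hydrogen at setpoint `s` requires
#' `Q_N2 = Q_H2 * (100 - s)/s - Q_CO2` (all flows at headspace temperature).
#' The result is floored at `floor_flow`; an `empty_trigger` attribute flags
#' when the (pre-floor) demand falls below the emptying threshold, the
#' condition that ends a fermentation cycle.
#'
#' @param Q_H2,Q_CO2 biological gas production flows at headspace temperature,
#'   mL min^-1.
#' @param config a [headspace_config()].
#' @param floor_flow minimum carrier flow, mL min^-1 at headspace temperature;
#'   defaults to the temperature-corrected `initial_n2_flow`.
#' @return Carrier flow at headspace temperature (mL min^-1), with logical
#'   attribute `empty_trigger`.
#' @examples
#' control_n2_flow(3, 1.5) # 3*19 - 1.5 = 55.5 mL/min
#' @export
control_n2_flow <- function(Q_H2, Q_CO2, config = headspace_config(),
                            floor_flow = correct_flow_to_headspace(
                              config$initial_n2_flow, config)) {
  .assert_nonneg(Q_H2, "Q_H2")
  .assert_nonneg(Q_CO2, "Q_CO2")
  s <- config$h2_setpoint
  if (s <= 0) .stopf("invalid configuration: h2_setpoint must be positive")
  demand <- Q_H2 * (100 - s) / s - Q_CO2
  flow <- pmax(demand, floor_flow)
  trigger_level <- correct_flow_to_headspace(config$empty_trigger_flow, config)
  structure(flow, empty_trigger = flow < trigger_level)
}
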