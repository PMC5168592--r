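# Containers for the two sides of the headspace inverse problem: what the
# off-gas train measures (outlet_gas_series) and what the organism does
# (production_series).

#' Outlet gas record of a sparged bioreactor
#'
#' Timestamped outlet gas composition together with the carrier-flow record of
#' the mass-flow meter: the measured object of the inverse problem. Fractions
#' are percentages of total pressure and must sum to 100 within `tol` at every
#' sample (the closure constraint of an isobaric headspace).
#'
#' @param time_h sampling times, hours, strictly increasing.
#' @param p_n2,p_h2,p_co2 outlet fractions of N2, H2 and CO2, percent.
#' @param q_n2_ref carrier (N2) flow at the meter reference temperature,
#'   mL min^-1, aligned to `time_h`.
#' @param pH optional culture pH record (used by the dissolved-CO2
#'   correction); recycled if length 1.
#' @param tol closure tolerance on `p_n2 + p_h2 + p_co2 - 100`, percent.
#' @return A `data.frame` of class `outlet_gas_series`.
#' @export
outlet_gas_series <- function(time_h, p_n2, p_h2, p_co2, q_n2_ref,
                              pH = NA_real_, tol = 0.5) {
  .assert_increasing(time_h, "time_h")
  n <- length(time_h)
  stopifnot(length(p_n2) == n, length(p_h2) == n, length(p_co2) == n,
            length(q_n2_ref) == n)
  for (nm in c("p_n2", "p_h2", "p_co2")) {
    v <- get(nm)
    if (any(v < 0 | v > 100)) .stopf("'%s' must lie in [0, 100] %%", nm)
  }
  .assert_nonneg(q_n2_ref, "q_n2_ref")
  closure <- p_n2 + p_h2 + p_co2 - 100
  if (any(abs(closure) > tol)) {
    .stopf("outlet fractions do not sum to 100 %% within %g (worst %.3g at row %d)",
           tol, max(abs(closure)), which.max(abs(closure)))
  }
  structure(
    data.frame(time_h = time_h, p_n2 = p_n2, p_h2 = p_h2, p_co2 = p_co2,
               q_n2_ref = q_n2_ref, pH = rep_len(pH, n)),
    class = c("outlet_gas_series", "data.frame")
  )
}

#' Biological gas production series
#'
#' Biological H2 and CO2 production flows at headspace temperature, with
#' their cumulative totals per litre of culture: the latent object the inverse
#' problem reconstructs, and the input of the forward simulation.
#'
#' @param time_h times, hours, strictly increasing.
#' @param Q_H2,Q_CO2 production flows at headspace temperature, mL min^-1.
#' @param cum_H2,cum_CO2 cumulative production, mmol per litre of culture;
#'   computed by trapezoidal integration of the flows (via the ideal-gas
#'   molar conversion) when omitted.
#' @param config a [headspace_config()] used for the molar conversion.
#' @return A `data.frame` of class `production_series`.
#' @export
production_series <- function(time_h, Q_H2, Q_CO2, cum_H2 = NULL,
                              cum_CO2 = NULL, config = headspace_config()) {
  .assert_increasing(time_h, "time_h")
  n <- length(time_h)
  stopifnot(length(Q_H2) == n, length(Q_CO2) == n)
  .assert_nonneg(Q_H2, "Q_H2")
  .assert_nonneg(Q_CO2, "Q_CO2")
  to_mmol_l <- function(q) {
    rate <- .flow_to_mmol_min(q, config$T_head, config$P_total)
    .cumtrapz(.hours_to_min(time_h), rate) / config$liquid_volume
  }
  if (is.null(cum_H2)) cum_H2 <- to_mmol_l(Q_H2)
  if (is.null(cum_CO2)) cum_CO2 <- to_mmol_l(Q_CO2)
  if (any(diff(cum_H2) < -1e-9) || any(diff(cum_CO2) < -1e-9)) {
    .stopf("cumulative production must be non-decreasing")
  }
  structure(
    data.frame(time_h = time_h, Q_H2 = Q_H2, Q_CO2 = Q_CO2,
               cum_H2 = cum_H2, cum_CO2 = cum_CO2),
    class = c("production_series", "data.frame")
  )
}
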