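# Physical constants and unit helpers shared across the package.
# Flows are handled in mL min^-1, volumes in mL, time externally in hours and
# internally in minutes; all conversions live here.

# Gas constant in mL bar mmol^-1 K^-1 (8.3145 J mol^-1 K^-1).
.R_GAS <- 0.0831446

# Standard atomic masses, g mol^-1.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)

.C_TO_K <- function(temp_c) temp_c + 273.15

#' Convert a volumetric gas flow to a molar flow
#'
#' Ideal-gas conversion of a volumetric flow measured at a given temperature
#' and pressure into a molar flow.
#'
#' @param flow_ml_min volumetric flow, mL min^-1.
#' @param temp_c gas temperature, degrees Celsius.
#' @param pressure_bar total pressure, bar.
#' @return molar flow, mmol min^-1.
#' @keywords internal
#' @noRd
.flow_to_mmol_min <- function(flow_ml_min, temp_c, pressure_bar) {
  flow_ml_min * pressure_bar / (.R_GAS * .C_TO_K(temp_c) * 1000)
}

.hours_to_min <- function(h) h * 60
.min_to_hours <- function(m) m / 60

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    .stopf("'%s' must be finite and non-negative", name)
  }
  invisible(x)
}

.assert_increasing <- function(time, name = "time") {
  if (length(time) < 2L || any(diff(time) <= 0)) {
    bad <- if (length(time) >= 2L) which(diff(time) <= 0)[1L] + 1L else 1L
    .stopf("'%s' must be strictly increasing (violation at row %d)", name, bad)
  }
  invisible(time)
}

# Trapezoidal cumulative integral of y over x, same length as x, starts at 0.
.cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Central finite differences on a possibly non-uniform grid; one-sided at the
# ends. Matches the truncation order of numpy-style gradient estimates.
.grad <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    h1 <- x[2:(n - 1)] - x[1:(n - 2)]
    h2 <- x[3:n] - x[2:(n - 1)]
    d[2:(n - 1)] <- (h1^2 * y[3:n] - h2^2 * y[1:(n - 2)] +
      (h2^2 - h1^2) * y[2:(n - 1)]) / (h1 * h2 * (h1 + h2))
  }
  d
}
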