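# Derived fermentation quantities: carbon recoveries, molar yields,
# volumetric and specific rates, thiosulfate yield regression, sulfur budget.

#' Stoichiometric constants of the accounting layer
#'
#' Carbon atoms per mole of each measured pool, the carbon mass fraction of
#' dry cells, the ideal fermentation ratios (2 H2 and 1 CO2 per acetate), the
#' H2-per-thiosulfate detoxification stoichiometry, and the elemental cell
#' formula C1 H1.6 O0.6 N0.2 S0.005 whose formula-unit mass (~26.18 g per
#' formula mol) converts cell dry weight to elemental inventories.
#'
#' @param carbon named vector of carbon atoms per mole.
#' @param cell_c_fraction g carbon per g cell dry weight.
#' @param h2_per_acetate ideal mol H2 per mol acetate.
#' @param h2_per_thiosulfate mol H2 oxidised per mol thiosulfate reduced to
#'   sulfide.
#' @param cell_formula named vector of atoms per carbon in the cell formula.
#' @return An object of class `stoichiometry_profile`; `$formula_mass` holds
#'   the derived formula-unit mass in g per formula mol.
#' @export
stoichiometry_profile <- function(carbon = c(glucose = 6, acetate = 2,
                                             lactate = 3, alanine = 3,
                                             eps_glucose_equiv = 6, co2 = 1),
                                  cell_c_fraction = 0.5,
                                  h2_per_acetate = 2,
                                  h2_per_thiosulfate = 4,
                                  cell_formula = c(C = 1, H = 1.6, O = 0.6,
                                                   N = 0.2, S = 0.005)) {
  stopifnot(all(carbon > 0), cell_c_fraction > 0, h2_per_acetate > 0,
            h2_per_thiosulfate > 0, all(cell_formula >= 0))
  formula_mass <- sum(cell_formula * .ATOMIC_MASS[names(cell_formula)])
  structure(
    list(carbon = carbon, cell_c_fraction = cell_c_fraction,
         h2_per_acetate = h2_per_acetate,
         h2_per_thiosulfate = h2_per_thiosulfate,
         cell_formula = cell_formula, formula_mass = formula_mass),
    class = "stoichiometry_profile"
  )
}

# CO2 change over a window honouring the run's co2_mode.
.delta_co2 <- function(run, window) {
  if (run$co2_mode == "acetate_stoichiometric" || all(is.na(run$data$co2))) {
    .run_delta(run, "acetate", window)
  } else {
    .run_delta(run, "co2", window)
  }
}

#' Carbon recovery of a fermentation window
#'
#' Fraction of the carbon in the glucose consumed over a window that is
#' recovered in the measured pools. Mode `"C1"` counts produced cells
#' (biomass above the window-start value, at `cell_c_fraction` g C per g dry
#' weight), lactate, acetate and CO2; mode `"C2"` additionally counts alanine
#' and EPS (in glucose equivalents). CO2 follows the run's `co2_mode`: either
#' the measured column or one mole per mole of acetate.
#'
#' @param run a [fermentation_run()].
#' @param window window specification (see [volumetric_rates()]).
#' @param mode `"C1"` or `"C2"`.
#' @param profile a [stoichiometry_profile()].
#' @return Carbon recovery, percent.
#' @export
carbon_recovery <- function(run, window = "to_t2", mode = c("C1", "C2"),
                            profile = stoichiometry_profile()) {
  mode <- match.arg(mode)
  w <- .resolve_window(run, window)
  d_glu <- .run_delta(run, "glucose_consumed", w)
  if (!is.finite(d_glu) || d_glu <= 0) {
    .stopf("no glucose consumed over the window: carbon recovery undefined")
  }
  cc <- profile$carbon
  c_cells <- profile$cell_c_fraction * .run_delta(run, "cells", w) /
    .ATOMIC_MASS[["C"]]
  c_out <- c_cells +
    cc[["lactate"]] * .run_delta(run, "lactate", w) +
    cc[["acetate"]] * .run_delta(run, "acetate", w) +
    cc[["co2"]] * .delta_co2(run, w)
  if (mode == "C2") {
    c_out <- c_out +
      cc[["alanine"]] * .run_delta(run, "alanine", w) +
      cc[["eps_glucose_equiv"]] * .run_delta(run, "eps_glucose_equiv", w)
  }
  100 * c_out / (cc[["glucose"]] * d_glu)
}

#' Volumetric production and consumption rates
#'
#' Average rates over a window: cell productivity (mg L^-1 h^-1), glucose
#' consumption and hydrogen productivity (mmol L^-1 h^-1). Windows may be
#' given as a numeric pair of times in hours, a single end time (start at
#' t0, the serum-bottle convention), or a name: `"growth"` (t1 to t2, the
#' bioreactor growth-phase convention), `"to_t2"`, `"full"`.
#'
#' @inheritParams carbon_recovery
#' @return Named numeric vector `Qcells`, `Qglu`, `QH2`.
#' @export
volumetric_rates <- function(run, window = "growth") {
  w <- .resolve_window(run, window)
  dt <- w[2] - w[1]
  c(Qcells = .run_delta(run, "cells", w) / dt,
    Qglu = .run_delta(run, "glucose_consumed", w) / dt,
    QH2 = .run_delta(run, "h2", w) / dt)
}

#' Logarithmic-mean biomass over a window
#'
#' `(X2 - X1)/ln(X2/X1)`, the biomass average for which an average specific
#' rate times the average biomass reproduces the observed volumetric rate
#' under exponential growth; equals `X1` when the biomass does not change.
#'
#' @inheritParams carbon_recovery
#' @return Logarithmic-mean cell concentration, mg L^-1.
#' @export
log_mean_biomass <- function(run, window = "growth") {
  w <- .resolve_window(run, window)
  x1 <- .run_at(run, "cells", w[1])
  x2 <- .run_at(run, "cells", w[2])
  if (x1 <= 0 || x2 <= 0) .stopf("biomass must be positive at both window ends")
  if (abs(x2 - x1) < 1e-12) x1 else (x2 - x1) / log(x2 / x1)
}

#' Specific glucose consumption and hydrogen production rates
#'
#' Volumetric rates divided by the logarithmic-mean biomass of the window,
#' expressed per gram of cell dry weight. For exponential growth at constant
#' specific rate this estimator recovers the specific rate exactly.
#'
#' @inheritParams carbon_recovery
#' @return Named numeric vector `q_glucose`, `q_H2`, mmol g^-1 h^-1.
#' @export
specific_rates <- function(run, window = "growth") {
  x_lm_g <- log_mean_biomass(run, window) / 1000
  rates <- volumetric_rates(run, window)
  c(q_glucose = unname(rates["Qglu"]) / x_lm_g,
    q_H2 = unname(rates["QH2"]) / x_lm_g)
}

#' Molar yields of a fermentation window
#'
#' Product formed per glucose consumed over a window: cells/glucose in grams
#' of dry weight per mole, the organic acids, H2, alanine and EPS (glucose
#' equivalents) as mol per mol, plus the H2/acetate ratio, the classic check
#' of the 2-H2-per-acetate fermentation stoichiometry.
#'
#' @inheritParams carbon_recovery
#' @return Named numeric vector `cells_per_glu` (g mol^-1), `acetate_per_glu`,
#'   `lactate_per_glu`, `h2_per_glu`, `alanine_per_glu`, `eps_per_glu`,
#'   `co2_per_acetate`, `h2_per_acetate` (mol mol^-1).
#' @export
molar_yields <- function(run, window = "to_t2") {
  w <- .resolve_window(run, window)
  d_glu <- .run_delta(run, "glucose_consumed", w)
  if (!is.finite(d_glu) || d_glu <= 0) {
    .stopf("no glucose consumed over the window: yields undefined")
  }
  d_ac <- .run_delta(run, "acetate", w)
  c(cells_per_glu = .run_delta(run, "cells", w) / d_glu,
    acetate_per_glu = d_ac / d_glu,
    lactate_per_glu = .run_delta(run, "lactate", w) / d_glu,
    h2_per_glu = .run_delta(run, "h2", w) / d_glu,
    alanine_per_glu = .run_delta(run, "alanine", w) / d_glu,
    eps_per_glu = .run_delta(run, "eps_glucose_equiv", w) / d_glu,
    co2_per_acetate = if (d_ac > 0) .delta_co2(run, w) / d_ac else NA_real_,
    h2_per_acetate = if (d_ac > 0) {
      .run_delta(run, "h2", w) / d_ac
    } else NA_real_)
}

#' Full accounting report for a window
#'
#' Bundles carbon recoveries, molar yields, volumetric and specific rates of
#' a window into one report mirroring the derived columns of a fermentation
#' summary table.
#'
#' @inheritParams carbon_recovery
#' @return An object of class `yield_report` (a list with `window`,
#'   `recovery`, `yields`, `volumetric`, `specific`, `log_mean_biomass`).
#' @export
yield_report <- function(run, window = "to_t2",
                         profile = stoichiometry_profile()) {
  w <- .resolve_window(run, window)
  structure(
    list(label = run$label, window = w,
         recovery = c(C1 = carbon_recovery(run, w, "C1", profile),
                      C2 = carbon_recovery(run, w, "C2", profile)),
         yields = molar_yields(run, w),
         volumetric = volumetric_rates(run, w),
         specific = specific_rates(run, w),
         log_mean_biomass = log_mean_biomass(run, w)),
    class = "yield_report"
  )
}

#' @export
print.yield_report <- function(x, digits = 3, ...) {
  cat(sprintf("Yield report%s, window %g-%g h\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$window[1], x$window[2]))
  cat("  C recovery (%):", paste(sprintf("%s %.1f", names(x$recovery),
                                         x$recovery), collapse = ", "), "\n")
  cat("  molar yields  :", paste(sprintf("%s %.*g", names(x$yields), digits,
                                         x$yields), collapse = ", "), "\n")
  cat("  volumetric    :", paste(sprintf("%s %.*g", names(x$volumetric),
                                         digits, x$volumetric),
                                 collapse = ", "), "\n")
  cat("  specific      :", paste(sprintf("%s %.*g", names(x$specific), digits,
                                         x$specific), collapse = ", "), "\n")
  invisible(x)
}

#' Cell yield on thiosulfate by restricted least squares
#'
#' Ordinary least-squares fit of maximum cell concentration against initial
#' thiosulfate, restricted to the growth-limited range (at most
#' `limited_range_max`, default 0.06 mmol L^-1). The slope is the cell yield
#' on thiosulfate Y_X/Thio in mg dry weight per mmol. The leftward x-axis
#' extrapolation `-intercept/slope` measures the thiosulfate equivalent of
#' the sulfur nutrients supplied by the rest of the medium (yeast extract);
#' it is returned as the positive `ye_equivalent`.
#'
#' @param thiosulfate initial thiosulfate concentrations, mmol L^-1.
#' @param max_cells maximum cell concentrations reached, mg L^-1.
#' @param limited_range_max upper bound of the growth-limited range included
#'   in the fit, mmol L^-1.
#' @return An object of class `thiosulfate_yield`: list with `slope`,
#'   `slope_se`, `intercept`, `ye_equivalent`, `n`, and the underlying `fit`.
#' @examples
#' yield_on_thiosulfate(c(0, 0.01, 0.03, 0.06), c(127.6, 178.0, 265.0, 353.5))
#' @export
yield_on_thiosulfate <- function(thiosulfate, max_cells,
                                 limited_range_max = 0.06) {
  stopifnot(length(thiosulfate) == length(max_cells))
  keep <- thiosulfate <= limited_range_max
  if (sum(keep) < 2L) {
    .stopf("need at least 2 points with thiosulfate <= %g", limited_range_max)
  }
  x <- thiosulfate[keep]
  y <- max_cells[keep]
  if (stats::var(x) == 0) .stopf("zero variance in thiosulfate: slope undefined")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  slope <- co["x", "Estimate"]
  structure(
    list(slope = slope,
         slope_se = co["x", "Std. Error"],
         intercept = co["(Intercept)", "Estimate"],
         ye_equivalent = co["(Intercept)", "Estimate"] / slope,
         n = sum(keep), fit = fit),
    class = "thiosulfate_yield"
  )
}

#' @export
print.thiosulfate_yield <- function(x, ...) {
  cat(sprintf("Cell yield on thiosulfate (n = %d points in range)\n", x$n))
  cat(sprintf("  Y_X/Thio : %.0f +/- %.0f mg mmol^-1\n", x$slope, x$slope_se))
  cat(sprintf("  intercept: %.1f mg L^-1 (medium sulfur ~ %.3f mmol/L thiosulfate equivalent)\n",
              x$intercept, x$ye_equivalent))
  invisible(x)
}

#' Sulfur budget of a culture
#'
#' Compares the sulfur incorporated into cell material against the sulfur
#' supplied by the medium: organic sulfur from yeast extract (0.07 mmol per
#' gram, from its cystine and methionine content), 2 sulfur atoms per mole of
#' thiosulfate, and cellular sulfur from the elemental cell formula.
#'
#' @param cells maximum cell concentration, mg L^-1.
#' @param yeast_extract yeast extract, g L^-1.
#' @param thiosulfate initial thiosulfate, mmol L^-1.
#' @param s_ye_per_g organic sulfur content of yeast extract, mmol g^-1.
#' @param profile a [stoichiometry_profile()].
#' @return An object of class `sulfur_budget`: list with `S_YE`,
#'   `S_thiosulfate`, `S_cells` (mmol L^-1) and `incorporation_ratio`
#'   (percent of supplied sulfur found in cells).
#' @examples
#' sulfur_budget(cells = 354, yeast_extract = 1, thiosulfate = 0.06)
#' @export
sulfur_budget <- function(cells, yeast_extract, thiosulfate,
                          s_ye_per_g = 0.07,
                          profile = stoichiometry_profile()) {
  .assert_nonneg(cells, "cells")
  .assert_nonneg(yeast_extract, "yeast_extract")
  .assert_nonneg(thiosulfate, "thiosulfate")
  s_ye <- s_ye_per_g * yeast_extract
  s_thio <- 2 * thiosulfate
  s_cells <- profile$cell_formula[["S"]] * cells / profile$formula_mass
  supplied <- s_ye + s_thio
  ratio <- if (supplied > 0) 100 * s_cells / supplied else 0
  structure(
    list(S_YE = s_ye, S_thiosulfate = s_thio, S_cells = s_cells,
         incorporation_ratio = ratio),
    class = "sulfur_budget"
  )
}

#' @export
print.sulfur_budget <- function(x, ...) {
  cat("Sulfur budget (mmol/L)\n")
  cat(sprintf("  S-YE %.3f + S-thiosulfate %.3f -> supplied %.3f\n",
              x$S_YE, x$S_thiosulfate, x$S_YE + x$S_thiosulfate))
  cat(sprintf("  S-cells %.3f (%.0f %% incorporated)\n",
              x$S_cells, x$incorporation_ratio))
  invisible(x)
}

#' Hydrogen detoxification capacity of thiosulfate
#'
#' Moles of H2 that a given amount of thiosulfate can oxidise when reduced to
#' sulfide (4 mol H2 per mol thiosulfate). Used to judge whether a sulfur
#' dose could plausibly act as an electron sink rather than a nutrient.
#'
#' @param thiosulfate thiosulfate, mmol L^-1.
#' @param profile a [stoichiometry_profile()].
#' @return H2 oxidisable, mmol L^-1.
#' @examples
#' thiosulfate_detox_capacity(0.15) # 0.6 mmol/L of H2
#' @export
thiosulfate_detox_capacity <- function(thiosulfate,
                                       profile = stoichiometry_profile()) {
  .assert_nonneg(thiosulfate, "thiosulfate")
  profile$h2_per_thiosulfate * thiosulfate
}
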