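# Liquid-phase time series of a batch fermentation with its metadata: the
# object every accounting operation consumes.

#' Batch fermentation run
#'
#' Liquid-phase assays of a batch culture (cells, substrate, products) with
#' the metadata needed for accounting: initial thiosulfate, yeast extract,
#' phase markers and how CO2 was obtained. Concentrations are mmol per litre
#' except cells (mg dry weight per litre). `glucose_consumed` is cumulative
#' from the start of the run.
#'
#' @param time_h sampling times, hours, strictly increasing from 0.
#' @param cells cell dry weight, mg L^-1 (see [od_to_dry_weight()]).
#' @param glucose_consumed cumulative glucose consumption, mmol L^-1,
#'   non-decreasing.
#' @param lactate,acetate,alanine,eps_glucose_equiv,h2,co2 product
#'   concentrations, mmol L^-1 (EPS in glucose equivalents). `co2` may be NA
#'   when not measured; `alanine` and `eps_glucose_equiv` default to 0.
#' @param thiosulfate initial thiosulfate, mmol L^-1.
#' @param yeast_extract yeast extract, g L^-1.
#' @param phases named numeric vector with times `t0` (inoculation),
#'   `t1` (growth onset), `t2` (end of growth), `t3` (end of run), hours,
#'   satisfying t0 <= t1 < t2 <= t3.
#' @param co2_mode `"measured"` (use the co2 column) or
#'   `"acetate_stoichiometric"` (estimate CO2 as 1 mol per mol acetate, the
#'   serum-bottle convention).
#' @param label optional run label.
#' @return An object of class `fermentation_run`.
#' @export
fermentation_run <- function(time_h, cells, glucose_consumed, lactate,
                             acetate, h2, co2 = NA_real_,
                             alanine = 0, eps_glucose_equiv = 0,
                             thiosulfate = 0, yeast_extract = 1,
                             phases = c(t0 = min(time_h), t1 = min(time_h),
                                        t2 = max(time_h), t3 = max(time_h)),
                             co2_mode = c("measured", "acetate_stoichiometric"),
                             label = NULL) {
  co2_mode <- match.arg(co2_mode)
  n <- length(time_h)
  if (n == 0L) .stopf("empty run")
  if (n > 1L) .assert_increasing(time_h, "time_h")
  recycle <- function(x) rep_len(x, n)
  df <- data.frame(time_h = time_h, cells = recycle(cells),
                   glucose_consumed = recycle(glucose_consumed),
                   lactate = recycle(lactate), acetate = recycle(acetate),
                   h2 = recycle(h2), co2 = recycle(co2),
                   alanine = recycle(alanine),
                   eps_glucose_equiv = recycle(eps_glucose_equiv))
  # co2 and h2 may be NA (not measured); everything else must be complete
  for (nm in setdiff(names(df), "time_h")) {
    v <- df[[nm]]
    if (nm %in% c("co2", "h2")) v <- v[!is.na(v)]
    if (any(!is.finite(v) | v < 0)) {
      .stopf("column '%s' must be finite and non-negative (row %d)", nm,
             which(!is.finite(df[[nm]]) | df[[nm]] < 0)[1L])
    }
  }
  if (any(diff(df$glucose_consumed) < -1e-9)) {
    .stopf("'glucose_consumed' must be non-decreasing (row %d)",
           which(diff(df$glucose_consumed) < -1e-9)[1L] + 1L)
  }
  stopifnot(all(c("t0", "t1", "t2", "t3") %in% names(phases)))
  if (!(phases["t0"] <= phases["t1"] && phases["t1"] < phases["t2"] &&
        phases["t2"] <= phases["t3"])) {
    .stopf("phase markers must satisfy t0 <= t1 < t2 <= t3")
  }
  if (co2_mode == "measured" && all(is.na(df$co2))) {
    .stopf("co2_mode = \"measured\" but the co2 column is all NA")
  }
  .assert_nonneg(thiosulfate, "thiosulfate")
  .assert_nonneg(yeast_extract, "yeast_extract")
  structure(
    list(data = df, thiosulfate = thiosulfate, yeast_extract = yeast_extract,
         phases = phases[c("t0", "t1", "t2", "t3")], co2_mode = co2_mode,
         label = label),
    class = "fermentation_run"
  )
}

#' @export
print.fermentation_run <- function(x, ...) {
  cat(sprintf("Fermentation run%s: %d samples over %g h\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              nrow(x$data), max(x$data$time_h)))
  cat(sprintf("  thiosulfate %g mmol/L, yeast extract %g g/L, CO2 %s\n",
              x$thiosulfate, x$yeast_extract, x$co2_mode))
  cat(sprintf("  phases: t0 = %g, t1 = %g, t2 = %g, t3 = %g h\n",
              x$phases["t0"], x$phases["t1"], x$phases["t2"], x$phases["t3"]))
  print(utils::head(x$data, 4))
  if (nrow(x$data) > 4) cat(sprintf("  ... %d more rows\n", nrow(x$data) - 4))
  invisible(x)
}

# Resolve a window specification to c(start, end) in hours.
# Accepted: numeric length 2; "growth" (t1 -> t2); "full" (t0 -> t3);
# "to_t2" (t0 -> t2); a single number (t0 -> that time, Table-1 style).
.resolve_window <- function(run, window) {
  ph <- run$phases
  w <- if (is.character(window)) {
    switch(window,
           growth = c(ph["t1"], ph["t2"]),
           full = c(ph["t0"], ph["t3"]),
           to_t2 = c(ph["t0"], ph["t2"]),
           .stopf("unknown window '%s'", window))
  } else if (is.numeric(window) && length(window) == 1L) {
    c(ph["t0"], window)
  } else if (is.numeric(window) && length(window) == 2L) {
    window
  } else {
    .stopf("'window' must be numeric (length 1 or 2) or a window name")
  }
  w <- unname(as.numeric(w))
  if (w[2] <= w[1]) .stopf("window has non-positive duration")
  w
}

# Linear interpolation of a run column at a time point.
.run_at <- function(run, column, t) {
  d <- run$data
  y <- d[[column]]
  ok <- !is.na(y)
  if (!any(ok)) return(NA_real_)
  if (sum(ok) == 1L) return(y[ok])
  stats::approx(d$time_h[ok], y[ok], xout = t, rule = 2)$y
}

# Change of a column over a window.
.run_delta <- function(run, column, window) {
  .run_at(run, column, window[2]) - .run_at(run, column, window[1])
}

#' Convert optical density to cell dry weight
#'
#' Linear conversion of OD600 to cell dry weight; one OD unit corresponds to
#' 330 mg L^-1 for this organism.
#'
#' @param od optical density at 600 nm, non-negative.
#' @param mg_per_od conversion factor, mg L^-1 per OD unit.
#' @return Cell dry weight, mg L^-1.
#' @examples
#' od_to_dry_weight(1.0) # 330
#' @export
od_to_dry_weight <- function(od, mg_per_od = 330) {
  .assert_nonneg(od, "od")
  od * mg_per_od
}
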