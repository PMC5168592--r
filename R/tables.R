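# Published summary tables of the thiosulfate dark-fermentation study, typed
# in as packaged fixtures. Values are the reported means (uncertainties are
# not carried); column units follow fermentation_run(). These tables are the
# desk-scale inputs of the accounting layer's regression tests.

#' Serum-bottle sulfur-nutrient screening runs
#'
#' Batch serum-bottle cultures (glucose 25 mmol L^-1, yeast extract 1 g L^-1)
#' comparing sulfured nutrients at 0.3 mmol L^-1 sulfur equivalent, sampled
#' at 0, 14.5 and 22 h. CO2 was not measured in bottles; carbon accounting
#' uses the 1-CO2-per-acetate convention (`co2_mode =
#' "acetate_stoichiometric"`). Returns one [fermentation_run()] per
#' condition.
#'
#' @return Named list of `fermentation_run` objects: `control`, `DMSO`,
#'   `S0`, `methionine`, `thiosulfate`, `cysteine`, `Na2S`.
#' @export
serum_bottle_runs <- function() {
  times <- c(0, 14.5, 22)
  mk <- function(label, cells, glu, lac, ac, h2, thio = 0) {
    fermentation_run(
      time_h = times, cells = cells, glucose_consumed = glu, lactate = lac,
      acetate = ac, h2 = h2, thiosulfate = thio, yeast_extract = 1,
      phases = c(t0 = 0, t1 = 0, t2 = 14.5, t3 = 22),
      co2_mode = "acetate_stoichiometric", label = label)
  }
  list(
    control = mk("control", c(4.8, 108.2, 158.2), c(0, 3.8, 7.1),
                 c(0, 0.5, 0.8), c(0, 5.4, 10.1), c(0, 9.3, 21.3)),
    DMSO = mk("DMSO", c(6.0, 129.7, 160.8), c(0, 5.2, 9.2),
              c(0, 0.4, 0.8), c(0, 7.4, 13.3), c(0, 14.9, 28.7)),
    S0 = mk("S0", c(5.9, 191.8, 158.2), c(0, 11.0, 16.6),
            c(0, 1.3, 3.4), c(0, 16.3, 23.8), c(0, 28.0, 46.1)),
    methionine = mk("methionine", c(5.1, 217.7, 227.8), c(0, 11.9, 18.3),
                    c(0, 1.1, 3.1), c(0, 17.3, 26.5), c(0, 30.0, 53.3)),
    thiosulfate = mk("thiosulfate", c(4.1, 250.6, 157.0), c(0, 15.4, 17.5),
                     c(0, 3.6, 6.3), c(0, 22.0, 24.1), c(0, 39.7, 47.3),
                     thio = 0.15),
    cysteine = mk("cysteine", c(4.7, 300.6, 158.2), c(0, 16.8, 20.4),
                  c(0, 2.2, 4.1), c(0, 25.4, 30.5), c(0, 45.0, 58.5)),
    Na2S = mk("Na2S", c(4.7, 264.6, 234.2), c(0, 20.4, 20.4),
              c(0, 4.7, 4.7), c(0, 28.1, 30.7), c(0, 50.9, 54.9))
  )
}

#' Bioreactor runs at controlled hydrogen partial pressures
#'
#' Batch bioreactor cultures (glucose 25 mmol L^-1, yeast extract 1 g L^-1)
#' perfused at constant 50 mL min^-1 with H2/N2 mixtures setting the
#' headspace hydrogen partial pressure; sampled at the phase markers t0, t1,
#' t2, t3. H2 could not be quantified at the highest pH2 (85 % feed) and is
#' recorded as NA there.
#'
#' @return Named list of `fermentation_run` objects keyed by pH2 in mbar:
#'   `"7.1"`, `"71.4"`, `"178.5"`, `"606.9"`.
#' @export
ph2_runs <- function() {
  mk <- function(label, t, cells, glu, lac, ac, h2, co2) {
    fermentation_run(
      time_h = t, cells = cells, glucose_consumed = glu, lactate = lac,
      acetate = ac, h2 = h2, co2 = co2, thiosulfate = 0, yeast_extract = 1,
      phases = c(t0 = t[1], t1 = t[2], t2 = t[3], t3 = t[4]),
      co2_mode = "measured", label = label)
  }
  list(
    "7.1" = mk("pH2 7.1 mbar", c(0, 6.7, 41.7, 49.8),
               c(14.8, 17.5, 127.5, 122.5), c(0, 0.3, 18.5, 19.8),
               c(0, 0.1, 8.9, 10.5), c(0, 0.6, 23.6, 25.0),
               c(0, 0.4, 44.5, 46.4), c(0, 0.4, 22.5, 23.3)),
    "71.4" = mk("pH2 71.4 mbar", c(0, 5.5, 40.4, 46.2),
                c(14.7, 19.1, 123.6, 118.2), c(0, 0.5, 18.1, 19.7),
                c(0, 0.2, 8.8, 11.0), c(0, 0.7, 22.5, 24.6),
                c(0, 1.4, 43.0, 48.0), c(0, 0.3, 20.0, 21.8)),
    "178.5" = mk("pH2 178.5 mbar", c(0, 5.5, 38.2, 39.0),
                 c(12.7, 22.7, 129.8, 127.3), c(0, 0.2, 16.9, 17.2),
                 c(0, 0.1, 9.2, 9.4), c(0, 0.2, 19.9, 20.1),
                 c(0, 0.6, 39.3, 40.0), c(0, 0.3, 19.2, 19.5)),
    "606.9" = mk("pH2 606.9 mbar", c(0, 4.4, 41.7, 48.5),
                 c(18.9, 23.9, 96.4, 96.3), c(0, 1.0, 11.9, 13.4),
                 c(0, 0.0, 8.9, 11.0), c(0, 0.0, 12.0, 13.0),
                 c(NA, NA, NA, NA), c(0, 0.3, 11.1, 12.2))
  )
}

#' Bioreactor runs at graded initial thiosulfate
#'
#' The central dataset of the study: batch bioreactor cultures (glucose
#' 60 mmol L^-1, yeast extract 1 g L^-1) under the 5 % outlet-H2 control
#' loop, with initial thiosulfate from 0 to 0.24 mmol L^-1, sampled at the
#' phase markers t0, t1, t2, t3. Alanine and EPS were assayed at t2 for the
#' 0, 0.12 and 0.24 mmol L^-1 runs only; elsewhere they are carried as 0 and
#' the C2 recovery is not meaningful there.
#'
#' @return Named list of `fermentation_run` objects keyed by initial
#'   thiosulfate in mmol L^-1.
#' @export
thiosulfate_runs <- function() {
  mk <- function(thio, t, cells, glu, lac, ac, co2, h2, ala = 0, eps = 0) {
    fermentation_run(
      time_h = t, cells = cells, glucose_consumed = glu, lactate = lac,
      acetate = ac, co2 = co2, h2 = h2, alanine = ala,
      eps_glucose_equiv = eps, thiosulfate = thio, yeast_extract = 1,
      phases = c(t0 = t[1], t1 = t[2], t2 = t[3], t3 = t[4]),
      co2_mode = "measured",
      label = sprintf("thiosulfate %g mmol/L", thio))
  }
  list(
    "0" = mk(0, c(0, 4.8, 29.5, 30.6), c(19.3, 31.8, 127.6, 119.8),
             c(0, 1.3, 16.4, 17.7), c(0, 0.2, 4.9, 5.4),
             c(0, 0.5, 11.8, 12.8), c(0, 0.2, 11.1, 11.9),
             c(0, 0.3, 23.2, 25.0), ala = c(0, 0, 1.39, 1.39),
             eps = c(0, 0, 4.7, 4.7)),
    "0.01" = mk(0.01, c(0, 3.1, 22.8, 23.0), c(16.8, 22.8, 178.0, 177.4),
                c(0, 2.1, 19.8, 20.0), c(0, 0.1, 10.0, 10.2),
                c(0, 0.2, 16.0, 16.0), c(0, 0.2, 15.0, 15.0),
                c(0, 0.4, 30.7, 31.0)),
    "0.03" = mk(0.03, c(0, 6.7, 24.1, 27.5), c(23.6, 32.1, 265.0, 264.1),
                c(0, 0.0, 25.2, 28.0), c(0, 0.0, 6.8, 8.2),
                c(0, 0.0, 27.5, 30.6), c(0, 0.2, 27.3, 29.7),
                c(0, 0.3, 53.5, 57.9)),
    "0.06" = mk(0.06, c(0, 1.8, 20.4, 22.3), c(26.1, 33.7, 353.5, 352.3),
                c(0, 0.7, 38.2, 38.5), c(0, 0.0, 18.0, 18.1),
                c(0, 0.1, 37.7, 38.2), c(0, 0.1, 35.7, 35.8),
                c(0, 0.3, 73.2, 73.3)),
    "0.12" = mk(0.12, c(0, 3.0, 17.9, 23.2), c(24.4, 34.1, 404.0, 396.6),
                c(0, 1.1, 42.4, 45.7), c(0, 0.0, 15.9, 15.4),
                c(0, 0.8, 47.0, 52.4), c(0, 0.3, 44.2, 51.9),
                c(0, 0.3, 90.5, 99.7), ala = c(0, 0, 3.8, 3.8),
                eps = c(0, 0, 3.6, 3.6)),
    "0.18" = mk(0.18, c(0, 1.2, 16.8, 17.0), c(25.3, 32.7, 428.8, 418.0),
                c(0, 0.3, 45.0, 45.4), c(0, 0.0, 23.3, 23.4),
                c(0, 0.0, 44.5, 45.0), c(0, 0.4, 44.6, 44.7),
                c(0, 0.4, 86.7, 86.9)),
    "0.24" = mk(0.24, c(0, 2.1, 17.0, 22.8), c(27.5, 33.8, 423.9, 422.4),
                c(0, 0.9, 41.7, 43.8), c(0, 0.0, 22.5, 26.4),
                c(0, 0.0, 43.4, 46.1), c(0, 0.2, 40.0, 42.2),
                c(0, 0.5, 84.0, 88.6), ala = c(0, 0, 3.8, 3.8),
                eps = c(0, 0, 2.9, 2.9))
  )
}

#' Published sulfur-budget rows
#'
#' The two culture conditions whose sulfur budgets are reported: yeast
#' extract alone, and yeast extract plus 0.06 mmol L^-1 thiosulfate, with
#' the maximum cell concentrations used for the cellular-sulfur estimate.
#'
#' @return A data.frame with columns `yeast_extract` (g L^-1), `thiosulfate`
#'   (mmol L^-1) and `cells` (mg L^-1).
#' @export
sulfur_budget_conditions <- function() {
  data.frame(
    condition = c("YE only", "YE + 0.06 mM thiosulfate"),
    yeast_extract = c(1, 1),
    thiosulfate = c(0, 0.06),
    cells = c(128, 354)
  )
}

#' Maximum-cell-versus-thiosulfate points of the yield regression
#'
#' Initial thiosulfate and the cell concentration reached at the end of the
#' growth phase (t2) for the bioreactor runs, the input of
#' [yield_on_thiosulfate()].
#'
#' @return A data.frame with columns `thiosulfate` (mmol L^-1) and
#'   `max_cells` (mg L^-1).
#' @export
thiosulfate_yield_points <- function() {
  runs <- thiosulfate_runs()
  data.frame(
    thiosulfate = vapply(runs, function(r) r$thiosulfate, numeric(1)),
    max_cells = vapply(runs, function(r) .run_at(r, "cells", r$phases["t2"]),
                       numeric(1)),
    row.names = NULL
  )
}

#' Write the packaged study tables as run CSV files
#'
#' Serialises every packaged fixture run through [write_run()] into a
#' directory, one file per run, using the standard run CSV schema.
#'
#' @param dir output directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
emit_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs <- c(
    stats::setNames(serum_bottle_runs(),
                    paste0("serum_", names(serum_bottle_runs()))),
    stats::setNames(ph2_runs(), paste0("ph2_", names(ph2_runs()))),
    stats::setNames(thiosulfate_runs(),
                    paste0("thio_", names(thiosulfate_runs())))
  )
  paths <- vapply(names(runs), function(nm) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.]", "_", nm), ".csv"))
    write_run(runs[[nm]], path)
    path
  }, character(1))
  invisible(paths)
}
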