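# File interfaces: run CSVs with a commented metadata header, off-gas CSVs,
# and JSON reports. All formats are plain text, UTF-8, decimal point.

.RUN_COLUMNS <- c(time_h = "time_h", cells_mg_L = "cells",
                  glucose_consumed_mM = "glucose_consumed",
                  lactate_mM = "lactate", acetate_mM = "acetate",
                  H2_mM = "h2", CO2_mM = "co2", alanine_mM = "alanine",
                  eps_glcEq_mM = "eps_glucose_equiv")

#' Write a fermentation run to CSV
#'
#' Serialises a run in the standard schema: a commented metadata block
#' (`# key: value` lines holding thiosulfate, yeast extract, phase markers,
#' CO2 mode and label) followed by the time-series columns `time_h`,
#' `cells_mg_L`, `glucose_consumed_mM`, `lactate_mM`, `acetate_mM`, `H2_mM`,
#' `CO2_mM`, `alanine_mM`, `eps_glcEq_mM`.
#'
#' @param run a [fermentation_run()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "fermentation_run"))
  meta <- c(
    sprintf("# thiosulfate_mM: %.15g", run$thiosulfate),
    sprintf("# yeast_extract_g_L: %.15g", run$yeast_extract),
    sprintf("# phases: t0=%.15g t1=%.15g t2=%.15g t3=%.15g",
            run$phases["t0"], run$phases["t1"], run$phases["t2"],
            run$phases["t3"]),
    sprintf("# co2_mode: %s", run$co2_mode),
    if (!is.null(run$label)) sprintf("# label: %s", run$label)
  )
  out <- run$data[, unname(.RUN_COLUMNS)]
  names(out) <- names(.RUN_COLUMNS)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fermentation run from CSV
#'
#' Parses the schema written by [write_run()], validating columns, time
#' monotonicity and sign constraints; violations are reported with the
#' offending row or column.
#'
#' @param path path to a run CSV.
#' @return A [fermentation_run()].
#' @export
load_run <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) .stopf("empty file: %s", path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) .stopf("no data rows in %s", path)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.RUN_COLUMNS), names(df))
  if (length(missing_cols)) {
    .stopf("missing columns in %s: %s", path,
           paste(missing_cols, collapse = ", "))
  }
  phases <- c(t0 = 0, t1 = 0, t2 = max(df$time_h), t3 = max(df$time_h))
  if (!is.null(meta$phases)) {
    kv <- regmatches(meta$phases,
                     gregexpr("t[0-3]=[-0-9.eE+]+", meta$phases))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      phases[parts[1]] <- as.numeric(parts[2])
    }
  }
  fermentation_run(
    time_h = df$time_h, cells = df$cells_mg_L,
    glucose_consumed = df$glucose_consumed_mM, lactate = df$lactate_mM,
    acetate = df$acetate_mM, h2 = df$H2_mM, co2 = df$CO2_mM,
    alanine = df$alanine_mM, eps_glucose_equiv = df$eps_glcEq_mM,
    thiosulfate = if (is.null(meta$thiosulfate_mM)) 0 else
      as.numeric(meta$thiosulfate_mM),
    yeast_extract = if (is.null(meta$yeast_extract_g_L)) 1 else
      as.numeric(meta$yeast_extract_g_L),
    phases = phases,
    co2_mode = if (is.null(meta$co2_mode)) "measured" else meta$co2_mode,
    label = meta$label
  )
}

#' Write an off-gas record to CSV
#'
#' Columns `time_h`, `pN2_pct`, `pH2_pct`, `pCO2_pct`, `qN2_ref_mL_min`,
#' `pH`; header required, decimal point, UTF-8.
#'
#' @param outlet an [outlet_gas_series()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gas <- function(outlet, path) {
  out <- data.frame(time_h = outlet$time_h, pN2_pct = outlet$p_n2,
                    pH2_pct = outlet$p_h2, pCO2_pct = outlet$p_co2,
                    qN2_ref_mL_min = outlet$q_n2_ref, pH = outlet$pH)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an off-gas record from CSV
#'
#' @param path path to a gas CSV in the [write_gas()] schema.
#' @param tol closure tolerance forwarded to [outlet_gas_series()].
#' @return An [outlet_gas_series()].
#' @export
load_gas <- function(path, tol = 0.5) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "pN2_pct", "pH2_pct", "pCO2_pct", "qN2_ref_mL_min")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    .stopf("missing columns in %s: %s", path,
           paste(missing_cols, collapse = ", "))
  }
  outlet_gas_series(df$time_h, df$pN2_pct, df$pH2_pct, df$pCO2_pct,
                    df$qN2_ref_mL_min,
                    pH = if ("pH" %in% names(df)) df$pH else NA_real_,
                    tol = tol)
}

.SCHEMA_VERSION <- "1"

#' Serialise accounting reports to JSON
#'
#' Writes one or more [yield_report()] / [sulfur_budget()] /
#' [yield_on_thiosulfate()] results as a versioned JSON document with stable
#' key order and full-precision values, plus a rounded table-style view.
#'
#' @param reports a named list of report objects (may be empty).
#' @param path output file path.
#' @param digits digits for the rounded view.
#' @return Invisibly, `path`.
#' @export
write_report <- function(reports, path, digits = 2) {
  stopifnot(is.list(reports))
  # named atomic vectors must become lists to keep their names in JSON
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  strip <- function(x) {
    if (inherits(x, "yield_report")) {
      x <- unclass(x)
    } else if (inherits(x, c("sulfur_budget", "thiosulfate_yield"))) {
      x <- unclass(x)
      x$fit <- NULL
    }
    listify(x)
  }
  payload <- list(schema_version = .SCHEMA_VERSION,
                  reports = lapply(reports, strip))
  payload$rounded <- lapply(payload$reports, function(r) {
    rapply(r, function(v) if (is.numeric(v)) signif(v, digits + 2) else v,
           how = "replace")
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON accounting report
#'
#' @param path path written by [write_report()].
#' @return The parsed document (list with `schema_version` and `reports`).
#' @export
load_report <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
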