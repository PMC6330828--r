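# Plain-text export of simulation traces and analysis reports.

#' Write a simulation trace as tidy CSV plus a JSON run manifest
#'
#' `trace.csv` holds one row per (iteration, metric) pair; `survival.csv`
#' the per-day age cohorts; `manifest.json` the full configuration, master
#' seed, and package version.
#'
#' @param sim A `"dg_sim"` object.
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_sim_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "dg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$trace
  long <- do.call(rbind, lapply(setdiff(names(tr), "day"), function(m) {
    data.frame(day = tr$day, metric = m, value = tr[[m]])
  }))
  utils::write.csv(long, file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(sim$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  manifest <- list(config = sim$config, package = "dgturnover",
                   version = as.character(utils::packageVersion("dgturnover")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Export an analysis report to CSV
#'
#' Writes a report as CSV preceded by one comment line (`# {...}`) holding a
#' JSON schema: the report type and its column names. Context-bias and SNR
#' reports become one-row-per-unit / one-row tables; spectral reports export
#' the per-component quantities; representation diagnostics export the
#' correlation matrix in long `(pattern_i, pattern_j, r)` format; turnover
#' accounting exports its per-day table.
#'
#' @param report A `"context_bias"`, `"snr_report"`, `"spectral_report"`,
#'   `"turnover_accounting"`, or the list returned by
#'   [representation_diagnostics()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_report_csv <- function(report, file) {
  if (inherits(report, "context_bias")) {
    df <- data.frame(unit = seq_along(report$psi), psi = report$psi,
                     f_plus = report$f_plus, f_minus = report$f_minus)
    type <- "context_bias"
  } else if (inherits(report, "snr_report")) {
    df <- data.frame(variant = report$variant, signal = report$signal,
                     noise = report$noise, snr = report$snr)
    type <- "snr_report"
  } else if (inherits(report, "spectral_report")) {
    df <- data.frame(component = seq_along(report$d),
                     singular_value = report$d,
                     sv_ratio_centered = report$sv_ratios,
                     alpha = report$alpha,
                     rank_by_alpha = order(report$ranking))
    type <- "spectral_report"
  } else if (inherits(report, "turnover_accounting")) {
    df <- report$per_day
    type <- "turnover_accounting"
  } else if (is.list(report) && !is.null(report$correlation)) {
    R <- report$correlation
    idx <- which(upper.tri(R, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(pattern_i = idx[, 1], pattern_j = idx[, 2],
                     r = R[idx])
    type <- "correlation_long"
  } else {
    stop("unsupported report type")
  }
  schema <- jsonlite::toJSON(list(type = type, columns = names(df)),
                             auto_unbox = TRUE)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", schema), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(file)
}
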