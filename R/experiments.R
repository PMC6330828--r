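# Preset experiments and one-parameter scans, with CSV/JSON output.
#
# Named presets bundle the package's standard experiments: learning curves,
# SNR tracking at sparse vs dense coding, correlation/PCA diagnostics,
# singular-value dimensionality maps, context-bias/weight joint evolution,
# the multicontext rule, and the synaptic-turnover rule with material
# accounting.

dg_presets <- function() {
  base <- list(M = 200, N = 500, C = 1, P = 100, n_contexts = 2, nu = 0.2,
               f = 0.04, connectivity = 1, model = "model1",
               turnover_rate = 0.3, slope = 2.5, train_on = "mean",
               test_instances = 10, days = 128)
  list(
    fig1 = list(base = base, replicates = 20),
    fig2 = list(base = base, grid = list(f = c(0.5, 0.04)), replicates = 20),
    fig3 = list(base = base, grid = list(f = c(0.5, 0.04)), replicates = 1,
                analysis = "representation"),
    fig4 = list(base = base,
                grid = list(f = c(0.02, 0.04, 0.1, 0.2, 0.35, 0.5)),
                replicates = 1, analysis = "spectral"),
    fig5 = list(base = utils::modifyList(base, list(train_on = "noisy",
                                                    train_instances = 100)),
                grid = list(f = c(0.5, 0.04)), replicates = 1,
                analysis = "spectral"),
    fig6 = list(base = utils::modifyList(base, list(model = "model2", C = 3,
                                                    n_contexts = 8, P = 96,
                                                    nu = 0.05)),
                grid = list(f = c(0.04, 0.15, 0.5)), replicates = 20),
    fig7 = list(base = utils::modifyList(base, list(model = "model3")),
                grid = list(f = c(0.04, 0.1, 0.25, 0.5)),
                replicates = 100, analysis = "accounting")
  )
}

#' Available experiment presets
#'
#' @return Character vector of preset names accepted by [run_experiment()].
#' @export
experiment_presets <- function() names(dg_presets())

#' Run a preset experiment
#'
#' Executes a preset's simulations over its condition grid and replicates,
#' aggregates the traces (mean and standard error of the generalization
#' error per day and condition), and optionally writes `trace.csv`,
#' `summary.csv`, and a `manifest.json` (configuration, seed, package
#' version) into `out`. Replicate seeds are derived from `seed`, so the
#' result is deterministic.
#'
#' Preset-specific analyses are attached: `fig3` adds correlation/PCA
#' diagnostics ([representation_diagnostics()]) of the training
#' representation at day 0 and the final day; `fig4`/`fig5` add
#' [spectral_decomposition()] reports of the final representation; `fig7`
#' adds [turnover_accounting()] per condition.
#'
#' @param preset One of [experiment_presets()].
#' @param days,replicates Optional overrides of the preset defaults.
#' @param seed Master integer seed.
#' @param out Optional output directory.
#' @param eval_days Override of the evaluation schedule (default: all days).
#' @param ... Further overrides passed to [dg_simulate()] (e.g.
#'   `test_instances`).
#' @return Object of class `"dg_experiment"`: list with `preset`,
#'   `summary` (data frame: condition columns, day, mean error, se),
#'   `final` (final-day summary per condition), `sims` (list of
#'   `"dg_sim"`), `analysis` (preset-specific reports or `NULL`), and
#'   `config`.
#' @examples
#' ex <- run_experiment("fig1", days = 2, replicates = 2, seed = 1,
#'                      test_instances = 2)
#' ex$summary
#' @export
run_experiment <- function(preset, days = NULL, replicates = NULL, seed = 1,
                           out = NULL, eval_days = NULL, ...) {
  presets <- dg_presets()
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  pdef <- presets[[preset]]
  base <- pdef$base
  if (!is.null(days)) base$days <- days
  reps <- if (is.null(replicates)) pdef$replicates else replicates
  stopifnot(reps >= 1)
  overrides <- list(...)
  base[names(overrides)] <- overrides
  if (!is.null(eval_days)) base$eval_days <- eval_days

  grid <- pdef$grid
  if (is.null(grid)) grid <- list(f = base$f)
  par_name <- names(grid)[1]
  values <- grid[[1]]

  sims <- list()
  rows <- list()
  for (ci in seq_along(values)) {
    cfg <- base
    cfg[[par_name]] <- values[ci]
    for (r in seq_len(reps)) {
      cfg$seed <- child_seed(seed, round(values[ci] * 1e6), r)
      sim <- do.call(dg_simulate, cfg)
      key <- sprintf("%s=%g.rep%d", par_name, values[ci], r)
      sims[[key]] <- sim
      tr <- sim$trace
      tr$condition <- values[ci]
      tr$replicate <- r
      rows[[key]] <- tr
    }
  }
  all_traces <- do.call(rbind, rows)
  ev <- all_traces[!is.na(all_traces$error), ]
  agg_m <- stats::aggregate(error ~ condition + day, data = ev, FUN = mean)
  agg_s <- stats::aggregate(error ~ condition + day, data = ev,
                            FUN = function(x) {
                              stats::sd(x) / sqrt(length(x))
                            })
  names(agg_m)[3] <- "error_mean"
  names(agg_s)[3] <- "error_se"
  summary_df <- merge(agg_m, agg_s, by = c("condition", "day"))
  names(summary_df)[1] <- par_name
  summary_df <- summary_df[order(summary_df[[1]], summary_df$day), ]
  rownames(summary_df) <- NULL
  final_df <- summary_df[summary_df$day == max(summary_df$day), ]
  rownames(final_df) <- NULL

  analysis <- NULL
  if (identical(pdef$analysis, "representation")) {
    analysis <- lapply(sims, function(s) {
      list(initial = representation_diagnostics(s$activities_initial,
                                                s$ensemble$context_of),
           final = representation_diagnostics(s$activities_final,
                                              s$ensemble$context_of))
    })
  } else if (identical(pdef$analysis, "spectral")) {
    analysis <- lapply(sims, function(s) {
      if (s$config$C != 1) return(NULL)
      spectral_decomposition(s$activities_final, s$train_labels[1, ],
                             W = s$readout)
    })
  } else if (identical(pdef$analysis, "accounting")) {
    analysis <- lapply(sims, turnover_accounting)
  }

  res <- structure(
    list(preset = preset, summary = summary_df, final = final_df,
         sims = sims, analysis = analysis, traces = all_traces,
         config = list(preset = preset, base = base, grid = grid,
                       replicates = reps, seed = seed)),
    class = "dg_experiment"
  )
  if (!is.null(out)) write_experiment(res, out)
  res
}

#' @export
print.dg_experiment <- function(x, ...) {
  cat("Experiment preset '", x$preset, "': ", length(x$sims),
      " simulation(s)\n", sep = "")
  print(x$final)
  invisible(x)
}

# Write traces, summary, and a JSON manifest for a finished experiment.
write_experiment <- function(res, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$traces, file.path(out, "trace.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(out, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    preset = res$preset, config = res$config,
    package = "dgturnover",
    version = as.character(utils::packageVersion("dgturnover"))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out, "manifest.json"))
  invisible(out)
}

#' Scan one parameter and locate the error-minimising value
#'
#' Runs independent simulations over a grid of one parameter (`f`,
#' `turnover_rate`, `connectivity`, or `slope`), averaging the final-day
#' generalization error over replicates, and flags the argmin grid point.
#' Error is evaluated on the final day only (and day 0 when `days == 1`
#' this is the untrained-turnover baseline).
#'
#' @param param Name of the scanned parameter.
#' @param grid Non-empty numeric grid.
#' @param days Iterations per simulation.
#' @param replicates Replicates per grid point.
#' @param seed Master integer seed.
#' @param base Named list of overrides of the [dg_simulate()] defaults
#'   applied to every grid point.
#' @param test_instances Fresh noisy test instances per prototype on the
#'   evaluated day.
#' @return Object of class `"dg_scan"`: data frame with columns `value`,
#'   `error_mean`, `error_se`, `argmin` (logical), plus attributes
#'   `param` and `argmin` (the minimising value).
#' @examples
#' sc <- scan_parameter("turnover_rate", c(0.1, 0.5), days = 2,
#'                      replicates = 2, seed = 1,
#'                      base = list(N = 60, M = 40, P = 20),
#'                      test_instances = 2)
#' attr(sc, "argmin")
#' @export
scan_parameter <- function(param = c("f", "turnover_rate", "connectivity",
                                     "slope"),
                           grid, days = 128, replicates = 20, seed = 1,
                           base = list(), test_instances = 5) {
  param <- match.arg(param)
  if (length(grid) == 0) stop("empty grid")
  stopifnot(replicates >= 1)
  err <- matrix(NA_real_, nrow = length(grid), ncol = replicates)
  for (gi in seq_along(grid)) {
    cfg <- utils::modifyList(
      list(days = days, test_instances = test_instances,
           eval_days = days - 1),
      base)
    cfg[[param]] <- grid[gi]
    # seeds keyed by the grid *value*, so the argmin cannot depend on the
    # ordering of the grid points
    for (r in seq_len(replicates)) {
      cfg$seed <- child_seed(seed, round(grid[gi] * 1e6), r)
      sim <- do.call(dg_simulate, cfg)
      err[gi, r] <- sim$trace$error[days]
    }
  }
  res <- data.frame(
    value = grid,
    error_mean = rowMeans(err),
    error_se = apply(err, 1, stats::sd) / sqrt(replicates)
  )
  best <- which.min(res$error_mean)
  res$argmin <- seq_along(grid) == best
  attr(res, "param") <- param
  attr(res, "argmin") <- grid[best]
  class(res) <- c("dg_scan", "data.frame")
  res
}

#' @export
print.dg_scan <- function(x, ...) {
  cat("Scan over ", attr(x, "param"), "; argmin = ", attr(x, "argmin"),
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
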