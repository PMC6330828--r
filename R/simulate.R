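# Day-by-day neurogenesis simulation: train -> test -> select -> replace.

#' Simulate neurogenesis-driven learning in the EC -> DG -> CA3 network
#'
#' Runs the full day-by-day loop. Each iteration (one "day"): (a) survivor
#' ages advance; (b) the DG representation of the training patterns is
#' computed (noise-averaged by default); (c) the CA3 readout is trained by
#' pseudoinverse; (d) if the day is scheduled for evaluation, fresh noisy
#' test instances are drawn and the generalization error (and, for a single
#' output, the empirical signal-to-noise decomposition) is measured; (e) the
#' turnover rule selects units/synapses; (f) fresh random material replaces
#' them. The day-`t` row of the trace therefore describes the network after
#' `t` turnover events, with day 0 the random-projection baseline.
#'
#' Randomness is split into independent streams (prototypes, weights, test
#' noise, training noise, turnover) derived from `seed`, so e.g. a different
#' number of test instances does not perturb the turnover trajectory.
#'
#' @param days Number of iterations (trace rows), labelled day `0:(days-1)`.
#' @param M,N,C Numbers of EC units, DG units, CA3 outputs.
#' @param P Total number of prototype patterns.
#' @param n_contexts Number of contexts (even split of the P patterns).
#' @param nu Flip-noise probability.
#' @param f Target coding level used to calibrate the threshold.
#' @param connectivity EC->DG connection fraction in (0, 1].
#' @param model Turnover rule: `"model1"`, `"model2"`, or `"model3"`.
#' @param turnover_rate Fraction of units replaced per day (Models 1-2).
#' @param slope Slope of the Model 3 linear transfer function.
#' @param weight_normalization `|W|` statistic normalising the Model 3
#'   transfer function: `"max"` (default) or `"mean"`.
#' @param train_on `"mean"` trains on noise-averaged prototype activities;
#'   `"noisy"` trains on hard activities of `train_instances` fresh noisy
#'   copies of each prototype per day.
#' @param train_instances Noisy training copies per prototype
#'   (`train_on = "noisy"` only).
#' @param test_instances Fresh noisy test instances per prototype per
#'   evaluation.
#' @param eval_days Which days to evaluate generalization error on: `NULL`
#'   for all days, or an integer vector of day labels (e.g. `c(0, days - 1)`).
#' @param seed Master integer seed; the run is bit-reproducible given it.
#' @return An object of class `"dg_sim"`; see Details. Key components:
#'   `trace` (one row per day: `error`, `f_realized`, `signal`, `noise`,
#'   `snr`, `n_replaced`, `frac_neuron_turnover`, `frac_synapse_turnover`,
#'   `cum_replaced`), `survival` (long data frame: day, age, n, survived),
#'   `ensemble`, `layer` (final), `readout` (final), `theta`,
#'   `activities_initial` / `activities_final` (training-set DG activities
#'   at day 0 and the last day), and `config`.
#' @examples
#' sim <- dg_simulate(days = 3, M = 40, N = 60, P = 20, test_instances = 2,
#'                    seed = 1)
#' sim$trace$error
#' @export
dg_simulate <- function(days = 128,
                        M = 200, N = 500, C = 1, P = 100, n_contexts = 2,
                        nu = 0.2, f = 0.04, connectivity = 1,
                        model = c("model1", "model2", "model3"),
                        turnover_rate = 0.3, slope = 2.5,
                        weight_normalization = "max",
                        train_on = c("mean", "noisy"), train_instances = 100,
                        test_instances = 10, eval_days = NULL,
                        seed = NULL) {
  model <- match.arg(model)
  train_on <- match.arg(train_on)
  stopifnot(days >= 1, test_instances >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (model %in% c("model1", "model3") && C != 1) {
    stop(model, " is defined for a single CA3 output (C = 1)")
  }

  ens <- generate_context_set(M, P, n_contexts, C, nu,
                              seed = child_seed(seed, 1))
  layer <- init_input_weights(N, M, connectivity, seed = child_seed(seed, 2))
  theta <- calibrate_threshold(layer$M_effective, f)
  s_test <- rng_stream(child_seed(seed, 3))
  s_train <- rng_stream(child_seed(seed, 4))
  s_turn <- rng_stream(child_seed(seed, 5))

  if (is.null(eval_days)) eval_days <- 0:(days - 1)
  n_syn_total <- sum(layer$mask)
  alive0 <- rep(TRUE, N)  # day-0 cohort members never yet replaced

  trace <- data.frame(
    day = 0:(days - 1), error = NA_real_, f_realized = NA_real_,
    signal = NA_real_, noise = NA_real_, snr = NA_real_,
    n_replaced = NA_integer_, frac_neuron_turnover = NA_real_,
    frac_synapse_turnover = NA_real_, cum_replaced = NA_real_
  )
  surv <- vector("list", days)
  readout <- NULL
  A_init <- A_final <- NULL
  g0 <- NULL       # cached prototype currents (mean-prototype training);
  changed <- NULL  # only rows touched by turnover are recomputed

  for (t in 0:(days - 1)) {
    layer$ages <- layer$ages + 1L

    # -- train ------------------------------------------------------------
    if (train_on == "mean") {
      if (is.null(g0)) {
        g0 <- dg_currents(layer, ens$prototypes)
        A <- mean_dg_activity(g0, theta, nu, layer$M_effective)
      } else if (length(changed) > 0) {
        g0[changed, ] <- layer$J[changed, , drop = FALSE] %*% ens$prototypes
        A[changed, ] <- mean_dg_activity(g0[changed, , drop = FALSE],
                                         theta, nu, layer$M_effective)
      }
      lab_train <- ens$labels
    } else {
      noisy <- with_stream(s_train,
                           noisy_instances(ens, instances = train_instances))
      A <- dg_activity(dg_currents(layer, noisy$patterns), theta)$S
      lab_train <- noisy$labels
    }
    readout <- train_readout(A, lab_train, trained_on = train_on)
    if (!all(is.finite(readout$W))) stop("non-finite readout weights at day ", t)
    if (t == 0) A_init <- A

    # -- test -------------------------------------------------------------
    if (t %in% eval_days) {
      test <- with_stream(s_test,
                          noisy_instances(ens, instances = test_instances))
      act <- dg_activity(dg_currents(layer, test$patterns), theta)
      out <- ca3_output(readout$W, act$S)
      trace$error[t + 1] <- generalization_error(out$codes, test$labels)
      trace$f_realized[t + 1] <- act$f_realized
      if (C == 1) {
        rep_snr <- empirical_snr(out$h[1, ], test$labels[1, ])
        trace$signal[t + 1] <- rep_snr$signal
        trace$noise[t + 1] <- rep_snr$noise
        trace$snr[t + 1] <- rep_snr$snr
      }
    }

    # -- select -----------------------------------------------------------
    if (model == "model1") {
      sel <- select_turnover_model1(readout, turnover_rate, layer$ages)
      resample <- NULL
      syn_frac <- sum(layer$mask[sel, , drop = FALSE]) / n_syn_total
    } else if (model == "model2") {
      sel <- select_turnover_model2(readout, turnover_rate, layer$ages)
      resample <- NULL
      syn_frac <- sum(layer$mask[sel, , drop = FALSE]) / n_syn_total
    } else {
      st <- with_stream(s_turn,
        synaptic_turnover_model3(readout, layer, slope,
                                 normalization = weight_normalization))
      sel <- st$dead
      resample <- st$resample
      syn_frac <- sum(st$resample) / n_syn_total
    }

    # -- survival by age (before replacement) ------------------------------
    killed <- tabulate(layer$ages[sel] + 1L, nbins = max(layer$ages) + 1L)
    at_risk <- tabulate(layer$ages + 1L, nbins = max(layer$ages) + 1L)
    ages_present <- which(at_risk > 0)
    surv[[t + 1]] <- data.frame(
      day = t, age = ages_present - 1L, n = at_risk[ages_present],
      survived = at_risk[ages_present] - killed[ages_present]
    )

    # -- replace ----------------------------------------------------------
    layer <- with_stream(s_turn, rebirth(layer, sel, resample))
    changed <- if (is.null(resample)) sel else which(rowSums(resample) > 0)
    alive0[sel] <- FALSE
    trace$n_replaced[t + 1] <- length(sel)
    trace$frac_neuron_turnover[t + 1] <- length(sel) / N
    trace$frac_synapse_turnover[t + 1] <- syn_frac
    trace$cum_replaced[t + 1] <- 1 - mean(alive0)

    if (t == days - 1) A_final <- A
  }

  structure(
    list(trace = trace, survival = do.call(rbind, surv),
         ensemble = ens, layer = layer, readout = readout, theta = theta,
         activities_initial = A_init, activities_final = A_final,
         train_labels = lab_train,
         config = list(days = days, M = M, N = N, C = C, P = P,
                       n_contexts = n_contexts, nu = nu, f = f,
                       connectivity = connectivity, model = model,
                       turnover_rate = turnover_rate, slope = slope,
                       weight_normalization = weight_normalization,
                       train_on = train_on, train_instances = train_instances,
                       test_instances = test_instances,
                       eval_days = eval_days, seed = seed)),
    class = "dg_sim"
  )
}

#' Fresh noisy test set for a finished simulation
#'
#' Convenience wrapper drawing flip-noise instances of the simulation's
#' training prototypes together with their DG activities under the final
#' (or initial-equivalent) layer.
#'
#' @param sim A `"dg_sim"` object.
#' @param instances Noisy copies per prototype.
#' @param seed Integer seed.
#' @return List with `patterns`, `labels`, `S` (DG activities under the
#'   final layer), and `context_of`.
#' @export
dg_test_set <- function(sim, instances = 10, seed = 1) {
  stopifnot(inherits(sim, "dg_sim"))
  test <- noisy_instances(sim$ensemble, instances = instances, seed = seed)
  test$S <- dg_activity(dg_currents(sim$layer, test$patterns), sim$theta)$S
  test
}

#' @export
print.dg_sim <- function(x, ...) {
  cfg <- x$config
  cat("DG turnover simulation (", cfg$model, "): ", cfg$M, " EC -> ",
      cfg$N, " DG -> ", cfg$C, " CA3, f = ", cfg$f, ", nu = ", cfg$nu,
      ", ", cfg$days, " day(s)\n", sep = "")
  ev <- x$trace[!is.na(x$trace$error), ]
  if (nrow(ev) > 0) {
    cat("  generalization error: day ", ev$day[1], " = ",
        signif(ev$error[1], 3), "; day ", ev$day[nrow(ev)], " = ",
        signif(ev$error[nrow(ev)], 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.dg_sim <- function(object, ...) {
  ev <- object$trace[!is.na(object$trace$error), ]
  out <- list(
    config = object$config,
    error_first = if (nrow(ev)) ev$error[1] else NA_real_,
    error_last = if (nrow(ev)) ev$error[nrow(ev)] else NA_real_,
    snr_last = if (nrow(ev)) ev$snr[nrow(ev)] else NA_real_,
    f_realized_last = if (nrow(ev)) ev$f_realized[nrow(ev)] else NA_real_,
    cum_replaced = object$trace$cum_replaced[object$config$days],
    mean_neuron_turnover = mean(object$trace$frac_neuron_turnover),
    mean_synapse_turnover = mean(object$trace$frac_synapse_turnover)
  )
  class(out) <- "summary.dg_sim"
  out
}

#' @export
print.summary.dg_sim <- function(x, ...) {
  cat("DG turnover simulation summary (", x$config$model, ")\n", sep = "")
  cat("  days:                 ", x$config$days, "\n")
  cat("  error first/last:     ", signif(x$error_first, 3), "/",
      signif(x$error_last, 3), "\n")
  cat("  final SNR:            ", signif(x$snr_last, 4), "\n")
  cat("  realized f (last):    ", signif(x$f_realized_last, 3), "\n")
  cat("  mean daily neuron turnover: ", signif(x$mean_neuron_turnover, 3),
      "\n")
  cat("  mean daily synapse turnover:", signif(x$mean_synapse_turnover, 3),
      "\n")
  cat("  cumulative replacement of day-0 cohort: ",
      signif(x$cum_replaced, 3), "\n")
  invisible(x)
}

#' @export
coef.dg_sim <- function(object, ...) object$readout$W

#' @export
as.data.frame.dg_sim <- function(x, ...) x$trace

#' Plot the learning curve of a simulation
#'
#' Generalization error against day; days without evaluation are skipped.
#'
#' @param x A `"dg_sim"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dg_sim <- function(x, ...) {
  ev <- x$trace[!is.na(x$trace$error), ]
  graphics::plot(ev$day, ev$error, type = "l", xlab = "day",
                 ylab = "generalization error",
                 main = paste0("DG turnover (", x$config$model, ")"), ...)
  invisible(x)
}

#' Predict CA3 output codes for new EC patterns
#'
#' Applies the final layer and readout of a simulation to new \eqn{\pm 1}
#' EC patterns.
#'
#' @param object A `"dg_sim"` object.
#' @param newdata M x K matrix of \eqn{\pm 1} patterns; defaults to the
#'   training prototypes.
#' @param ... Unused.
#' @return C x K matrix of \eqn{\pm 1} output codes.
#' @export
predict.dg_sim <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$ensemble$prototypes
  S <- dg_activity(dg_currents(object$layer, newdata), object$theta)$S
  ca3_output(object$readout$W, S)$codes
}
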