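# The three competitive turnover rules and the rebirth of replaced material.
#
# Model 1: kill the units with the smallest |W_i| (single readout).
# Model 2: multi-output generalization, ranking by sum_c |W_ic|.
# Model 3: per-synapse resampling with probability decreasing linearly in
#          |W_i|; a unit dies only when all of its synapses are targeted.

# Shared bottom-k selection with the documented tie-break:
# ascending score, then older units first, then unit index.
bottom_k_units <- function(score, k, ages = NULL) {
  n <- length(score)
  if (k <= 0) return(integer(0))
  if (is.null(ages)) ages <- integer(n)
  ord <- order(score, -ages, seq_len(n))
  sort(ord[seq_len(k)])
}

#' Model 1 turnover selection: weakest single-output weights
#'
#' Selects the `floor(rate * N)` DG units with the smallest absolute readout
#' weight \eqn{|W_i|} for replacement. Requires a single CA3 output; with
#' several outputs use [select_turnover_model2()]. Ties at the cutoff are
#' broken by replacing older units first, then by unit index.
#'
#' @param W A `"dg_readout"` object or an N x 1 matrix / length-N vector of
#'   readout weights.
#' @param rate Fraction of units to replace per iteration, in \[0, 1\].
#' @param ages Optional integer ages used in tie-breaking.
#' @return Sorted integer vector of unit indices to replace.
#' @export
select_turnover_model1 <- function(W, rate, ages = NULL) {
  if (inherits(W, "dg_readout")) W <- W$W
  if (is.vector(W)) W <- matrix(W, ncol = 1)
  if (ncol(W) != 1) {
    stop("Model 1 requires a single CA3 output; use select_turnover_model2()")
  }
  stopifnot(rate >= 0, rate <= 1)
  bottom_k_units(abs(W[, 1]), floor(rate * nrow(W)), ages)
}

#' Model 2 turnover selection: weakest summed multi-output weights
#'
#' Ranks units by \eqn{\sum_c |W_{ic}|} and selects the bottom
#' `floor(rate * N)` for replacement. Reduces to Model 1 when there is one
#' output column.
#'
#' @inheritParams select_turnover_model1
#' @param W A `"dg_readout"` object or an N x C weight matrix.
#' @return Sorted integer vector of unit indices to replace.
#' @export
select_turnover_model2 <- function(W, rate, ages = NULL) {
  if (inherits(W, "dg_readout")) W <- W$W
  if (is.vector(W)) W <- matrix(W, ncol = 1)
  stopifnot(rate >= 0, rate <= 1)
  bottom_k_units(rowSums(abs(W)), floor(rate * nrow(W)), ages)
}

#' Model 3: probabilistic synaptic turnover
#'
#' Each unit's probability of synaptic destabilisation decreases linearly in
#' its readout-weight magnitude:
#' \eqn{p_i = \mathrm{clip}(1 - s\,|W_i| / \bar w,\; 0,\; 1)}, where `s` is
#' the slope and \eqn{\bar w} the population statistic of \eqn{|W|}
#' (maximum by default; the population mean is available but lets the
#' weight distribution tighten until no unit is below the p = 0 cutoff,
#' freezing the dynamics — see the methods vignette). Every connected
#' input synapse of unit
#' `i` independently enters the resample set with probability \eqn{p_i}; a
#' unit dies only if all of its connected synapses are targeted in the same
#' iteration.
#'
#' @param W A `"dg_readout"` object, N x 1 matrix, or length-N vector
#'   (single CA3 output).
#' @param layer The `"dg_layer"` whose connectivity mask defines the
#'   candidate synapses.
#' @param slope Positive slope of the linear transfer function.
#' @param normalization Statistic of `|W|` used as \eqn{\bar w}: `"max"`
#'   (default) or `"mean"`.
#' @param seed Optional integer seed.
#' @return List with `resample` (N x M logical mask of synapses to redraw),
#'   `dead` (integer indices of units with all synapses targeted), `p`
#'   (per-unit probabilities), and `normalization`.
#' @export
synaptic_turnover_model3 <- function(W, layer, slope,
                                     normalization = c("max", "mean"),
                                     seed = NULL) {
  if (inherits(W, "dg_readout")) W <- W$W
  if (is.matrix(W)) {
    if (ncol(W) != 1) stop("Model 3 is defined for a single CA3 output")
    W <- W[, 1]
  }
  stopifnot(inherits(layer, "dg_layer"), length(W) == layer$N)
  if (slope <= 0) stop("slope must be positive")
  normalization <- match.arg(normalization)
  if (!is.null(seed)) set.seed(as.integer(seed))

  w_abs <- abs(W)
  wbar <- switch(normalization, mean = mean(w_abs), max = max(w_abs))
  if (wbar == 0) {
    p <- rep(1, layer$N)  # degenerate all-zero readout: everything unstable
  } else {
    p <- pmin(pmax(1 - slope * w_abs / wbar, 0), 1)
  }
  # p recycles down columns, i.e. p[i] applies to all synapses of row i
  resample <- layer$mask &
    (matrix(stats::runif(layer$N * layer$M), layer$N) < p)
  n_conn <- rowSums(layer$mask)
  dead <- which(rowSums(resample) == n_conn & n_conn > 0)
  list(resample = resample, dead = dead, p = p, normalization = normalization)
}

#' Replace dead units and resampled synapses with fresh random material
#'
#' Dead/selected units get a completely new afferent set: fresh connected
#' positions (under partial connectivity a new neuron forms new synapses,
#' not the dead neuron's) and i.i.d. N(0, 1) weights, and their age resets
#' to 0. Synapses in `resample` belonging to surviving units are redrawn
#' N(0, 1) in place (positions kept). All other entries are untouched.
#' Survivor ages are not modified here; the simulation loop increments them
#' once per iteration.
#'
#' @param layer A `"dg_layer"` object.
#' @param dead_units Integer indices of units to rebuild completely.
#' @param resample Optional N x M logical mask of individual synapses to
#'   redraw (Model 3); entries in rows listed in `dead_units` are ignored.
#' @param seed Optional integer seed.
#' @return The updated `"dg_layer"`.
#' @export
rebirth <- function(layer, dead_units = integer(0), resample = NULL,
                    seed = NULL) {
  stopifnot(inherits(layer, "dg_layer"))
  if (length(dead_units) > 0) {
    stopifnot(all(dead_units >= 1), all(dead_units <= layer$N))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length(dead_units) > 0) {
    if (layer$M_effective == layer$M) {
      k <- length(dead_units)
      layer$J[dead_units, ] <- matrix(stats::rnorm(k * layer$M), k)
    } else {
      for (i in dead_units) {
        layer$mask[i, ] <- FALSE
        layer$mask[i, sample.int(layer$M, layer$M_effective)] <- TRUE
        layer$J[i, ] <- 0
        layer$J[i, layer$mask[i, ]] <- stats::rnorm(layer$M_effective)
      }
    }
    layer$ages[dead_units] <- 0L
  }
  if (!is.null(resample)) {
    partial <- resample
    partial[dead_units, ] <- FALSE
    n <- sum(partial)
    if (n > 0) layer$J[partial] <- stats::rnorm(n)
  }
  layer
}
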