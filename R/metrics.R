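# Performance and representation metrics: generalization error, context-bias,
# empirical and closed-form signal-to-noise, correlation/PCA diagnostics, and
# material-turnover accounting.

#' Generalization error on output codes
#'
#' A test pattern counts as an error unless its full output code matches the
#' label code exactly (all `C` bits); the mean over patterns is returned.
#'
#' @param outputs C x P matrix (or length-P vector) of \eqn{\pm 1} output
#'   codes.
#' @param labels Matching matrix/vector of \eqn{\pm 1} label codes.
#' @return Error fraction in \[0, 1\].
#' @export
generalization_error <- function(outputs, labels) {
  if (is.vector(outputs)) outputs <- matrix(outputs, nrow = 1)
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1)
  stopifnot(all(dim(outputs) == dim(labels)))
  mean(colSums(outputs != labels) > 0)
}

#' Context-bias of DG units
#'
#' For a single output and balanced contexts, a unit's context-bias is
#' \eqn{\Psi_i = f_i^+ - f_i^-}, the difference between the fractions of
#' (+)-labelled and (-)-labelled patterns that activate it
#' (`S = +1`). The equivalent matrix form \eqn{\Psi = S\eta / P} (with `P`
#' the total pattern count) is computed as a cross-check and the two must
#' agree; \eqn{\Psi} equals the separation between the context means of the
#' DG representation.
#'
#' @param S N x P matrix of \eqn{\pm 1} DG activities (columns = patterns).
#' @param labels Length-P vector of \eqn{\pm 1} context labels; the two
#'   classes must be equally large.
#' @return Object of class `"context_bias"`: list with `psi`, `f_plus`,
#'   `f_minus` (each length N).
#' @export
context_bias <- function(S, labels) {
  labels <- drop(labels)
  if (!is.null(dim(labels))) stop("context_bias is defined for C = 1")
  stopifnot(ncol(S) == length(labels))
  pos <- labels == 1
  if (sum(pos) != sum(!pos)) {
    stop("context sizes must be equal for the matrix form to hold")
  }
  f_plus <- rowMeans(S[, pos, drop = FALSE] == 1)
  f_minus <- rowMeans(S[, !pos, drop = FALSE] == 1)
  psi <- f_plus - f_minus
  psi_mat <- as.vector(S %*% labels) / ncol(S)
  if (max(abs(psi - psi_mat)) > 1e-10) {
    stop("counting and matrix forms of the context-bias disagree")
  }
  structure(list(psi = psi, f_plus = f_plus, f_minus = f_minus),
            class = "context_bias")
}

#' Empirical signal-to-noise ratio of CA3 currents
#'
#' Signal is the squared separation of the class-conditional mean currents;
#' noise is the sum of the class-conditional variances; SNR their ratio.
#' Zero noise with positive signal is reported as `snr = Inf` with
#' `infinite = TRUE` rather than an error.
#'
#' @param h Length-P vector of CA3 currents.
#' @param labels Length-P vector of \eqn{\pm 1} labels; both classes must be
#'   present.
#' @return Object of class `"snr_report"`: list with `signal`, `noise`,
#'   `snr`, `infinite`, `variant = "empirical"`.
#' @export
empirical_snr <- function(h, labels) {
  h <- drop(h)
  labels <- drop(labels)
  stopifnot(length(h) == length(labels))
  pos <- labels == 1
  if (!any(pos) || !any(!pos)) stop("both classes must be present")
  signal <- (mean(h[pos]) - mean(h[!pos]))^2
  noise <- stats::var(h[pos]) + stats::var(h[!pos])
  structure(
    list(signal = signal, noise = noise,
         snr = if (noise > 0) signal / noise else Inf,
         infinite = noise == 0, variant = "empirical"),
    class = "snr_report"
  )
}

#' Closed-form signal-to-noise ratio from context-bias
#'
#' For a single output, signal \eqn{= (2 W^T \Psi)^2} and noise
#' \eqn{= 4 \sum_i W_i^2 [f_i^+(1 - f_i^-) + f_i^-(1 - f_i^+) -
#' (f_i^+ - f_i^-)^2]}, valid when unit activities are conditionally
#' independent given the context. Also returns the large-N form that drops
#' the cross term \eqn{\sum_{i \ne j} W_i \Psi_i W_j \Psi_j} from the
#' signal, which vanishes as \eqn{N \to \infty}.
#'
#' @param W Length-N readout weight vector (or N x 1 matrix, or
#'   `"dg_readout"`).
#' @param bias A [context_bias()] report.
#' @return Object of class `"snr_report"` with elements `signal`, `noise`,
#'   `snr`, `snr_large_n`, `infinite`, `variant = "analytic"`.
#' @export
analytic_snr <- function(W, bias) {
  if (inherits(W, "dg_readout")) W <- W$W
  W <- drop(W)
  stopifnot(inherits(bias, "context_bias"), length(W) == length(bias$psi))
  fp <- bias$f_plus
  fm <- bias$f_minus
  psi <- bias$psi
  signal <- (2 * sum(W * psi))^2
  per_unit <- fp * (1 - fm) + fm * (1 - fp) - psi^2
  noise <- 4 * sum(W^2 * per_unit)
  num_large_n <- 4 * sum(W^2 * psi^2)
  structure(
    list(signal = signal, noise = noise,
         snr = if (noise > 0) signal / noise else Inf,
         snr_large_n = if (noise > 0) num_large_n / noise else Inf,
         infinite = noise == 0, variant = "analytic"),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(x$variant, " SNR: signal = ", signif(x$signal, 4), ", noise = ",
      signif(x$noise, 4), ", snr = ", signif(x$snr, 4), "\n", sep = "")
  invisible(x)
}

#' Correlation and PCA diagnostics of the DG representation
#'
#' Pearson correlations between pattern columns, mean within-context and
#' between-context correlations, and pattern coordinates on the top two
#' left singular directions of the per-unit centered activity matrix.
#' Zero-variance columns yield `NA` correlations.
#'
#' @param S N x P matrix of DG activities (columns = patterns).
#' @param context_of Length-P integer vector of context memberships.
#' @return List with `correlation` (P x P), `within`, `between` (scalar
#'   means over off-diagonal pairs), and `pc_scores` (2 x P).
#' @export
representation_diagnostics <- function(S, context_of) {
  stopifnot(ncol(S) == length(context_of))
  if (min(table(context_of)) < 2) {
    stop("need at least 2 patterns per context")
  }
  sds <- apply(S, 2, stats::sd)
  R <- suppressWarnings(stats::cor(S))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  same <- outer(context_of, context_of, "==")
  off <- !diag(TRUE, ncol(S))
  within <- mean(R[same & off], na.rm = TRUE)
  between <- mean(R[!same], na.rm = TRUE)
  Sc <- S - rowMeans(S)
  sv <- svd(Sc, nu = 2, nv = 0)
  pc_scores <- crossprod(sv$u, Sc)
  list(correlation = R, within = within, between = between,
       pc_scores = pc_scores)
}

#' Material-turnover accounting for a simulation
#'
#' Summarises a [dg_simulate()] trace into: per-iteration neuron and synapse
#' turnover fractions with running cumulative sums; survival fraction by age
#' cohort (pooled over iterations); the cumulative fraction of the day-0
#' population ever replaced; and cumulative error reduction against
#' cumulative material turnover.
#'
#' @param sim A `"dg_sim"` object.
#' @return List of class `"turnover_accounting"` with data frames
#'   `per_day` (day, neuron/synapse turnover fractions and their cumsums,
#'   `cum_replaced`, `error_reduction`) and `survival_by_age` (age,
#'   n at risk, survived, survival fraction).
#' @export
turnover_accounting <- function(sim) {
  stopifnot(inherits(sim, "dg_sim"))
  tr <- sim$trace
  err0 <- tr$error[!is.na(tr$error)][1]
  per_day <- data.frame(
    day = tr$day,
    frac_neuron_turnover = tr$frac_neuron_turnover,
    frac_synapse_turnover = tr$frac_synapse_turnover,
    cum_neuron_turnover = cumsum(tr$frac_neuron_turnover),
    cum_synapse_turnover = cumsum(tr$frac_synapse_turnover),
    cum_replaced = tr$cum_replaced,
    error_reduction = if (length(err0)) err0 - tr$error else NA_real_
  )
  sv <- sim$survival
  agg_n <- stats::aggregate(n ~ age, data = sv, FUN = sum)
  agg_s <- stats::aggregate(survived ~ age, data = sv, FUN = sum)
  survival_by_age <- merge(agg_n, agg_s, by = "age")
  survival_by_age$survival <- survival_by_age$survived / survival_by_age$n
  structure(list(per_day = per_day, survival_by_age = survival_by_age),
            class = "turnover_accounting")
}

#' @export
print.turnover_accounting <- function(x, ...) {
  n <- nrow(x$per_day)
  cat("Turnover accounting over ", n, " day(s)\n", sep = "")
  cat("  mean daily neuron turnover: ",
      signif(mean(x$per_day$frac_neuron_turnover), 3), "\n", sep = "")
  cat("  mean daily synapse turnover:",
      signif(mean(x$per_day$frac_synapse_turnover), 3), "\n", sep = "")
  cat("  cumulative replacement:     ",
      signif(x$per_day$cum_replaced[n], 3), "\n", sep = "")
  invisible(x)
}
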