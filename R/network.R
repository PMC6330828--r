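# The EC -> DG expansion layer: random Gaussian input weights, optional
# partial connectivity, a single global activation threshold calibrated to a
# target coding level, and the DG/CA3 current computations.

#' Initialise the EC to DG input layer
#'
#' Weights are i.i.d. standard normal. Under partial connectivity each DG
#' unit receives exactly `round(connectivity * M)` afferents at uniformly
#' random positions; masked entries of `J` are exactly zero.
#'
#' @param N Number of DG units.
#' @param M Number of EC units.
#' @param connectivity Fraction of EC units each DG unit connects to, in
#'   (0, 1].
#' @param seed Optional integer seed.
#' @return An object of class `"dg_layer"`: list with `J` (N x M weights),
#'   `mask` (N x M logical), `ages` (integer N, all zero), `N`, `M`,
#'   `connectivity`, and `M_effective = round(connectivity * M)`.
#' @examples
#' layer <- init_input_weights(N = 50, M = 20, seed = 1)
#' range(layer$ages)
#' @export
init_input_weights <- function(N, M, connectivity = 1, seed = NULL) {
  stopifnot(N >= 1, M >= 1, connectivity > 0, connectivity <= 1)
  M_eff <- as.integer(round(connectivity * M))
  if (M_eff < 1) {
    stop("connectivity ", connectivity, " yields zero afferents per unit")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (M_eff == M) {
    mask <- matrix(TRUE, N, M)
  } else {
    mask <- matrix(FALSE, N, M)
    for (i in seq_len(N)) mask[i, sample.int(M, M_eff)] <- TRUE
  }
  J <- matrix(0, N, M)
  J[mask] <- stats::rnorm(sum(mask))
  structure(
    list(J = J, mask = mask, ages = integer(N), N = N, M = M,
         connectivity = connectivity, M_effective = M_eff),
    class = "dg_layer"
  )
}

#' @export
print.dg_layer <- function(x, ...) {
  cat("DG layer: ", x$N, " units x ", x$M, " EC afferents (connectivity ",
      x$connectivity, ", ", x$M_effective, " per unit)\n", sep = "")
  invisible(x)
}

#' Calibrate the activation threshold for a target coding level
#'
#' The pre-activation current of a random unit on a random \eqn{\pm 1}
#' pattern is N(0, M_effective), so the threshold achieving an expected
#' coding level `f_target` is \eqn{\theta = \sqrt{M_{\rm eff}}\,
#' \Phi^{-1}(1 - f)}. The threshold is global and held fixed during training;
#' under partial connectivity only the connected afferents contribute
#' variance, hence `M_effective` rather than `M`.
#'
#' @param M_effective Number of connected afferents per unit.
#' @param f_target Target coding level, strictly between 0 and 1.
#' @return The scalar threshold theta.
#' @export
calibrate_threshold <- function(M_effective, f_target) {
  stopifnot(M_effective >= 1)
  if (f_target <= 0 || f_target >= 1) {
    stop("f_target must be strictly between 0 and 1")
  }
  sqrt(M_effective) * stats::qnorm(1 - f_target)
}

#' DG synaptic currents
#'
#' \eqn{g_i^\mu = \sum_j J_{ij} \xi_j^\mu}; masked weights are zero and so
#' contribute nothing.
#'
#' @param layer A [init_input_weights()] layer.
#' @param patterns M x P matrix of \eqn{\pm 1} patterns (or a length-M
#'   vector).
#' @return N x P matrix of currents.
#' @export
dg_currents <- function(layer, patterns) {
  stopifnot(inherits(layer, "dg_layer"))
  if (is.vector(patterns)) patterns <- matrix(patterns, ncol = 1)
  if (nrow(patterns) != layer$M) {
    stop("pattern length ", nrow(patterns), " does not match M = ", layer$M)
  }
  layer$J %*% patterns
}

# sign with the package-wide convention sign(0) -> +1
sign_pm <- function(x) {
  out <- x
  out[] <- -1
  out[x >= 0] <- 1
  out
}

#' Threshold DG currents into +/-1 activities
#'
#' `S = +1` where `g >= theta`, else `-1` (ties at the threshold map to +1,
#' the single convention used throughout the package). Also reports the
#' realized coding level, the average of `(S + 1) / 2`.
#'
#' @param g Current matrix from [dg_currents()].
#' @param theta Scalar activation threshold.
#' @return List with `S` (matrix of -1/+1) and `f_realized` (scalar).
#' @export
dg_activity <- function(g, theta) {
  S <- sign_pm(g - theta)
  list(S = S, f_realized = mean((S + 1) / 2))
}

#' Noise-averaged DG activities
#'
#' Expected value of the thresholded activity of a unit under flip noise:
#' the current is Gaussian with mean \eqn{\bar g = g(1 - 2\nu)} and variance
#' \eqn{\sigma_g^2 = 4 M \nu(1-\nu)}, giving
#' \eqn{\bar S = \mathrm{erf}\!\big((\bar g - \theta)/(\sqrt 2\,\sigma_g)\big)},
#' i.e. \eqn{1 - 2 F(\theta \mid \bar g, \sigma_g^2)}, which is increasing in
#' \eqn{\bar g} and lies in (-1, 1). At `nu = 0` the variance vanishes and
#' the hard threshold is returned.
#'
#' @param g_prototype Currents computed from noise-free prototypes.
#' @param theta Scalar activation threshold.
#' @param nu Flip probability.
#' @param M_effective Number of connected afferents per unit.
#' @return Matrix of expected activities, entries in \[-1, 1\].
#' @export
mean_dg_activity <- function(g_prototype, theta, nu, M_effective) {
  mom <- mean_current_and_variance(g_prototype, nu, M_effective)
  if (mom$var == 0) {
    return(sign_pm(mom$mean - theta))
  }
  sigma <- sqrt(mom$var)
  2 * stats::pnorm((mom$mean - theta) / sigma) - 1
}

#' CA3 output currents and codes
#'
#' \eqn{h^\mu = W^T S^\mu} per output unit; the output code is the sign of
#' `h` with sign(0) -> +1.
#'
#' @param W N x C readout weight matrix (or length-N vector for a single
#'   output), or a `"dg_readout"` object.
#' @param S N x P matrix of \eqn{\pm 1} DG activities.
#' @return List with `h` (C x P currents) and `codes` (C x P of -1/+1).
#' @export
ca3_output <- function(W, S) {
  if (inherits(W, "dg_readout")) W <- W$W
  if (is.vector(W)) W <- matrix(W, ncol = 1)
  if (is.vector(S)) S <- matrix(S, ncol = 1)
  if (nrow(W) != nrow(S)) {
    stop("W has ", nrow(W), " rows but S has ", nrow(S))
  }
  h <- crossprod(W, S)
  list(h = h, codes = sign_pm(h))
}

#' Write a DG layer to a CSV bundle
#'
#' Writes `J.csv`, `mask.csv`, and `meta.json` (ages, sizes, connectivity)
#' into `dir` for checkpoint/restart.
#'
#' @param layer A `"dg_layer"` object.
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_dg_layer <- function(layer, dir) {
  stopifnot(inherits(layer, "dg_layer"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(layer$J, file.path(dir, "J.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(layer$mask * 1L, file.path(dir, "mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(N = layer$N, M = layer$M, connectivity = layer$connectivity,
               M_effective = layer$M_effective, ages = layer$ages)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a DG layer written by [write_dg_layer()]
#'
#' @param dir Directory containing the bundle.
#' @return A `"dg_layer"` object.
#' @export
read_dg_layer <- function(dir) {
  J <- as.matrix(utils::read.table(file.path(dir, "J.csv"), sep = ","))
  mask <- as.matrix(utils::read.table(file.path(dir, "mask.csv"),
                                      sep = ",")) == 1
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  dimnames(J) <- NULL
  dimnames(mask) <- NULL
  structure(
    list(J = J, mask = mask, ages = as.integer(meta$ages), N = meta$N,
         M = meta$M, connectivity = meta$connectivity,
         M_effective = meta$M_effective),
    class = "dg_layer"
  )
}
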