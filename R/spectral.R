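# SVD analysis of the DG population code: projected context-bias vectors,
# reconstruction of the pseudoinverse readout from them, and readouts
# restricted to the leading components.

#' Spectral decomposition of the DG activity matrix
#'
#' Computes the SVD of the (uncentered) activity matrix `S`, the context-bias
#' vector \eqn{\Psi} and its projections \eqn{\hat\Psi_i = u_i u_i^T \Psi}
#' onto the left singular directions, and verifies the identity
#' \eqn{W^T = P \sum_i \sigma_i^{-2} \hat\Psi_i^T} (with `P` the total
#' pattern count) against the pseudoinverse-trained readout. Singular-value
#' ratios \eqn{\lambda(i)/\lambda(1)} are taken from the per-unit centered
#' matrix, matching their use as dimensionality diagnostics, while the
#' readout identity uses the uncentered matrix that the pseudoinverse is
#' defined on. Readout coefficients \eqn{\alpha_i = u_i^T W} are ranked by
#' `|alpha|` descending.
#'
#' @param S N x P matrix of DG activities (columns = patterns), typically
#'   hard activities of noisy training instances.
#' @param labels Length-P vector of \eqn{\pm 1} context labels (balanced).
#' @param W Optional length-N readout (vector, N x 1 matrix, or
#'   `"dg_readout"`) trained on this same `S`; defaults to the
#'   reconstruction.
#' @param tol Relative singular-value cutoff excluding zero modes from the
#'   \eqn{\sigma^{-2}} sum.
#' @return Object of class `"spectral_report"`: list with `u`, `d`, `v`
#'   (SVD factors), `sv_ratios` (from the centered matrix), `psi`,
#'   `psi_hat` (N x D matrix, column i = \eqn{\hat\Psi_i}), `alpha`,
#'   `ranking` (component order by `|alpha|`), `W`, `W_reconstructed`,
#'   `D`, and `reconstruction_error` (relative, against `W`).
#' @export
spectral_decomposition <- function(S, labels, W = NULL, tol = NULL) {
  labels <- drop(labels)
  stopifnot(ncol(S) == length(labels))
  sv <- svd(S)
  D <- length(sv$d)
  if (is.null(tol)) tol <- max(dim(S)) * .Machine$double.eps
  keep <- sv$d > tol * sv$d[1]

  # matrix form of the context-bias; agrees with the counting definition
  # for hard +/-1 activities and extends it to noise-averaged activities
  psi <- as.vector(S %*% labels) / ncol(S)
  proj <- as.vector(crossprod(sv$u, psi))        # u_i . psi
  psi_hat <- sweep(sv$u, 2, proj, "*")           # column i = u_i (u_i.psi)
  inv_d2 <- ifelse(keep, 1 / sv$d^2, 0)
  W_rec <- ncol(S) * as.vector(psi_hat %*% inv_d2)

  if (is.null(W)) {
    W_use <- W_rec
    rec_err <- 0
  } else {
    if (inherits(W, "dg_readout")) W <- W$W
    W_use <- drop(W)
    rec_err <- sqrt(sum((W_rec - W_use)^2)) / max(sqrt(sum(W_use^2)),
                                                  .Machine$double.eps)
  }
  alpha <- as.vector(crossprod(sv$u, W_use))
  ranking <- order(abs(alpha), decreasing = TRUE)

  Sc <- S - rowMeans(S)
  dc <- svd(Sc, nu = 0, nv = 0)$d
  sv_ratios <- dc / dc[1]

  structure(
    list(u = sv$u, d = sv$d, v = sv$v, sv_ratios = sv_ratios, psi = psi,
         psi_hat = psi_hat, alpha = alpha, ranking = ranking, W = W_use,
         W_reconstructed = W_rec, D = D, reconstruction_error = rec_err),
    class = "spectral_report"
  )
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("Spectral report: D = ", x$D, " components; readout reconstruction ",
      "relative error ", signif(x$reconstruction_error, 3), "\n", sep = "")
  invisible(x)
}

#' Readout restricted to the leading spectral components
#'
#' Builds the cumulative weight vector
#' \eqn{\hat W_d = \sum_{i \le d} \alpha_i u_i} over the top `d` components
#' in the `|alpha|`-descending ranking, evaluates its generalization error
#' on a test set, and reports the cumulative performance
#' \eqn{(0.5 - \mathrm{err}) / 0.5}.
#'
#' @param report A [spectral_decomposition()] object.
#' @param d Number of components, `1 <= d <= D`.
#' @param test_S N x K matrix of test DG activities.
#' @param test_labels Length-K vector of \eqn{\pm 1} labels.
#' @return List with `W_hat`, `error`, `perf_cum`.
#' @export
restricted_readout <- function(report, d, test_S, test_labels) {
  stopifnot(inherits(report, "spectral_report"))
  if (d < 1 || d > report$D) stop("d must be in 1..", report$D)
  top <- report$ranking[seq_len(d)]
  W_hat <- as.vector(report$u[, top, drop = FALSE] %*% report$alpha[top])
  out <- ca3_output(W_hat, test_S)
  err <- generalization_error(out$codes[1, ], drop(test_labels))
  list(W_hat = W_hat, error = err, perf_cum = (0.5 - err) / 0.5)
}
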