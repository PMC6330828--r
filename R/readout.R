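# Pseudoinverse training of the DG -> CA3 readout.

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse with a relative singular-value cutoff
#' `tol * max(singular value)`; the default tolerance is
#' `max(dim(A)) * .Machine$double.eps`, the conventional rank threshold.
#' Results at the scales used here are insensitive to the cutoff.
#'
#' @param A Numeric matrix.
#' @param tol Relative cutoff for treating singular values as zero.
#' @return The pseudoinverse of `A` (`ncol(A)` x `nrow(A)`).
#' @export
pseudoinverse <- function(A, tol = NULL) {
  if (!all(is.finite(A))) stop("matrix contains non-finite values")
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Train the CA3 readout by pseudoinverse
#'
#' Solves the least-squares problem
#' \eqn{W^T = \arg\min_{\tilde W} \sum_\mu \|\eta^\mu - \tilde W^T S^\mu\|^2}
#' via \eqn{W^T = \eta S^{+}}: the minimum-norm least-squares readout mapping
#' each training activity column to its target code. `activities` may be the
#' noise-averaged activities (mean-prototype training) or hard-thresholded
#' noisy-instance activities. When there are fewer training columns than
#' units and the Gram matrix is clearly well-conditioned the solution is
#' computed by Cholesky-factored normal equations (identical result, much
#' faster); near-singular or wide activity matrices go through the SVD
#' pseudoinverse with its rank tolerance.
#'
#' @param activities N x P matrix of DG activities (columns are patterns).
#' @param labels C x P matrix (or length-P vector) of \eqn{\pm 1} target
#'   codes aligned with the activity columns.
#' @param tol Rank tolerance passed to [pseudoinverse()].
#' @param trained_on Optional tag recording the training variant
#'   (`"mean"` or `"noisy"`).
#' @return Object of class `"dg_readout"`: list with `W` (N x C matrix) and
#'   `trained_on`.
#' @examples
#' A <- matrix(rnorm(30), 6, 5)
#' eta <- sample(c(-1, 1), 5, replace = TRUE)
#' rd <- train_readout(A, eta)
#' max(abs(crossprod(rd$W, A) - eta))  # zero residual: full column rank
#' @export
train_readout <- function(activities, labels, tol = NULL,
                          trained_on = "mean") {
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1)
  if (ncol(activities) != ncol(labels)) {
    stop("activities have ", ncol(activities), " columns but labels ",
         ncol(labels))
  }
  # Fast path: with fewer training columns than units and a clearly
  # well-conditioned Gram matrix, the minimum-norm solution is
  # W = A (A^T A)^{-1} eta^T (Cholesky); otherwise fall back to the SVD
  # pseudoinverse, which also handles rank deficiency.
  if (is.null(tol) && ncol(activities) < nrow(activities)) {
    ch <- tryCatch(chol(crossprod(activities)), error = function(e) NULL)
    if (!is.null(ch) && min(diag(ch)) > 1e-8 * max(diag(ch))) {
      W <- activities %*% chol2inv(ch) %*% t(labels)
      return(structure(list(W = W, trained_on = trained_on),
                       class = "dg_readout"))
    }
  }
  Wt <- labels %*% pseudoinverse(activities, tol = tol)
  structure(list(W = t(Wt), trained_on = trained_on), class = "dg_readout")
}

#' @export
print.dg_readout <- function(x, ...) {
  cat("DG->CA3 readout: ", nrow(x$W), " units x ", ncol(x$W),
      " output(s), trained on ", x$trained_on, " activities\n", sep = "")
  invisible(x)
}

#' @export
coef.dg_readout <- function(object, ...) object$W
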