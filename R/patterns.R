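# Entorhinal context patterns: +/-1 prototypes grouped into contexts, noisy
# instances by sign flips, and the Gaussian moments of the induced currents.

#' Generate a set of context prototype patterns
#'
#' Draws `P` prototype EC activity patterns with independent equiprobable
#' \eqn{\pm 1} entries, splits them evenly into `n_contexts` contexts, and
#' assigns each context a distinct \eqn{\pm 1} target code of length `C`
#' (the number of CA3 output units). Context `k` receives the `C`-bit binary
#' expansion of `k - 1` mapped \{0 -> -1, 1 -> +1\}, which guarantees
#' distinct, reproducible codes.
#'
#' @param M Number of EC units (pattern length).
#' @param P Total number of prototype patterns; must be divisible by
#'   `n_contexts`.
#' @param n_contexts Number of contexts; must satisfy `n_contexts <= 2^C`.
#' @param C Number of CA3 output units (label-code length).
#' @param nu Flip-noise probability in \[0, 1\] attached to the ensemble.
#' @param seed Optional integer seed; when supplied the ensemble is
#'   bit-reproducible.
#' @return An object of class `"context_ensemble"`: a list with elements
#'   `prototypes` (M x P matrix of -1/+1), `context_of` (integer vector in
#'   `1:n_contexts`), `labels` (C x P matrix of -1/+1 target codes),
#'   `nu`, `M`, `P`, `n_contexts`, `C`.
#' @examples
#' ens <- generate_context_set(M = 20, P = 10, n_contexts = 2, C = 1, seed = 1)
#' table(ens$context_of)
#' @export
generate_context_set <- function(M, P, n_contexts = 2, C = 1, nu = 0.2,
                                 seed = NULL) {
  stopifnot(M >= 1, P >= 1, n_contexts >= 1, C >= 1)
  if (P %% n_contexts != 0) {
    stop("P (", P, ") must be divisible by n_contexts (", n_contexts, ")")
  }
  if (n_contexts > 2^C) {
    stop("n_contexts (", n_contexts, ") exceeds the 2^C = ", 2^C,
         " distinct label codes available")
  }
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))

  prototypes <- matrix(sample(c(-1, 1), M * P, replace = TRUE), nrow = M)
  per <- P %/% n_contexts
  context_of <- rep(seq_len(n_contexts), each = per)
  codes <- context_codes(n_contexts, C)
  labels <- codes[, context_of, drop = FALSE]

  structure(
    list(prototypes = prototypes, context_of = context_of, labels = labels,
         nu = nu, M = M, P = P, n_contexts = n_contexts, C = C),
    class = "context_ensemble"
  )
}

# C x n_contexts matrix of distinct +/-1 codes (binary expansion of k-1).
context_codes <- function(n_contexts, C) {
  matrix(vapply(seq_len(n_contexts) - 1L, function(k) {
    bits <- as.integer(intToBits(k))[seq_len(C)]
    2 * bits - 1
  }, numeric(C)), nrow = C)
}

#' @export
print.context_ensemble <- function(x, ...) {
  cat("Context ensemble: ", x$P, " patterns of ", x$M, " EC units, ",
      x$n_contexts, " context(s), ", x$C, " output unit(s), nu = ", x$nu,
      "\n", sep = "")
  invisible(x)
}

#' Apply flip noise to +/-1 patterns
#'
#' Each entry is independently negated with probability `nu`, modelling
#' trial-to-trial variability of the EC input. Draws come from the current
#' generator state unless `seed` is given.
#'
#' @param patterns A vector or matrix with entries -1/+1.
#' @param nu Flip probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Object of the same shape with entries -1/+1.
#' @export
apply_flip_noise <- function(patterns, nu, seed = NULL) {
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  if (!all(patterns == 1 | patterns == -1)) {
    stop("patterns must contain only -1 and +1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nu == 0) return(patterns)
  flips <- stats::runif(length(patterns)) < nu
  patterns[flips] <- -patterns[flips]
  patterns
}

#' Noise-averaged current mean and variance
#'
#' For a DG current `g` computed from a noise-free prototype, flip noise at
#' rate `nu` over `M` afferents gives mean current \eqn{\bar g = g (1 - 2\nu)}
#' and variance \eqn{\sigma_g^2 = 4 M \nu (1 - \nu)} (the afferent weights
#' are standard normal, so each flipped term contributes variance 4).
#'
#' @param g Vector or matrix of prototype currents.
#' @param nu Flip probability in \[0, 1\].
#' @param M Number of (connected) afferents contributing to the current.
#' @return A list with `mean` (same shape as `g`) and `var` (scalar).
#' @export
mean_current_and_variance <- function(g, nu, M) {
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  stopifnot(M >= 1)
  list(mean = g * (1 - 2 * nu), var = 4 * M * nu * (1 - nu))
}

#' Noisy test instances of an ensemble's prototypes
#'
#' Generates `instances` fresh flip-noise copies of every prototype, with the
#' matching label codes, for measuring generalization error.
#'
#' @param ensemble A [generate_context_set()] object.
#' @param instances Number of noisy copies per prototype.
#' @param seed Optional integer seed.
#' @return A list with `patterns` (M x P*instances), `labels`
#'   (C x P*instances), and `context_of`.
#' @export
noisy_instances <- function(ensemble, instances = 10, seed = NULL) {
  stopifnot(inherits(ensemble, "context_ensemble"), instances >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- rep(seq_len(ensemble$P), times = instances)
  patterns <- apply_flip_noise(ensemble$prototypes[, idx, drop = FALSE],
                               ensemble$nu)
  list(patterns = patterns,
       labels = ensemble$labels[, idx, drop = FALSE],
       context_of = ensemble$context_of[idx])
}

#' Write a context ensemble to CSV
#'
#' One pattern per column; the first two header-like rows carry the context
#' index and the label code bits, followed by the M EC rows.
#'
#' @param ensemble A [generate_context_set()] object.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, file) {
  stopifnot(inherits(ensemble, "context_ensemble"))
  block <- rbind(ensemble$context_of, ensemble$labels, ensemble$prototypes)
  rownames(block) <- c("context",
                       paste0("label", seq_len(ensemble$C)),
                       paste0("ec", seq_len(ensemble$M)))
  colnames(block) <- paste0("pattern", seq_len(ensemble$P))
  utils::write.csv(block, file)
  invisible(file)
}

#' Read a context ensemble written by [write_ensemble_csv()]
#'
#' @param file Path to the CSV file.
#' @param nu Flip probability to attach (not stored in the CSV).
#' @return A `"context_ensemble"` object.
#' @export
read_ensemble_csv <- function(file, nu = 0.2) {
  block <- as.matrix(utils::read.csv(file, row.names = 1))
  C <- sum(startsWith(rownames(block), "label"))
  M <- nrow(block) - 1L - C
  context_of <- as.integer(block[1, ])
  structure(
    list(prototypes = unname(block[-(seq_len(C + 1)), , drop = FALSE]),
         context_of = context_of,
         labels = unname(block[1L + seq_len(C), , drop = FALSE]),
         nu = nu, M = M, P = ncol(block),
         n_contexts = length(unique(context_of)), C = C),
    class = "context_ensemble"
  )
}
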