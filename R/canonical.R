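#' Canonical (spectral) form of a fitted Poisson model
#'
#' Eigendecomposes the weighted cross-product X'LX at the MLE and rotates the
#' coefficient vector into its eigenbasis. Every shrinkage estimator in the
#' package acts componentwise in this basis, and every theoretical MSE
#' expression is a sum over the eigenvalues, so this object is the common
#' currency between fitting, parameter selection and MSE theory.
#'
#' @param fit An [fit_poisson_mle()] result; must have converged.
#' @param sample The [poisson_sample()] the fit came from.
#'
#' @return An object of class `canonical_form`:
#'   \describe{
#'     \item{eigenvalues}{eigenvalues of X'LX, descending, all positive}
#'     \item{eigenvectors}{orthogonal matrix Q of eigenvectors (columns)}
#'     \item{alpha}{canonical coefficients `t(Q) %*% beta_hat`}
#'   }
#'
#' @details Eigenvector columns are sign-normalised so that the
#'   largest-magnitude entry of each column is positive, which makes the
#'   canonical coefficients reproducible across LAPACK builds. A non-positive
#'   smallest eigenvalue aborts with a rank-deficiency error.
#'
#' @examples
#' set.seed(1)
#' s <- poisson_sample(matrix(rnorm(60), 30, 2), rpois(30, 3))
#' cf <- canonical_decompose(fit_poisson_mle(s), s)
#' cf$eigenvalues
#' @export
canonical_decompose <- function(fit, sample) {
  stopifnot(inherits(fit, "iwls_fit"), inherits(sample, "poisson_sample"))
  if (!fit$converged) {
    stop("canonical decomposition requires a converged fit", call. = FALSE)
  }
  S <- crossprod(sample$X * sqrt(fit$weight_diag))
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  lambda <- ev$values
  if (min(lambda) <= 0) {
    stop(sprintf(
      "weighted cross-product is rank deficient (smallest eigenvalue %.3e)",
      min(lambda)
    ), call. = FALSE)
  }
  Q <- ev$vectors
  # reproducible sign convention: largest-magnitude entry of each column > 0
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  structure(
    list(eigenvalues = lambda,
         eigenvectors = Q,
         alpha = drop(crossprod(Q, fit$beta_hat))),
    class = "canonical_form"
  )
}

#' Build a canonical form directly from eigenvalues and coefficients
#'
#' Convenience constructor used by the MSE theory functions and by tests that
#' study the estimators on synthetic spectra without fitting a model.
#'
#' @param eigenvalues Positive eigenvalues (any order; sorted descending).
#' @param alpha Canonical coefficients, same length.
#' @param eigenvectors Optional orthogonal matrix; identity if omitted.
#' @return A `canonical_form` object.
#' @export
canonical_form <- function(eigenvalues, alpha, eigenvectors = NULL) {
  stopifnot(length(eigenvalues) == length(alpha), all(eigenvalues > 0))
  ord <- order(eigenvalues, decreasing = TRUE)
  if (is.null(eigenvectors)) {
    eigenvectors <- diag(length(eigenvalues))
  } else {
    eigenvectors <- eigenvectors[, ord, drop = FALSE]
  }
  structure(
    list(eigenvalues = eigenvalues[ord],
         eigenvectors = eigenvectors,
         alpha = alpha[ord]),
    class = "canonical_form"
  )
}

#' Scalar mean squared error of the Poisson MLE
#'
#' The trace of the asymptotic covariance (X'LX)^{-1}, i.e. the sum of
#' reciprocal eigenvalues of the weighted cross-product. This is the
#' benchmark every shrinkage estimator is compared against.
#'
#' @param canon A [canonical_decompose()] result.
#' @return The scalar MSE `sum(1 / eigenvalues)`.
#' @export
mle_scalar_mse <- function(canon) {
  stopifnot(inherits(canon, "canonical_form"))
  if (any(canon$eigenvalues <= 0)) {
    stop("all eigenvalues must be strictly positive", call. = FALSE)
  }
  sum(1 / canon$eigenvalues)
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("Canonical form of X'LX\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  cat("  alpha:      ", paste(signif(x$alpha, 5), collapse = ", "), "\n")
  invisible(x)
}
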