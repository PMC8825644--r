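#' Theoretical scalar mean squared error of a shrinkage estimator
#'
#' Evaluates the closed-form trace mean squared error of each estimator in
#' canonical coordinates, where the variance term is a sum of squared
#' shrinkage factors over reciprocal eigenvalues and the bias term a sum of
#' squared (factor - 1) weights over the canonical coefficients:
#' \describe{
#'   \item{MLE}{`sum(1/lambda_j)`}
#'   \item{PRE}{`sum(lambda_j/(lambda_j+k)^2) + k^2 sum(alpha_j^2/(lambda_j+k)^2)`}
#'   \item{PLE}{`sum((lambda_j+d)^2/(lambda_j (lambda_j+1)^2)) + (d-1)^2 sum(alpha_j^2/(lambda_j+1)^2)`}
#'   \item{PKL}{`sum((lambda_j-k)^2/(lambda_j (lambda_j+k)^2)) + 4 k^2 sum(alpha_j^2/(lambda_j+k)^2)`}
#'   \item{PMKL}{`sum(lambda_j (lambda_j-k)^2/(lambda_j+k)^4) + k^2 sum((3 lambda_j+k)^2 alpha_j^2/(lambda_j+k)^4)`}
#' }
#'
#' @param kind One of `"MLE"`, `"PRE"`, `"PLE"`, `"PKL"`, `"PMKL"`.
#' @param canon A [canonical_decompose()] or [canonical_form()] object.
#' @param param The biasing parameter (`k`, or `d` for `"PLE"`; ignored for
#'   `"MLE"`).
#' @return The scalar MSE.
#' @examples
#' cf <- canonical_form(c(4, 2), c(1, 1))
#' scalar_mse("PRE", cf, 0.5)
#' @export
scalar_mse <- function(kind, canon, param = NULL) {
  stopifnot(inherits(canon, "canonical_form"))
  kind <- match.arg(kind, c("MLE", "PRE", "PLE", "PKL", "PMKL"))
  l <- canon$eigenvalues
  a2 <- canon$alpha^2
  if (kind == "MLE") return(sum(1 / l))
  if (is.null(param)) stop("param is required for shrinkage estimators",
                           call. = FALSE)
  k <- param
  switch(kind,
    PRE  = sum(l / (l + k)^2) + k^2 * sum(a2 / (l + k)^2),
    PLE  = sum((l + k)^2 / (l * (l + 1)^2)) +
           (k - 1)^2 * sum(a2 / (l + 1)^2),
    PKL  = sum((l - k)^2 / (l * (l + k)^2)) +
           4 * k^2 * sum(a2 / (l + k)^2),
    PMKL = sum(l * (l - k)^2 / (l + k)^4) +
           k^2 * sum((3 * l + k)^2 * a2 / (l + k)^4)
  )
}

#' Bias, variance and MSE of the modified KL estimator in the linear model
#'
#' Scalar-form moments of the modified Kibria-Lukman estimator under the
#' Gaussian linear model, where the error variance sigma^2 enters the
#' variance term explicitly (in the Poisson fit the asymptotic covariance
#' absorbs it, so the GLM-side formulas carry no sigma^2). Kept separate so
#' the linear-model theory can be exercised on its own.
#'
#' @param eigenvalues Positive eigenvalues of the cross-product matrix.
#' @param beta Coefficient value(s) entering the bias; a scalar is recycled
#'   across components.
#' @param sigma2 Error variance, positive.
#' @param k Positive biasing parameter.
#' @return A list with `bias` (signed, per component
#'   `k (-3 lambda_j - k) beta_j / (lambda_j + k)^2`), `variance`
#'   (`sigma2 sum(lambda_j (lambda_j - k)^2 / (lambda_j + k)^4)`) and `mse`
#'   (`variance + k^2 sum((3 lambda_j + k)^2 beta_j^2 / (lambda_j + k)^4)`).
#' @export
mkl_linear_moments <- function(eigenvalues, beta, sigma2, k) {
  stopifnot(all(eigenvalues > 0), sigma2 > 0, k > 0)
  beta <- rep_len(beta, length(eigenvalues))
  l <- eigenvalues
  bias <- k * (-3 * l - k) * beta / (l + k)^2
  variance <- sigma2 * sum(l * (l - k)^2 / (l + k)^4)
  mse <- variance + k^2 * sum((3 * l + k)^2 * beta^2 / (l + k)^4)
  list(bias = bias, variance = variance, mse = mse)
}

#' Matrix mean squared error of one estimator in canonical coordinates
#'
#' MSEM = variance matrix + bias outer product. With sigma2 = 1 this is the
#' Poisson (GLM) asymptotic form; a different sigma2 gives the linear-model
#' variant.
#' @noRd
canonical_msem <- function(kind, canon, param, sigma2 = 1) {
  f <- shrink_factor(kind, canon$eigenvalues, if (is.null(param)) 0 else param)
  b <- (f - 1) * canon$alpha
  diag(sigma2 * f^2 / canon$eigenvalues, nrow = length(f)) + tcrossprod(b)
}

#' Matrix-MSE dominance comparison of two estimators
#'
#' Tests whether the challenger estimator dominates the reference in the
#' matrix mean-squared-error sense, MSEM(reference) - MSEM(challenger) > 0,
#' using the classical two-step criterion: the variance-difference matrix
#' must be positive definite, and then the challenger's bias must satisfy
#' `b2' [D + b1 b1']^{-1} b2 < 1` where `D` is the variance difference and
#' `b1`, `b2` the two bias vectors. All matrices are assembled in canonical
#' coordinates, where every variance matrix is diagonal.
#'
#' @param pair Character vector of length 2, `c(reference, challenger)`,
#'   each one of `"MLE"`, `"PRE"`, `"PLE"`, `"PKL"`, `"PMKL"`.
#' @param canon A [canonical_form()] object.
#' @param k Biasing parameter used for any k-type estimator in the pair.
#' @param d Liu parameter, required when the pair involves `"PLE"`.
#' @param sigma2 Variance scale (1 for the Poisson asymptotics).
#' @return An object of class `dominance_report`: the pair, parameters, the
#'   eigenvalues of the MSEM difference, the diagonal of the variance
#'   difference, `condition_ok` (variance difference positive definite,
#'   within floating point tolerance), and `dominates` (`TRUE`/`FALSE`, or
#'   `NA` with `note = "condition_out_of_range"` when the variance
#'   difference is not positive definite so the scalar criterion does not
#'   apply).
#' @examples
#' cf <- canonical_form(c(2, 1), c(0.5, 0.5))
#' msem_difference(c("MLE", "PMKL"), cf, k = 0.5)
#' @export
msem_difference <- function(pair, canon, k = NULL, d = NULL, sigma2 = 1) {
  stopifnot(inherits(canon, "canonical_form"), length(pair) == 2)
  kinds <- match.arg(pair, c("MLE", "PRE", "PLE", "PKL", "PMKL"),
                     several.ok = TRUE)
  if (length(kinds) != 2) stop("pair must name two estimators", call. = FALSE)
  param_for <- function(kind) {
    if (kind == "MLE") return(NULL)
    if (kind == "PLE") {
      if (is.null(d)) stop("d is required for PLE comparisons", call. = FALSE)
      if (d < 0 || d > 1) stop("d must lie in [0, 1]", call. = FALSE)
      return(d)
    }
    if (is.null(k) || k <= 0) stop("k > 0 is required", call. = FALSE)
    k
  }
  p1 <- param_for(kinds[1]); p2 <- param_for(kinds[2])
  l <- canon$eigenvalues
  f1 <- shrink_factor(kinds[1], l, if (is.null(p1)) 0 else p1)
  f2 <- shrink_factor(kinds[2], l, if (is.null(p2)) 0 else p2)
  b1 <- (f1 - 1) * canon$alpha
  b2 <- (f2 - 1) * canon$alpha
  var_diff <- sigma2 * (f1^2 - f2^2) / l

  M1 <- canonical_msem(kinds[1], canon, p1, sigma2)
  M2 <- canonical_msem(kinds[2], canon, p2, sigma2)
  diff_eig <- eigen((M1 - M2 + t(M1 - M2)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values

  scale <- max(abs(var_diff), 1)
  condition_ok <- all(var_diff > -1e-12 * scale)
  dominates <- NA
  note <- ""
  if (all(var_diff > 0)) {
    A <- diag(var_diff, nrow = length(l)) + tcrossprod(b1)
    rc <- rcond(A)
    if (rc < .Machine$double.eps * 100) {
      stop(sprintf(
        "ill-conditioned variance-difference system (rcond %.3e)", rc),
        call. = FALSE)
    }
    dominates <- drop(crossprod(b2, solve(A, b2))) < 1
  } else {
    note <- "condition_out_of_range"
  }
  structure(
    list(pair = kinds, k = k, d = d,
         difference_eigenvalues = diff_eig,
         variance_difference = var_diff,
         condition_ok = condition_ok,
         dominates = dominates,
         note = note),
    class = "dominance_report"
  )
}

#' @export
print.dominance_report <- function(x, ...) {
  cat(sprintf("MSEM comparison: %s (reference) vs %s (challenger)\n",
              x$pair[1], x$pair[2]))
  if (!is.null(x$k)) cat(sprintf("  k = %.4f", x$k))
  if (!is.null(x$d)) cat(sprintf("  d = %.4f", x$d))
  cat("\n  difference eigenvalues:",
      paste(signif(x$difference_eigenvalues, 4), collapse = ", "), "\n")
  if (is.na(x$dominates)) {
    cat("  verdict: not applicable (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("  challenger dominates: %s\n", x$dominates))
  }
  invisible(x)
}
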