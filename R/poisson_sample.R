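#' Construct a Poisson regression sample
#'
#' Bundles a design matrix and a count response into the validated container
#' that every fitting and simulation function in the package consumes. An
#' intercept column of ones is prepended unless the supplied matrix already
#' carries one as its first column.
#'
#' @param x Numeric matrix (or data frame coercible to one) of predictors,
#'   one row per observation. May or may not already contain a leading
#'   intercept column of ones.
#' @param y Vector of non-negative integer counts, one per row of `x`.
#' @param predictor_names Optional character vector of labels for the
#'   predictor columns (excluding the intercept).
#'
#' @return An object of class `poisson_sample` with components
#'   \describe{
#'     \item{X}{the `n x (p+1)` design matrix, intercept first}
#'     \item{y}{the integer count response}
#'     \item{n, p}{number of observations and number of predictors}
#'     \item{predictor_names}{column labels, `"(Intercept)"` first}
#'   }
#'
#' @details The container enforces `n >= p + 2` (at least one residual degree
#'   of freedom beyond the coefficients), integer non-negative counts, and a
#'   fully finite design. These are the preconditions of the IWLS fit and of
#'   every spectral quantity derived from it.
#'
#' @examples
#' s <- poisson_sample(matrix(rnorm(40), 20, 2), rpois(20, 2))
#' s$n; s$p
#' @export
poisson_sample <- function(x, y, predictor_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) {
    stop("design matrix contains non-finite values", call. = FALSE)
  }
  y <- as.vector(y)
  if (any(is.na(y))) stop("response contains missing values", call. = FALSE)
  bad <- which(y < 0 | abs(y - round(y)) > 1e-8)
  if (length(bad)) {
    stop(sprintf(
      "response must be non-negative integers; offending rows: %s",
      paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  y <- as.integer(round(y))
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)

  has_intercept <- ncol(x) >= 1 && all(x[, 1] == 1)
  if (!has_intercept) {
    x <- cbind(1, x)
  }
  p <- ncol(x) - 1L
  n <- nrow(x)
  if (n < p + 2L) {
    stop(sprintf("need n >= p + 2 observations (n = %d, p = %d)", n, p),
         call. = FALSE)
  }
  if (is.null(predictor_names)) {
    cn <- colnames(x)
    predictor_names <- if (!is.null(cn)) {
      cn[-1]
    } else if (p > 0) {
      paste0("x", seq_len(p))
    } else {
      character(0)
    }
  }
  if (length(predictor_names) != p) {
    stop("predictor_names must have one entry per predictor column",
         call. = FALSE)
  }
  colnames(x) <- c("(Intercept)", predictor_names)
  structure(
    list(X = x, y = y, n = n, p = p,
         predictor_names = colnames(x)),
    class = "poisson_sample"
  )
}

#' @export
print.poisson_sample <- function(x, ...) {
  cat(sprintf("Poisson regression sample: n = %d, p = %d predictors\n",
              x$n, x$p))
  cat("  predictors:", paste(x$predictor_names[-1], collapse = ", "), "\n")
  cat(sprintf("  response: counts in [%d, %d], mean %.3f\n",
              min(x$y), max(x$y), mean(x$y)))
  invisible(x)
}
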