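#' Load a count-data regression dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row, validates the response column as
#' non-negative integer counts, and returns a [poisson_sample()] with the
#' intercept column prepended.
#'
#' @param path File path.
#' @param response Name of the count response column.
#' @param predictors Character vector of predictor column names, in the order
#'   coefficients should be reported; defaults to every other numeric column
#'   in file order.
#' @param delimiter Field delimiter, `","` or `"\t"`.
#' @return A [poisson_sample()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' generate_fixture(30, 3, 0.9, intercept = 0.5, seed = 1, path = f)
#' s <- load_dataset(f, response = "y")
#' s$n
#' @export
load_dataset <- function(path, response, predictors = NULL, delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE)
  if (!response %in% names(df)) {
    stop(sprintf("response column '%s' not found", response), call. = FALSE)
  }
  if (is.null(predictors)) predictors <- setdiff(names(df), response)
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols)) {
    stop(sprintf("predictor column(s) not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (response %in% predictors) {
    stop("response column cannot also be a predictor", call. = FALSE)
  }
  y <- df[[response]]
  if (any(is.na(y)) || any(vapply(df[predictors], anyNA, logical(1)))) {
    stop("dataset contains missing values", call. = FALSE)
  }
  poisson_sample(as.matrix(df[predictors]), y, predictor_names = predictors)
}

#' Collinearity diagnostics for a count-data design
#'
#' Reports the eigenvalue spectrum of the predictor cross-product X'X
#' (intercept column excluded), the condition number on two conventions —
#' the square-root index `sqrt(lambda_max / lambda_min)` and the raw ratio
#' `lambda_max / lambda_min` — and for reference the same ratio for the
#' weighted cross-product X'LX when a fit is supplied. The multicollinearity
#' flag is raised when either convention exceeds the threshold — in practice
#' the raw ratio, the more sensitive of the two readings — so that moderate
#' as well as severe collinearity is surfaced.
#'
#' @param sample A [poisson_sample()].
#' @param threshold Flagging cutoff on the square-root index scale
#'   (default 30, the conventional rule of thumb); the raw ratio is compared
#'   against the same value directly as well, which is the more sensitive of
#'   the two readings.
#' @param fit Optional [fit_poisson_mle()] result; adds the weighted-matrix
#'   spectrum to the report.
#' @return An object of class `diagnostics_report` with `eigenvalues`
#'   (descending), `condition_number` (square-root convention),
#'   `condition_ratio`, `weighted_condition_ratio` (or `NA`), `flagged`, and
#'   `exact_collinearity` when the smallest eigenvalue is numerically zero.
#' @examples
#' set.seed(1)
#' s <- poisson_sample(generate_design(100, 3, 0.99, 1), rpois(100, 2))
#' collinearity_diagnostics(s)
#' @export
collinearity_diagnostics <- function(sample, threshold = 30, fit = NULL) {
  stopifnot(inherits(sample, "poisson_sample"))
  Xp <- sample$X[, -1, drop = FALSE]
  ev <- sort(eigen(crossprod(Xp), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  tiny <- max(ev) * 1e-12  # numerically-zero cutoff, forgiving of eigen noise
  exact <- min(ev) <= tiny
  if (exact) {
    ratio <- Inf
    cn <- Inf
  } else {
    ratio <- max(ev) / min(ev)
    cn <- sqrt(ratio)
  }
  wratio <- NA_real_
  if (!is.null(fit)) {
    evw <- eigen(crossprod(sample$X * sqrt(fit$weight_diag)),
                 symmetric = TRUE, only.values = TRUE)$values
    wratio <- max(evw) / max(min(evw), .Machine$double.xmin)
  }
  structure(
    list(eigenvalues = ev,
         condition_number = cn,
         condition_ratio = ratio,
         weighted_condition_ratio = wratio,
         threshold = threshold,
         flagged = exact || cn > threshold || ratio > threshold,
         exact_collinearity = exact),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Collinearity diagnostics (predictor block X'X)\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 6), collapse = ", "), "\n")
  if (x$exact_collinearity) {
    cat("  EXACT collinearity: smallest eigenvalue is numerically zero\n")
  } else {
    cat(sprintf("  condition number (sqrt convention): %.4f\n",
                x$condition_number))
    cat(sprintf("  eigenvalue ratio: %.4f\n", x$condition_ratio))
  }
  if (!is.na(x$weighted_condition_ratio)) {
    cat(sprintf("  weighted X'LX eigenvalue ratio: %.4f\n",
                x$weighted_condition_ratio))
  }
  cat(sprintf("  multicollinearity flag (threshold %g): %s\n",
              x$threshold, x$flagged))
  invisible(x)
}

#' Pearson chi-square goodness of fit for a Poisson fit
#'
#' `sum((y - mu)^2 / mu)` referred to the upper tail of the chi-square
#' distribution with `n - (p + 1)` degrees of freedom; a small p-value
#' signals lack of fit (often overdispersion).
#'
#' @param fit A converged [fit_poisson_mle()] result.
#' @param sample The [poisson_sample()] it came from.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
pearson_gof <- function(fit, sample) {
  stopifnot(inherits(fit, "iwls_fit"), inherits(sample, "poisson_sample"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  stat <- sum((sample$y - fit$mu_hat)^2 / fit$mu_hat)
  df <- as.integer(sample$n - sample$p - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Write a synthetic collinear count-data fixture to CSV
#'
#' Generates a dataset from the package's own simulation design (collinear
#' normal predictors, log-linear Poisson response with equal slopes summing
#' to unit squared norm) and writes it as a header-row CSV with columns
#' `y, x1, ..., xp`. Deterministic given the seed, so fixtures can be
#' regenerated instead of stored.
#'
#' @param n,p,rho,intercept,seed Simulation settings; see
#'   [generate_design()] and [make_coefficients()].
#' @param path Output CSV path.
#' @return Invisibly, a list describing the written file (`path`,
#'   `response`, `predictors`, `beta_true`, `seed`).
#' @export
generate_fixture <- function(n, p, rho, intercept = 1, seed = 1, path) {
  X <- generate_design(n, p, rho, seed)
  beta <- make_coefficients(p, intercept)
  y <- simulate_response(cbind(1, X), beta, seed + 1)
  df <- data.frame(y = y, X)
  names(df) <- c("y", paste0("x", seq_len(p)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(list(path = path, response = "y",
                 predictors = paste0("x", seq_len(p)),
                 beta_true = beta, seed = seed))
}

#' Load the aircraft damage dataset from a user-supplied CSV
#'
#' The classical aircraft damage data (30 strike missions of two naval
#' aircraft; response is the number of damaged locations, predictors are
#' aircraft type, bomb load in tons and months of aircrew experience) is a
#' standard collinear count-data benchmark. It is a textbook dataset and is
#' not bundled; supply it as a CSV with columns `y, x1, x2, x3`.
#'
#' @param path Path to the CSV.
#' @return A [poisson_sample()].
#' @export
load_aircraft_data <- function(path) {
  load_dataset(path, response = "y", predictors = c("x1", "x2", "x3"))
}
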