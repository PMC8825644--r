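#' Generate a collinear predictor matrix
#'
#' Draws `n x p` predictors from the shared-latent-factor construction
#' `x_ij = sqrt(1 - rho^2) z_ij + rho z_{i,p+1}` with all `z` independent
#' standard normal. Every column has unit variance and every pair of columns
#' has population correlation `rho^2`, so `rho` close to 1 produces the
#' near-singular designs the shrinkage estimators are built for. The induced
#' pairwise correlation being `rho^2` (not `rho`) is a property of this
#' classical construction and is deliberately left as is.
#'
#' @param n Number of rows.
#' @param p Number of predictors.
#' @param rho Collinearity level in `[0, 1)`.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return An `n x p` numeric matrix.
#' @examples
#' X <- generate_design(100, 4, 0.95, seed = 1)
#' cor(X)[1, 2]
#' @export
generate_design <- function(n, p, rho, seed) {
  stopifnot(n >= 1, p >= 1)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * (p + 1)), n, p + 1)
  sqrt(1 - rho^2) * z[, seq_len(p), drop = FALSE] + rho * z[, p + 1]
}

#' True coefficient vector for the simulation studies
#'
#' All slopes equal with unit squared norm (`beta_j = 1/sqrt(p)`), the
#' standard normalisation that makes mean squared errors comparable across
#' `p`; the intercept is set separately since its value shifts the overall
#' count level and therefore the information in the sample.
#'
#' @param p Number of predictors.
#' @param intercept Intercept value (the studies use -1, 0 and 1).
#' @return Numeric vector of length `p + 1`, intercept first.
#' @export
make_coefficients <- function(p, intercept = 1) {
  stopifnot(p >= 1)
  c(intercept, rep(1 / sqrt(p), p))
}

#' Draw Poisson counts for a design and coefficient vector
#'
#' @param X_full Design matrix including the leading intercept column.
#' @param beta Coefficient vector, conformable with `X_full`.
#' @param seed Integer seed.
#' @return Integer vector of counts.
#' @export
simulate_response <- function(X_full, beta, seed) {
  eta <- drop(X_full %*% beta)
  if (any(eta > log(.Machine$double.xmax) - 1)) {
    stop("Poisson mean overflows; linear predictor too large", call. = FALSE)
  }
  set.seed(as.integer(seed))
  stats::rpois(length(eta), exp(eta))
}

# deterministic per-replicate seed stream, kept inside 32-bit range
replicate_seed <- function(root_seed, cell_index, r) {
  as.integer((as.numeric(root_seed) * 48271 + cell_index * 100003 + r) %%
               2147483647)
}

default_estimators <- c("MLE", "PRE", "PLE", "PKL", "PMKL1", "PMKL2", "PMKL3")

estimate_by_name <- function(name, canon) {
  switch(name,
    MLE   = drop(canon$eigenvectors %*% canon$alpha),
    PRE   = estimate_pre(canon, NULL, select_k(canon, "ridge_default"))$beta,
    PLE   = estimate_ple(canon, NULL, select_d_liu(canon))$beta,
    PKL   = estimate_pkl(canon, NULL, select_k(canon, "pkl_default"))$beta,
    PMKL1 = estimate_pmkl(canon, NULL, select_k(canon, "mkl_k1"))$beta,
    PMKL2 = estimate_pmkl(canon, NULL, select_k(canon, "mkl_k2"))$beta,
    PMKL3 = estimate_pmkl(canon, NULL, select_k(canon, "mkl_k3"))$beta,
    stop(sprintf("unknown estimator '%s'", name), call. = FALSE)
  )
}

#' Monte-Carlo mean squared error comparison of the estimators
#'
#' Runs the full simulation experiment: for every cell of the factor grid
#' (intercept, n, rho) it draws `replications` fresh designs and Poisson
#' responses, fits the model by IWLS, computes every requested estimator with
#' its default data-driven biasing parameter, and records the empirical mean
#' squared error `mean(sum((beta_hat - beta_true)^2))` over the converged
#' replicates. Both the design and the shared collinearity factor are redrawn
#' each replicate.
#'
#' @param n Vector of sample sizes.
#' @param p Number of predictors (scalar per call).
#' @param rho Vector of collinearity levels in `[0, 1)`.
#' @param intercept Vector of intercept values.
#' @param replications Replicates per cell (default 1000).
#' @param seed Root seed; per-replicate seeds are derived from it through a
#'   counter so that every cell and replicate is independently reproducible.
#' @param estimators Character subset of
#'   `c("MLE","PRE","PLE","PKL","PMKL1","PMKL2","PMKL3")`.
#' @param max_iter,tol Passed to [fit_poisson_mle()].
#' @return An object of class `mse_table`: a long-format data frame with one
#'   row per (intercept, n, rho, estimator) holding `mse`, the Monte-Carlo
#'   standard error `se`, the number of converged replicates `effective_R`
#'   and the count of dropped replicates `n_failed`. Cells where every
#'   replicate failed carry `mse = NA` and `failed = TRUE`.
#' @examples
#' tab <- run_mse_experiment(n = 50, p = 4, rho = 0.9, intercept = 1,
#'                           replications = 20, seed = 1)
#' tab
#' @export
run_mse_experiment <- function(n, p, rho, intercept = 1,
                               replications = 1000L, seed = 1L,
                               estimators = default_estimators,
                               max_iter = 100L, tol = 1e-8) {
  stopifnot(all(n > p + 1), all(rho >= 0 & rho < 1), replications >= 1)
  estimators <- match.arg(estimators, default_estimators, several.ok = TRUE)
  grid <- expand.grid(intercept = intercept, n = n, rho = rho,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * length(estimators))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    gi <- grid$intercept[g]; gn <- grid$n[g]; gr <- grid$rho[g]
    beta_true <- make_coefficients(p, gi)
    sq_err <- matrix(NA_real_, replications, length(estimators),
                     dimnames = list(NULL, estimators))
    failed <- 0L
    for (r in seq_len(replications)) {
      s1 <- replicate_seed(seed, g, 2L * r)
      s2 <- replicate_seed(seed, g, 2L * r + 1L)
      X <- generate_design(gn, p, gr, s1)
      Xf <- cbind(1, X)
      y <- simulate_response(Xf, beta_true, s2)
      smp <- tryCatch(poisson_sample(Xf, y), error = function(e) NULL)
      fit <- if (is.null(smp)) NULL else
        tryCatch(fit_poisson_mle(smp, max_iter = max_iter, tol = tol),
                 error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
      canon <- tryCatch(canonical_decompose(fit, smp),
                        error = function(e) NULL)
      if (is.null(canon)) { failed <- failed + 1L; next }
      for (e in estimators) {
        bh <- tryCatch(suppressWarnings(estimate_by_name(e, canon)),
                       error = function(err) NULL)
        if (!is.null(bh)) sq_err[r, e] <- sum((bh - beta_true)^2)
      }
    }
    for (e in estimators) {
      v <- sq_err[, e]
      v <- v[is.finite(v)]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        intercept = gi, n = gn, rho = gr, estimator = e,
        mse = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        effective_R = length(v),
        n_failed = replications - length(v),
        failed = length(v) == 0L
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "p") <- p
  attr(out, "replications") <- replications
  attr(out, "seed") <- seed
  class(out) <- c("mse_table", "data.frame")
  out
}

#' Write an MSE table to CSV
#'
#' @param table An [run_mse_experiment()] result.
#' @param path Output file.
#' @param wide If `TRUE`, pivot to one row per (intercept, n, rho) with one
#'   column per estimator in the order MLE, PRE, PLE, PKL, PMKL1, PMKL2,
#'   PMKL3 — the layout used in published comparison tables.
#' @return `path`, invisibly.
#' @export
write_mse_table <- function(table, path, wide = FALSE) {
  stopifnot(inherits(table, "mse_table"))
  out <- if (wide) mse_table_wide(table) else as.data.frame(table)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pivot an MSE table to the published wide layout
#' @param table An [run_mse_experiment()] result.
#' @return A data frame, one row per factor cell, estimators as columns.
#' @export
mse_table_wide <- function(table) {
  keys <- unique(table[, c("intercept", "n", "rho")])
  ests <- intersect(default_estimators, unique(table$estimator))
  out <- keys
  for (e in ests) {
    sub <- table[table$estimator == e, ]
    out[[e]] <- sub$mse[match(
      paste(keys$intercept, keys$n, keys$rho),
      paste(sub$intercept, sub$n, sub$rho))]
  }
  rownames(out) <- NULL
  out
}
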