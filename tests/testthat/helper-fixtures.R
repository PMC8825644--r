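# Shared fixtures: all data is generated in code, nothing is stored on disk.

# a small collinear count-data sample with known generating coefficients
make_test_sample <- function(n = 60, p = 3, rho = 0.9, intercept = 0.5,
                             seed = 101) {
  X <- generate_design(n, p, rho, seed)
  beta <- make_coefficients(p, intercept)
  y <- simulate_response(cbind(1, X), beta, seed + 1)
  list(sample = poisson_sample(cbind(1, X), y), beta_true = beta)
}

# random canonical instance for MSE-theory oracles
random_canon <- function(m = sample(2:8, 1)) {
  canonical_form(eigenvalues = sort(exp(stats::runif(m, -2, 3)),
                                    decreasing = TRUE),
                 alpha = stats::rnorm(m))
}

# Independent dense-matrix oracle for the matrix mean squared error of an
# estimator, built from the matrix definitions (resolvent products), not
# from the package's canonical shrinkage factors.
brute_msem <- function(kind, canon, param, sigma2 = 1) {
  L <- diag(canon$eigenvalues, nrow = length(canon$eigenvalues))
  I <- diag(nrow(L))
  Fm <- switch(kind,
    MLE  = I,
    PRE  = solve(L + param * I) %*% L,
    PLE  = solve(L + I) %*% (L + param * I),
    PKL  = solve(L + param * I) %*% (L - param * I),
    PMKL = solve(L + param * I) %*% (L - param * I) %*%
           solve(L + param * I) %*% L
  )
  V <- sigma2 * Fm %*% solve(L) %*% t(Fm)
  b <- (Fm - I) %*% canon$alpha
  V + b %*% t(b)
}
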