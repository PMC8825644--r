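test_that("diagonal-case estimators reduce to scalar shrinkage factors", {
  # ridge: lambda/(lambda+k) with X'LX = diag(2, 4), beta = (1, 1), k = 2
  cf <- canonical_form(c(2, 4), c(1, 1))
  pre <- estimate_pre(cf, NULL, k = 2)
  expect_equal(sort(pre$beta), sort(c(2 / 4, 4 / 6)), tolerance = 1e-12)
  # Liu: (lambda+d)/(lambda+1) with lambda = 1, d = 0 -> 0.5
  ple <- estimate_ple(canonical_form(1, 1), NULL, d = 0)
  expect_equal(ple$beta, 0.5, tolerance = 1e-12)
  # KL: (lambda-k)/(lambda+k) with lambda = 3, k = 1 -> 0.5
  pkl <- estimate_pkl(canonical_form(3, 1), NULL, k = 1)
  expect_equal(pkl$beta, 0.5, tolerance = 1e-12)
  # modified KL: lambda(lambda-k)/(lambda+k)^2 = 3*2/16 = 0.375
  pmkl <- estimate_pmkl(canonical_form(3, 1), NULL, k = 1)
  expect_equal(pmkl$beta, 0.375, tolerance = 1e-12)
})

test_that("estimators agree with their dense matrix definitions on a fit", {
  tc <- make_test_sample(n = 80, p = 4, rho = 0.95, seed = 81)
  fit <- fit_poisson_mle(tc$sample)
  cf <- canonical_decompose(fit, tc$sample)
  S <- crossprod(tc$sample$X * sqrt(fit$weight_diag))
  I <- diag(nrow(S))
  b <- fit$beta_hat
  k <- 0.7; d <- 0.4
  expect_equal(estimate_pre(cf, NULL, k)$beta,
               unname(drop(solve(S + k * I) %*% S %*% b)), tolerance = 1e-9)
  expect_equal(estimate_ple(cf, NULL, d)$beta,
               unname(drop(solve(S + I) %*% (S + d * I) %*% b)),
               tolerance = 1e-9)
  expect_equal(estimate_pkl(cf, NULL, k)$beta,
               unname(drop(solve(S + k * I) %*% (S - k * I) %*% b)),
               tolerance = 1e-9)
  expect_equal(estimate_pmkl(cf, NULL, k)$beta,
               unname(drop(solve(S + k * I) %*% (S - k * I) %*%
                           solve(S + k * I) %*% S %*% b)),
               tolerance = 1e-9)
  # every estimate satisfies beta = Q alpha
  for (est in list(estimate_pre(cf, NULL, k), estimate_ple(cf, NULL, d),
                   estimate_pkl(cf, NULL, k), estimate_pmkl(cf, NULL, k))) {
    expect_lt(max(abs(est$beta - drop(cf$eigenvectors %*% est$alpha))), 1e-12)
  }
})

test_that("limit identities recover the MLE", {
  for (seed in c(91, 92)) {
    tc <- make_test_sample(n = 70, p = 3, rho = 0.9, seed = seed)
    fit <- fit_poisson_mle(tc$sample)
    cf <- canonical_decompose(fit, tc$sample)
    b <- unname(fit$beta_hat)
    expect_equal(estimate_pre(cf, NULL, 1e-12)$beta, b, tolerance = 1e-8)
    expect_equal(estimate_pkl(cf, NULL, 1e-12)$beta, b, tolerance = 1e-8)
    expect_equal(estimate_pmkl(cf, NULL, 1e-12)$beta, b, tolerance = 1e-8)
    expect_equal(estimate_ple(cf, NULL, 1)$beta, b, tolerance = 1e-12)
  }
})

test_that("shrinkage factors are ordered |PMKL| <= |PKL| <= PRE for 0 < k < lambda", {
  set.seed(101)
  for (i in 1:200) {
    lambda <- exp(runif(1, -2, 3))
    k <- runif(1) * lambda
    f_pre <- lambda / (lambda + k)
    f_pkl <- (lambda - k) / (lambda + k)
    f_pmkl <- lambda * (lambda - k) / (lambda + k)^2
    expect_lte(abs(f_pmkl), abs(f_pkl) + 1e-15)
    expect_lte(abs(f_pkl), f_pre + 1e-15)
  }
})

test_that("parameter domain errors are raised", {
  cf <- canonical_form(c(2, 1), c(1, 1))
  expect_error(estimate_pre(cf, NULL, 0), "positive")
  expect_error(estimate_pkl(cf, NULL, -1), "positive")
  expect_error(estimate_pmkl(cf, NULL, 0), "positive")
  expect_error(estimate_ple(cf, NULL, 1.2), "\\[0, 1\\]")
  expect_error(estimate_ple(cf, NULL, -0.1), "\\[0, 1\\]")
})

test_that("Liu selector follows the clamped minimum rule", {
  # all alpha^2 < 1: inner minimum negative, clamped to 0
  expect_equal(select_d_liu(canonical_form(c(3, 2), c(0.5, -0.3))), 0)
  # single component: (4 - 1)/(4 + 1/2) = 2/3
  expect_equal(select_d_liu(canonical_form(2, 2)), 2 / 3, tolerance = 1e-12)
  # never outside [0, 1]
  set.seed(111)
  for (i in 1:50) {
    d <- select_d_liu(random_canon())
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("k selectors match their hand-computed forms", {
  cf <- canonical_form(c(4, 2, 1), c(1, -1, 1))
  expect_equal(select_k(cf, "ridge_default"), 1)
  expect_equal(select_k(cf, "mkl_k1"), 1)
  # pkl_default: min over 1/(2*1 + 1/lambda)
  expect_equal(select_k(cf, "pkl_default"),
               min(1 / (2 + 1 / c(4, 2, 1))), tolerance = 1e-12)
  expect_equal(select_k(cf, "pkl_default", alt_reading = TRUE),
               min(1 / (2 + 1 / c(4, 2, 1))), tolerance = 1e-12)
  # k2: m / sum(2 alpha^2 + 1/lambda)
  expect_equal(select_k(cf, "mkl_k2"),
               3 / sum(2 + 1 / c(4, 2, 1)), tolerance = 1e-12)
  # the two pkl readings differ once alpha varies
  cf2 <- canonical_form(c(4, 2), c(2, 0.5))
  expect_false(isTRUE(all.equal(select_k(cf2, "pkl_default"),
                                select_k(cf2, "pkl_default",
                                         alt_reading = TRUE))))
})

test_that("k3 roots satisfy the stationarity condition and match a grid search", {
  set.seed(121)
  for (i in 1:20) {
    cf <- random_canon()
    k3 <- select_k(cf, "mkl_k3")
    lambda <- cf$eigenvalues
    a2 <- cf$alpha^2
    # per-component roots: residual of beta2*k*(3l+k) = (l-k) below 1e-8
    roots <- vapply(seq_along(lambda), function(j) {
      r <- pmkl:::mkl_k3_component(lambda[j], a2[j])
      if (a2[j] > 1e-12) {
        expect_lt(abs(a2[j] * r * (3 * lambda[j] + r) - (lambda[j] - r)),
                  1e-8)
        # closed-form quadratic root agrees
        expect_equal(r, pmkl:::mkl_k3_closed_form(lambda[j], a2[j]),
                     tolerance = 1e-9)
      }
      r
    }, numeric(1))
    expect_equal(k3, min(roots), tolerance = 1e-12)
    # the selected component's root minimises its per-component MSE
    j <- which.min(roots)
    mse_j <- function(k) {
      lambda[j] * (lambda[j] - k)^2 / (lambda[j] + k)^4 +
        k^2 * (3 * lambda[j] + k)^2 * a2[j] / (lambda[j] + k)^4
    }
    grid <- seq(1e-4, lambda[j], length.out = 4000)
    expect_lt(abs(grid[which.min(mse_j(grid))] - roots[j]),
              2 * lambda[j] / 4000)
  }
})

test_that("selectors are finite and positive on fitted fixtures", {
  for (seed in c(131, 132, 133)) {
    tc <- make_test_sample(n = 60, p = 4, rho = 0.95, seed = seed)
    fit <- fit_poisson_mle(tc$sample)
    cf <- canonical_decompose(fit, tc$sample)
    for (rule in c("ridge_default", "pkl_default", "mkl_k1", "mkl_k2",
                   "mkl_k3")) {
      k <- select_k(cf, rule)
      expect_true(is.finite(k))
      expect_gt(k, 0)
    }
    expect_true(is.finite(select_d_liu(cf)))
  }
})

test_that("degenerate selector inputs are handled explicitly", {
  expect_error(select_k(canonical_form(c(2, 1), c(0, 0)), "mkl_k1"), "zero")
})

test_that("fit_all_estimators returns one labelled row per estimator", {
  tc <- make_test_sample(n = 60, p = 3, rho = 0.9, seed = 141)
  res <- fit_all_estimators(tc$sample)
  tab <- res$table
  expect_identical(tab$estimator,
                   c("MLE", "PRE", "PLE", "PKL", "PMKL1", "PMKL2", "PMKL3"))
  expect_true(all(c("(Intercept)", "param", "rule", "scalar_mse") %in%
                  names(tab)))
  expect_true(all(tab$scalar_mse > 0))
  # every shrinkage estimator has smaller theoretical MSE than the MLE here
  expect_true(all(tab$scalar_mse[-1] <= tab$scalar_mse[1] + 1e-12))
  # PMKL1 and PRE share k1; PKL and PMKL3 use their own rules
  expect_equal(tab$param[tab$estimator == "PRE"],
               tab$param[tab$estimator == "PMKL1"])
})
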