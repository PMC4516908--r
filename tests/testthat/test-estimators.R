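test_that("ratio estimate is Y/X with first-order standard error", {
  f <- mr_ratio(0.5, 0.1, 0.1, 0.05)
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, 0.1)
  expect_equal(unname(f$ci), 0.2 + c(-1, 1) * qnorm(0.975) * 0.1)

  expect_equal(mr_ratio(1, 0.1, 0, 0.05)$beta, 0)
  fneg <- mr_ratio(-0.5, 0.1, 0.1, 0.05)
  expect_equal(fneg$beta, -0.2)
  expect_equal(fneg$se, 0.1)
  expect_error(mr_ratio(0, 0.1, 0.1, 0.05), "zero")
})

test_that("IVW reduces to the ratio estimate at K = 1 and averages equal-weight ratios", {
  d1 <- mr_summary_data("rs1", 2, 0.1, 0.4, 0.1)
  f1 <- mr_ivw(d1)
  r1 <- mr_ratio(2, 0.1, 0.4, 0.1)
  expect_equal(f1$beta, r1$beta, tolerance = 1e-14)
  expect_equal(f1$se, r1$se, tolerance = 1e-14)
  expect_equal(f1$beta, 0.2)
  expect_equal(f1$se, 0.05)

  d2 <- mr_summary_data(c("a", "b"), c(1, 1), c(0.1, 0.1),
                        c(0.3, 0.1), c(0.1, 0.1))
  expect_equal(mr_ivw(d2)$beta, 0.2)
})

test_that("IVW equals zero-intercept weighted least squares on random instances", {
  set.seed(101)
  for (i in 1:200) {
    K <- sample(2:15, 1)
    d <- rand_summary(K, beta = runif(1, -0.5, 0.5),
                      sigma_x = runif(1, 0.005, 0.05),
                      sigma_y = runif(1, 0.002, 0.02))
    oracle <- unname(coef(lm(beta_outcome ~ 0 + beta_exposure, data = d,
                             weights = 1 / d$se_outcome^2)))
    expect_equal(mr_ivw(d)$beta, oracle, tolerance = 1e-10)
  }
})

test_that("IVW is invariant to recoding the effect allele of any variant", {
  d <- rand_summary(8, seed = 5)
  b0 <- mr_ivw(d)$beta
  for (k in c(1, 4, 8)) {
    d2 <- d
    d2$beta_exposure[k] <- -d2$beta_exposure[k]
    d2$beta_outcome[k] <- -d2$beta_outcome[k]
    expect_equal(mr_ivw(d2)$beta, b0, tolerance = 1e-14)
  }
})

test_that("the log-likelihood factorizes into univariate densities when independent", {
  # K = 1 at the exact-fit parameters: both residuals vanish
  d1 <- mr_summary_data("rs1", 0.5, 0.1, 0.1, 0.05)
  ll <- mr_loglik(d1, beta = 0.1 / 0.5, xi = 0.5)
  expect_equal(ll, dnorm(0.5, 0.5, 0.1, log = TRUE) +
                 dnorm(0.1, 0.1, 0.05, log = TRUE), tolerance = 1e-12)

  d <- rand_summary(6, seed = 3)
  xi <- d$beta_exposure * 0.9
  ll_simple <- mr_loglik(d, 0.25, xi)
  ll_uni <- sum(dnorm(d$beta_exposure, xi, d$se_exposure, log = TRUE)) +
    sum(dnorm(d$beta_outcome, 0.25 * xi, d$se_outcome, log = TRUE))
  expect_equal(ll_simple, ll_uni, tolerance = 1e-10)

  # the correlated path with an identity matrix is the same function
  ll_id <- mr_loglik(d, 0.25, xi, corr = mr_ld_matrix(diag(6)))
  expect_equal(ll_id, ll_simple, tolerance = 1e-10)
})

test_that("the log-likelihood matches a generic multivariate-normal oracle", {
  set.seed(202)
  for (i in 1:20) {
    K <- sample(2:5, 1)
    theta <- runif(1, -0.6, 0.6)
    rho <- rand_corr(K)
    d <- rand_summary(K)
    xi <- rnorm(K, d$beta_exposure, 0.01)
    beta <- runif(1, -0.5, 0.5)
    S <- cov_oracle(d$se_exposure, d$se_outcome, unclass(rho), theta)
    oracle <- mvn_logdens_oracle(c(d$beta_exposure, d$beta_outcome),
                                 c(xi, beta * xi), S)
    expect_equal(mr_loglik(d, beta, xi, corr = rho, theta = theta),
                 oracle, tolerance = 1e-8)
  }
  # singular covariance is reported, not silently inverted
  dd <- rand_summary(2, seed = 9)
  expect_error(mr_loglik(dd, 0.2, dd$beta_exposure,
                         corr = structure(matrix(c(1, 1, 1, 1), 2),
                                          class = c("mr_ld_matrix", "matrix", "array"))),
               "singular|indefinite")
})

test_that("ML recovers the exact-fit slope and matches IVW when exposure error is negligible", {
  d <- mr_summary_data(paste0("v", 1:5), c(0.2, 0.4, 0.6, 0.8, 1.0),
                       rep(0.05, 5), 0.3 * c(0.2, 0.4, 0.6, 0.8, 1.0),
                       rep(0.01, 5))
  f <- mr_ml(d)
  expect_equal(f$beta, 0.3, tolerance = 1e-6)
  expect_true(f$diagnostics$convergence)
  expect_true(f$ci[1] <= f$beta && f$beta <= f$ci[2])

  set.seed(303)
  for (i in 1:50) {
    K <- sample(2:12, 1)
    d <- rand_summary(K, beta = runif(1, -0.5, 0.5),
                      sigma_x = 1e-6 * 0.005, sigma_y = 0.005)
    ivw <- mr_ivw(d)$beta
    expect_equal(mr_ml(d)$beta, ivw, tolerance = 1e-3)
  }
})

test_that("ML matches an independent full-parameter maximization at K = 2", {
  set.seed(404)
  for (i in 1:5) {
    d <- rand_summary(2, sigma_x = 0.03, sigma_y = 0.01)
    # independent oracle: maximize over (beta, xi1, xi2) with Nelder-Mead
    nll <- function(p) {
      -(sum(dnorm(d$beta_exposure, p[2:3], d$se_exposure, log = TRUE)) +
          sum(dnorm(d$beta_outcome, p[1] * p[2:3], d$se_outcome, log = TRUE)))
    }
    o <- optim(c(0, d$beta_exposure), nll, control = list(maxit = 5000,
                                                          reltol = 1e-14))
    expect_equal(mr_ml(d)$beta, o$par[1], tolerance = 1e-4)
  }
})

test_that("ML with an LD matrix widens intervals relative to naive IVW on correlated data", {
  # positively correlated variants: IVW treats them as independent
  # replicates and overstates precision
  K <- 6
  rho <- mr_ld_matrix(0.6 + 0.4 * diag(K))
  d <- mr_simulate_summary(K = K, rho = rho, seed = 77)
  ivw <- mr_ivw(d)
  ml_corr <- mr_ml(d, corr = rho)
  expect_lt(ivw$se, ml_corr$se)
  expect_lt(diff(unname(ivw$ci)), diff(unname(ml_corr$ci)))
})

test_that("the overlap sensitivity scan is ordered, finite and continuous in theta", {
  d <- rand_summary(6, seed = 15)
  s0 <- mr_theta_scan(d, 0)
  f0 <- mr_ml(d, theta = 0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$beta, f0$beta, tolerance = 1e-10)

  s <- mr_theta_scan(d, c(0.2, -0.2, 0))
  expect_equal(s$theta, c(-0.2, 0, 0.2))
  expect_true(all(is.finite(s$beta)))

  grid <- seq(-0.2, 0.2, by = 0.01)
  sg <- mr_theta_scan(d, grid)
  jumps <- abs(diff(sg$beta))
  expect_lt(max(jumps), 20 * stats::median(jumps) + 1e-8)

  expect_error(mr_theta_scan(d, c(0, 1.2)), "\\(-1, 1\\)")
})
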