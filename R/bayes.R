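# Bayesian fit of the summarized-data likelihood. The model is
# conditionally Gaussian in beta given xi and in xi given beta (the
# 2K-normal likelihood has mean A(beta) xi with A = [I; beta I] and a
# fixed covariance), so with normal priors a Gibbs sampler draws from
# the exact full conditionals -- no tuning, no rejections.

.split_rhat <- function(draws) {
  # draws: iterations x chains; split each chain in half
  n <- nrow(draws); m <- ncol(draws)
  half <- floor(n / 2)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1):n, , drop = FALSE])
  means <- colMeans(segs)
  vars <- apply(segs, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

.ess_bulk <- function(draws) {
  # crude combined-chain ESS from chain-averaged autocorrelations
  n <- nrow(draws); m <- ncol(draws)
  centred <- sweep(draws, 2, colMeans(draws))
  max_lag <- min(n - 1, 200)
  rho <- sapply(seq_len(m), function(j) {
    a <- stats::acf(centred[, j], lag.max = max_lag, plot = FALSE,
                    demean = FALSE)$acf[-1]
    a
  })
  rho_bar <- rowMeans(rho)
  s <- 0
  for (l in seq_along(rho_bar)) {
    if (rho_bar[l] < 0) break
    s <- s + rho_bar[l]
  }
  m * n / (1 + 2 * s)
}

#' Bayesian likelihood-based causal estimate
#'
#' Fits the same measurement-error model as [mr_ml()] in a Bayesian
#' framework with vague normal priors, beta ~ N(0, `prior_sd_beta`^2)
#' and xi_k ~ N(0, `prior_sd_xi`^2), using a Gibbs sampler that
#' alternates the exact Gaussian full conditionals of beta and of the
#' nuisance means xi. Supports correlated variants (LD matrix) and
#' overlapping samples (theta), like the likelihood surface itself.
#'
#' The point estimate is the posterior median (the mean is reported in
#' the diagnostics); the interval is the equal-tailed 95\% credible
#' interval. Convergence is monitored by the split-chain potential
#' scale reduction factor: a warning is issued above 1.05 and an error
#' above 1.1 (set `check_convergence = FALSE` to downgrade the error
#' to a warning).
#'
#' @inheritParams mr_ml
#' @param prior_sd_beta,prior_sd_xi prior standard deviations of the
#'   causal effect and of the nuisance means (defaults 100: vague on
#'   the per-allele association scale).
#' @param chains number of independent chains (default 4).
#' @param iter iterations per chain including warmup (default 5000).
#' @param warmup discarded initial iterations per chain (default 1000).
#' @param seed integer seed; required, so that credible intervals are
#'   reproducible.
#' @param check_convergence error (rather than warn) when the split
#'   R-hat of beta is 1.1 or more.
#' @return An object of class `mr_fit` with `se = NA` (the posterior
#'   sd is in `diagnostics$post_sd`) and diagnostics `rhat`, `ess`,
#'   `post_mean`, `post_sd`, `chains`, `iter`, `warmup`.
#' @export
mr_bayes <- function(data, corr = NULL, theta = 0,
                     prior_sd_beta = 100, prior_sd_xi = 100,
                     chains = 4, iter = 5000, warmup = 1000,
                     seed, check_convergence = TRUE) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (missing(seed)) stop("'seed' is required for reproducible sampling")
  if (iter - warmup < 1000)
    stop("at least 1000 post-warmup iterations per chain are required")
  K <- n_variants(data)
  z <- c(data$beta_exposure, data$beta_outcome)
  S <- .mr_covariance(data, corr, theta)
  ch <- .chol_or_fail(S)
  Omega <- chol2inv(ch)
  O11 <- Omega[seq_len(K), seq_len(K), drop = FALSE]
  O12 <- Omega[seq_len(K), K + seq_len(K), drop = FALSE]
  O22 <- Omega[K + seq_len(K), K + seq_len(K), drop = FALSE]
  zx <- z[seq_len(K)]; zy <- z[K + seq_len(K)]

  set.seed(as.integer(seed))
  keep <- iter - warmup
  beta_draws <- matrix(NA_real_, keep, chains)
  init_beta <- tryCatch(mr_ivw(data)$beta, error = function(e) 0)
  init_scale <- tryCatch(mr_ivw(data)$se, error = function(e) 1)

  for (c_i in seq_len(chains)) {
    beta <- init_beta + stats::rnorm(1, 0, 2 * init_scale)  # overdispersed
    xi <- zx + stats::rnorm(K, 0, data$se_exposure)
    for (it in seq_len(iter)) {
      # xi | beta: N(P^{-1} A'Omega z, P^{-1}),  P = A'Omega A + I/sd_xi^2
      P <- O11 + beta * (O12 + t(O12)) + beta^2 * O22 +
        diag(1 / prior_sd_xi^2, K)
      b <- drop((O11 + beta * t(O12)) %*% zx + (O12 + beta * O22) %*% zy)
      Pch <- chol(P)
      mu <- backsolve(Pch, backsolve(Pch, b, transpose = TRUE))
      xi <- mu + backsolve(Pch, stats::rnorm(K))
      # beta | xi: mean of z is c + beta d with c = (xi, 0), d = (0, xi)
      dOd <- drop(crossprod(xi, O22 %*% xi))
      dOr <- drop(crossprod(xi, t(O12) %*% (zx - xi) + O22 %*% zy))
      prec <- dOd + 1 / prior_sd_beta^2
      beta <- stats::rnorm(1, dOr / prec, sqrt(1 / prec))
      if (it > warmup) beta_draws[it - warmup, c_i] <- beta
    }
  }

  rhat <- .split_rhat(beta_draws)
  ess <- .ess_bulk(beta_draws)
  if (rhat >= 1.1) {
    msg <- paste0("MCMC did not converge: split R-hat = ",
                  format(rhat, digits = 4))
    if (check_convergence) stop(msg) else warning(msg, call. = FALSE)
  } else if (rhat >= 1.05) {
    warning("split R-hat = ", format(rhat, digits = 4),
            " exceeds 1.05; consider more iterations", call. = FALSE)
  }

  all_draws <- as.vector(beta_draws)
  qs <- stats::quantile(all_draws, c(0.025, 0.5, 0.975), names = FALSE)
  .new_mr_fit(qs[2], NA_real_, c(qs[1], qs[3]), "bayes", K, data = data,
              diagnostics = list(rhat = rhat, ess = ess,
                                 post_mean = mean(all_draws),
                                 post_sd = stats::sd(all_draws),
                                 chains = chains, iter = iter,
                                 warmup = warmup, theta = theta,
                                 correlated = !is.null(corr)))
}
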