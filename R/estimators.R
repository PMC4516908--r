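# Core estimators for summarized-data Mendelian randomization.
#
# Model: X_k ~ N(xi_k, sigma_Xk^2), Y_k ~ N(beta * xi_k, sigma_Yk^2).
# With correlated variants the K-vectors X and Y are multivariate normal
# with Sigma_Xij = sigma_Xi sigma_Xj rho_ij (likewise Sigma_Y), and with
# overlapping samples the joint 2K-vector (X, Y) has cross-covariance
# Sigma_XYij = theta sigma_Xi sigma_Yj rho_ij.

.new_mr_fit <- function(beta, se, ci, method, K_used, diagnostics = list(),
                        data = NULL, level = 0.95) {
  structure(list(beta = beta, se = se,
                 ci = c(lower = ci[1], upper = ci[2]),
                 level = level, method = method, K_used = as.integer(K_used),
                 diagnostics = diagnostics, data = data),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Mendelian randomization causal estimate (", x$method, ")\n", sep = "")
  cat("  variants used: ", x$K_used, "\n", sep = "")
  cat("  beta = ", format(x$beta, digits = digits),
      if (!is.na(x$se)) paste0("  (se = ", format(x$se, digits = digits), ")"),
      "\n", sep = "")
  cat("  ", format(100 * x$level), "% ",
      if (x$method == "bayes") "credible" else "confidence",
      " interval: [", format(x$ci[1], digits = digits), ", ",
      format(x$ci[2], digits = digits), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object)
  d <- object$diagnostics
  if (length(d)) {
    cat("Diagnostics:\n")
    for (nm in names(d)) {
      v <- d[[nm]]
      if (is.numeric(v) && length(v) <= 4)
        cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = ", "),
            "\n", sep = "")
      else if (is.character(v) || is.logical(v))
        cat("  ", nm, ": ", paste(v, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) c(beta = object$beta)

#' @export
confint.mr_fit <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$level)))
    stop("the interval was computed at level ", object$level,
         "; refit to change it")
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("beta", c("lower", "upper")))
  m
}

# ---- ratio and IVW ---------------------------------------------------------

#' Ratio (Wald) estimate from a single variant
#'
#' The causal effect estimate from one genetic variant is the ratio of
#' its outcome association to its exposure association,
#' \eqn{Y_k / X_k}, with the first-order standard error
#' \eqn{\sigma_{Yk} / |X_k|} (uncertainty in the denominator ignored,
#' as in the usual asymptotic approximation).
#'
#' @param beta_exposure,se_exposure association with the exposure and
#'   its standard error (\eqn{X_k}, \eqn{\sigma_{Xk}}).
#' @param beta_outcome,se_outcome association with the outcome and its
#'   standard error (\eqn{Y_k}, \eqn{\sigma_{Yk}}).
#' @return An object of class `mr_fit`.
#' @export
mr_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  stopifnot(length(beta_exposure) == 1, se_exposure > 0, se_outcome > 0)
  if (beta_exposure == 0)
    stop("ratio estimate undefined: exposure association is zero")
  beta <- beta_outcome / beta_exposure
  se <- se_outcome / abs(beta_exposure)
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  .new_mr_fit(beta, se, ci, "ratio", 1L)
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Combines per-variant ratio estimates \eqn{Y_k / X_k} with
#' inverse-variance weights, as in a fixed-effect meta-analysis:
#' \deqn{\hat\beta_{IVW} = \frac{\sum_k X_k Y_k \sigma_{Yk}^{-2}}
#'                              {\sum_k X_k^2 \sigma_{Yk}^{-2}},
#'   \quad se = \sqrt{1 / \sum_k X_k^2 \sigma_{Yk}^{-2}},}
#' equivalently the slope of the weighted regression of Y on X through
#' the origin with weights \eqn{\sigma_{Yk}^{-2}}. The method assumes
#' uncorrelated variants and precisely estimated exposure associations;
#' with correlated variants it overstates precision, and with imprecise
#' exposure associations its intervals are over-precise — use
#' [mr_ml()] in those settings.
#'
#' @param data an [mr_summary_data] object.
#' @return An object of class `mr_fit` (Wald 95\% interval).
#' @export
mr_ivw <- function(data) {
  stopifnot(inherits(data, "mr_summary_data"))
  x <- data$beta_exposure; y <- data$beta_outcome
  w <- data$se_outcome^-2
  denom <- sum(x^2 * w)
  if (denom == 0) stop("IVW undefined: all exposure associations are zero")
  beta <- sum(x * y * w) / denom
  se <- sqrt(1 / denom)
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  .new_mr_fit(beta, se, ci, "ivw", n_variants(data), data = data)
}

# ---- multivariate-normal machinery -----------------------------------------

# 2K x 2K covariance of (X, Y) given the LD correlations and overlap theta.
.mr_covariance <- function(data, corr = NULL, theta = 0) {
  K <- n_variants(data)
  sx <- data$se_exposure; sy <- data$se_outcome
  rho <- if (is.null(corr)) diag(K) else unclass(corr)[seq_len(K), seq_len(K)]
  Sx <- outer(sx, sx) * rho
  Sy <- outer(sy, sy) * rho
  Sxy <- theta * outer(sx, sy) * rho
  rbind(cbind(Sx, Sxy), cbind(t(Sxy), Sy))
}

.chol_or_fail <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    stop("covariance matrix is singular or indefinite (eigenvalue range [",
         format(min(ev)), ", ", format(max(ev)), "], condition number ",
         format(max(ev) / max(min(ev), .Machine$double.eps), digits = 3), ")")
  }
  ch
}

# log N(z; mean, S) with S given by its upper Cholesky factor
.mvn_logdens <- function(z, mean, ch) {
  r <- backsolve(ch, z - mean, transpose = TRUE)
  -0.5 * length(z) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

#' Exact log-likelihood of the summarized-data model
#'
#' Evaluates the joint multivariate-normal log density of the observed
#' association estimates (X, Y) at causal effect `beta` and per-variant
#' nuisance means `xi`: X has mean xi and covariance
#' \eqn{\Sigma_X} (\eqn{\Sigma_{Xij} = \sigma_{Xi}\sigma_{Xj}\rho_{ij}}),
#' Y has mean beta*xi and covariance \eqn{\Sigma_Y}, and the
#' cross-covariance \eqn{\theta \sigma_{Xi}\sigma_{Yj}\rho_{ij}}
#' captures exposure/outcome sample overlap. With `corr = NULL` and
#' `theta = 0` this reduces exactly to the sum of 2K univariate normal
#' log densities.
#'
#' @param data an [mr_summary_data] object.
#' @param beta causal effect parameter.
#' @param xi numeric vector of K nuisance means \eqn{\xi_k}.
#' @param corr optional `mr_ld_matrix` (identity assumed when absent).
#' @param theta correlation in (-1, 1) between the exposure and outcome
#'   association estimates induced by overlapping samples; 0 for a
#'   strict two-sample design.
#' @return The log-likelihood (a scalar).
#' @export
mr_loglik <- function(data, beta, xi, corr = NULL, theta = 0) {
  stopifnot(inherits(data, "mr_summary_data"))
  K <- n_variants(data)
  if (length(xi) != K) stop("'xi' must have length K = ", K)
  if (abs(theta) >= 1) stop("'theta' must lie in (-1, 1)")
  S <- .mr_covariance(data, corr, theta)
  ch <- .chol_or_fail(S)
  z <- c(data$beta_exposure, data$beta_outcome)
  .mvn_logdens(z, c(xi, beta * xi), ch)
}

# Profile machinery: for fixed beta the MLE of xi is a generalized
# least-squares solve; uncorrelated theta=0 case has a closed form.
.profile_xi <- function(z, beta, K, Omega = NULL, wx = NULL, wy = NULL) {
  if (is.null(Omega)) {
    x <- z[seq_len(K)]; y <- z[K + seq_len(K)]
    (wx * x + beta * wy * y) / (wx + beta^2 * wy)
  } else {
    # A = [I; beta I]; solve (A' Omega A) xi = A' Omega z
    O11 <- Omega[seq_len(K), seq_len(K), drop = FALSE]
    O12 <- Omega[seq_len(K), K + seq_len(K), drop = FALSE]
    O22 <- Omega[K + seq_len(K), K + seq_len(K), drop = FALSE]
    M <- O11 + beta * (O12 + t(O12)) + beta^2 * O22
    b <- cbind(O11 + beta * t(O12), O12 + beta * O22) %*% z
    drop(solve(M, b))
  }
}

.make_profile <- function(data, corr, theta) {
  K <- n_variants(data)
  z <- c(data$beta_exposure, data$beta_outcome)
  S <- .mr_covariance(data, corr, theta)
  ch <- .chol_or_fail(S)
  simple <- is.null(corr) && theta == 0
  Omega <- if (simple) NULL else chol2inv(ch)
  wx <- if (simple) data$se_exposure^-2 else NULL
  wy <- if (simple) data$se_outcome^-2 else NULL
  const <- -0.5 * 2 * K * log(2 * pi) - sum(log(diag(ch)))
  list(
    pl = function(beta) {
      xi <- .profile_xi(z, beta, K, Omega, wx, wy)
      if (simple) {
        r <- c((z[seq_len(K)] - xi) * sqrt(wx),
               (z[K + seq_len(K)] - beta * xi) * sqrt(wy))
        const - 0.5 * sum(r^2)
      } else {
        .mvn_logdens(z, c(xi, beta * xi), ch)
      }
    },
    xi_hat = function(beta) .profile_xi(z, beta, K, Omega, wx, wy),
    saturated = const,   # log density with zero residuals
    z = z, ch = ch
  )
}

#' Likelihood-based (maximum likelihood) causal estimate
#'
#' Fits the measurement-error model
#' \eqn{X_k \sim N(\xi_k, \sigma_{Xk}^2)},
#' \eqn{Y_k \sim N(\beta \xi_k, \sigma_{Yk}^2)} by maximizing the
#' profile log-likelihood in \eqn{\beta} (the nuisance means
#' \eqn{\xi_k} are profiled out in closed form, or by generalized least
#' squares when variants are correlated or samples overlap). Unlike
#' IVW, the likelihood-based estimator accounts for uncertainty in the
#' exposure associations and, given an LD matrix, for correlation
#' between variants.
#'
#' The primary 95\% interval inverts the profile likelihood (drop of
#' qchisq(0.95, 1)/2 = 1.92 from the maximum); a Wald interval from
#' the numerical curvature at the maximum is recorded in
#' `diagnostics$se_wald` and used as a fallback if the inversion fails
#' to bracket (`diagnostics$ci_method` records which was used).
#'
#' @inheritParams mr_loglik
#' @param level interval level (default 0.95).
#' @return An object of class `mr_fit` with `diagnostics` including
#'   `loglik` (maximized value), `convergence`, `se_wald`, `ci_method`
#'   and the profiled `xi` at the optimum.
#' @export
mr_ml <- function(data, corr = NULL, theta = 0, level = 0.95) {
  stopifnot(inherits(data, "mr_summary_data"))
  if (abs(theta) >= 1) stop("'theta' must lie in (-1, 1)")
  prof <- .make_profile(data, corr, theta)

  init <- tryCatch(mr_ivw(data)$beta, error = function(e) 0)
  step0 <- max(10 * tryCatch(mr_ivw(data)$se, error = function(e) 1), 1e-3)

  # expand the bracket until the maximum is interior
  lo <- init - step0; hi <- init + step0
  opt <- NULL
  for (attempt in 1:8) {
    opt <- stats::optimize(prof$pl, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    interior <- (opt$maximum - lo) > 1e-6 * (hi - lo) &&
                (hi - opt$maximum) > 1e-6 * (hi - lo)
    if (interior) break
    width <- hi - lo
    lo <- lo - width; hi <- hi + width
  }
  converged <- !is.null(opt) && interior
  if (!converged)
    stop("profile-likelihood maximization did not converge; ",
         "best value beta = ", format(opt$maximum))
  bhat <- opt$maximum
  lmax <- opt$objective

  # Wald curvature (central second difference)
  h <- max(abs(bhat), 1) * 1e-4
  d2 <- (prof$pl(bhat + h) - 2 * lmax + prof$pl(bhat - h)) / h^2
  se_wald <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_

  drop_ll <- stats::qchisq(level, 1) / 2
  target <- lmax - drop_ll
  find_bound <- function(direction) {
    step <- if (is.na(se_wald)) step0 / 5 else 2 * se_wald
    b1 <- bhat; b2 <- bhat + direction * step
    for (i in 1:40) {
      if (prof$pl(b2) < target) {
        return(stats::uniroot(function(b) prof$pl(b) - target,
                              sort(c(b1, b2)), tol = 1e-10)$root)
      }
      b1 <- b2; b2 <- bhat + direction * step * 2^i
    }
    NA_real_
  }
  ci_lo <- find_bound(-1); ci_hi <- find_bound(1)
  ci_method <- "profile"
  if (is.na(ci_lo) || is.na(ci_hi)) {
    ci_method <- "wald"
    q <- stats::qnorm(1 - (1 - level) / 2)
    ci_lo <- bhat - q * se_wald; ci_hi <- bhat + q * se_wald
  }

  .new_mr_fit(bhat, se_wald, c(ci_lo, ci_hi), "ml", n_variants(data),
              level = level, data = data,
              diagnostics = list(loglik = lmax, convergence = converged,
                                 se_wald = se_wald, ci_method = ci_method,
                                 theta = theta,
                                 correlated = !is.null(corr),
                                 xi = prof$xi_hat(bhat)))
}

#' Sensitivity of the causal estimate to the sample-overlap correlation
#'
#' When the exposure and outcome samples overlap, the association
#' estimates X_k and Y_k are correlated with an overlap parameter
#' theta that usually cannot be estimated from summarized data alone.
#' This function refits the likelihood-based model across a grid of
#' plausible theta values so the stability of the causal estimate can
#' be judged.
#'
#' @inheritParams mr_ml
#' @param theta_grid numeric vector of overlap correlations, each in
#'   (-1, 1); reported in increasing order.
#' @return A data frame of class `mr_theta_scan` with columns `theta`,
#'   `beta`, `se_wald`, `ci_lower`, `ci_upper`, `K_used`.
#' @export
mr_theta_scan <- function(data, theta_grid, corr = NULL, level = 0.95) {
  if (any(abs(theta_grid) >= 1))
    stop("all theta grid values must lie in (-1, 1)")
  theta_grid <- sort(theta_grid)
  rows <- lapply(theta_grid, function(th) {
    f <- mr_ml(data, corr = corr, theta = th, level = level)
    data.frame(theta = th, beta = f$beta, se_wald = f$se,
               ci_lower = f$ci[1], ci_upper = f$ci[2], K_used = f$K_used)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_theta_scan", "data.frame")
  out
}

#' @export
print.mr_theta_scan <- function(x, digits = 4, ...) {
  cat("Sensitivity of the likelihood-based estimate to sample overlap\n")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}
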