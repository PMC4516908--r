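#' Heterogeneity (overidentification) test of a common causal effect
#'
#' Tests whether the per-variant causal effects are compatible with a
#' single common effect beta. The likelihood-ratio statistic is twice
#' the difference between the saturated log-likelihood — means set to
#' the observed associations themselves (\eqn{\xi_k = X_k},
#' \eqn{\beta_k \xi_k = Y_k}), evaluated analytically since all
#' residuals vanish — and the maximized log-likelihood of the
#' common-effect model. Under the null of homogeneity the statistic is
#' chi-squared on K - 1 degrees of freedom. Large statistics point to
#' pleiotropy of individual variants or to genuinely heterogeneous
#' mechanisms.
#'
#' With an LD matrix (and/or overlap theta) the same construction is
#' applied with the correlated covariance in both the saturated and
#' constrained terms, so the normalizing constants cancel.
#'
#' @inheritParams mr_ml
#' @return An object of class `mr_het`: list with `statistic`, `df`
#'   (= K - 1), `pvalue`, and the constrained `fit` (`mr_fit`).
#' @export
mr_heterogeneity <- function(data, corr = NULL, theta = 0) {
  stopifnot(inherits(data, "mr_summary_data"))
  K <- n_variants(data)
  if (K < 2)
    stop("heterogeneity test requires at least 2 variants (df = K - 1)")
  fit <- mr_ml(data, corr = corr, theta = theta)
  prof <- .make_profile(data, corr, theta)
  stat <- max(0, 2 * (prof$saturated - fit$diagnostics$loglik))
  df <- K - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, pvalue = p, fit = fit),
            class = "mr_het")
}

#' Chi-squared tail probability for a heterogeneity statistic
#'
#' Upper-tail probability of the chi-squared distribution on K - 1
#' degrees of freedom, for comparing a reported heterogeneity statistic
#' against its null. Full precision is returned; comparisons against
#' published values typically round to 2 decimals.
#'
#' @param statistic nonnegative likelihood-ratio statistic.
#' @param df degrees of freedom (K - 1).
#' @return The p-value.
#' @export
mr_het_pvalue <- function(statistic, df) {
  stopifnot(statistic >= 0, df >= 1)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' @export
print.mr_het <- function(x, digits = 4, ...) {
  cat("Heterogeneity (overidentification) test, common causal effect\n")
  cat("  LRT statistic = ", format(x$statistic, digits = digits),
      " on ", x$df, " df, p = ", format(x$pvalue, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' Scatter plot of genetic associations with fitted causal slope
#'
#' Plots the per-variant outcome associations \eqn{Y_k} against the
#' exposure associations \eqn{X_k}, with 95\% error bars
#' (\eqn{\pm 1.96} standard errors) on both axes, and overlays the
#' fitted line through the origin with slope equal to the causal
#' estimate. Points off the line (allowing for their uncertainty) are
#' candidates for pleiotropy or effect heterogeneity.
#'
#' @param x an `mr_fit` object carrying its data (as returned by
#'   [mr_ivw()], [mr_ml()], [mr_bayes()]).
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, a list with `slope` (= the fit's beta) and `K`.
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  if (is.null(d))
    stop("this fit does not carry its data; refit from an mr_summary_data")
  q <- stats::qnorm(0.975)
  xv <- d$beta_exposure; yv <- d$beta_outcome
  xl <- range(xv - q * d$se_exposure, xv + q * d$se_exposure, 0)
  yl <- range(yv - q * d$se_outcome, yv + q * d$se_outcome, 0)
  graphics::plot(xv, yv, xlim = xl, ylim = yl, pch = 19,
                 xlab = "Genetic association with exposure",
                 ylab = "Genetic association with outcome", ...)
  graphics::arrows(xv - q * d$se_exposure, yv, xv + q * d$se_exposure, yv,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  graphics::arrows(xv, yv - q * d$se_outcome, xv, yv + q * d$se_outcome,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  graphics::abline(a = 0, b = x$beta, col = "firebrick", lwd = 2)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(list(slope = x$beta, K = x$K_used))
}

#' Write the association scatter plot to an image file
#'
#' Convenience wrapper around [plot.mr_fit()] that renders to a PNG or
#' SVG file and returns the plot metadata.
#'
#' @param fit an `mr_fit` object carrying its data.
#' @param file output path; format chosen from the extension
#'   (`.png` or `.svg`).
#' @param width,height device size in inches.
#' @return Invisibly, a list with `file`, `slope` and `K`.
#' @export
mr_plot_file <- function(fit, file, width = 6, height = 5) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    grDevices::png(file, width = width, height = height, units = "in",
                   res = 150)
  } else if (ext == "svg") {
    grDevices::svg(file, width = width, height = height)
  } else stop("unsupported image format: '", ext, "' (use png or svg)")
  on.exit(grDevices::dev.off())
  meta <- plot(fit)
  invisible(c(list(file = file), meta))
}
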