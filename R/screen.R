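# Instrument-validity screening with individual-level data: a genetic
# variant used as an instrument must not be associated with confounders
# of the risk factor--outcome relationship. Associations with measured
# covariates are the practical, if partial, check.

#' Screen variants for association with covariates
#'
#' For every (variant, covariate) pair, fits a linear regression of the
#' standardized covariate on the variant dosage (plus any adjustment
#' columns, e.g. age, sex, centre) and records the coefficient —
#' the standard-deviation difference in the covariate per additional
#' effect allele — and its two-sided p-value.
#'
#' @param genotypes N x K numeric matrix of allele dosages in [0, 2]
#'   (column names become variant IDs).
#' @param covariates N x V numeric matrix or data frame of covariates
#'   to test (column names become covariate names).
#' @param adjustment optional N x C numeric matrix of adjustment
#'   covariates included in every regression.
#' @return An object of class `mr_screen`: list with `variant_ids`,
#'   `covariate_names`, `pvalues` (K x V) and `betas` (K x V,
#'   standardized per-allele differences).
#' @export
mr_covariate_screen <- function(genotypes, covariates, adjustment = NULL) {
  G <- as.matrix(genotypes)
  Cv <- as.matrix(covariates)
  if (nrow(G) != nrow(Cv)) stop("genotypes and covariates must have the same rows")
  K <- ncol(G); V <- ncol(Cv)
  if (V < 1) stop("at least one covariate is required")
  A <- if (is.null(adjustment)) NULL else as.matrix(adjustment)
  C_adj <- if (is.null(A)) 0L else ncol(A)
  if (nrow(G) <= K + C_adj + 2)
    stop("too few individuals (N must exceed K + C + 2)")

  sds <- apply(Cv, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(Cv)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("rank-deficient design: constant covariate column(s) ",
         paste(bad, collapse = ", "))
  }
  Z <- scale(Cv)

  vids <- colnames(G); if (is.null(vids)) vids <- paste0("snp", seq_len(K))
  cnames <- colnames(Cv); if (is.null(cnames)) cnames <- paste0("cov", seq_len(V))
  pv <- bt <- matrix(NA_real_, K, V, dimnames = list(vids, cnames))

  for (k in seq_len(K)) {
    X <- cbind(1, G[, k], A)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      keep_cols <- qrx$pivot[seq_len(qrx$rank)]
      dropped <- setdiff(seq_len(ncol(X)), keep_cols)
      labs <- c("(intercept)", vids[k],
                if (C_adj) paste0("adjustment:",
                                  colnames(A) %||% seq_len(C_adj)))
      stop("rank-deficient design for variant ", vids[k],
           ": collinear column(s) ", paste(labs[dropped], collapse = ", "))
    }
    XtXinv <- chol2inv(chol(crossprod(X)))
    for (v in seq_len(V)) {
      fit <- stats::lm.fit(X, Z[, v])
      rdf <- length(Z[, v]) - qrx$rank
      s2 <- sum(fit$residuals^2) / rdf
      se <- sqrt(s2 * XtXinv[2, 2])
      bt[k, v] <- fit$coefficients[2]
      pv[k, v] <- 2 * stats::pt(-abs(bt[k, v] / se), df = rdf)
    }
  }
  structure(list(variant_ids = vids, covariate_names = cnames,
                 pvalues = pv, betas = bt),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  cat("Covariate association screen: ", length(x$variant_ids),
      " variant(s) x ", length(x$covariate_names), " covariate(s)\n", sep = "")
  cat("minimum p-value per variant:\n")
  print(apply(x$pvalues, 1, min))
  invisible(x)
}

#' Select conservative and liberal instrument sets
#'
#' Partitions variants into two nested instrument sets based on each
#' variant's minimum p-value across the screened covariates: a
#' conservative set (minimum p above `conservative_p`, default 0.01)
#' for the primary analysis, and a liberal set (minimum p above the
#' Bonferroni-corrected threshold `alpha / V`, where V is the number of
#' covariates tested) for a secondary analysis. With the defaults the
#' conservative set is a subset of the liberal set whenever V >= 5
#' (0.01 >= 0.05/V); for smaller V the thresholds may invert the
#' nesting, which is detected and reported.
#'
#' @param screen an `mr_screen` object from [mr_covariate_screen()],
#'   or a K x V p-value matrix with variant-ID rownames.
#' @param conservative_p p-value threshold of the conservative set.
#' @param alpha family-wise level for the Bonferroni liberal threshold.
#' @return An object of class `mr_instrument_sets`: list with
#'   `conservative`, `liberal` (character vectors of variant IDs) and
#'   `thresholds`.
#' @export
mr_instrument_sets <- function(screen, conservative_p = 0.01, alpha = 0.05) {
  if (inherits(screen, "mr_screen")) {
    pv <- screen$pvalues; vids <- screen$variant_ids
  } else {
    pv <- as.matrix(screen)
    vids <- rownames(pv); if (is.null(vids)) vids <- paste0("snp", seq_len(nrow(pv)))
  }
  if (length(pv) == 0) stop("empty screen")
  if (conservative_p <= 0 || conservative_p >= 1)
    stop("'conservative_p' must lie in (0, 1)")
  V <- ncol(pv)
  liberal_p <- alpha / V
  minp <- apply(pv, 1, min)
  conservative <- vids[minp > conservative_p]
  liberal <- vids[minp > liberal_p]
  if (conservative_p >= liberal_p) {
    stopifnot(all(conservative %in% liberal))
  } else {
    stopifnot(all(liberal %in% conservative))
  }
  structure(list(conservative = conservative, liberal = liberal,
                 thresholds = c(conservative_p = conservative_p,
                                liberal_p = liberal_p)),
            class = "mr_instrument_sets")
}

#' @export
print.mr_instrument_sets <- function(x, ...) {
  cat("Instrument sets (conservative p > ", x$thresholds[["conservative_p"]],
      "; liberal p > ", format(x$thresholds[["liberal_p"]], digits = 4),
      ")\n", sep = "")
  cat("  conservative (", length(x$conservative), "): ",
      paste(x$conservative, collapse = ", "), "\n", sep = "")
  cat("  liberal      (", length(x$liberal), "): ",
      paste(x$liberal, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-variant allele-score weights from the data under analysis
#'
#' Regresses the risk factor on each variant in turn (with optional
#' adjustment) and returns the coefficients as allele-score weights.
#' Deriving weights from the same data being analysed can lead to
#' overfitting and weak instrument bias in a one-sample setting, so a
#' warning is always issued; externally derived weights are preferable
#' for a primary analysis.
#'
#' @param genotypes N x K dosage matrix.
#' @param risk_factor numeric vector of length N.
#' @param adjustment optional N x C adjustment matrix.
#' @return Numeric vector of K weights.
#' @export
mr_score_weights <- function(genotypes, risk_factor, adjustment = NULL) {
  G <- as.matrix(genotypes)
  A <- if (is.null(adjustment)) NULL else as.matrix(adjustment)
  w <- vapply(seq_len(ncol(G)), function(k) {
    stats::lm.fit(cbind(1, G[, k], A), risk_factor)$coefficients[2]
  }, numeric(1))
  warning("allele-score weights derived from the data under analysis can ",
          "lead to overfitting and weak instrument bias in a one-sample ",
          "setting", call. = FALSE)
  names(w) <- colnames(G)
  w
}

#' Weighted allele score, calibrated to the risk-factor scale
#'
#' Computes the weighted allele count score_i = sum_k w_k g_ik and
#' rescales it so that a unit increase in the score is associated with
#' `scale_to` units of the risk factor (e.g. one standard deviation).
#' Calibration regresses the risk factor on the raw score in the same
#' data: if that slope is s, the returned score is raw * s / scale_to,
#' so that regressing the risk factor on the returned score gives slope
#' `scale_to` by construction.
#'
#' @param genotypes N x K dosage matrix (entries in [0, 2]).
#' @param weights numeric vector of K per-variant weights (not all
#'   zero).
#' @param scale_to risk-factor change per unit score (e.g. 1 SD of the
#'   risk factor).
#' @param risk_factor numeric vector of length N used for calibration.
#' @param adjustment optional adjustment matrix for the calibration
#'   regression.
#' @return Numeric vector of N calibrated scores, with attribute
#'   `calibration_slope` (the raw-score slope s).
#' @export
mr_allele_score <- function(genotypes, weights, scale_to, risk_factor,
                            adjustment = NULL) {
  G <- as.matrix(genotypes)
  if (length(weights) != ncol(G)) stop("'weights' must have length K")
  if (all(weights == 0)) stop("all-zero weights: the score is degenerate")
  if (any(G < 0 | G > 2)) stop("dosages must lie in [0, 2]")
  raw <- drop(G %*% weights)
  A <- if (is.null(adjustment)) NULL else as.matrix(adjustment)
  s <- stats::lm.fit(cbind(1, raw, A), risk_factor)$coefficients[2]
  if (!is.finite(s) || s == 0)
    stop("calibration failed: the raw score is unrelated to the risk factor")
  score <- raw * s / scale_to
  attr(score, "calibration_slope") <- unname(s)
  score
}

#' Mediation check: is a covariate association explained by the risk factor?
#'
#' A variant associated with a covariate need not violate the
#' instrumental-variable assumptions: if its effect on the covariate is
#' entirely mediated through the risk factor, conditioning on the risk
#' factor should substantially attenuate the variant--covariate
#' coefficient. For each variant this returns the coefficient from the
#' regression of the covariate on the variant, before (`raw_beta`) and
#' after (`adjusted_beta`) adding the risk factor as a regressor,
#' plus the attenuation ratio `1 - adjusted/raw`. No pass/fail
#' threshold is applied: attenuation is rarely complete, because of
#' measurement error in the risk factor and confounding between the
#' risk factor and the covariate.
#'
#' @param genotypes N x K dosage matrix.
#' @param covariate numeric vector of length N.
#' @param risk_factor numeric vector of length N.
#' @param adjustment optional N x C adjustment matrix.
#' @return Data frame with one row per variant: `snp`, `raw_beta`,
#'   `adjusted_beta`, `attenuation`.
#' @export
mr_mediation_check <- function(genotypes, covariate, risk_factor,
                               adjustment = NULL) {
  G <- as.matrix(genotypes)
  A <- if (is.null(adjustment)) NULL else as.matrix(adjustment)
  vids <- colnames(G); if (is.null(vids)) vids <- paste0("snp", seq_len(ncol(G)))
  raw <- adj <- numeric(ncol(G))
  for (k in seq_len(ncol(G))) {
    raw[k] <- stats::lm.fit(cbind(1, G[, k], A), covariate)$coefficients[2]
    adj[k] <- stats::lm.fit(cbind(1, G[, k], risk_factor, A),
                            covariate)$coefficients[2]
  }
  data.frame(snp = vids, raw_beta = raw, adjusted_beta = adj,
             attenuation = ifelse(raw != 0, 1 - adj / raw, NA_real_),
             stringsAsFactors = FALSE)
}
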