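# Synthetic two-sample / subsample / one-sample Mendelian randomization
# studies. The structural model is the instrumental-variable one: the
# variants affect the outcome only through the exposure (unless a
# direct pleiotropic path is requested), and a shared confounder drives
# both exposure and outcome.

#' Configuration of a simulated Mendelian randomization study
#'
#' Defaults describe a well-powered two-sample study of a continuous
#' risk factor: 10 common variants (MAF 0.30) in linkage equilibrium,
#' each shifting the exposure by 0.1 residual SD per allele (per-variant
#' F around 40 at n = 5000), a true causal effect of 0.2, and positive
#' confounding of moderate strength on both traits. Scalar arguments
#' are recycled to length K.
#'
#' @param K number of variants.
#' @param maf minor (effect) allele frequencies, each in (0.01, 0.5).
#' @param variant_effects per-allele effects of each variant on the
#'   exposure.
#' @param beta_true causal effect of the exposure on the outcome.
#' @param confounder_effect_x,confounder_effect_y effects of a shared
#'   standard-normal confounder on exposure and outcome.
#' @param pleiotropy direct variant-to-outcome effects bypassing the
#'   exposure (default all zero: valid instruments).
#' @param ld_rho optional K x K target dosage correlation matrix (or
#'   `mr_ld_matrix`); `NULL` for linkage equilibrium.
#' @param n_exposure,n_outcome sample sizes of the exposure and
#'   outcome samples.
#' @param overlap_fraction fraction of the smaller sample shared by
#'   both samples: 0 gives a strict two-sample design, 1 with equal
#'   sample sizes gives a one-sample design.
#' @param outcome_type `"continuous"` or `"binary"` (logistic
#'   structural model; summary associations are log odds ratios).
#' @param binary_prevalence baseline outcome probability (binary only).
#' @param sigma_exposure,sigma_outcome residual standard deviations.
#' @param seed optional integer seed stored in the config and applied
#'   by [mr_simulate()].
#' @return An object of class `mr_sim_config` (a list).
#' @export
mr_sim_config <- function(K = 10, maf = 0.30, variant_effects = 0.1,
                          beta_true = 0.2,
                          confounder_effect_x = 0.3,
                          confounder_effect_y = 0.3,
                          pleiotropy = 0, ld_rho = NULL,
                          n_exposure = 5000, n_outcome = 5000,
                          overlap_fraction = 0,
                          outcome_type = c("continuous", "binary"),
                          binary_prevalence = 0.3,
                          sigma_exposure = 1, sigma_outcome = 1,
                          seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  maf <- rep_len(maf, K)
  variant_effects <- rep_len(variant_effects, K)
  pleiotropy <- rep_len(pleiotropy, K)
  if (any(maf <= 0.01 | maf >= 0.5))
    stop("'maf' values must lie in (0.01, 0.5)")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("'overlap_fraction' must lie in [0, 1]")
  if (!is.null(ld_rho)) {
    ld_rho <- if (inherits(ld_rho, "mr_ld_matrix")) ld_rho else mr_ld_matrix(ld_rho)
    if (nrow(ld_rho) != K) stop("'ld_rho' must be K x K")
  }
  structure(list(K = as.integer(K), maf = maf,
                 variant_effects = variant_effects, beta_true = beta_true,
                 confounder_effect_x = confounder_effect_x,
                 confounder_effect_y = confounder_effect_y,
                 pleiotropy = pleiotropy, ld_rho = ld_rho,
                 n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome),
                 overlap_fraction = overlap_fraction,
                 outcome_type = outcome_type,
                 binary_prevalence = binary_prevalence,
                 sigma_exposure = sigma_exposure,
                 sigma_outcome = sigma_outcome, seed = seed),
            class = "mr_sim_config")
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' @param path file with keys matching the arguments of
#'   [mr_sim_config()] (`ld_rho` as a nested list of rows).
#' @return An `mr_sim_config` object.
#' @export
mr_sim_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package")
    jsonlite::fromJSON(path)
  } else stop("unsupported config format: '", ext, "'")
  if (!is.null(cfg$ld_rho)) {
    cfg$ld_rho <- do.call(rbind, lapply(cfg$ld_rho, as.numeric))
  }
  do.call(mr_sim_config, cfg)
}

# Pairwise latent (tetrachoric-style) correlation that makes thresholded
# Gaussian alleles reproduce a target dosage correlation. P(both alleles
# minor) is integrated numerically; no closed form for the bivariate
# normal orthant is needed.
.latent_from_dosage_corr <- function(target, p1, p2) {
  if (target == 0) return(0)
  q1 <- stats::qnorm(p1); q2 <- stats::qnorm(p2)
  phi_of_r <- function(r) {
    p11 <- stats::integrate(function(t) {
      stats::pnorm((q2 - r * t) / sqrt(1 - r^2)) * stats::dnorm(t)
    }, -Inf, q1, rel.tol = 1e-9)$value
    (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  }
  lim <- 0.999
  lo_val <- phi_of_r(-lim); hi_val <- phi_of_r(lim)
  if (target < lo_val || target > hi_val)
    stop("infeasible LD/MAF combination: dosage correlation ", target,
         " is outside the achievable range [", format(lo_val, digits = 3),
         ", ", format(hi_val, digits = 3), "] for MAFs ", p1, ", ", p2)
  stats::uniroot(function(r) phi_of_r(r) - target, c(-lim, lim),
                 tol = 1e-8)$root
}

.genotype_matrix <- function(n, K, maf, ld_rho) {
  if (is.null(ld_rho)) {
    G <- matrix(stats::rbinom(n * K, 2L, rep(maf, each = n)), n, K)
  } else {
    L <- matrix(0, K, K)
    diag(L) <- 1
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      L[i, j] <- L[j, i] <- .latent_from_dosage_corr(ld_rho[i, j],
                                                     maf[i], maf[j])
    }
    chL <- tryCatch(chol(L), error = function(e)
      stop("infeasible LD/MAF combination: calibrated latent correlation ",
           "matrix is not positive definite"))
    thr <- stats::qnorm(maf)
    allele <- function() {
      Z <- matrix(stats::rnorm(n * K), n, K) %*% chL
      sweep(Z, 2, thr, "<") + 0L
    }
    G <- allele() + allele()
  }
  colnames(G) <- paste0("rs", seq_len(K))
  G
}

#' Simulate an individual-level Mendelian randomization study
#'
#' Draws genotypes (binomial dosages, optionally correlated through a
#' calibrated Gaussian copula on the haplotype level), a standard
#' normal confounder, the exposure as a linear function of genotypes
#' and confounder, and the outcome as a linear (or logistic) function
#' of exposure, confounder and any direct pleiotropic variant effects.
#' Individuals are partitioned into an exposure sample and an outcome
#' sample with the configured overlap.
#'
#' @param config an [mr_sim_config()] object.
#' @param seed overrides `config$seed` when supplied.
#' @return An object of class `mr_sim_study`: list with `genotypes`
#'   (N x K), `exposure`, `outcome`, `confounder`, `sample_labels`
#'   (factor: `exposure`/`both`/`outcome`), index vectors
#'   `exposure_idx`, `outcome_idx`, and the `config`.
#' @export
mr_simulate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mr_sim_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_e <- config$n_exposure; n_o <- config$n_outcome
  n_ov <- round(config$overlap_fraction * min(n_e, n_o))
  N <- n_e + n_o - n_ov
  K <- config$K

  G <- .genotype_matrix(N, K, config$maf, config$ld_rho)
  U <- stats::rnorm(N)
  x <- drop(G %*% config$variant_effects) +
    config$confounder_effect_x * U +
    stats::rnorm(N, 0, config$sigma_exposure)
  lp <- config$beta_true * x + config$confounder_effect_y * U +
    drop(G %*% config$pleiotropy)
  y <- if (config$outcome_type == "binary") {
    stats::rbinom(N, 1L, stats::plogis(stats::qlogis(config$binary_prevalence) + lp))
  } else {
    lp + stats::rnorm(N, 0, config$sigma_outcome)
  }

  exposure_idx <- seq_len(n_e)
  outcome_idx <- (n_e - n_ov + 1):(n_e - n_ov + n_o)
  labels <- factor(ifelse(seq_len(N) %in% exposure_idx,
                          ifelse(seq_len(N) %in% outcome_idx, "both", "exposure"),
                          "outcome"),
                   levels = c("exposure", "both", "outcome"))
  structure(list(genotypes = G, exposure = x, outcome = y, confounder = U,
                 sample_labels = labels, exposure_idx = exposure_idx,
                 outcome_idx = outcome_idx, config = config),
            class = "mr_sim_study")
}

#' @export
print.mr_sim_study <- function(x, ...) {
  cat("Simulated MR study: ", length(x$exposure), " individuals, ",
      x$config$K, " variants (", x$config$outcome_type, " outcome)\n",
      "  exposure sample n = ", length(x$exposure_idx),
      ", outcome sample n = ", length(x$outcome_idx),
      ", overlap = ", sum(x$sample_labels == "both"), "\n", sep = "")
  invisible(x)
}

# slope, se and p from a univariate regression, closed form
.uni_reg <- function(yv, g) {
  n <- length(yv)
  gc <- g - mean(g); yc <- yv - mean(yv)
  sxx <- sum(gc^2)
  if (sxx == 0) return(NULL)
  slope <- sum(gc * yc) / sxx
  s2 <- (sum(yc^2) - slope^2 * sxx) / (n - 2)
  se <- sqrt(s2 / sxx)
  c(beta = slope, se = se)
}

#' Summarize a simulated study into two-sample association estimates
#'
#' Runs the per-variant univariate regressions a GWAS consortium would
#' report: exposure on dosage in the exposure sample (X_k, sigma_Xk)
#' and outcome on dosage in the outcome sample (Y_k, sigma_Yk; logistic
#' regression yielding log odds ratios for a binary outcome). Variants
#' monomorphic in either sample are dropped with a warning. The result
#' is already harmonized (a simulated study has a single known strand).
#'
#' @param study an `mr_sim_study` from [mr_simulate()].
#' @return An [mr_summary_data] object.
#' @export
mr_summarize_study <- function(study) {
  stopifnot(inherits(study, "mr_sim_study"))
  Ge <- study$genotypes[study$exposure_idx, , drop = FALSE]
  Go <- study$genotypes[study$outcome_idx, , drop = FALSE]
  xe <- study$exposure[study$exposure_idx]
  yo <- study$outcome[study$outcome_idx]
  binary <- study$config$outcome_type == "binary"
  K <- ncol(Ge)

  keep <- logical(K)
  bx <- sx <- by <- sy <- numeric(K)
  for (k in seq_len(K)) {
    rx <- .uni_reg(xe, Ge[, k])
    ry <- if (binary) {
      if (stats::var(Go[, k]) == 0) NULL else {
        f <- stats::glm(yo ~ Go[, k], family = stats::binomial())
        s <- summary(f)$coefficients
        c(beta = s[2, 1], se = s[2, 2])
      }
    } else .uni_reg(yo, Go[, k])
    if (is.null(rx) || is.null(ry)) {
      warning("variant ", colnames(Ge)[k],
              " is monomorphic in one sample and was dropped", call. = FALSE)
      next
    }
    keep[k] <- TRUE
    bx[k] <- rx["beta"]; sx[k] <- rx["se"]
    by[k] <- ry["beta"]; sy[k] <- ry["se"]
  }
  if (!any(keep)) stop("no polymorphic variants left to summarize")
  mr_summary_data(
    snp = colnames(Ge)[keep],
    beta_exposure = bx[keep], se_exposure = sx[keep],
    beta_outcome = by[keep], se_outcome = sy[keep],
    effect_allele = rep("A", sum(keep)), other_allele = rep("G", sum(keep)),
    eaf = colMeans(study$genotypes[, keep, drop = FALSE]) / 2
  )
}

#' Simulate summary-level data directly from the measurement model
#'
#' Draws association estimates (X, Y) from the summarized-data
#' likelihood itself: X ~ N(xi, Sigma_X), Y ~ N(beta * xi, Sigma_Y),
#' with optional LD correlations and overlap correlation theta. Useful
#' for calibration studies (parameter recovery, interval coverage,
#' test size) where the fitted model is exactly true.
#'
#' The defaults mimic a well-powered two-sample study of a biomarker:
#' 17 variants with per-allele exposure effects spread over
#' 0.02--0.10, exposure-side standard errors of 0.02 (a cross-sectional
#' sample of a few thousand) and outcome-side standard errors of 0.005
#' (a large consortium meta-analysis), and a causal effect of 0.2.
#'
#' @param K number of variants.
#' @param xi true per-variant exposure association means.
#' @param sigma_x,sigma_y standard errors of the exposure and outcome
#'   associations (recycled to length K).
#' @param beta true causal effect.
#' @param rho optional K x K LD correlation matrix.
#' @param theta overlap correlation in (-1, 1).
#' @param seed optional integer seed.
#' @return An [mr_summary_data] object.
#' @export
mr_simulate_summary <- function(K = 17, xi = seq(0.02, 0.10, length.out = K),
                                sigma_x = 0.02, sigma_y = 0.005,
                                beta = 0.2, rho = NULL, theta = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sigma_x <- rep_len(sigma_x, K); sigma_y <- rep_len(sigma_y, K)
  xi <- rep_len(xi, K)
  if (is.null(rho) && theta == 0) {
    X <- stats::rnorm(K, xi, sigma_x)
    Y <- stats::rnorm(K, beta * xi, sigma_y)
  } else {
    rhom <- if (is.null(rho)) diag(K) else unclass(rho)
    S <- rbind(cbind(outer(sigma_x, sigma_x) * rhom,
                     theta * outer(sigma_x, sigma_y) * rhom),
               cbind(t(theta * outer(sigma_x, sigma_y) * rhom),
                     outer(sigma_y, sigma_y) * rhom))
    z <- c(xi, beta * xi) + drop(stats::rnorm(2 * K) %*% chol(S))
    X <- z[seq_len(K)]; Y <- z[K + seq_len(K)]
  }
  mr_summary_data(snp = paste0("rs", seq_len(K)),
                  beta_exposure = X, se_exposure = sigma_x,
                  beta_outcome = Y, se_outcome = sigma_y)
}

#' Replicated bias and coverage experiment across study designs
#'
#' Repeatedly simulates studies under each configuration, summarizes
#' them, applies an estimator, and reports the mean estimate, its
#' Monte Carlo standard error, the empirical SD, 95\% interval
#' coverage of the true effect, and the mean per-variant instrument
#' F statistic (approximated by mean (X_k / sigma_Xk)^2). This is the
#' tool for demonstrating the direction of weak-instrument bias:
#' toward the null in a two-sample design, toward the confounded
#' observational association in a one-sample design.
#'
#' @param configs a single [mr_sim_config()] or a (possibly named)
#'   list of them.
#' @param estimator function mapping an [mr_summary_data] to an
#'   `mr_fit` (default [mr_ivw]).
#' @param replicates number of simulated studies per configuration
#'   (>= 100 for a stable mean).
#' @param seed integer seed for the whole experiment.
#' @return A data frame with one row per configuration: `config`,
#'   `beta_true`, `mean_estimate`, `mc_se`, `empirical_sd`,
#'   `coverage`, `mean_F`, `replicates`.
#' @export
mr_bias_experiment <- function(configs, estimator = mr_ivw,
                               replicates = 500, seed = 1) {
  if (inherits(configs, "mr_sim_config")) configs <- list(configs)
  if (replicates < 100) stop("'replicates' must be at least 100")
  nm <- names(configs)
  if (is.null(nm)) nm <- paste0("config", seq_along(configs))
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    cfg$seed <- NULL  # replicates stream from the experiment-level seed
    est <- cov <- Fst <- numeric(replicates)
    for (r in seq_len(replicates)) {
      study <- mr_simulate(cfg, seed = NULL)  # stream from the experiment seed
      sd_ <- mr_summarize_study(study)
      fit <- estimator(sd_)
      est[r] <- fit$beta
      cov[r] <- cfg$beta_true >= fit$ci[1] && cfg$beta_true <= fit$ci[2]
      Fst[r] <- mean((sd_$beta_exposure / sd_$se_exposure)^2)
    }
    data.frame(config = nm[i], beta_true = cfg$beta_true,
               mean_estimate = mean(est),
               mc_se = stats::sd(est) / sqrt(replicates),
               empirical_sd = stats::sd(est),
               coverage = mean(cov), mean_F = mean(Fst),
               replicates = replicates, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
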