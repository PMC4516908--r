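# Fixture builders and independent oracles shared across the suite.

# random summarized dataset with comfortably strong instruments
rand_summary <- function(K, seed = NULL, beta = 0.2,
                         sigma_x = 0.02, sigma_y = 0.005) {
  if (!is.null(seed)) set.seed(seed)
  xi <- runif(K, 0.02, 0.12)
  mr_summary_data(
    snp = paste0("rs", seq_len(K)),
    beta_exposure = rnorm(K, xi, sigma_x), se_exposure = rep(sigma_x, K),
    beta_outcome = rnorm(K, beta * xi, sigma_y), se_outcome = rep(sigma_y, K)
  )
}

# random positive-definite correlation matrix (moderate off-diagonals)
rand_corr <- function(K, seed = NULL, scale = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(K * K), K)
  S <- crossprod(A) + K * diag(K)
  D <- diag(1 / sqrt(diag(S)))
  mr_ld_matrix(scale * (D %*% S %*% D) + (1 - scale) * diag(K))
}

# generic multivariate normal log density, direct solve/determinant route
mvn_logdens_oracle <- function(z, mean, S) {
  r <- z - mean
  as.numeric(-0.5 * (length(z) * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S) %*% r))
}

# the full 2K covariance assembled from first principles
cov_oracle <- function(sx, sy, rho, theta) {
  Sx <- outer(sx, sx) * rho
  Sy <- outer(sy, sy) * rho
  Sxy <- theta * outer(sx, sy) * rho
  rbind(cbind(Sx, Sxy), cbind(t(Sxy), Sy))
}

# write a small summary-statistics file
write_sumstat_file <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

sumstat_df <- function(snp, ea, oa, beta, se, eaf = NULL) {
  d <- data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                  beta = beta, se = se, stringsAsFactors = FALSE)
  if (!is.null(eaf)) d$eaf <- eaf
  d
}
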