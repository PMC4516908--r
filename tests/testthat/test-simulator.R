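test_that("identical config and seed reproduce the study bit for bit", {
  cfg <- mr_sim_config(K = 5, n_exposure = 500, n_outcome = 500, seed = 17)
  s1 <- mr_simulate(cfg)
  s2 <- mr_simulate(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$sample_labels, s2$sample_labels)
})

test_that("sample membership follows the overlap fraction across designs", {
  two <- mr_simulate(mr_sim_config(K = 2, n_exposure = 300, n_outcome = 400,
                                   overlap_fraction = 0, seed = 1))
  expect_equal(sum(two$sample_labels == "both"), 0)
  expect_equal(length(two$exposure), 700)

  one <- mr_simulate(mr_sim_config(K = 2, n_exposure = 300, n_outcome = 300,
                                   overlap_fraction = 1, seed = 1))
  expect_equal(sum(one$sample_labels == "both"), 300)
  expect_identical(one$exposure_idx, one$outcome_idx)

  half <- mr_simulate(mr_sim_config(K = 2, n_exposure = 400, n_outcome = 300,
                                    overlap_fraction = 0.5, seed = 1))
  expect_equal(sum(half$sample_labels == "both"), 150)
  expect_true(all(half$genotypes %in% 0:2))
})

test_that("a null model yields genotype-outcome slopes centred on zero", {
  cfg <- mr_sim_config(K = 3, beta_true = 0, confounder_effect_x = 0,
                       confounder_effect_y = 0, n_exposure = 800,
                       n_outcome = 800)
  set.seed(91)
  slopes <- replicate(40, {
    d <- mr_summarize_study(mr_simulate(cfg))
    mean(d$beta_outcome)
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("realized dosage correlations track the requested LD structure", {
  K <- 4
  rho <- matrix(c(1, 0.5, 0.2, 0, 0.5, 1, 0.3, 0.1,
                  0.2, 0.3, 1, 0.4, 0, 0.1, 0.4, 1), K, K)
  cfg <- mr_sim_config(K = K, maf = c(0.2, 0.3, 0.4, 0.25),
                       ld_rho = rho, n_exposure = 5000, n_outcome = 5000,
                       seed = 19)
  st <- mr_simulate(cfg)
  realized <- cor(st$genotypes)
  expect_lt(max(abs(realized - rho)), 0.05)

  # unreachable dosage correlation is refused
  expect_error(
    mr_simulate(mr_sim_config(K = 2, maf = c(0.05, 0.45),
                              ld_rho = matrix(c(1, 0.95, 0.95, 1), 2),
                              n_exposure = 100, n_outcome = 100, seed = 1)),
    "infeasible")
})

test_that("summarized exposure associations are calibrated against the generating effects", {
  cfg <- mr_sim_config(K = 6, n_exposure = 3000, n_outcome = 1000)
  set.seed(23)
  hits <- unlist(replicate(15, {
    d <- mr_summarize_study(mr_simulate(cfg))
    abs(d$beta_exposure - cfg$variant_effects) <= 3 * d$se_exposure
  }, simplify = FALSE))
  expect_gte(mean(hits), 0.95)
})

test_that("binary outcomes produce log odds ratios on a sensible scale", {
  cfg <- mr_sim_config(K = 3, variant_effects = 0.3, beta_true = 0.4,
                       outcome_type = "binary", n_exposure = 3000,
                       n_outcome = 3000, seed = 29)
  st <- mr_simulate(cfg)
  expect_true(all(st$outcome %in% 0:1))
  d <- mr_summarize_study(st)
  # per-variant log odds ratio approx beta_true * variant effect
  expect_equal(mean(d$beta_outcome / d$beta_exposure), 0.4, tolerance = 0.25)
})

test_that("monomorphic variants are dropped from the summary with a warning", {
  st <- mr_simulate(mr_sim_config(K = 3, n_exposure = 200, n_outcome = 200,
                                  seed = 3))
  st$genotypes[, 2] <- 0
  expect_warning(d <- mr_summarize_study(st), "monomorphic")
  expect_equal(n_variants(d), 2L)
  expect_equal(d$snp, c("rs1", "rs3"))
})

test_that("the heterogeneity test gains power against a strongly pleiotropic variant", {
  set.seed(37)
  reject <- replicate(100, {
    d <- mr_simulate_summary(K = 10, xi = seq(0.02, 0.10, length.out = 10))
    d$beta_outcome[5] <- d$beta_outcome[5] + 5 * d$se_outcome[5]
    mr_heterogeneity(d)$pvalue < 0.05
  })
  expect_gt(mean(reject), 0.5)
})

test_that("config files round-trip through YAML and JSON", {
  path_y <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(K = 3, maf = 0.25, beta_true = 0.1,
                        n_exposure = 100, n_outcome = 100, seed = 5), path_y)
  cfg <- mr_sim_config_from_file(path_y)
  expect_s3_class(cfg, "mr_sim_config")
  expect_equal(cfg$K, 3L)
  expect_equal(cfg$maf, rep(0.25, 3))

  path_j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(K = 2, beta_true = 0.3, seed = 9), path_j,
                       auto_unbox = TRUE)
  cfg2 <- mr_sim_config_from_file(path_j)
  expect_equal(cfg2$beta_true, 0.3)
})
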