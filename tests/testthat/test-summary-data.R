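test_that("constructor validates standard errors and checks p-value consistency", {
  expect_error(mr_summary_data("rs1", 0.5, -0.1, 0.1, 0.05), "positive")
  expect_error(mr_summary_data(character(0), numeric(0), numeric(0),
                               numeric(0), numeric(0)), "at least one")
  # consistent p passes silently, badly inconsistent p warns
  expect_silent(mr_summary_data("rs1", 0.5, 0.1, 0.1, 0.05,
                                pval_exposure = 2 * pnorm(-5)))
  expect_warning(mr_summary_data("rs1", 0.5, 0.1, 0.1, 0.05,
                                 pval_exposure = 0.9),
                 "disagree")
})

test_that("harmonization keeps matched alleles, flips swapped ones, excludes ambiguous ones", {
  ex <- list(snp = "rs1", effect_allele = "A", other_allele = "G",
             beta = 0.5, se = 0.1)
  ou_same <- list(snp = "rs1", effect_allele = "A", other_allele = "G",
                  beta = 0.1, se = 0.05)
  h <- harmonize_alleles(ex, ou_same)
  expect_equal(h$action, "keep")
  expect_equal(h$beta, 0.1)

  ou_swap <- list(snp = "rs1", effect_allele = "G", other_allele = "A",
                  beta = 0.1, se = 0.05, eaf = 0.3)
  h <- harmonize_alleles(ex, ou_swap)
  expect_equal(h$action, "flip")
  expect_equal(h$beta, -0.1)
  expect_equal(h$eaf, 0.7)
  expect_equal(h$effect_allele, "A")

  # flipping twice restores the original record (involution)
  h2 <- harmonize_alleles(list(snp = "rs1", effect_allele = "G",
                               other_allele = "A", beta = 2, se = 1),
                          h[c("snp", "effect_allele", "other_allele",
                              "beta", "se", "eaf")])
  expect_equal(h2$beta, ou_swap$beta)
  expect_equal(h2$eaf, ou_swap$eaf)
  expect_equal(h2$effect_allele, ou_swap$effect_allele)

  # palindromic without frequency evidence is flagged out
  pal_ex <- list(snp = "rs2", effect_allele = "A", other_allele = "T",
                 beta = 0.5, se = 0.1)
  pal_ou <- list(snp = "rs2", effect_allele = "A", other_allele = "T",
                 beta = 0.1, se = 0.05)
  expect_equal(harmonize_alleles(pal_ex, pal_ou)$action, "exclude")

  # irreconcilable alleles are flagged out
  bad <- list(snp = "rs1", effect_allele = "C", other_allele = "G",
              beta = 0.1, se = 0.05)
  expect_equal(harmonize_alleles(ex, bad)$action, "exclude")

  expect_error(harmonize_alleles(ex, list(snp = "rs9", effect_allele = "A",
                                          other_allele = "G", beta = 1,
                                          se = 1)), "same variant")
})

test_that("loading restricts to shared variants, preserves exposure order, flips swapped alleles", {
  ef <- write_sumstat_file(
    sumstat_df(c("rs1", "rs2", "rs3"), c("A", "C", "G"), c("G", "T", "A"),
               c(0.5, 0.4, 0.3), c(0.05, 0.05, 0.05)),
    tempfile(fileext = ".tsv"))
  of <- write_sumstat_file(
    sumstat_df(c("rs4", "rs2", "rs1"), c("C", "T", "A"), c("G", "C", "G"),
               c(0.9, 0.08, 0.10), c(0.02, 0.02, 0.02)),
    tempfile(fileext = ".csv"), sep = ",")
  d <- suppressMessages(read_mr_summary(ef, of))
  expect_equal(n_variants(d), 2L)
  expect_equal(d$snp, c("rs1", "rs2"))              # exposure-file order
  expect_equal(d$beta_outcome, c(0.10, -0.08))      # rs2 alleles swapped
  expect_equal(d$beta_exposure, c(0.5, 0.4))

  # zero overlap is fatal
  of2 <- write_sumstat_file(
    sumstat_df("rs99", "A", "G", 0.1, 0.01), tempfile(fileext = ".tsv"))
  expect_error(suppressMessages(read_mr_summary(ef, of2)), "no overlapping")

  # missing required column is fatal and names the column
  of3 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(snp = "rs1", effect_allele = "A", b = 1),
                     of3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressMessages(read_mr_summary(ef, of3)), "beta")
})

test_that("a 17-variant pair of files loads with K = 17 in exposure order", {
  set.seed(42)
  snps <- paste0("rs", sample(1000, 17))
  ef <- write_sumstat_file(
    sumstat_df(snps, "A", "G", rnorm(17, 0.05, 0.02), runif(17, 0.01, 0.03)),
    tempfile(fileext = ".tsv"))
  of <- write_sumstat_file(
    sumstat_df(rev(snps), "A", "G", rnorm(17, 0.01, 0.005),
               runif(17, 0.003, 0.008)),
    tempfile(fileext = ".tsv"))
  d <- suppressMessages(read_mr_summary(ef, of))
  expect_equal(n_variants(d), 17L)
  expect_equal(d$snp, snps)
})

test_that("writing and reloading reproduces all numeric fields exactly", {
  d <- rand_summary(9, seed = 7)
  ef <- tempfile(fileext = ".tsv"); of <- tempfile(fileext = ".tsv")
  write_mr_summary(d, ef, of)
  d2 <- suppressMessages(read_mr_summary(ef, of))
  expect_identical(d2$beta_exposure, d$beta_exposure)
  expect_identical(d2$se_exposure, d$se_exposure)
  expect_identical(d2$beta_outcome, d$beta_outcome)
  expect_identical(d2$se_outcome, d$se_outcome)
  expect_identical(d2$snp, d$snp)
})

test_that("LD matrix validation enforces symmetry, range, unit diagonal and PSD", {
  expect_s3_class(mr_ld_matrix(diag(3)), "mr_ld_matrix")
  expect_error(mr_ld_matrix(matrix(c(1, 1.5, 1.5, 1), 2)), "lie in")
  expect_error(mr_ld_matrix(matrix(c(1, 0.2, 0.4, 1), 2)), "asymmetric")
  expect_error(mr_ld_matrix(matrix(c(2, 0, 0, 1), 2)), "unit diagonal")
  m <- matrix(c(1, 0.9999999999, 0.9999999999, 1), 2)
  expect_warning(mr_ld_matrix(m), "near-singular")
  # ridge regularization restores usability
  expect_silent(r <- mr_ld_matrix(m, ridge = 0.05))
  expect_equal(unclass(r)[1, 2], 0.95 * 0.9999999999, tolerance = 1e-12)
})

test_that("LD matrix loading is invariant to row/column permutation of the file", {
  set.seed(11)
  rho <- unclass(rand_corr(4))
  ids <- paste0("rs", 1:4)
  dimnames(rho) <- list(ids, ids)
  perm <- c(3, 1, 4, 2)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(
    cbind(data.frame(id = ids[perm]),
          as.data.frame(rho[perm, perm])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- read_ld_matrix(path, ids)
  expect_equal(unclass(loaded), rho, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(read_ld_matrix(path, c(ids, "rs9")), "missing variant")
})
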