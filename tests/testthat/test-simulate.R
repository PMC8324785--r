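small_cfg <- function(...) {
  sim_config(n_cohorts = 1, n_individuals = 600, m_snps = 300,
             raters = c("mother", "teacher"), assessed_frac = 1, ...)
}

test_that("residual correlation solves the phenotypic-correlation decomposition", {
  expect_equal(residual_corr_for_target(0.03, 0.03, 0.8, 0.29),
               (0.29 - 0.8 * 0.03) / 0.97, tolerance = 1e-12)
  expect_equal(residual_corr_for_target(0.03, 0.03, 0.8, 0.29), 0.2742, tolerance = 1e-3)
  expect_equal(residual_corr_for_target(0, 0, 0, 0.29), 0.29)
  expect_equal(residual_corr_for_target(0.2, 0.2, 0.5, 0.5 * 0.2), 0)
  expect_error(residual_corr_for_target(0.9, 0.9, -1, 0.9), "unreachable")
})

test_that("simulation is bit-reproducible from the config seed", {
  cfg <- small_cfg(seed = 33)
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a, b)
  other <- simulate_cohort(small_cfg(seed = 34), 1)
  expect_false(identical(a$genotypes, other$genotypes))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$spec$r_p, s2$spec$r_p)
})

test_that("true effects are shared across cohorts of one study", {
  cfg <- sim_config(n_cohorts = 2, n_individuals = 300, m_snps = 100, seed = 2)
  c1 <- simulate_cohort(cfg, 1)
  c2 <- simulate_cohort(cfg, 2)
  expect_identical(c1$truth$beta, c2$truth$beta)
  expect_identical(c1$maf, c2$maf)
  expect_false(identical(c1$genotypes, c2$genotypes))
})

test_that("null GWAS chi-square statistics are calibrated", {
  cfg <- sim_config(n_cohorts = 1, n_individuals = 1500, m_snps = 4000,
                    raters = "mother", assessed_frac = 1, h2 = 0, seed = 9)
  cd <- simulate_cohort(cfg, 1)
  ss <- run_stratum_gwas(cd, "mother")
  expect_equal(mean(ss$z^2), 1, tolerance = 0.05)
})

test_that("the realized phenotype correlation hits the target in shared individuals", {
  cfg <- sim_config(n_cohorts = 1, n_individuals = 5000, m_snps = 200,
                    raters = c("mother", "teacher"), assessed_frac = 1,
                    h2 = 0.03, rg = 0.8, rp_target = 0.29, seed = 10)
  cd <- simulate_cohort(cfg, 1)
  r <- cor(cd$phenotypes[, "mother"], cd$phenotypes[, "teacher"])
  expect_lt(abs(r - 0.29), 0.03)  # sampling-error bound at n = 5000
})

test_that("a constant phenotype yields all-zero Z scores", {
  cfg <- small_cfg(h2 = 0, seed = 5)
  cd <- simulate_cohort(cfg, 1)
  cd$phenotypes[, "mother"] <- 1
  ss <- run_stratum_gwas(cd, "mother")
  expect_true(all(ss$z == 0))
  expect_error(run_stratum_gwas(cd, "self"), "not assessed")
})

test_that("a single strong causal SNP attains the largest chi-square", {
  cfg <- sim_config(n_cohorts = 1, n_individuals = 4000, m_snps = 500,
                    raters = "mother", assessed_frac = 1,
                    h2 = 0.25, k_causal = 1, seed = 12)
  cd <- simulate_cohort(cfg, 1)
  ss <- run_stratum_gwas(cd, "mother")
  expect_equal(which.max(abs(ss$z)), which(cd$truth$causal))
})

test_that("stratum GWAS output round-trips the io and harmonization layers unchanged", {
  cfg <- small_cfg(seed = 20)
  cd <- simulate_cohort(cfg, 1)
  ss <- run_stratum_gwas(cd, "mother")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, tf)
  back <- read_sumstats(tf, ss$stratum_id[1])
  expect_equal(back$z, ss$z, tolerance = 1e-12)
  harm <- harmonize_sumstats(list(a = ss, b = back))
  expect_equal(harm$b$z, ss$z, tolerance = 1e-12)
  expect_equal(attr(harm, "harmonize_log")$n_dropped_mismatch, c(0L, 0L))
})

test_that("mask bookkeeping reproduces exact overlap counts and correlations", {
  cfg <- sim_config(n_cohorts = 2, n_individuals = 2000, m_snps = 50,
                    raters = c("mother", "teacher"), assessed_frac = 0.5, seed = 21)
  cohorts <- purrr::map(1:2, ~ simulate_cohort(cfg, .x))
  sp <- overlap_spec_from_masks(cohorts)
  expect_equal(nrow(validate_overlap_spec(sp)), 0L)
  cd <- cohorts[[1]]
  shared <- cd$masks[, "mother"] & cd$masks[, "teacher"]
  expect_equal(sp$n_s["cohort1_mother", "cohort1_teacher"], sum(shared))
  expect_equal(sp$r_p["cohort1_mother", "cohort1_teacher"],
               cor(cd$phenotypes[shared, "mother"], cd$phenotypes[shared, "teacher"]))
  # cross-cohort entries are zero by construction
  expect_equal(sp$n_s["cohort1_mother", "cohort2_mother"], 0)
  expect_equal(sp$r_p["cohort1_mother", "cohort2_teacher"], 0)
  # disjoint and identical subsets as limiting cases
  cd2 <- cd
  cd2$masks[, "mother"] <- rep(c(TRUE, FALSE), length.out = 2000)
  cd2$masks[, "teacher"] <- !cd2$masks[, "mother"]
  sp2 <- overlap_spec_from_masks(list(cd2))
  expect_equal(sp2$n_s[1, 2], 0)
  expect_equal(sp2$r_p[1, 2], 0)
  cd3 <- cd
  cd3$masks[, "teacher"] <- cd3$masks[, "mother"]
  cd3$phenotypes[, "teacher"] <- cd3$phenotypes[, "mother"]
  sp3 <- overlap_spec_from_masks(list(cd3))
  expect_equal(sp3$n_s[1, 2], sum(cd3$masks[, "mother"]))
  expect_equal(sp3$r_p[1, 2], 1)
})

test_that("masks + expected CTI give a combined statistic with unit null variance", {
  cfg <- sim_config(n_cohorts = 2, n_individuals = 1500, m_snps = 3000,
                    h2 = 0, seed = 23)
  sim <- simulate_study(cfg)
  res <- run_meta(sim$tables, sim$meta, sim$spec)
  expect_equal(var(res$z_multi), 1, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(assessed_frac = 0), "assessed_frac")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(raters = c("mother", "mother")), "unique")
  expect_error(sim_config(h2 = 0.5, rg = 0, rp_target = 0.9), "residual")
})
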