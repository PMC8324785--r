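test_that("univariate regression recovers null, polygenic and confounded models", {
  withr::local_seed(8)
  ld <- simulate_ld_profile(3000)
  # null: no heritability, no confounding
  f0 <- univariate_ldsc(simulate_ldsc_sumstats(ld, 50000, 0), ld)
  expect_lt(abs(f0$h2), 2 * f0$h2_se)
  expect_lt(abs(f0$intercept - 1), 2 * f0$intercept_se)
  # polygenic signal at the published scale
  f1 <- univariate_ldsc(simulate_ldsc_sumstats(ld, 50000, 0.03), ld)
  expect_lt(abs(f1$h2 - 0.03), 2 * f1$h2_se)
  expect_gt(f1$h2 / f1$h2_se, 4)
  expect_gt(f1$mean_chi2, 1)
  # uniform inflation loads on the intercept, not the slope
  f2 <- univariate_ldsc(simulate_ldsc_sumstats(ld, 50000, 0.03, intercept = 1.05), ld)
  expect_lt(abs(f2$intercept - 1.05), 2 * f2$intercept_se)
  expect_lt(abs(f2$h2 - 0.03), 2 * f2$h2_se)
})

test_that("intercept estimates are unbiased over replicates of a clean model", {
  withr::local_seed(9)
  ints <- replicate(50, {
    ld <- simulate_ld_profile(1000)
    univariate_ldsc(simulate_ldsc_sumstats(ld, 50000, 0.02), ld)$intercept
  })
  expect_lt(abs(mean(ints) - 1), 0.02)
})

test_that("regression degenerates are rejected or repaired", {
  withr::local_seed(10)
  ld_const <- ld_profile(sprintf("snp%d", 1:300), rep(2, 300))
  ss <- simulate_ldsc_sumstats(ld_const, 1000, 0.1)
  expect_error(univariate_ldsc(ss, ld_const), "zero variance")
  ld <- simulate_ld_profile(250)
  ss <- simulate_ldsc_sumstats(ld, 1000, 0.1)
  expect_warning(f <- univariate_ldsc(ss, ld, n_blocks = 300), "fewer SNPs")
  expect_equal(f$n_blocks, 250)
  expect_error(univariate_ldsc(ss[1:150, ], ld), "at least 200")
})

test_that("identical traits in independent samples have rg near 1", {
  withr::local_seed(12)
  ld <- simulate_ld_profile(3000)
  z <- simulate_ldsc_sumstats(ld, 30000, 0.05)
  f <- bivariate_ldsc(z, z, ld)
  expect_lt(abs(f$rg - 1), 2 * max(f$rg_se, 1e-3))
})

test_that("cross-trait regression recovers the generative rg", {
  withr::local_seed(13)
  ld <- simulate_ld_profile(3000)
  pair <- simulate_ldsc_pair(ld, 50000, 50000, 0.05, 0.05, rg = 0.81)
  f <- bivariate_ldsc(pair[[1]], pair[[2]], ld)
  expect_lt(abs(f$rg - 0.81), 2 * f$rg_se)
  expect_gt(f$rg, 0.5)
})

test_that("sample overlap and pleiotropy are separated by the free intercept", {
  withr::local_seed(14)
  ld <- simulate_ld_profile(3000)
  pair <- simulate_ldsc_pair(ld, 20000, 20000, 0.05, 0.05, rg = 0, cti = 0.2)
  f <- bivariate_ldsc(pair[[1]], pair[[2]], ld)
  expect_lt(abs(f$rg), 2 * f$rg_se)
  expect_lt(abs(f$cti_hat - 0.2), 2 * f$cti_se)
  # fixing the intercept at the known overlap gives the same conclusion
  ff <- bivariate_ldsc(pair[[1]], pair[[2]], ld, n_s = 0.2 * 20000, r_p = 1,
                       intercept = "fixed")
  expect_lt(abs(ff$rg), 3 * ff$rg_se)
  expect_equal(ff$cti_hat, 0.2, tolerance = 1e-10)
})

test_that("rg is invariant to consistent rescaling of one trait's Z and N", {
  withr::local_seed(15)
  ld <- simulate_ld_profile(3000)
  pair <- simulate_ldsc_pair(ld, 40000, 40000, 0.04, 0.04, rg = 0.6)
  f1 <- bivariate_ldsc(pair[[1]], pair[[2]], ld)
  scaled <- pair[[2]]
  scaled$z <- 2 * scaled$z
  scaled$n <- 4 * scaled$n
  f2 <- bivariate_ldsc(pair[[1]], scaled, ld)
  # invariance is exact up to the heteroscedasticity weights, whose model
  # pins the intercept at 1 and so shifts slightly under rescaling
  expect_equal(f2$rg, f1$rg, tolerance = 0.01)
})

test_that("the heritability Z-score gate is inclusive at 4", {
  mk <- function(h2, se) structure(list(h2 = h2, h2_se = se), class = "ldsc_fit")
  expect_true(rg_gate(mk(0.04, 0.01)))
  expect_false(rg_gate(mk(0.039, 0.01)))
  # the under-powered father-report regime is excluded
  expect_false(rg_gate(mk(0.04, 0.03)))
  expect_error(rg_gate(mk(0.04, 0)), "positive h2_se")
})

test_that("rg_matrix fits all gated pairs and records exclusions", {
  withr::local_seed(16)
  ld <- simulate_ld_profile(2000)
  sigs <- list(mother = 0.06, teacher = 0.06, self = 0.06, father = 0)
  results <- purrr::imap(sigs, function(h2, nm) simulate_ldsc_sumstats(ld, 40000, h2))
  out <- rg_matrix(results, ld)
  expect_equal(out$excluded, "father")
  expect_equal(nrow(out$rg), 3L)   # 3 gated strata -> 3 pairs
  expect_setequal(out$univariate$stratum_id, names(sigs))
  expect_equal(sum(out$univariate$gated), 3L)
})

test_that("jackknife SEs give near-nominal coverage on the null", {
  withr::local_seed(17)
  hits <- replicate(200, {
    ld <- simulate_ld_profile(800)
    f <- univariate_ldsc(simulate_ldsc_sumstats(ld, 20000, 0), ld)
    abs(f$h2) <= qnorm(0.975) * f$h2_se
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 1.00)
})

test_that("fits tidy into broom-style frames", {
  withr::local_seed(18)
  ld <- simulate_ld_profile(1500)
  f <- univariate_ldsc(simulate_ldsc_sumstats(ld, 30000, 0.03), ld)
  td <- tidy(f)
  expect_equal(td$term, c("h2", "intercept"))
  expect_true(all(td$std.error > 0))
  expect_equal(glance(f)$n_snps, 1500)
  pair <- simulate_ldsc_pair(ld, 30000, 30000, 0.05, 0.05, 0.7)
  fr <- bivariate_ldsc(pair[[1]], pair[[2]], ld)
  expect_equal(tidy(fr)$term, c("rg", "cti"))
  expect_equal(glance(fr)$n_blocks, 200)
})

test_that("LD profiles round-trip through the file format", {
  ld <- simulate_ld_profile(300, snp_ids = sprintf("rs%d", 1:300))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ld_profile(ld, tf)
  back <- read_ld_profile(tf)
  expect_equal(back$ld_score, ld$ld_score)
  expect_equal(attr(back, "m"), 300)
})
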