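test_that("weights are sqrt(N * h2) with the expected symmetries", {
  expect_equal(snp_weights(c(100, 100), 0.03), rep(sqrt(3), 2))
  w <- snp_weights(c(400, 100), 0.03)
  expect_equal(w[1] / w[2], 2)
  expect_equal(snp_weights(c(100, 400), c(0.04, 0.01)), rep(2, 2))
  expect_error(snp_weights(c(100, 100), c(0.03, 0)), "uniform")
})

test_that("meta_z reduces to the single-stratum Z and the independent case", {
  expect_equal(meta_z(1.7, 3.2, matrix(1)), 1.7)
  expect_equal(meta_z(c(1, 1), c(1, 1), diag(2)), sqrt(2))
  # hand-evaluated quadratic form with correlated strata
  expect_equal(meta_z(c(2, 1), c(1, 1), matrix(c(1, 0.29, 0.29, 1), 2)),
               3 / sqrt(2 + 2 * 0.29), tolerance = 1e-12)
})

test_that("gls form is weight-scale invariant; literal form matches it at unit weights", {
  withr::local_seed(4)
  cti <- matrix(c(1, 0.3, 0.3, 1), 2)
  z <- rnorm(2); w <- runif(2, 0.5, 3)
  expect_equal(meta_z(z, w, cti), meta_z(z, 10 * w, cti), tolerance = 1e-12)
  expect_equal(meta_z(z, c(1, 1), cti, form = "as_printed"),
               meta_z(z, c(1, 1), cti, form = "gls"), tolerance = 1e-12)
  expect_error(meta_z(c(1, 1), c(1, 1), matrix(c(1, 2, 2, 1), 2)), "semi-definite")
})

test_that("the combined null statistic has unit variance under a correct CTI", {
  withr::local_seed(5)
  corr <- matrix(c(1, 0.145, 0, 0,
                   0.145, 1, 0, 0,
                   0, 0, 1, 0.145,
                   0, 0, 0.145, 1), 4)
  z <- rmvn_corr(100000, corr)
  w <- snp_weights(rep(1000, 4), 0.03)
  zm <- drop(z %*% w) / sqrt(drop(crossprod(w, corr %*% w)))
  expect_equal(var(zm), 1, tolerance = 0.02)
  # ignoring the overlap inflates the variance detectably
  zm_naive <- drop(z %*% w) / sqrt(sum(w^2))
  expect_gt(var(zm_naive), 1.05)
})

test_that("run_meta on a single stratum returns the input Z scores", {
  tbl <- make_sumstats(z = c(1.2, -0.5, 0.8))
  meta <- make_meta_tbl("s1", "c1")
  sp <- overlap_spec("s1", matrix(1000), matrix(1))
  res <- run_meta(list(s1 = tbl), meta, sp)
  expect_s3_class(res, "meta_result")
  expect_equal(res$z_multi, tbl$z)
  expect_equal(res$n_eff, rep(1000, 3))
  expect_equal(res$n_strata, rep(1L, 3))
})

test_that("two independent equal-weight strata combine classically", {
  t1 <- make_sumstats("s1", z = 1)
  t2 <- make_sumstats("s2", z = 1)
  meta <- make_meta_tbl(c("s1", "s2"), c("c1", "c2"))
  sp <- overlap_spec(c("s1", "s2"), diag(c(1000, 1000)), diag(2),
                     cohort_ids = c("c1", "c2"))
  res <- run_meta(list(s1 = t1, s2 = t2), meta, sp)
  expect_equal(res$z_multi, rep(sqrt(2), 3))
  expect_equal(res$n_eff, rep(2000, 3))
  expect_equal(res$n_cohorts, rep(2L, 3))
  expect_equal(res$direction, rep("++", 3))
})

test_that("a near-duplicate stratum adds (almost) nothing", {
  t1 <- make_sumstats("s1", z = c(2, -1.3, 0.4))
  t2 <- t1; t2$stratum_id <- "s2"
  meta <- make_meta_tbl(c("s1", "s2"), "c1")
  sp <- spec2(n_s = 1000, r_p = 0.999)
  res <- run_meta(list(s1 = t1, s2 = t2), meta, sp)
  expect_equal(res$z_multi, t1$z, tolerance = 0.01)
  expect_equal(res$n_eff, rep(1000, 3), tolerance = 0.01)
  expect_equal(res$n_cohorts, rep(1L, 3))
})

test_that("SNPs carried by a subset of strata use the submatrix", {
  t1 <- make_sumstats("s1", snp_id = c("rs1", "rs2"), a1 = "A", a2 = "G",
                      z = c(1, 2), eaf = 0.2)
  t2 <- make_sumstats("s2", snp_id = "rs1", a1 = "A", a2 = "G", z = 1, eaf = 0.4)
  meta <- make_meta_tbl(c("s1", "s2"), c("c1", "c2"))
  sp <- overlap_spec(c("s1", "s2"), diag(c(1000, 1000)), diag(2))
  res <- run_meta(list(s1 = t1, s2 = t2), meta, sp)
  expect_equal(res$z_multi[res$snp_id == "rs1"], sqrt(2))
  expect_equal(res$z_multi[res$snp_id == "rs2"], 2)
  expect_equal(res$direction[res$snp_id == "rs2"], "+.")
  expect_equal(res$n_strata[res$snp_id == "rs2"], 1L)
  # meta_eaf is sample-size weighted
  expect_equal(res$meta_eaf[res$snp_id == "rs1"], 0.3)
  expect_error(run_meta(list(s1 = t1, s2 = t2), meta, sp, subset = "s3"),
               "missing from the overlap spec")
})

test_that("post_filter enforces the three published rules exactly", {
  res <- tibble::tibble(
    snp_id = sprintf("rs%d", 1:6),
    meta_eaf = c(0.5, 0.995, 0.2, 0.5, 0.005, 0.009),
    z_multi = 1, p = 0.3,
    n_eff = c(20000, 20000, 14999, 20000, 20000, 15000),
    n_strata = 2L,
    n_cohorts = c(2L, 2L, 2L, 1L, 2L, 2L))
  out <- post_filter(res)
  expect_equal(out$result$snp_id, "rs1")
  expect_equal(unname(out$counts), c(3L, 1L, 1L, 1L))  # maf, neff, cohorts, retained
  # idempotent
  again <- post_filter(out$result)
  expect_identical(again$result, out$result)
  expect_equal(unname(again$counts[["retained"]]), 1L)
})

test_that("Benjamini-Hochberg flags match the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_fdr(0.049), TRUE)
  expect_equal(bh_fdr(numeric()), logical())
  # mixed case, thresholds i * alpha / m
  p <- c(0.001, 0.012, 0.04, 0.9)
  expect_equal(bh_fdr(p), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})
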