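# in-code fixtures shared across test files

make_sumstats <- function(stratum_id = "s1",
                          snp_id = c("rs1", "rs2", "rs3"),
                          a1 = c("A", "C", "A"),
                          a2 = c("G", "T", "T"),
                          eaf = c(0.2, 0.3, 0.25),
                          z = c(1.2, -0.5, 0.8),
                          n = 1000) {
  k <- length(snp_id)
  tibble::tibble(stratum_id = stratum_id, snp_id = snp_id,
                 chrom = "1", pos = seq_len(k) * 1000L,
                 a1 = a1, a2 = a2,
                 eaf = rep_len(eaf, k), z = rep_len(z, k), n = rep_len(n, k))
}

write_sumstats_file <- function(tbl, path) {
  out <- tbl[, c("snp_id", "chrom", "pos", "a1", "a2", "eaf", "z", "n")]
  names(out) <- c("SNP", "CHR", "POS", "A1", "A2", "EAF", "Z", "N")
  readr::write_tsv(out, path, progress = FALSE)
  path
}

make_meta_tbl <- function(stratum_id, cohort_id, rater = "mother",
                          instrument = "ASEBA", mean_age = 10, n_obs = 1000) {
  tibble::tibble(stratum_id = stratum_id, cohort_id = cohort_id,
                 rater = rep_len(rater, length(stratum_id)),
                 instrument = rep_len(instrument, length(stratum_id)),
                 mean_age = rep_len(mean_age, length(stratum_id)),
                 n_obs = rep_len(n_obs, length(stratum_id)))
}

# two-stratum overlap spec with configurable overlap and correlation
spec2 <- function(n_obs = c(1000, 1000), n_s = 500, r_p = 0.29,
                  ids = c("s1", "s2")) {
  overlap_spec(ids,
               matrix(c(n_obs[1], n_s, n_s, n_obs[2]), 2),
               matrix(c(1, r_p, r_p, 1), 2))
}

# multivariate normal draws with given correlation, for null-calibration checks
rmvn_corr <- function(n, corr) {
  ev <- eigen(corr, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n * nrow(corr)), n) %*% root
}
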