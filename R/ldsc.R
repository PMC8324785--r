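#' LD-score profile
#'
#' Per-SNP LD scores plus the total SNP count `M` used as the polygenicity
#' denominator in the regression.
#'
#' @param snp_id Character vector of SNP ids.
#' @param ld_score Non-negative numeric vector of LD scores.
#' @param m Total SNP count M (defaults to `length(snp_id)`).
#' @return An `ld_profile` tibble with attribute `"m"`.
#' @export
ld_profile <- function(snp_id, ld_score, m = length(snp_id)) {
  if (length(snp_id) != length(ld_score)) abort("snp_id and ld_score lengths differ")
  if (any(ld_score < 0)) abort("LD scores must be non-negative")
  if (m <= 0) abort("M must be positive")
  out <- tibble::tibble(snp_id = as.character(snp_id), ld_score = as.numeric(ld_score))
  attr(out, "m") <- m
  class(out) <- c("ld_profile", class(out))
  out
}

#' Read an LD-score profile (TSV with SNP and L2 columns, `# M=` header)
#'
#' @param path TSV path; an optional first comment line `# M=<count>`
#'   supplies the polygenicity denominator, else the row count is used.
#' @return An [ld_profile()].
#' @export
read_ld_profile <- function(path) {
  first <- readLines(path, n = 1L)
  m <- NA_real_
  if (grepl("^#", first)) {
    m <- suppressWarnings(as.numeric(sub("^#\\s*M\\s*=\\s*", "", first)))
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  nm <- toupper(names(tbl))
  snp_col <- which(nm %in% c("SNP", "SNP_ID", "RSID"))[1]
  ld_col <- which(nm %in% c("L2", "LD_SCORE", "LDSCORE"))[1]
  if (is.na(snp_col) || is.na(ld_col)) abort("LD profile needs SNP and L2 columns")
  ld_profile(tbl[[snp_col]], tbl[[ld_col]],
             m = if (is.finite(m)) m else nrow(tbl))
}

#' Write an LD-score profile
#' @param ld An [ld_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_profile <- function(ld, path) {
  writeLines(paste0("# M=", attr(ld, "m")), path)
  readr::write_tsv(tibble::tibble(SNP = ld$snp_id, L2 = ld$ld_score), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Simulate an LD-score profile
#'
#' Draws `l = 1 + Gamma(shape, scale)` scores (long right tail, minimum 1,
#' loosely mimicking genome-wide LD-score distributions). With
#' `mean_one = TRUE` the scores are rescaled to mean 1, the normalisation
#' under which the genotype-level simulator's per-SNP effect variances
#' reproduce the canonical LDSC regression slope (see the methods
#' vignette).
#'
#' @param m Number of SNPs (and polygenicity denominator M).
#' @param shape,scale Gamma parameters of the spread above 1.
#' @param mean_one Rescale scores to mean 1.
#' @param snp_ids Optional SNP ids (default `snp00001`, ...).
#' @return An [ld_profile()].
#' @export
simulate_ld_profile <- function(m, shape = 2, scale = 10, mean_one = FALSE,
                                snp_ids = NULL) {
  l <- 1 + rgamma(m, shape = shape, scale = scale)
  if (mean_one) l <- l / mean(l)
  ld_profile(snp_ids %||% sprintf("snp%05d", seq_len(m)), l, m = m)
}

# weighted simple-regression sufficient statistics, optionally per block
wls_sums <- function(x, y, w, block) {
  agg <- function(v) as.numeric(rowsum(v, block, reorder = TRUE))
  list(sw = agg(w), swx = agg(w * x), swy = agg(w * y),
       swxx = agg(w * x * x), swxy = agg(w * x * y))
}

wls_coef <- function(s, drop_block = 0L) {
  pick <- function(v) if (drop_block > 0L) sum(v[-drop_block]) else sum(v)
  sw <- pick(s$sw); swx <- pick(s$swx); swy <- pick(s$swy)
  swxx <- pick(s$swxx); swxy <- pick(s$swxy)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  c(intercept = (swy - slope * swx) / sw, slope = slope)
}

jackknife_se <- function(est_blocks) {
  b <- nrow(est_blocks)
  ctr <- colMeans(est_blocks)
  sqrt((b - 1) / b * colSums((est_blocks - rep(ctr, each = b))^2))
}

align_ldsc_input <- function(tbl, ld) {
  z <- tbl[["z_multi"]] %||% tbl[["z"]]
  n <- tbl[["n_eff"]] %||% tbl[["n"]]
  if (is.null(z) || is.null(n)) abort("input needs z/z_multi and n/n_eff columns")
  d <- tibble::tibble(snp_id = tbl$snp_id, z = z, n = n)
  d <- dplyr::inner_join(d, ld[, c("snp_id", "ld_score")], by = "snp_id")
  if (nrow(d) < 200L) abort("LD-score regression requires at least 200 aligned SNPs")
  d
}

make_blocks <- function(n_snps, n_blocks) {
  if (n_blocks > n_snps) {
    warn(paste0("fewer SNPs (", n_snps, ") than jackknife blocks (", n_blocks,
                "); reducing the block count"))
    n_blocks <- n_snps
  }
  list(block = ceiling(seq_len(n_snps) / (n_snps / n_blocks)), n_blocks = n_blocks)
}

#' Univariate LD-score regression (heritability and intercept)
#'
#' Weighted least squares of the per-SNP chi-square statistic on
#' `N * l / M` with a free intercept: the slope estimates the
#' SNP-heritability and the intercept captures confounding inflation
#' (1 under a clean polygenic model). Heteroscedasticity weights
#' `1 / (2 * (1 + N * h2_0 * l / M)^2)` come from a one-step pre-fit;
#' standard errors are delete-a-block jackknife over contiguous blocks.
#'
#' @param tbl Summary statistics: a tibble with `snp_id` and either
#'   `z`/`n` or (for meta-analysis output) `z_multi`/`n_eff`.
#' @param ld An [ld_profile()].
#' @param n_blocks Jackknife block count (default 200).
#' @return An `ldsc_fit` with fields `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `mean_chi2`, `n_blocks`, `n_snps`, `m`.
#' @export
univariate_ldsc <- function(tbl, ld, n_blocks = 200) {
  d <- align_ldsc_input(tbl, ld)
  m <- attr(ld, "m")
  if (sd(d$ld_score) == 0) abort("LD scores have zero variance; the regression is unidentified")
  x <- d$n * d$ld_score / m
  y <- d$z^2
  bl <- make_blocks(nrow(d), n_blocks)
  # one-step pre-fit for the heteroscedasticity weights
  pre <- wls_coef(wls_sums(x, y, rep(1, length(x)), bl$block))
  h2_0 <- min(max(pre[["slope"]], 0), 1)
  w <- 1 / (2 * (1 + h2_0 * x)^2)
  s <- wls_sums(x, y, w, bl$block)
  est <- wls_coef(s)
  loo <- t(vapply(seq_len(bl$n_blocks), function(b) wls_coef(s, b), numeric(2)))
  se <- jackknife_se(loo)
  structure(list(h2 = est[["slope"]], h2_se = se[["slope"]],
                 intercept = est[["intercept"]], intercept_se = se[["intercept"]],
                 mean_chi2 = mean(y), n_blocks = bl$n_blocks,
                 n_snps = nrow(d), m = m),
            class = "ldsc_fit")
}

#' Cross-trait LD-score regression (genetic correlation)
#'
#' Regresses the per-SNP product `z1 * z2` on `sqrt(N1 * N2) * l / M`; the
#' slope estimates the genetic covariance and the intercept the cross-trait
#' intercept (sample-overlap term `N_s * r_p / sqrt(N1 * N2)`). The genetic
#' correlation is the slope divided by `sqrt(h2_1 * h2_2)` from companion
#' univariate fits, jackknifed jointly with them, and is deliberately not
#' truncated to \[-1, 1\].
#'
#' @param tbl1,tbl2 Summary statistics for the two traits (see
#'   [univariate_ldsc()] for accepted columns).
#' @param ld An [ld_profile()].
#' @param n_s,r_p Known sample overlap and phenotypic correlation, used
#'   when `intercept = "fixed"` to pin the intercept at its expected value.
#' @param intercept `"free"` (estimate) or `"fixed"`.
#' @param n_blocks Jackknife block count.
#' @return An `rg_fit` with fields `rg`, `rg_se`, `cti_hat`, `cti_se`,
#'   `rho_g`, `h2_1`, `h2_2`, `n_blocks`, `n_snps`.
#' @export
bivariate_ldsc <- function(tbl1, tbl2, ld, n_s = 0, r_p = 0,
                           intercept = c("free", "fixed"), n_blocks = 200) {
  intercept <- match.arg(intercept)
  d1 <- align_ldsc_input(tbl1, ld)
  d2 <- align_ldsc_input(tbl2, ld)
  d <- dplyr::inner_join(d1, d2, by = c("snp_id", "ld_score"),
                         suffix = c("1", "2"))
  if (nrow(d) < 200L) abort("fewer than 200 SNPs shared between the two traits")
  m <- attr(ld, "m")
  # companion univariate fits on the shared SNP set, sharing the jackknife blocks
  dj1 <- tibble::tibble(snp_id = d$snp_id, z = d$z1, n = d$n1, ld_score = d$ld_score)
  dj2 <- tibble::tibble(snp_id = d$snp_id, z = d$z2, n = d$n2, ld_score = d$ld_score)
  fit1 <- univariate_ldsc(dj1, ld, n_blocks)
  fit2 <- univariate_ldsc(dj2, ld, n_blocks)
  if (fit1$h2 <= 0 || fit2$h2 <= 0) {
    abort("genetic correlation undefined: a univariate h2 estimate is non-positive")
  }
  x <- sqrt(d$n1 * d$n2) * d$ld_score / m
  y <- d$z1 * d$z2
  cti_expected <- n_s * r_p / sqrt(d$n1 * d$n2)
  bl <- make_blocks(nrow(d), n_blocks)
  pre <- wls_coef(wls_sums(x, y, rep(1, length(x)), bl$block))
  rho_0 <- pre[["slope"]]
  v1 <- 1 + fit1$h2 * d$n1 * d$ld_score / m
  v2 <- 1 + fit2$h2 * d$n2 * d$ld_score / m
  w <- 1 / (v1 * v2 + (mean(cti_expected) + rho_0 * x)^2)

  h2s1 <- univariate_block_sums(dj1, ld, bl)
  h2s2 <- univariate_block_sums(dj2, ld, bl)
  if (intercept == "fixed") {
    y_adj <- y - cti_expected
    s <- wls_sums(x, y_adj, w, bl$block)
    slope_of <- function(drop) {
      pick <- function(v) if (drop > 0L) sum(v[-drop]) else sum(v)
      pick(s$swxy) / pick(s$swxx)  # through-the-origin WLS
    }
    est_rho <- slope_of(0L)
    cti_hat <- mean(cti_expected); cti_blocks <- rep(cti_hat, bl$n_blocks)
    rho_blocks <- vapply(seq_len(bl$n_blocks), slope_of, numeric(1))
  } else {
    s <- wls_sums(x, y, w, bl$block)
    est <- wls_coef(s)
    est_rho <- est[["slope"]]; cti_hat <- est[["intercept"]]
    loo <- t(vapply(seq_len(bl$n_blocks), function(b) wls_coef(s, b), numeric(2)))
    rho_blocks <- loo[, "slope"]; cti_blocks <- loo[, "intercept"]
  }
  rg_of <- function(rho, h2a, h2b) rho / sqrt(pmax(h2a, 1e-12) * pmax(h2b, 1e-12))
  rg <- rg_of(est_rho, fit1$h2, fit2$h2)
  rg_blocks <- vapply(seq_len(bl$n_blocks), function(b) {
    rg_of(rho_blocks[b], wls_coef(h2s1, b)[["slope"]], wls_coef(h2s2, b)[["slope"]])
  }, numeric(1))
  se <- jackknife_se(cbind(rg = rg_blocks, cti = cti_blocks))
  structure(list(rg = rg, rg_se = se[["rg"]],
                 cti_hat = cti_hat, cti_se = se[["cti"]],
                 rho_g = est_rho, h2_1 = fit1$h2, h2_2 = fit2$h2,
                 n_blocks = bl$n_blocks, n_snps = nrow(d)),
            class = "rg_fit")
}

# weighted sufficient statistics of a univariate fit, reusing its own
# one-step weights, for joint jackknifing inside bivariate_ldsc
univariate_block_sums <- function(d, ld, bl) {
  m <- attr(ld, "m")
  x <- d$n * d$ld_score / m
  y <- d$z^2
  pre <- wls_coef(wls_sums(x, y, rep(1, length(x)), bl$block))
  h2_0 <- min(max(pre[["slope"]], 0), 1)
  wls_sums(x, y, 1 / (2 * (1 + h2_0 * x)^2), bl$block)
}

#' Heritability Z-score gate for genetic-correlation analyses
#'
#' A stratum's meta-analysis enters pairwise genetic-correlation estimation
#' only when the Z score of its SNP-heritability (`h2 / SE`) is 4 or
#' higher; under-powered strata (e.g. a fit with h2 = 0.04, SE = 0.03,
#' Z ~ 1.3) are excluded.
#'
#' @param fit An `ldsc_fit`.
#' @return `TRUE` iff `h2 / h2_se >= 4`.
#' @export
rg_gate <- function(fit) {
  if (!is.finite(fit$h2) || !is.finite(fit$h2_se) || fit$h2_se <= 0) {
    abort("rg_gate requires finite h2 and positive h2_se")
  }
  fit$h2 / fit$h2_se >= 4
}

#' Pairwise genetic correlations across gated strata
#'
#' Fits univariate LDSC per stratum, applies [rg_gate()], and estimates the
#' genetic correlation for every pair of gated strata (free intercept).
#'
#' @param results Named list of per-stratum summary statistics or
#'   meta-analysis results.
#' @param ld An [ld_profile()].
#' @param n_blocks Jackknife block count.
#' @return List with `rg` (tibble: `stratum_1`, `stratum_2`, `rg`, `rg_se`,
#'   `cti_hat`), `univariate` (tibble of per-stratum `h2`, `h2_se`, `h2_z`,
#'   `gated`), and `excluded` (character vector of gated-out strata).
#' @export
rg_matrix <- function(results, ld, n_blocks = 200) {
  stopifnot(!is.null(names(results)))
  fits <- purrr::map(results, univariate_ldsc, ld = ld, n_blocks = n_blocks)
  uni <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(stratum_id = nm, h2 = f$h2, h2_se = f$h2_se,
                   h2_z = f$h2 / f$h2_se, gated = rg_gate(f))
  })
  gated <- uni$stratum_id[uni$gated]
  pairs <- if (length(gated) >= 2L) utils::combn(gated, 2L, simplify = FALSE) else list()
  rg <- purrr::map_dfr(pairs, function(pr) {
    f <- bivariate_ldsc(results[[pr[1]]], results[[pr[2]]], ld,
                        intercept = "free", n_blocks = n_blocks)
    tibble::tibble(stratum_1 = pr[1], stratum_2 = pr[2],
                   rg = f$rg, rg_se = f$rg_se, cti_hat = f$cti_hat)
  })
  if (nrow(rg) == 0L) {
    rg <- tibble::tibble(stratum_1 = character(), stratum_2 = character(),
                         rg = numeric(), rg_se = numeric(), cti_hat = numeric())
  }
  list(rg = rg, univariate = uni, excluded = setdiff(uni$stratum_id, gated))
}

#' Simulate summary statistics directly from the LDSC model
#'
#' Draws `z_j ~ Normal(0, sqrt(intercept + N * h2 * l_j / M))`, the
#' marginal model under which LD-score regression is exactly calibrated.
#' Useful for recovery tests without genotype-level simulation.
#'
#' @param ld An [ld_profile()].
#' @param n Sample size (scalar or per-SNP).
#' @param h2 True SNP-heritability.
#' @param intercept True intercept (1 = no confounding; e.g. 1.05 injects
#'   uniform inflation into every chi-square statistic).
#' @return Tibble with `snp_id`, `z`, `n`.
#' @export
simulate_ldsc_sumstats <- function(ld, n, h2, intercept = 1) {
  v <- intercept + n * h2 * ld$ld_score / attr(ld, "m")
  tibble::tibble(snp_id = ld$snp_id, z = rnorm(nrow(ld), 0, sqrt(v)),
                 n = rep_len(n, nrow(ld)))
}

#' Simulate a correlated pair of traits from the cross-trait LDSC model
#'
#' Per SNP, `(z1, z2)` are bivariate normal with variances
#' `intercept_i + N_i * h2_i * l / M`, and covariance
#' `cti + sqrt(N1 * N2) * rg * sqrt(h2_1 * h2_2) * l / M`.
#'
#' @param ld An [ld_profile()].
#' @param n1,n2 Sample sizes.
#' @param h2_1,h2_2 True SNP-heritabilities.
#' @param rg True genetic correlation.
#' @param cti True cross-trait intercept (overlap term).
#' @param intercept1,intercept2 True univariate intercepts.
#' @return List of two tibbles (`snp_id`, `z`, `n`).
#' @export
simulate_ldsc_pair <- function(ld, n1, n2, h2_1, h2_2, rg, cti = 0,
                               intercept1 = 1, intercept2 = 1) {
  m <- attr(ld, "m")
  l <- ld$ld_score
  v1 <- intercept1 + n1 * h2_1 * l / m
  v2 <- intercept2 + n2 * h2_2 * l / m
  cv <- cti + sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * l / m
  u1 <- rnorm(length(l)); u2 <- rnorm(length(l))
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(pmax(v2 - cv^2 / v1, 1e-12)) * u2
  list(tibble::tibble(snp_id = ld$snp_id, z = z1, n = rep_len(n1, length(l))),
       tibble::tibble(snp_id = ld$snp_id, z = z2, n = rep_len(n2, length(l))))
}
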