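#' Per-SNP meta-analysis weights
#'
#' The weight of GWAS `i` at a SNP is `w_i = sqrt(N_i * h2_i)`, `N_i` the
#' per-SNP sample size and `h2_i` the assumed SNP-heritability of the trait
#' in that stratum. With a uniform `h2` the weights reduce to `sqrt(N)`,
#' i.e. classic sample-size weighting.
#'
#' @param n_per_snp Positive numeric P-vector of per-SNP sample sizes.
#' @param h2 Positive scalar or P-vector of per-stratum SNP-heritabilities.
#' @return A numeric P-vector of weights (named if `n_per_snp` is named).
#' @export
#' @examples
#' snp_weights(c(400, 100), 0.03)          # 2:1 ratio
#' snp_weights(c(100, 400), c(0.04, 0.01)) # equal
snp_weights <- function(n_per_snp, h2) {
  h2 <- rep_len(h2, length(n_per_snp))
  if (any(h2 <= 0)) {
    abort("all h2 values must be positive; for N-weighted meta-analysis use a uniform h2 (e.g. 0.03)")
  }
  if (any(n_per_snp <= 0)) abort("all per-SNP sample sizes must be positive")
  w <- sqrt(n_per_snp * h2)
  if (any(!is.finite(w))) abort("weights must be finite")
  w
}

#' Overlap-corrected multivariate Z statistic for one SNP
#'
#' Combines per-stratum Z scores with weights `w` under the null covariance
#' `CTI`. Two denominators are available:
#'
#' * `form = "gls"` (default): `Z = sum(w * z) / sqrt(w' CTI w)`, the
#'   variance-consistent quadratic form — under a correct CTI the statistic
#'   has unit variance under the null;
#' * `form = "as_printed"`: denominator
#'   `sqrt(sum(w * V) + sum_{i != k} sqrt(w_i w_k) CTI_ik)` with `V = 1`,
#'   the formula exactly as typeset in the source method table. It is kept
#'   for comparison; it is not scale-invariant in the weights and matches
#'   the quadratic form only when all weights equal 1.
#'
#' @param z Numeric P-vector of per-stratum Z scores.
#' @param weights Numeric P-vector from [snp_weights()].
#' @param cti P x P cross-trait-intercept matrix.
#' @param form `"gls"` or `"as_printed"`.
#' @return The combined Z score (scalar).
#' @export
#' @examples
#' meta_z(c(1, 1), c(1, 1), diag(2))  # sqrt(2)
meta_z <- function(z, weights, cti, form = c("gls", "as_printed")) {
  form <- match.arg(form)
  cti <- unclass(cti)
  p <- length(z)
  stopifnot(length(weights) == p, all(dim(cti) == p))
  ev_min <- min(eigen(cti, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) abort("CTI matrix must be positive semi-definite")
  num <- sum(weights * z)
  if (form == "gls") {
    denom2 <- drop(crossprod(weights, cti %*% weights))
  } else {
    sw <- sqrt(weights)
    cross <- outer(sw, sw) * cti
    diag(cross) <- 0
    denom2 <- sum(weights) + sum(cross)
  }
  if (denom2 <= 0) abort("non-positive variance for the combined statistic")
  num / sqrt(denom2)
}

#' Run the multivariate meta-analysis over harmonized strata
#'
#' For each SNP, restricts to the selected strata that carry it, builds the
#' per-SNP expected CTI submatrix and weights, and emits the combined Z,
#' its two-sided normal P value, the effective sample size on the same
#' submatrix, contribution counts and a per-stratum direction string
#' (`+`/`-` for the sign of the stratum's Z, `?` for present but zero,
#' `.` for a stratum not carrying the SNP; strata in `subset` order).
#'
#' @param tables Named list of *harmonized* summary-statistics tibbles (see
#'   [harmonize_sumstats()]).
#' @param meta Stratum-metadata tibble with columns `stratum_id`,
#'   `cohort_id`, `rater`, `instrument`, `mean_age`, `n_obs`.
#' @param spec An [overlap_spec()] covering at least the selected strata.
#' @param subset Character vector of stratum ids to meta-analyse
#'   (default: all strata in `tables`).
#' @param h2 Assumed per-stratum SNP-heritability for the weights: scalar
#'   or vector named by stratum id. Default 0.03.
#' @param form Passed to [meta_z()].
#' @return A `meta_result` tibble with columns `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `meta_eaf`, `z_multi`, `p`, `n_eff`, `n_strata`,
#'   `n_cohorts`, `direction`.
#' @export
run_meta <- function(tables, meta, spec, subset = NULL, h2 = 0.03,
                     form = c("gls", "as_printed")) {
  form <- match.arg(form)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) t$stratum_id[1], character(1))
  }
  subset <- subset %||% names(tables)
  if (length(subset) < 1L) abort("subset must select at least one stratum")
  missing_spec <- setdiff(subset, spec$stratum_ids)
  if (length(missing_spec) > 0L) {
    abort(paste0("strata in subset missing from the overlap spec: ",
                 paste(missing_spec, collapse = ", ")))
  }
  missing_tab <- setdiff(subset, names(tables))
  if (length(missing_tab) > 0L) {
    abort(paste0("strata in subset missing from tables: ",
                 paste(missing_tab, collapse = ", ")))
  }
  p_all <- length(subset)
  h2_vec <- if (!is.null(names(h2))) {
    if (!all(subset %in% names(h2))) abort("h2 vector must name every stratum in subset")
    unname(h2[subset])
  } else rep_len(h2, p_all)
  cohort_of <- setNames(meta$cohort_id, meta$stratum_id)

  combined <- dplyr::bind_rows(tables[subset])
  if (nrow(combined) == 0L) abort("no SNPs in the selected strata")
  sidx <- match(combined$stratum_id, subset)
  snp_ids <- unique(combined$snp_id)
  ridx <- match(combined$snp_id, snp_ids)
  nsnp <- length(snp_ids)
  zmat <- nmat <- emat <- matrix(NA_real_, nsnp, p_all)
  zmat[cbind(ridx, sidx)] <- combined$z
  nmat[cbind(ridx, sidx)] <- combined$n
  emat[cbind(ridx, sidx)] <- combined$eaf
  anno <- combined[!duplicated(combined$snp_id), c("snp_id", "chrom", "pos", "a1", "a2")]
  anno <- anno[match(snp_ids, anno$snp_id), ]

  present <- !is.na(zmat)
  # group SNPs sharing a presence pattern and per-SNP N vector: the CTI
  # submatrix, weights and N_eff are identical within a group
  key <- apply(cbind(present, nmat), 1L, paste, collapse = "\r")
  groups <- split(seq_len(nsnp), key)

  z_multi <- n_eff <- rep(NA_real_, nsnp)
  n_strata <- n_cohorts <- rep(NA_integer_, nsnp)
  for (g in groups) {
    pres <- present[g[1L], ]
    ids_g <- subset[pres]
    n_g <- nmat[g[1L], pres]
    sub_spec <- list(stratum_ids = ids_g,
                     n_s = spec$n_s[ids_g, ids_g, drop = FALSE],
                     r_p = spec$r_p[ids_g, ids_g, drop = FALSE])
    cti <- build_cti(sub_spec, n_g)
    w <- snp_weights(n_g, h2_vec[pres])
    denom2 <- if (form == "gls") {
      drop(crossprod(w, unclass(cti) %*% w))
    } else {
      sw <- sqrt(w); cross <- outer(sw, sw) * unclass(cti); diag(cross) <- 0
      sum(w) + sum(cross)
    }
    zg <- zmat[g, pres, drop = FALSE]
    z_multi[g] <- (zg %*% w) / sqrt(denom2)
    n_eff[g] <- effective_sample_size(n_g, cti)
    n_strata[g] <- length(ids_g)
    n_cohorts[g] <- length(unique(cohort_of[ids_g]))
  }
  dir_chr <- matrix(".", nsnp, p_all)
  dir_chr[present & zmat > 0] <- "+"
  dir_chr[present & zmat < 0] <- "-"
  dir_chr[present & zmat == 0] <- "?"
  direction <- apply(dir_chr, 1L, paste, collapse = "")
  meta_eaf <- rowSums(nmat * emat, na.rm = TRUE) / rowSums(nmat, na.rm = TRUE)

  out <- tibble::tibble(
    snp_id = anno$snp_id, chrom = anno$chrom, pos = anno$pos,
    a1 = anno$a1, a2 = anno$a2,
    meta_eaf = meta_eaf, z_multi = z_multi,
    p = pmax(2 * pnorm(-abs(z_multi)), .Machine$double.xmin),
    n_eff = n_eff, n_strata = n_strata, n_cohorts = n_cohorts,
    direction = direction)
  class(out) <- c("meta_result", class(out))
  attr(out, "subset") <- subset
  attr(out, "form") <- form
  out
}

#' Post-meta-analysis SNP filters
#'
#' Removes SNPs with meta-level MAF below `min_maf`, effective sample size
#' below `min_neff`, or observed in fewer than `min_cohorts` distinct
#' cohorts. A SNP is counted in the drop tally of every rule it fails.
#'
#' @param result A `meta_result` tibble from [run_meta()].
#' @param min_maf Minimum minor-allele frequency (from `meta_eaf`).
#' @param min_neff Minimum effective sample size.
#' @param min_cohorts Minimum number of distinct contributing cohorts.
#' @return A list with `result` (retained rows, same class) and `counts`
#'   (named integer vector: `maf`, `neff`, `cohorts`, `retained`).
#' @export
post_filter <- function(result, min_maf = 0.01, min_neff = 15000, min_cohorts = 2) {
  if (nrow(result) == 0L) abort("post_filter requires a non-empty meta result")
  maf <- pmin(result$meta_eaf, 1 - result$meta_eaf)
  fail_maf <- maf < min_maf
  fail_neff <- result$n_eff < min_neff
  fail_coh <- result$n_cohorts < min_cohorts
  keep <- !(fail_maf | fail_neff | fail_coh)
  counts <- c(maf = sum(fail_maf), neff = sum(fail_neff),
              cohorts = sum(fail_coh), retained = sum(keep))
  list(result = result[keep, , drop = FALSE], counts = counts)
}

#' Benjamini–Hochberg rejection flags
#'
#' Step-up false-discovery-rate control at level `alpha`; a thin wrapper
#' over [stats::p.adjust()] returning flags aligned with the input order.
#'
#' @param pvals Numeric vector of P values in (0, 1].
#' @param alpha FDR level.
#' @return Logical vector of rejections (empty input gives empty output).
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)  # all TRUE
bh_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("pvals must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH") <= alpha
}
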