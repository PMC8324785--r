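#' Configuration of the synthetic multi-cohort, multi-rater study
#'
#' Declares the generative parameters for individual-level data that the
#' per-stratum GWAS and meta-analysis layers consume: number of cohorts and
#' individuals, SNP panel, per-rater SNP-heritabilities, cross-rater genetic
#' correlations, target phenotypic correlations among raters (induced via
#' the residual correlation, see [residual_corr_for_target()]), and the
#' per-rater assessed-subset fractions that create sample overlap. All
#' randomness flows from `seed`.
#'
#' @param n_cohorts Number of independent cohorts.
#' @param n_individuals Individuals per cohort (scalar or per-cohort vector).
#' @param m_snps Number of independent SNPs.
#' @param maf_range Range the per-SNP allele frequencies are drawn from.
#' @param raters Character vector of rater labels (subset of
#'   mother/father/teacher/self, or any labels).
#' @param h2 Per-rater SNP-heritability in `[0, 1)` (scalar recycles; 0
#'   gives a null trait).
#' @param rg Cross-rater genetic-correlation matrix (scalar recycles to all
#'   off-diagonals).
#' @param rp_target Target cross-rater phenotypic correlation in shared
#'   individuals (scalar or matrix).
#' @param assessed_frac Fraction of each cohort assessed by each rater
#'   (scalar or per-rater); assessed subsets are drawn at random, so two
#'   raters share about `assessed_frac` of either one's subset.
#' @param k_causal `NULL` for an infinitesimal architecture (every SNP
#'   causal with tiny effects); an integer for a sparse one.
#' @param ld Optional [ld_profile()] (mean-1 scores) scaling per-SNP effect
#'   variances so LDSC sees the canonical regression; `NULL` gives flat
#'   `1/m` variances.
#' @param mean_age,instrument Per-rater stratum annotations used by the
#'   planner layer (recycled).
#' @param include_sex Add a balanced sex covariate (no effect) and regress
#'   it out before each GWAS.
#' @param seed Integer master seed.
#' @return A validated `sim_config`.
#' @export
sim_config <- function(n_cohorts = 2, n_individuals = 2000, m_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       raters = c("mother", "teacher"),
                       h2 = 0.03, rg = 0.8, rp_target = 0.29,
                       assessed_frac = 0.5, k_causal = NULL, ld = NULL,
                       mean_age = 10, instrument = "ASEBA",
                       include_sex = FALSE, seed = 1L) {
  r <- length(raters)
  if (anyDuplicated(raters)) abort("rater labels must be unique")
  n_individuals <- rep_len(n_individuals, n_cohorts)
  h2 <- rep_len(h2, r)
  if (any(h2 < 0 | h2 >= 1)) abort("h2 must lie in [0, 1)")
  as_corr <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == r)) abort(paste0(nm, " matrix must be raters x raters"))
      m <- x
    } else {
      m <- matrix(x, r, r)
    }
    diag(m) <- 1
    if (!isTRUE(all.equal(m, t(m)))) abort(paste0(nm, " matrix must be symmetric"))
    m
  }
  rg <- as_corr(rg, "rg")
  rp <- as_corr(rp_target, "rp_target")
  if (min(eigen(rg, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("rg matrix must be positive semi-definite")
  }
  assessed_frac <- rep_len(assessed_frac, r)
  if (any(assessed_frac <= 0 | assessed_frac > 1)) abort("assessed_frac must lie in (0, 1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5]")
  }
  if (!is.null(ld)) {
    if (nrow(ld) != m_snps) abort("ld profile must have one score per SNP")
  }
  # residual correlations implied by the phenotypic targets must be valid
  r_e <- diag(r)
  for (i in seq_len(r)) for (k in seq_len(r)) {
    if (i == k) next
    r_e[i, k] <- residual_corr_for_target(h2[i], h2[k], rg[i, k], rp[i, k])
  }
  if (min(eigen(r_e, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("implied residual-correlation matrix is not positive semi-definite; adjust rp_target/rg/h2")
  }
  structure(list(n_cohorts = n_cohorts, n_individuals = n_individuals,
                 m_snps = m_snps, maf_range = maf_range, raters = raters,
                 h2 = setNames(h2, raters), rg = rg, rp_target = rp,
                 residual_corr = r_e, assessed_frac = setNames(assessed_frac, raters),
                 k_causal = k_causal, ld = ld,
                 mean_age = setNames(rep_len(mean_age, r), raters),
                 instrument = setNames(rep_len(instrument, r), raters),
                 include_sex = include_sex, seed = as.integer(seed)),
            class = "sim_config")
}

#' Residual correlation needed to hit a target phenotypic correlation
#'
#' With standardized phenotypes `y = g + e`, `var(g) = h2`, the phenotypic
#' correlation between two raters decomposes into a genetic and a residual
#' part: `rp = rg * sqrt(h2_i * h2_k) + r_e * sqrt((1 - h2_i) * (1 - h2_k))`.
#' Solving for the residual correlation gives the value the generator must
#' use.
#'
#' @param h2_i,h2_k SNP-heritabilities of the two traits.
#' @param rg Genetic correlation between them.
#' @param rp_target Desired phenotypic correlation.
#' @return The residual correlation `r_e`.
#' @export
#' @examples
#' residual_corr_for_target(0.03, 0.03, 0.8, 0.29)  # ~0.2742
residual_corr_for_target <- function(h2_i, h2_k, rg, rp_target) {
  r_e <- (rp_target - rg * sqrt(h2_i * h2_k)) / sqrt((1 - h2_i) * (1 - h2_k))
  if (!is.finite(r_e) || abs(r_e) > 1) {
    abort(paste0("target phenotypic correlation ", rp_target,
                 " is unreachable with the given h2/rg; implied residual correlation ",
                 round(r_e, 4), " lies outside [-1, 1]"))
  }
  r_e
}

# study-level truth shared by all cohorts: per-SNP allele frequencies and
# the cross-rater effect-size matrix, drawn from the master seed only
study_truth <- function(config) {
  set.seed(config$seed)
  m <- config$m_snps
  r <- length(config$raters)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  v <- if (!is.null(config$ld)) {
    config$ld$ld_score / sum(config$ld$ld_score)
  } else rep(1 / m, m)
  causal <- rep(TRUE, m)
  if (!is.null(config$k_causal)) {
    causal <- seq_len(m) %in% sample.int(m, config$k_causal)
    v <- ifelse(causal, 1 / config$k_causal, 0)
  }
  sigma_g <- config$rg * outer(sqrt(config$h2), sqrt(config$h2))
  ev <- eigen(sigma_g, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  beta <- matrix(rnorm(m * r), m, r) %*% root * sqrt(v)
  colnames(beta) <- config$raters
  list(maf = maf, beta = beta, causal = causal,
       snp_id = sprintf("snp%05d", seq_len(m)))
}

#' Simulate one cohort's individual-level data
#'
#' Genotypes are independent SNPs drawn as `Binomial(2, maf)` dosages; true
#' effects (shared across cohorts, drawn from the master seed) act on
#' standardized genotypes; residuals are multivariate normal across raters
#' with the correlation implied by the phenotypic target. Each rater
#' assesses a random subset of the cohort, stored as a logical mask. The
#' same `(config, cohort_index)` pair always reproduces identical data.
#'
#' @param config A [sim_config()].
#' @param cohort_index Cohort number in `1:n_cohorts`.
#' @return A `cohort_data` list: `cohort_id`, `genotypes` (n x m), `maf`,
#'   `snp_id`, `phenotypes` (n x raters, NA outside assessed subsets),
#'   `masks` (logical n x raters), `sex`, `truth` (per-SNP effects and
#'   per-rater genetic values).
#' @export
simulate_cohort <- function(config, cohort_index) {
  stopifnot(inherits(config, "sim_config"))
  if (cohort_index < 1 || cohort_index > config$n_cohorts) abort("cohort_index out of range")
  truth <- study_truth(config)
  n <- config$n_individuals[cohort_index]
  m <- config$m_snps
  r <- length(config$raters)
  set.seed(config$seed + 7919L * as.integer(cohort_index))
  geno <- matrix(rbinom(n * m, 2L, rep(truth$maf, each = n)), n, m)
  sd_g <- sqrt(2 * truth$maf * (1 - truth$maf))
  gs <- sweep(sweep(geno, 2L, 2 * truth$maf), 2L, sd_g, "/")
  gval <- gs %*% truth$beta
  sigma_e <- config$residual_corr *
    outer(sqrt(1 - config$h2), sqrt(1 - config$h2))
  ev <- eigen(sigma_e, symmetric = TRUE)
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  resid <- matrix(rnorm(n * r), n, r) %*% root
  sex <- rbinom(n, 1L, 0.5)
  pheno <- gval + resid
  colnames(pheno) <- config$raters
  masks <- vapply(config$raters, function(rt) {
    idx <- sample.int(n, round(config$assessed_frac[rt] * n))
    seq_len(n) %in% idx
  }, logical(n))
  pheno_obs <- pheno
  pheno_obs[!masks] <- NA_real_
  structure(list(cohort_id = paste0("cohort", cohort_index),
                 genotypes = geno, maf = truth$maf, snp_id = truth$snp_id,
                 phenotypes = pheno_obs, masks = masks, sex = sex,
                 truth = list(beta = truth$beta, causal = truth$causal,
                              genetic_values = gval),
                 include_sex = config$include_sex),
            class = "cohort_data")
}

#' Univariate GWAS for one stratum (cohort x rater)
#'
#' Ordinary least squares of the standardized phenotype on allele dosage,
#' restricted to the rater's assessed subset; `z = beta / se`. When the
#' cohort was generated with a sex covariate enabled, the phenotype is
#' residualized on it first.
#'
#' @param data A `cohort_data` from [simulate_cohort()].
#' @param rater Rater label assessed in this cohort.
#' @return A validated summary-statistics tibble
#'   (`stratum_id = <cohort>_<rater>`); alleles are coded `A` (dosage-
#'   counted, effect) vs `G`.
#' @export
run_stratum_gwas <- function(data, rater) {
  if (!rater %in% colnames(data$masks)) abort(paste0("rater not assessed: ", rater))
  mask <- data$masks[, rater]
  y <- data$phenotypes[mask, rater]
  x <- data$genotypes[mask, , drop = FALSE]
  n <- length(y)
  if (data$include_sex) y <- stats::resid(stats::lm(y ~ data$sex[mask]))
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    z <- rep(0, ncol(x))
  } else {
    y <- (y - mean(y)) / sqrt(syy / (n - 1))
    xm <- colMeans(x)
    sxx <- colSums(x^2) - n * xm^2
    sxy <- drop(crossprod(x, y))  # y centred, so cross-products are centred
    beta <- ifelse(sxx > 0, sxy / sxx, 0)
    rss <- pmax((n - 1) - beta * sxy, 0)
    se <- sqrt(ifelse(sxx > 0, (rss / (n - 2)) / sxx, Inf))
    z <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  }
  tbl <- tibble::tibble(
    stratum_id = paste0(data$cohort_id, "_", rater),
    snp_id = data$snp_id,
    chrom = "1", pos = seq_along(data$snp_id) * 1000L,
    a1 = "A", a2 = "G",
    eaf = colMeans(x) / 2, z = z, n = n)
  validate_sumstats(tbl)
}

#' Exact overlap specification from stored assessment masks
#'
#' Within each cohort, `N_s` is the exact count of individuals assessed by
#' both raters and `r_p` the empirical phenotype correlation over that
#' shared set; cross-cohort entries are zero by construction.
#'
#' @param cohorts List of `cohort_data` objects.
#' @return An [overlap_spec()] over all cohort-by-rater strata, with
#'   cohort assignments attached.
#' @export
overlap_spec_from_masks <- function(cohorts) {
  strata <- purrr::map_dfr(cohorts, function(cd) {
    tibble::tibble(stratum_id = paste0(cd$cohort_id, "_", colnames(cd$masks)),
                   cohort_id = cd$cohort_id, rater = colnames(cd$masks))
  })
  p <- nrow(strata)
  n_s <- matrix(0, p, p); r_p <- diag(p)
  for (ci in seq_along(cohorts)) {
    cd <- cohorts[[ci]]
    rows <- which(strata$cohort_id == cd$cohort_id)
    for (a in seq_along(rows)) {
      ra <- strata$rater[rows[a]]
      n_s[rows[a], rows[a]] <- sum(cd$masks[, ra])
      for (b in seq_along(rows)) {
        if (b <= a) next
        rb <- strata$rater[rows[b]]
        shared <- cd$masks[, ra] & cd$masks[, rb]
        n_s[rows[a], rows[b]] <- n_s[rows[b], rows[a]] <- sum(shared)
        rp <- if (sum(shared) >= 2L) {
          cor(cd$phenotypes[shared, ra], cd$phenotypes[shared, rb])
        } else 0
        if (!is.finite(rp)) rp <- 0
        r_p[rows[a], rows[b]] <- r_p[rows[b], rows[a]] <- rp
      }
    }
  }
  overlap_spec(strata$stratum_id, n_s, r_p, cohort_ids = strata$cohort_id)
}

#' Simulate a full multi-cohort study and its per-stratum GWASs
#'
#' Runs [simulate_cohort()] for every cohort, a GWAS for every cohort x
#' rater stratum, derives the exact overlap specification from the masks,
#' and assembles stratum metadata for the planner layer.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list of summary-statistics tibbles),
#'   `meta` (stratum metadata tibble), `spec` ([overlap_spec()]),
#'   `cohorts` (the raw `cohort_data`), and `truth`.
#' @export
simulate_study <- function(config) {
  cohorts <- purrr::map(seq_len(config$n_cohorts), ~ simulate_cohort(config, .x))
  tables <- list()
  meta_rows <- list()
  for (cd in cohorts) {
    for (rt in config$raters) {
      tbl <- run_stratum_gwas(cd, rt)
      sid <- tbl$stratum_id[1]
      tables[[sid]] <- tbl
      meta_rows[[sid]] <- tibble::tibble(
        stratum_id = sid, cohort_id = cd$cohort_id, rater = rt,
        instrument = config$instrument[rt],
        mean_age = config$mean_age[rt], n_obs = tbl$n[1])
    }
  }
  list(tables = tables, meta = dplyr::bind_rows(meta_rows),
       spec = overlap_spec_from_masks(cohorts), cohorts = cohorts,
       truth = study_truth(config))
}

#' Identity-CTI variant of an overlap specification
#'
#' Zeroes all off-diagonal phenotypic correlations, so the expected CTI
#' matrix becomes the identity — the "overlap ignored" analysis used as the
#' naive comparator in calibration studies.
#'
#' @param spec An [overlap_spec()].
#' @return An [overlap_spec()] with the same strata and diagonal.
#' @export
ignore_overlap <- function(spec) {
  overlap_spec(spec$stratum_ids, diag(diag(spec$n_s)), diag(length(spec$stratum_ids)),
               cohort_ids = spec$cohort_ids)
}

#' Type-I-error calibration study for the overlap correction
#'
#' Simulates replicate null studies (the config should have `h2 = 0`),
#' meta-analyses each twice — once with the expected CTI built from the
#' true overlap, once with the CTI forced to identity — and reports the
#' empirical type-I error at `alpha`, the mean chi-square and the variance
#' of the combined statistic for both analyses, with Monte-Carlo confidence
#' intervals over the pooled SNP tests.
#'
#' @param config A [sim_config()] (null: all `h2 = 0`) .
#' @param n_replicates Number of independent replicate studies.
#' @param alpha Nominal test level.
#' @return A `calibration_report`: list with `summary` (one row per
#'   analysis) and `replicates` (per-replicate metrics).
#' @export
calibration_study <- function(config, n_replicates = 20, alpha = 0.05) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 104729L * r  # distinct stream per replicate
    sim <- simulate_study(cfg)
    aware <- run_meta(sim$tables, sim$meta, sim$spec)
    naive <- run_meta(sim$tables, sim$meta, ignore_overlap(sim$spec))
    purrr::map_dfr(list(aware = aware, naive = naive), function(res) {
      tibble::tibble(n_tests = nrow(res),
                     type1 = mean(res$p < alpha),
                     mean_chi2 = mean(res$z_multi^2),
                     var_z = var(res$z_multi))
    }, .id = "analysis") |>
      dplyr::mutate(replicate = r, .before = 1)
  })
  summary <- reps |>
    dplyr::group_by(.data$analysis) |>
    dplyr::summarise(
      type1 = sum(.data$type1 * .data$n_tests) / sum(.data$n_tests),
      mean_chi2 = sum(.data$mean_chi2 * .data$n_tests) / sum(.data$n_tests),
      var_z = mean(.data$var_z),
      n_tests = sum(.data$n_tests),
      .groups = "drop") |>
    dplyr::mutate(
      type1_ci_lo = .data$type1 - 1.96 * sqrt(.data$type1 * (1 - .data$type1) / .data$n_tests),
      type1_ci_hi = .data$type1 + 1.96 * sqrt(.data$type1 * (1 - .data$type1) / .data$n_tests),
      alpha = alpha)
  structure(list(summary = summary, replicates = reps, alpha = alpha),
            class = "calibration_report")
}
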