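#' Pairwise sample-overlap and phenotypic-correlation specification
#'
#' Bundles, for an ordered set of strata, the matrix of pairwise counts of
#' shared individuals (`n_s`, diagonal = each stratum's number of
#' observations) and the matrix of pairwise phenotypic correlations in the
#' shared individuals (`r_p`, unit diagonal). Strata from different cohorts
#' are assumed disjoint: their `n_s` and `r_p` entries must be zero.
#'
#' @param stratum_ids Character vector of P stratum identifiers (the
#'   row/column order of both matrices).
#' @param n_s P x P numeric matrix of overlapping-individual counts.
#' @param r_p P x P numeric matrix of phenotypic correlations.
#' @param cohort_ids Optional character vector mapping each stratum to its
#'   cohort; enables the cross-cohort zero checks in
#'   [validate_overlap_spec()].
#' @return An `overlap_spec` object.
#' @export
#' @examples
#' overlap_spec(c("s1", "s2"),
#'              n_s = matrix(c(1000, 500, 500, 1000), 2),
#'              r_p = matrix(c(1, 0.29, 0.29, 1), 2))
overlap_spec <- function(stratum_ids, n_s, r_p, cohort_ids = NULL) {
  stratum_ids <- as.character(stratum_ids)
  p <- length(stratum_ids)
  n_s <- as.matrix(n_s); r_p <- as.matrix(r_p)
  if (!all(dim(n_s) == p) || !all(dim(r_p) == p)) {
    abort("n_s and r_p must be P x P matrices matching stratum_ids")
  }
  dimnames(n_s) <- dimnames(r_p) <- list(stratum_ids, stratum_ids)
  spec <- structure(list(stratum_ids = stratum_ids, n_s = n_s, r_p = r_p,
                         cohort_ids = cohort_ids),
                    class = "overlap_spec")
  viol <- validate_overlap_spec(spec)
  if (nrow(viol) > 0L) {
    abort(paste0("invalid overlap specification:\n",
                 paste0("  - ", viol$rule, " [", viol$pair, "]", collapse = "\n")))
  }
  spec
}

#' Check an overlap specification against its invariants
#'
#' Reports (rather than errors on) violations: asymmetry of either matrix,
#' overlap counts exceeding the smaller stratum, correlations outside
#' \[-1, 1\], off-unit `r_p` diagonal, negative overlap, and non-zero
#' cross-cohort entries when cohort assignments are available.
#'
#' @param spec An `overlap_spec` (or an unchecked list with the same fields).
#' @return A tibble with columns `pair` and `rule`; zero rows when the
#'   specification is valid.
#' @export
validate_overlap_spec <- function(spec) {
  ids <- spec$stratum_ids; n_s <- spec$n_s; r_p <- spec$r_p
  p <- length(ids)
  out <- list()
  add <- function(i, k, rule) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      pair = paste(ids[i], ids[k], sep = " ~ "), rule = rule)
  }
  for (i in seq_len(p)) {
    if (r_p[i, i] != 1) add(i, i, "r_p diagonal must be 1")
    if (n_s[i, i] <= 0) add(i, i, "n_s diagonal (stratum n_obs) must be positive")
    for (k in seq_len(p)) {
      if (k <= i) next
      if (n_s[i, k] != n_s[k, i]) add(i, k, "n_s must be symmetric")
      if (r_p[i, k] != r_p[k, i]) add(i, k, "r_p must be symmetric")
      if (abs(r_p[i, k]) > 1) add(i, k, "|r_p| must be <= 1")
      if (n_s[i, k] < 0) add(i, k, "n_s must be non-negative")
      if (n_s[i, k] > min(n_s[i, i], n_s[k, k])) {
        add(i, k, "n_s exceeds the smaller stratum's n_obs")
      }
      if (!is.null(spec$cohort_ids) && spec$cohort_ids[i] != spec$cohort_ids[k]) {
        if (n_s[i, k] != 0) add(i, k, "cross-cohort n_s must be 0")
        if (r_p[i, k] != 0) add(i, k, "cross-cohort r_p must be 0")
      }
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(pair = character(), rule = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read an overlap specification from two square matrix files
#'
#' Each file is a TSV with stratum ids as both the header row and the first
#' column, mirroring the layout of consortium supplementary tables.
#'
#' @param n_s_path,r_p_path Paths to the overlap-count and phenotypic-
#'   correlation matrices.
#' @param cohort_ids Optional named character vector (stratum id -> cohort).
#' @return An `overlap_spec`.
#' @export
read_overlap_spec <- function(n_s_path, r_p_path, cohort_ids = NULL) {
  read_square <- function(path) {
    m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(m[[1]])
    mat <- as.matrix(m[, -1, drop = FALSE])
    mode(mat) <- "numeric"
    if (!identical(ids, colnames(mat))) {
      abort(paste0("row and column stratum ids disagree in ", path))
    }
    dimnames(mat) <- list(ids, ids)
    mat
  }
  n_s <- read_square(n_s_path)
  r_p <- read_square(r_p_path)
  if (!identical(rownames(n_s), rownames(r_p))) {
    abort("n_s and r_p files list different strata")
  }
  if (!is.null(cohort_ids)) cohort_ids <- unname(cohort_ids[rownames(n_s)])
  overlap_spec(rownames(n_s), n_s, r_p, cohort_ids = cohort_ids)
}

#' Expected cross-trait-intercept matrix for one SNP
#'
#' Under the null, the covariance between two GWASs' Z statistics induced by
#' shared individuals is `CTI_ik = N_s * r_p / sqrt(N_ji * N_jk)`, where
#' `N_ji`, `N_jk` are the per-SNP sample sizes. The overlap count is capped
#' at `min(N_ji, N_jk)` so that a SNP genotyped in only part of a stratum is
#' never claimed to share more individuals than it has. The diagonal is 1.
#'
#' If the assembled matrix is not positive semi-definite (user-supplied
#' overlap tables are often slightly inconsistent), eigenvalues are clipped
#' at `1e-8` and the matrix rescaled back to unit diagonal; the repair is
#' signalled via the `"repaired"` attribute and a message.
#'
#' @param spec An `overlap_spec`.
#' @param n_per_snp Numeric P-vector of per-SNP sample sizes, in
#'   `spec$stratum_ids` order (optionally named).
#' @return A `cti_matrix`: a P x P matrix with unit diagonal and attributes
#'   `"repaired"` (logical) and `"n_capped"` (number of capped pairs).
#' @export
#' @examples
#' sp <- overlap_spec(c("s1", "s2"),
#'                    matrix(c(1000, 500, 500, 1000), 2),
#'                    matrix(c(1, 0.29, 0.29, 1), 2))
#' build_cti(sp, c(1000, 1000))   # off-diagonal 0.145
build_cti <- function(spec, n_per_snp) {
  p <- length(spec$stratum_ids)
  n_per_snp <- as.numeric(n_per_snp)
  if (length(n_per_snp) != p) abort("n_per_snp length must match the number of strata")
  if (any(!is.finite(n_per_snp)) || any(n_per_snp <= 0)) {
    abort("all per-SNP sample sizes must be positive")
  }
  ns_cap <- pmin(spec$n_s, outer(n_per_snp, n_per_snp, pmin))
  n_capped <- sum((ns_cap < spec$n_s)[upper.tri(ns_cap)])
  denom <- sqrt(outer(n_per_snp, n_per_snp))
  cti <- ns_cap * spec$r_p / denom
  diag(cti) <- 1
  if (n_capped > 0.5 * p * (p - 1) / 2) {
    warn("overlap counts were capped at per-SNP sample sizes for more than half of all pairs")
  }
  repaired <- FALSE
  ev <- eigen(cti, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    cti <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(cti))
    cti <- cti / outer(d, d)
    diag(cti) <- 1
    repaired <- TRUE
    inform("CTI matrix was not positive semi-definite; eigenvalues clipped and diagonal rescaled")
  }
  dimnames(cti) <- list(spec$stratum_ids, spec$stratum_ids)
  structure(cti, class = c("cti_matrix", "matrix", "array"),
            repaired = repaired, n_capped = n_capped)
}

#' Effective sample size of a meta-analysis of correlated GWASs
#'
#' `N_eff = sqrt(N)' CTI^-1 sqrt(N)`. Equals the plain sum of sample sizes
#' exactly when the CTI matrix is the identity (no overlap, or zero
#' phenotypic correlation), and is strictly smaller otherwise.
#'
#' @param n_per_snp Numeric P-vector of per-SNP sample sizes.
#' @param cti P x P cross-trait-intercept matrix (unit diagonal, positive
#'   definite).
#' @return A positive scalar.
#' @export
#' @examples
#' effective_sample_size(c(100, 200), diag(2))          # 300
#' effective_sample_size(c(1000, 1000),
#'                       matrix(c(1, .5, .5, 1), 2))    # 2000/1.5
effective_sample_size <- function(n_per_snp, cti) {
  n_per_snp <- as.numeric(n_per_snp)
  cti <- unclass(cti)
  if (length(n_per_snp) != nrow(cti)) abort("dimension mismatch between n_per_snp and cti")
  if (any(n_per_snp <= 0)) abort("sample sizes must be positive")
  rn <- sqrt(n_per_snp)
  sol <- tryCatch(solve(cti, rn), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)) || rcond_sym(cti) < 1e-7) {
    abort(paste0("CTI matrix is (near-)singular: two strata are perfect duplicates; ",
                 "merge the duplicated strata upstream instead of meta-analysing them"))
  }
  drop(crossprod(rn, sol))
}

# reciprocal condition number of a small symmetric matrix
rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}
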