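#' @export
print.ldsc_fit <- function(x, ...) {
  cat("<ldsc_fit>  ", x$n_snps, " SNPs, M = ", x$m, ", ",
      x$n_blocks, " jackknife blocks\n", sep = "")
  cat(sprintf("  h2        %8.4f (SE %.4f, Z %.2f)\n", x$h2, x$h2_se, x$h2 / x$h2_se))
  cat(sprintf("  intercept %8.4f (SE %.4f)\n", x$intercept, x$intercept_se))
  cat(sprintf("  mean chi2 %8.4f\n", x$mean_chi2))
  invisible(x)
}

#' @export
print.rg_fit <- function(x, ...) {
  cat("<rg_fit>  ", x$n_snps, " SNPs, ", x$n_blocks, " jackknife blocks\n", sep = "")
  cat(sprintf("  rg       %8.4f (SE %.4f)\n", x$rg, x$rg_se))
  cat(sprintf("  cti_hat  %8.4f (SE %.4f)\n", x$cti_hat, x$cti_se))
  cat(sprintf("  h2 pair  %8.4f / %.4f\n", x$h2_1, x$h2_2))
  invisible(x)
}

#' Tidy an LD-score-regression fit
#'
#' @param x An `ldsc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term (`h2`, `intercept`): `estimate`,
#'   `std.error`, `statistic`.
#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble::tibble(term = c("h2", "intercept"),
                 estimate = c(x$h2, x$intercept),
                 std.error = c(x$h2_se, x$intercept_se),
                 statistic = c(x$h2 / x$h2_se, (x$intercept - 1) / x$intercept_se))
}

#' Glance at an LD-score-regression fit
#'
#' @param x An `ldsc_fit`.
#' @param ... Unused.
#' @return One-row tibble: `mean_chi2`, `n_snps`, `m`, `n_blocks`.
#' @export
glance.ldsc_fit <- function(x, ...) {
  tibble::tibble(mean_chi2 = x$mean_chi2, n_snps = x$n_snps,
                 m = x$m, n_blocks = x$n_blocks)
}

#' Tidy a cross-trait LD-score-regression fit
#'
#' @param x An `rg_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term (`rg`, `cti`).
#' @export
tidy.rg_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "cti"),
                 estimate = c(x$rg, x$cti_hat),
                 std.error = c(x$rg_se, x$cti_se),
                 statistic = c(x$rg / x$rg_se, x$cti_hat / x$cti_se))
}

#' Glance at a cross-trait fit
#'
#' @param x An `rg_fit`.
#' @param ... Unused.
#' @return One-row tibble: `h2_1`, `h2_2`, `n_snps`, `n_blocks`.
#' @export
glance.rg_fit <- function(x, ...) {
  tibble::tibble(h2_1 = x$h2_1, h2_2 = x$h2_2,
                 n_snps = x$n_snps, n_blocks = x$n_blocks)
}
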