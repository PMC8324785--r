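#' Quantile-quantile plot of a meta-analysis result
#'
#' Observed versus expected `-log10(P)` under the global null, the standard
#' first look at a GWAMA's calibration.
#'
#' @param object A `meta_result` from [run_meta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_result <- function(object, ...) {
  p <- sort(object$p)
  df <- tibble::tibble(
    expected = -log10((seq_along(p) - 0.5) / length(p)),
    observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](italic(P))),
                  y = expression(Observed ~ -log[10](italic(P))),
                  title = "Meta-analysis QQ plot") +
    ggplot2::theme_minimal()
}

#' Plot a calibration report
#'
#' Per-replicate mean chi-square of the overlap-aware and overlap-ignoring
#' analyses, against the unit reference line expected under correct
#' calibration.
#'
#' @param object A `calibration_report` from [calibration_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$replicate, y = .data$mean_chi2,
                               colour = .data$analysis)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Replicate", y = expression(mean ~ chi^2),
                  colour = "CTI",
                  title = "Null calibration: expected CTI vs overlap ignored") +
    ggplot2::theme_minimal()
}

#' Plot pairwise genetic correlations
#'
#' Point-range display of the pairwise genetic correlations produced by
#' [rg_matrix()], with approximate 95% intervals.
#'
#' @param rg Tibble from `rg_matrix()$rg`.
#' @return A ggplot object.
#' @export
plot_rg_pairs <- function(rg) {
  rg <- dplyr::mutate(rg, pair = paste(.data$stratum_1, .data$stratum_2, sep = " ~ "))
  ggplot2::ggplot(rg, ggplot2::aes(x = .data$rg, y = .data$pair)) +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = 2, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$rg - 1.96 * .data$rg_se,
                                          xmax = .data$rg + 1.96 * .data$rg_se)) +
    ggplot2::labs(x = expression(r[g]), y = NULL,
                  title = "Pairwise genetic correlations") +
    ggplot2::theme_minimal()
}
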