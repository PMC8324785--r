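#' Admit strata by minimum observation count
#'
#' A stratum (one univariate GWAS: cohort x rater x instrument x age group)
#' enters the meta-analysis only with at least `min_obs` observations.
#'
#' @param meta Stratum-metadata tibble (`stratum_id`, `cohort_id`, `rater`,
#'   `instrument`, `mean_age`, `n_obs`).
#' @param min_obs Inclusive admission threshold (default 450).
#' @return List with tibbles `admitted` and `rejected`.
#' @export
admit_strata <- function(meta, min_obs = 450) {
  keep <- meta$n_obs >= min_obs
  list(admitted = meta[keep, , drop = FALSE],
       rejected = meta[!keep, , drop = FALSE])
}

#' Plan age bins for one rater
#'
#' Greedy left-to-right accumulation over strata sorted by mean age:
#' adjacent strata are pooled until the running total of observations
#' strictly exceeds `min_bin_obs`, which closes a bin. A trailing remainder
#' that cannot reach the threshold is merged into the previous bin. When
#' the rater's grand total does not exceed the threshold, no bins are
#' produced and age-specific meta-analysis is unavailable for that rater.
#'
#' @param meta Admitted stratum metadata for a single rater.
#' @param min_bin_obs Strict lower bound on each bin's total observations.
#' @return Tibble of bins: `label`, `stratum_ids` (list-column),
#'   `total_n_obs`, `age_min`, `age_max`; zero rows when unattainable.
#' @export
plan_age_bins <- function(meta, min_bin_obs = 15000) {
  meta <- meta[order(meta$mean_age, meta$stratum_id), , drop = FALSE]
  if (sum(meta$n_obs) <= min_bin_obs) {
    return(tibble::tibble(label = character(), stratum_ids = list(),
                          total_n_obs = numeric(),
                          age_min = numeric(), age_max = numeric()))
  }
  bins <- list()
  cur <- integer(0)
  total <- 0
  for (i in seq_len(nrow(meta))) {
    cur <- c(cur, i)
    total <- total + meta$n_obs[i]
    if (total > min_bin_obs) {
      bins[[length(bins) + 1L]] <- cur
      cur <- integer(0)
      total <- 0
    }
  }
  if (length(cur) > 0L) {  # underweight remainder joins the previous bin
    bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
  }
  purrr::map_dfr(seq_along(bins), function(b) {
    rows <- meta[bins[[b]], , drop = FALSE]
    tibble::tibble(
      label = sprintf("%s_age%02d", rows$rater[1], b),
      stratum_ids = list(rows$stratum_id),
      total_n_obs = sum(rows$n_obs),
      age_min = min(rows$mean_age), age_max = max(rows$mean_age))
  })
}

#' Build the full meta-analysis plan
#'
#' Emits the subsets the pipeline meta-analyses: `overall` (all admitted
#' strata), one subset per rater present, instrument-specific subsets only
#' where the instrument's total observations strictly exceed
#' `min_bin_obs`, and per-rater age bins where attainable
#' (see [plan_age_bins()]).
#'
#' @param meta Stratum-metadata tibble.
#' @param min_obs Stratum admission threshold (see [admit_strata()]).
#' @param min_bin_obs Threshold for instrument subsets and age bins.
#' @return A `strata_plan`: list with `subsets` (named list of stratum-id
#'   vectors), `age_bins` (tibble), `admitted` and `rejected` metadata.
#' @export
build_plan <- function(meta, min_obs = 450, min_bin_obs = 15000) {
  adm <- admit_strata(meta, min_obs)
  a <- adm$admitted
  a <- a[order(a$stratum_id), , drop = FALSE]  # order-independent input
  subsets <- list(overall = a$stratum_id)
  for (r in sort(unique(a$rater))) {
    subsets[[paste0("rater:", r)]] <- a$stratum_id[a$rater == r]
  }
  for (ins in sort(unique(a$instrument))) {
    rows <- a[a$instrument == ins, , drop = FALSE]
    if (sum(rows$n_obs) > min_bin_obs) {
      subsets[[paste0("instrument:", ins)]] <- rows$stratum_id
    }
  }
  age_bins <- purrr::map_dfr(sort(unique(a$rater)), function(r) {
    plan_age_bins(a[a$rater == r, , drop = FALSE], min_bin_obs)
  })
  if (nrow(age_bins) > 0L) {
    for (b in seq_len(nrow(age_bins))) {
      subsets[[paste0("agebin:", age_bins$label[b])]] <- age_bins$stratum_ids[[b]]
    }
  }
  structure(list(subsets = subsets, age_bins = age_bins,
                 admitted = a, rejected = adm$rejected),
            class = "strata_plan")
}

#' @export
print.strata_plan <- function(x, ...) {
  cat("<strata_plan> ", nrow(x$admitted), " admitted strata (",
      nrow(x$rejected), " rejected)\n", sep = "")
  for (nm in names(x$subsets)) {
    cat("  ", nm, ": ", length(x$subsets[[nm]]), " strata\n", sep = "")
  }
  invisible(x)
}
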