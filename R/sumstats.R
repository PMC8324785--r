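#' Read per-stratum GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file (optionally
#' gzipped) into a validated tibble. Column names are matched case-insensitively
#' against common aliases: `SNP`/`RSID`/`SNP_ID`/`MARKERNAME`, `CHR`/`CHROM`,
#' `POS`/`BP`, `A1`/`EA`/`EFFECT_ALLELE`, `A2`/`OA`/`OTHER_ALLELE`,
#' `EAF`/`FRQ`/`FREQ`/`AF`, `Z`/`ZSCORE`, `N`. The first seven are mandatory;
#' per-SNP `N` falls back to `n_fallback` (typically the stratum's number of
#' observations) when the column is absent.
#'
#' Rows whose mandatory fields fail to parse or violate basic validity
#' (alleles outside A/C/G/T, `a1 == a2`, `eaf` outside \[0, 1\], non-positive
#' `n`, non-finite `z`, duplicated `snp_id`) are dropped and counted in the
#' `"drops"` attribute of the result.
#'
#' @param path Path to the summary-statistics file (`.gz` accepted).
#' @param stratum_id Identifier recorded in the `stratum_id` column.
#' @param n_fallback Per-SNP sample size to use when the file has no `N`
#'   column. Required in that case.
#' @param max_n Optional declared maximum sample size; rows with `n > max_n`
#'   are dropped as invalid.
#' @return A tibble with columns `stratum_id`, `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `eaf`, `z`, `n`, carrying a `"drops"` attribute (named
#'   integer vector of drop reasons).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tFRQ\tZ\tN",
#'              "rs1\t1\t1000\tA\tG\t0.2\t1.5\t900"), tf)
#' read_sumstats(tf, "cohortA_mother")
read_sumstats <- function(path, stratum_id, n_fallback = NULL, max_n = NULL) {
  if (!file.exists(path)) abort(paste0("summary-statistics file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) abort(paste0("empty summary-statistics file: ", path))
  delim_tab <- grepl("\t", first, fixed = TRUE)
  raw <- if (delim_tab) {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  } else {
    readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, show_col_types = FALSE)
  }
  if (nrow(raw) == 0L) abort(paste0("empty summary-statistics file: ", path))

  aliases <- list(
    snp_id = c("SNP", "RSID", "SNP_ID", "SNPID", "MARKERNAME"),
    chrom  = c("CHR", "CHROM", "CHROMOSOME"),
    pos    = c("POS", "BP", "POSITION"),
    a1     = c("A1", "EA", "EFFECT_ALLELE"),
    a2     = c("A2", "OA", "OTHER_ALLELE", "NEA"),
    eaf    = c("EAF", "FRQ", "FREQ", "AF"),
    z      = c("Z", "ZSCORE", "Z_SCORE"),
    n      = c("N", "NOBS", "N_OBS")
  )
  nm_up <- toupper(names(raw))
  col_for <- function(key) {
    hit <- which(nm_up %in% aliases[[key]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  idx <- vapply(names(aliases), col_for, integer(1))
  missing_cols <- setdiff(names(which(is.na(idx))), "n")
  if (length(missing_cols) > 0L) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }

  tbl <- tibble::tibble(
    stratum_id = stratum_id,
    snp_id = raw[[idx[["snp_id"]]]],
    chrom  = raw[[idx[["chrom"]]]],
    pos    = suppressWarnings(as.integer(raw[[idx[["pos"]]]])),
    a1     = toupper(raw[[idx[["a1"]]]]),
    a2     = toupper(raw[[idx[["a2"]]]]),
    eaf    = suppressWarnings(as.numeric(raw[[idx[["eaf"]]]])),
    z      = suppressWarnings(as.numeric(raw[[idx[["z"]]]]))
  )
  if (is.na(idx[["n"]])) {
    if (is.null(n_fallback)) {
      abort(paste0("no N column in ", path,
                   " and no n_fallback supplied (use the stratum's n_obs)"))
    }
    inform(paste0("stratum ", stratum_id, ": no per-SNP N column; using n_fallback = ",
                  n_fallback, " for all SNPs"))
    tbl$n <- as.numeric(n_fallback)
  } else {
    tbl$n <- suppressWarnings(as.numeric(raw[[idx[["n"]]]]))
  }
  validate_sumstats(tbl, max_n = max_n)
}

#' Validate a summary-statistics tibble
#'
#' Applies the row-level validity rules (parseable numerics, alleles in
#' A/C/G/T with `a1 != a2`, `eaf` in \[0, 1\], positive `n`, finite `z`,
#' unique `snp_id`), dropping and counting offending rows.
#'
#' @param tbl Tibble with columns `stratum_id`, `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `eaf`, `z`, `n`.
#' @param max_n Optional declared maximum `n`.
#' @return The cleaned tibble with a `"drops"` attribute.
#' @export
validate_sumstats <- function(tbl, max_n = NULL) {
  ok_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  bad_parse   <- is.na(tbl$snp_id) | is.na(tbl$pos) | is.na(tbl$eaf) |
                 is.na(tbl$z) | is.na(tbl$n) | is.na(tbl$chrom)
  bad_allele  <- !bad_parse & (!ok_allele(tbl$a1) | !ok_allele(tbl$a2) | tbl$a1 == tbl$a2)
  bad_range   <- !bad_parse & !bad_allele &
    (tbl$eaf < 0 | tbl$eaf > 1 | tbl$n <= 0 | !is.finite(tbl$z) |
       (if (is.null(max_n)) FALSE else tbl$n > max_n))
  keep <- !(bad_parse | bad_allele | bad_range)
  out <- tbl[keep, , drop = FALSE]
  dup <- duplicated(out$snp_id)
  out <- out[!dup, , drop = FALSE]
  drops <- c(unparseable = sum(bad_parse), bad_allele = sum(bad_allele),
             out_of_range = sum(bad_range), duplicate_id = sum(dup))
  attr(out, "drops") <- drops
  if (sum(drops) > 0L) {
    inform(paste0("stratum ", out$stratum_id[1] %||% tbl$stratum_id[1], ": dropped ",
                  sum(drops), " of ", nrow(tbl), " rows during validation"))
  }
  out
}

#' Write summary statistics with the canonical header
#'
#' @param tbl Summary-statistics or meta-analysis tibble.
#' @param path Output path; a `.gz` suffix gzips the output.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tbl, path) {
  canon <- c(snp_id = "SNP", chrom = "CHR", pos = "POS", a1 = "A1", a2 = "A2",
             eaf = "EAF", meta_eaf = "EAF", z = "Z", z_multi = "Z", p = "P",
             n = "N", n_eff = "N_EFF", n_strata = "N_STRATA",
             n_cohorts = "N_COHORTS", direction = "DIRECTION")
  keep <- intersect(names(canon), names(tbl))
  out <- tbl[, keep, drop = FALSE]
  names(out) <- unname(canon[keep])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Sample-size-tiered minor-allele-frequency QC configuration
#'
#' Smaller strata get a more stringent MAF bound. Tiers are half-open
#' intervals `[lower, upper)` on the stratum's number of observations and
#' must cover `[0, Inf)` without gaps or overlaps.
#'
#' @param lower,upper Numeric vectors of interval bounds.
#' @param min_maf Minimum minor-allele frequency for strata in each tier.
#' @return A `qc_tiers` tibble.
#' @export
#' @examples
#' qc_tiers()  # defaults: <5000 -> 0.05, <15000 -> 0.03, else 0.01
qc_tiers <- function(lower = c(0, 5000, 15000),
                     upper = c(5000, 15000, Inf),
                     min_maf = c(0.05, 0.03, 0.01)) {
  if (length(lower) == 0L) abort("empty QC tier configuration")
  if (length(lower) != length(upper) || length(lower) != length(min_maf)) {
    abort("QC tier vectors must have equal length")
  }
  ord <- order(lower)
  lower <- lower[ord]; upper <- upper[ord]; min_maf <- min_maf[ord]
  if (lower[1] != 0) abort("QC tiers must start at n_obs = 0")
  if (any(upper <= lower)) abort("QC tiers must have upper > lower")
  if (length(lower) > 1L && any(upper[-length(upper)] != lower[-1L])) {
    abort("QC tiers must be contiguous (no gaps or overlaps)")
  }
  if (!is.infinite(upper[length(upper)])) abort("last QC tier must be unbounded (upper = Inf)")
  if (any(min_maf < 0 | min_maf > 0.5)) abort("min_maf must lie in [0, 0.5]")
  structure(tibble::tibble(lower = lower, upper = upper, min_maf = min_maf),
            class = c("qc_tiers", class(tibble::tibble())))
}

#' Apply sample-size-tiered MAF QC to one stratum
#'
#' Looks up the MAF bound for the stratum's `n_obs` in `tiers` and removes
#' records with `min(eaf, 1 - eaf)` below it.
#'
#' @param tbl Validated summary-statistics tibble for one stratum.
#' @param n_obs Number of observations in the stratum's GWAS.
#' @param tiers A [qc_tiers()] configuration.
#' @return A list with elements `sumstats` (filtered tibble) and `report`
#'   (one-row QC report tibble whose counts reconcile:
#'   `n_input = n_retained + drops`).
#' @export
stratum_qc <- function(tbl, n_obs, tiers = qc_tiers()) {
  if (!inherits(tiers, "qc_tiers")) tiers <- do.call(qc_tiers, as.list(tiers))
  row <- which(n_obs >= tiers$lower & n_obs < tiers$upper)
  if (length(row) != 1L) abort(paste0("no QC tier covers n_obs = ", n_obs))
  maf <- pmin(tbl$eaf, 1 - tbl$eaf)
  keep <- maf >= tiers$min_maf[row]
  report <- tibble::tibble(
    stratum_id = tbl$stratum_id[1] %||% NA_character_,
    n_input = nrow(tbl),
    n_dropped_allele_mismatch = 0L,
    n_dropped_palindromic = 0L,
    n_dropped_maf = sum(!keep),
    n_dropped_info_proxy = 0L,
    n_retained = sum(keep)
  )
  list(sumstats = tbl[keep, , drop = FALSE], report = report)
}
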