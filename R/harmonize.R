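COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

#' Harmonize allele orientation across strata
#'
#' Aligns every table's effect alleles to a reference orientation so that Z
#' scores are directly combinable. For each SNP shared with the reference:
#'
#' * alleles identical: record kept as-is;
#' * alleles swapped: `a1`/`a2` exchanged, `z := -z`, `eaf := 1 - eaf`;
#' * alleles on the opposite strand: complemented, then the swap rule applied;
#' * alleles irreconcilable with the reference pair: record dropped.
#'
#' Palindromic SNPs (A/T or C/G) with `eaf` in `[0.4, 0.6]` in *any* table are
#' strand-ambiguous and dropped from every table. Outside that window a strand
#' flip cannot be told from an allele swap by the letters alone, so orientation
#' is resolved by whichever choice brings `eaf` closer to the reference `eaf`.
#'
#' SNPs absent from the reference are passed through unchanged. The operation
#' is idempotent.
#'
#' @param tables Named list of validated summary-statistics tibbles.
#' @param reference Name or index of the table providing the reference
#'   orientation (default: the first table).
#' @return A named list of harmonized tibbles, in the input order, carrying a
#'   `"harmonize_log"` attribute (per-stratum counts of swaps, strand
#'   complements and drops).
#' @export
harmonize_sumstats <- function(tables, reference = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) t$stratum_id[1], character(1))
  }
  ref_idx <- if (is.null(reference)) 1L else {
    if (is.character(reference)) match(reference, names(tables)) else as.integer(reference)
  }
  if (is.na(ref_idx) || ref_idx < 1L || ref_idx > length(tables)) {
    abort("reference table not found")
  }
  ref <- tables[[ref_idx]]

  # strand-ambiguous palindromic SNPs are dropped from every table
  ambiguous <- unique(unlist(lapply(tables, function(t) {
    t$snp_id[is_palindromic(t$a1, t$a2) & t$eaf >= 0.4 & t$eaf <= 0.6]
  })))

  ref_key <- ref[, c("snp_id", "a1", "a2", "eaf")]
  names(ref_key) <- c("snp_id", "ref_a1", "ref_a2", "ref_eaf")

  log_rows <- vector("list", length(tables))
  out <- tables
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    n_pal <- sum(t$snp_id %in% ambiguous)
    t <- t[!(t$snp_id %in% ambiguous), , drop = FALSE]
    if (i == ref_idx) {
      out[[i]] <- t
      log_rows[[i]] <- tibble::tibble(
        stratum_id = names(tables)[i], n_swapped = 0L, n_complemented = 0L,
        n_dropped_mismatch = 0L, n_dropped_palindromic = n_pal)
      next
    }
    m <- dplyr::left_join(t, ref_key, by = "snp_id")
    shared <- !is.na(m$ref_a1)
    same    <- shared & m$a1 == m$ref_a1 & m$a2 == m$ref_a2
    swapped <- shared & m$a1 == m$ref_a2 & m$a2 == m$ref_a1
    ca1 <- unname(COMPLEMENT[m$a1]); ca2 <- unname(COMPLEMENT[m$a2])
    comp_same    <- shared & !same & !swapped & ca1 == m$ref_a1 & ca2 == m$ref_a2
    comp_swapped <- shared & !same & !swapped & ca1 == m$ref_a2 & ca2 == m$ref_a1
    mismatch <- shared & !(same | swapped | comp_same | comp_swapped)

    pal <- shared & is_palindromic(m$a1, m$a2)
    # non-palindromic resolution by letters
    flip <- swapped | comp_swapped
    flip[pal] <- FALSE
    # palindromic resolution: letters are uninformative between "same" and a
    # strand-flipped swap; choose the orientation whose eaf is closer to the
    # reference eaf (strict inequality keeps the rule idempotent)
    pal_flip <- pal & (abs(m$eaf - m$ref_eaf) > abs((1 - m$eaf) - m$ref_eaf))
    flip <- flip | pal_flip

    m$z[flip] <- -m$z[flip]
    m$eaf[flip] <- 1 - m$eaf[flip]
    m$a1[shared] <- m$ref_a1[shared]
    m$a2[shared] <- m$ref_a2[shared]
    m <- m[!mismatch, , drop = FALSE]
    out[[i]] <- m[, names(t), drop = FALSE]
    log_rows[[i]] <- tibble::tibble(
      stratum_id = names(tables)[i],
      n_swapped = sum(flip & !(comp_same | comp_swapped)),
      n_complemented = sum(comp_same | comp_swapped),
      n_dropped_mismatch = sum(mismatch),
      n_dropped_palindromic = n_pal)
  }
  attr(out, "harmonize_log") <- dplyr::bind_rows(log_rows)
  out
}
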