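#' Default diploid sample sizes for the six panel populations
#'
#' The 1000 Genomes phase-3 super-population sample sizes (AFR 661, AMR 347,
#' EAS 504, EUR 503, SAS 489) plus TSI (107), the Toscani constituent
#' population analysed separately. Allele counts reconstructed from
#' frequencies scale with these, but test outcomes are frequency-driven and
#' insensitive to small deviations.
#'
#' @return Named integer vector of diploid sample sizes.
#' @export
default_sample_sizes <- function() {
  c(AFR = 661L, AMR = 347L, EAS = 504L, EUR = 503L, TSI = 107L, SAS = 489L)
}

round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct allele counts from an allele frequency
#'
#' Converts an associated-allele proportion and a diploid sample size into
#' the integer allele counts feeding the exact tests:
#' `associated = round_half_up(2 * n_diploid * freq)` and
#' `other = 2 * n_diploid - associated`. Rounding is half-up and
#' deterministic. Vectorized over `freq` and `n_diploid`.
#'
#' @param freq Associated-allele proportion(s) in `[0, 1]`.
#' @param n_diploid Diploid sample size(s), `>= 1`.
#' @return Tibble with columns `freq`, `n_diploid`, `associated`, `other`.
#' @examples
#' allele_counts(0.84, 661)  # 1110 associated, 212 other
#' @export
allele_counts <- function(freq, n_diploid) {
  if (any(is.na(freq)) || any(freq < 0 | freq > 1)) {
    abort("freq must be within [0, 1] and non-missing",
          class = "snpload_validation_error")
  }
  if (any(n_diploid < 1)) {
    abort("n_diploid must be >= 1", class = "snpload_validation_error")
  }
  assoc <- as.integer(round_half_up(2 * n_diploid * freq))
  tibble::tibble(
    freq = freq, n_diploid = as.integer(n_diploid),
    associated = assoc, other = as.integer(2 * n_diploid) - assoc
  )
}

#' Estimate allele frequencies from genotype dosages
#'
#' The synthetic-pathway mirror of a frequency lookup: given per-sample
#' genotype dosages (count of the associated allele, 0/1/2, `NA` = missing
#' call), computes the per-population associated-allele frequency
#' `sum(dosage) / (2 * n_called)`. Missing genotypes are excluded from both
#' numerator and denominator; a population with no called genotypes at a
#' SNP gets `NA`.
#'
#' @param genotypes Tibble with columns `sample`, `population`, `rsid`,
#'   `dosage` (as produced by [simulate_genotypes()] / [read_cohort()]).
#' @return Tibble with columns `population`, `rsid`, `n_called`, `freq`.
#' @export
estimate_frequencies <- function(genotypes) {
  stopifnot(all(c("sample", "population", "rsid", "dosage") %in% names(genotypes)))
  bad <- !is.na(genotypes$dosage) & !genotypes$dosage %in% c(0, 1, 2)
  if (any(bad)) {
    abort("dosage codes must be 0, 1, 2 or NA", class = "snpload_validation_error")
  }
  genotypes |>
    dplyr::group_by(.data$population, .data$rsid) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$dosage)),
      freq = ifelse(n_called > 0,
                    sum(.data$dosage, na.rm = TRUE) / (2 * n_called),
                    NA_real_),
      .groups = "drop"
    )
}
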