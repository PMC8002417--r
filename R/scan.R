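#' Pairwise cross-population association scan
#'
#' For every retained SNP and every unordered pair of populations,
#' reconstructs the 2x2 allele-count table from the panel frequencies
#' ([allele_counts()]), runs the two-sided Fisher exact test
#' ([fisher_exact_p()]), estimates the allelic odds ratio with its Woolf
#' confidence interval ([odds_ratio_ci()]), and attaches all five
#' corrected p-values. Corrections are applied within each population
#' pair's family of tests (m = retained-SNP count) by default, or to the
#' global family of all pair-by-SNP tests with `family = "global"`.
#'
#' Variants with an uninformative associated allele are dropped via
#' [filter_informative()] before testing.
#'
#' @param panel A `snp_panel` tibble.
#' @param sample_sizes Named vector of diploid sample sizes covering every
#'   panel population; defaults to [default_sample_sizes()].
#' @param alpha Significance threshold, default `0.05`.
#' @param method Correction used for the `significant` flag; default
#'   `"bonferroni"`, the most conservative of the five.
#' @param family `"pair"` (default) or `"global"` correction family.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return An `assoc_scan` tibble with one row per SNP per population pair:
#'   `rsid`, `pop_a`, `pop_b`, cells `a`, `b`, `c`, `d`, `p_raw`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_bonferroni`, `p_holm`,
#'   `p_sidak`, `p_bh`, `q_value`, `degenerate`, `significant`.
#' @examples
#' scan <- pairwise_scan(behaviour_panel(warn = FALSE))
#' nrow(scan)  # 21 SNPs x 15 pairs = 315
#' @export
pairwise_scan <- function(panel,
                          sample_sizes = default_sample_sizes(),
                          alpha = 0.05,
                          method = c("bonferroni", "holm", "sidak", "bh", "qvalue"),
                          family = c("pair", "global"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  family <- match.arg(family)
  stopifnot(alpha >= 0, alpha <= 1)
  pops <- panel_populations(panel)
  if (length(pops) < 2) {
    abort("pairwise scan needs at least two populations",
          class = "snpload_validation_error")
  }
  missing_n <- setdiff(pops, names(sample_sizes))
  if (length(missing_n) > 0) {
    abort(paste0("no sample size supplied for population(s): ",
                 paste(missing_n, collapse = ", ")),
          class = "snpload_config_error")
  }
  if (any(panel$associated_allele == "n.c.") ||
      anyNA(dplyr::select(panel, dplyr::all_of(paste0("freq_", pops))))) {
    panel <- filter_informative(panel, pops)
  }

  pairs <- utils::combn(pops, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    pa <- pairs[1, j]
    pb <- pairs[2, j]
    ca <- allele_counts(panel[[paste0("freq_", pa)]], sample_sizes[[pa]])
    cb <- allele_counts(panel[[paste0("freq_", pb)]], sample_sizes[[pb]])
    tibble::tibble(
      rsid = panel$rsid, pop_a = pa, pop_b = pb,
      a = ca$associated, b = ca$other, c = cb$associated, d = cb$other
    )
  })
  res$p_raw <- fisher_exact_p(res$a, res$b, res$c, res$d)
  res <- dplyr::bind_cols(
    res, odds_ratio_ci(res$a, res$b, res$c, res$d, conf_level = conf_level)
  )
  res$degenerate <- (res$a + res$c) == 0 | (res$b + res$d) == 0 |
    (res$a + res$b) == 0 | (res$c + res$d) == 0

  adj <- function(p, meth) {
    if (family == "global") {
      adjust_pvalues(p, meth)
    } else {
      stats::ave(p, paste(res$pop_a, res$pop_b),
                 FUN = function(x) adjust_pvalues(x, meth))
    }
  }
  res$p_bonferroni <- adj(res$p_raw, "bonferroni")
  res$p_holm <- adj(res$p_raw, "holm")
  res$p_sidak <- adj(res$p_raw, "sidak")
  res$p_bh <- adj(res$p_raw, "bh")
  res$q_value <- adj(res$p_raw, "qvalue")
  method_col <- if (method == "qvalue") "q_value" else paste0("p_", method)
  res$significant <- res[[method_col]] < alpha

  res <- dplyr::select(res, -"haldane")
  structure(res,
            class = c("assoc_scan", class(res)),
            populations = pops, alpha = alpha, method = method,
            family = family, n_snps = nrow(panel))
}

#' Per-pair counts of significant variants
#'
#' Summarises an association scan into, for each population pair, the
#' number of variants with significant and non-significant frequency
#' differences under a chosen correction and threshold -- the tabular twin
#' of the usual paired-bars figure.
#'
#' @param scan An `assoc_scan` tibble from [pairwise_scan()].
#' @param alpha Significance threshold; defaults to the scan's.
#' @param method Correction method; defaults to the scan's.
#' @return A `sig_counts` tibble: `pop_a`, `pop_b`, `n_significant`,
#'   `n_not_significant` (rows sum to the retained-SNP count).
#' @export
significance_counts <- function(scan,
                                alpha = attr(scan, "alpha") %||% 0.05,
                                method = attr(scan, "method") %||% "bonferroni") {
  method_col <- if (method == "qvalue") "q_value" else paste0("p_", method)
  stopifnot(method_col %in% names(scan))
  out <- scan |>
    dplyr::group_by(.data$pop_a, .data$pop_b) |>
    dplyr::summarise(
      n_significant = sum(.data[[method_col]] < alpha),
      n_not_significant = sum(.data[[method_col]] >= alpha),
      .groups = "drop"
    )
  structure(out,
            class = c("sig_counts", class(out)),
            alpha = alpha, method = method)
}
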