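#' Hardy-Weinberg genotype frequencies
#'
#' Genotype class frequencies implied by random mating at associated-allele
#' frequency `p`: homozygous associated `p^2`, heterozygous `2p(1-p)`,
#' homozygous other `(1-p)^2`. Vectorized.
#'
#' @param p Associated-allele proportion(s) in `[0, 1]`.
#' @return Tibble with columns `p`, `f_hom_assoc`, `f_het`, `f_hom_other`
#'   (rows sum to 1).
#' @examples
#' hwe_genotype_freqs(0.84)
#' @export
hwe_genotype_freqs <- function(p) {
  check_proportion(p)
  tibble::tibble(
    p = p,
    f_hom_assoc = p^2,
    f_het = 2 * p * (1 - p),
    f_hom_other = (1 - p)^2
  )
}

#' Expected associated-allele dosage under HWE
#'
#' The expected number of copies of the associated allele carried by one
#' individual at a locus with allele frequency `p`:
#' `2*p^2 + 1*2p(1-p) = 2p`, in `[0, 2]`.
#'
#' @inheritParams hwe_genotype_freqs
#' @return Numeric vector of expected dosages.
#' @export
expected_dosage <- function(p) {
  check_proportion(p)
  2 * p
}

check_proportion <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("proportions must be non-missing and within [0, 1]",
          class = "snpload_validation_error")
  }
  invisible(p)
}

#' Per-SNP expected dosages for each population
#'
#' Long table of expected associated-allele dosages (`2p`) for every
#' retained SNP and population of a panel.
#'
#' @param panel A `snp_panel` tibble; filtered automatically if needed.
#' @param populations Populations to include; defaults to all.
#' @return Tibble with columns `population`, `rsid`, `freq`, `dosage`.
#' @export
snp_dosages <- function(panel, populations = panel_populations(panel)) {
  panel <- ensure_informative(panel, populations)
  purrr::map_dfr(populations, function(pop) {
    freq <- panel[[paste0("freq_", pop)]]
    if (anyNA(freq)) {
      abort(paste0("missing ", pop, " frequency for: ",
                   paste(panel$rsid[is.na(freq)], collapse = ", ")),
            class = "snpload_validation_error")
    }
    tibble::tibble(population = pop, rsid = panel$rsid,
                   freq = freq, dosage = expected_dosage(freq))
  })
}

ensure_informative <- function(panel, populations = panel_populations(panel)) {
  cols <- paste0("freq_", populations)
  if (any(panel$associated_allele == "n.c.") ||
      anyNA(dplyr::select(panel, dplyr::all_of(cols)))) {
    panel <- filter_informative(panel, populations)
  }
  panel
}

#' Mean expected allele load per population
#'
#' The headline statistic: for each population, the expected number of
#' associated alleles carried per individual under HWE, i.e. the sum of
#' `2p` over the retained SNPs. Exact (no Monte-Carlo error).
#'
#' @inheritParams snp_dosages
#' @return A `pop_load` tibble: `population`, `n_snps`, `mean_load`.
#' @examples
#' population_load(behaviour_panel(warn = FALSE))
#' @export
population_load <- function(panel, populations = panel_populations(panel)) {
  out <- snp_dosages(panel, populations) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n_snps = dplyr::n(), mean_load = sum(.data$dosage),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$population, populations))
  structure(out, class = c("pop_load", class(out)))
}

#' Simulate per-individual allele loads
#'
#' Monte-Carlo realization of the HWE load model: each individual's
#' genotype at each SNP is drawn as Binomial(2, p), and the load is the
#' sum of dosages across SNPs. The mean and variance converge to
#' `sum(2p)` and `sum(2p(1-p))`.
#'
#' @inheritParams snp_dosages
#' @param population Single population label.
#' @param n_individuals Number of individuals to simulate, `>= 1`.
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   global RNG state untouched.
#' @return Integer vector of length `n_individuals`.
#' @export
simulate_individual_loads <- function(panel, population, n_individuals,
                                      seed = 42L) {
  stopifnot(length(population) == 1, n_individuals >= 1)
  dos <- snp_dosages(panel, population)
  withr::with_seed(seed, {
    draws <- vapply(dos$freq, function(p) rbinom(n_individuals, 2L, p),
                    integer(n_individuals))
    as.integer(rowSums(matrix(draws, nrow = n_individuals)))
  })
}

#' Compare expected allele loads between two populations
#'
#' Applies a two-sided Welch t-test and a two-sided Wilcoxon rank-sum test
#' (normal approximation with continuity correction, so ties in the
#' dosage vectors are handled deterministically) to the two populations'
#' per-SNP expected-dosage vectors. A paired variant (paired t-test and
#' signed-rank test over the per-SNP dosage differences) is available with
#' `paired = TRUE`.
#'
#' @inheritParams snp_dosages
#' @param pop_a,pop_b Population labels.
#' @param paired Pair the per-SNP dosages? Default `FALSE` (unpaired).
#' @return One-row tibble: `n_snps`, `pop_a`, `pop_b`, `p_t`, `p_wilcoxon`.
#' @export
compare_population_loads <- function(panel, pop_a, pop_b, paired = FALSE) {
  dos <- snp_dosages(panel, c(pop_a, pop_b))
  da <- dos$dosage[dos$population == pop_a]
  db <- dos$dosage[dos$population == pop_b]
  if (length(da) < 2) {
    abort("load comparison needs at least two SNPs",
          class = "snpload_validation_error")
  }
  p_t <- if (identical(da, db)) 1 else
    t.test(da, db, paired = paired, var.equal = FALSE)$p.value
  p_w <- suppressWarnings(
    wilcox.test(da, db, paired = paired, exact = FALSE, correct = TRUE)$p.value
  )
  tibble::tibble(n_snps = length(da), pop_a = pop_a, pop_b = pop_b,
                 p_t = p_t, p_wilcoxon = p_w)
}

#' All pairwise load comparisons
#'
#' Runs [compare_population_loads()] for every unordered pair of
#' populations.
#'
#' @inheritParams snp_dosages
#' @param paired Passed through to [compare_population_loads()].
#' @return A `load_comparison` tibble with one row per pair.
#' @examples
#' compare_all_loads(behaviour_panel(warn = FALSE))
#' @export
compare_all_loads <- function(panel, populations = panel_populations(panel),
                              paired = FALSE) {
  panel <- ensure_informative(panel, populations)
  pairs <- utils::combn(populations, 2L)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    compare_population_loads(panel, pairs[1, j], pairs[2, j], paired = paired)
  })
  structure(out, class = c("load_comparison", class(out)))
}
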