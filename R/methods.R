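#' Tidy an association scan
#'
#' @param x An `assoc_scan` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per SNP per population pair.
#' @method tidy assoc_scan
#' @export
tidy.assoc_scan <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' One-row summary of an association scan
#'
#' @param x An `assoc_scan` tibble.
#' @param ... Unused.
#' @return Tibble with `n_snps`, `n_pairs`, `n_tests`, `n_significant`,
#'   `alpha`, `method`, `family`.
#' @method glance assoc_scan
#' @export
glance.assoc_scan <- function(x, ...) {
  tibble::tibble(
    n_snps = attr(x, "n_snps"),
    n_pairs = dplyr::n_distinct(paste(x$pop_a, x$pop_b)),
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    method = attr(x, "method"),
    family = attr(x, "family")
  )
}

#' @method tidy pop_load
#' @export
tidy.pop_load <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' One-row summary of the population loads
#'
#' @param x A `pop_load` tibble.
#' @param ... Unused.
#' @return Tibble with `n_populations`, `min_load`, `max_load`,
#'   `band_width`.
#' @method glance pop_load
#' @export
glance.pop_load <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x),
    min_load = min(x$mean_load),
    max_load = max(x$mean_load),
    band_width = max(x$mean_load) - min(x$mean_load)
  )
}

#' @method tidy load_comparison
#' @export
tidy.load_comparison <- function(x, ...) tibble::as_tibble(unclass_result(x))

#' One-row summary of the pairwise load comparisons
#'
#' @param x A `load_comparison` tibble.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `min_p_t`, `min_p_wilcoxon`,
#'   `all_nonsignificant` (at 0.05).
#' @method glance load_comparison
#' @export
glance.load_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    min_p_t = min(x$p_t),
    min_p_wilcoxon = min(x$p_wilcoxon),
    all_nonsignificant = all(x$p_t > 0.05 & x$p_wilcoxon > 0.05)
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("assoc_scan", "sig_counts", "pop_load",
                                  "load_comparison", "snp_panel"))
  attr(x, "populations") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "method") <- NULL
  attr(x, "family") <- NULL
  attr(x, "n_snps") <- NULL
  attr(x, "excluded") <- NULL
  x
}

#' Plot per-pair significant-variant counts
#'
#' Paired-bars chart of significant vs non-significant variant counts for
#' each population pair, the graphical twin of [significance_counts()].
#'
#' @param object A `sig_counts` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sig_counts
#' @export
autoplot.sig_counts <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object)) |>
    dplyr::mutate(pair = paste0(.data$pop_a, "-", .data$pop_b)) |>
    tidyr::pivot_longer(c("n_significant", "n_not_significant"),
                        names_to = "status", values_to = "n") |>
    dplyr::mutate(status = ifelse(.data$status == "n_significant",
                                  "significant", "not significant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$n, fill = .data$status)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("significant" = "darkorange",
                                          "not significant" = "forestgreen")) +
    ggplot2::labs(x = "population pair", y = "number of variants", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mean expected allele load per population
#'
#' @param object A `pop_load` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pop_load
#' @export
autoplot.pop_load <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$mean_load)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "population",
                  y = "mean expected associated alleles per individual") +
    ggplot2::theme_minimal()
}

#' Plot pairwise load-comparison p-values
#'
#' Dot plot of the t-test and Wilcoxon p-values for every population
#' pair, with the 0.05 threshold marked.
#'
#' @param object A `load_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot load_comparison
#' @export
autoplot.load_comparison <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object)) |>
    dplyr::mutate(pair = paste0(.data$pop_a, "-", .data$pop_b)) |>
    tidyr::pivot_longer(c("p_t", "p_wilcoxon"),
                        names_to = "test", values_to = "p") |>
    dplyr::mutate(test = ifelse(.data$test == "p_t", "t-test", "Wilcoxon"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$p, colour = .data$test)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "population pair", y = "p-value", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
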