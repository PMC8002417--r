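#' Two-sided Fisher exact test for a 2x2 allele-count table
#'
#' Tests association in the table `rbind(c(a, b), c(c, d))` (row 1 =
#' population A associated/other allele counts, row 2 = population B) by
#' full enumeration of the hypergeometric distribution over the observed
#' margins. The two-sided p-value follows the probability-mass rule: the
#' sum of the probabilities of all margin-consistent tables whose
#' probability does not exceed the observed table's (with a relative
#' tolerance of 1e-7 on the comparison, the usual convention for this
#' test). A table with a zero row or column margin carries no information
#' and returns `p = 1`.
#'
#' Vectorized over `a`, `b`, `c`, `d`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_p(10, 0, 0, 10)  # ~1.08e-5
#' fisher_exact_p(5, 5, 5, 5)    # 1
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort("cell counts must be non-negative integers",
          class = "snpload_validation_error")
  }
  purrr::pmap_dbl(list(a, b, c, d), fisher_exact_p1)
}

fisher_exact_p1 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  tot <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == tot || c1 == tot) {
    return(1)  # degenerate margin: no information
  }
  support <- max(0, c1 - (tot - r1)):min(r1, c1)
  probs <- dhyper(support, c1, tot - c1, r1)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  if (p >= 1 - 1e-12) p <- 1  # full support summed: exact 1 up to fp error
  p
}

#' Odds ratio with Woolf confidence interval
#'
#' Sample (unconditional) odds ratio `(a*d)/(b*c)` for the table
#' `rbind(c(a, b), c(c, d))`, with the Haldane-Anscombe correction (0.5
#' added to every cell) applied whenever any cell is zero, and the Woolf
#' log-normal confidence interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` computed on the
#' (possibly corrected) cells. Vectorized.
#'
#' @inheritParams fisher_exact_p
#' @param conf_level Confidence level, default `0.95`.
#' @return Tibble with columns `odds_ratio`, `ci_low`, `ci_high`,
#'   `haldane` (whether the correction was applied).
#' @examples
#' odds_ratio_ci(20, 80, 40, 60)  # OR = 0.375
#' odds_ratio_ci(10, 0, 0, 10)    # Haldane-corrected, OR = 441
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  haldane <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * haldane
  b <- b + 0.5 * haldane
  c <- c + 0.5 * haldane
  d <- d + 0.5 * haldane
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    haldane = haldane
  )
}

#' Multiple-testing corrections
#'
#' Adjusts a vector of p-values by one of five methods: `"bonferroni"`
#' (`min(1, m*p)`), `"holm"` (step-down), `"sidak"` (`1 - (1-p)^m`),
#' `"bh"` (Benjamini-Hochberg step-up) or `"qvalue"` (Storey q-values with
#' the null proportion estimated at a single lambda = 0.5,
#' `pi0 = min(1, mean(p > 0.5) / 0.5)` clamped away from zero). Bonferroni,
#' Holm and BH delegate to [stats::p.adjust()]. Output order matches input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"bonferroni"`, `"holm"`, `"sidak"`, `"bh"`,
#'   `"qvalue"`.
#' @return Numeric vector of adjusted values in `[0, 1]`.
#' @examples
#' adjust_pvalues(c(0.01, 0.04), "holm")            # 0.02, 0.04
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh")  # all 0.04
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm", "sidak", "bh", "qvalue")) {
  method <- match.arg(method)
  if (length(p) < 1 || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be non-missing and within [0, 1]",
          class = "snpload_validation_error")
  }
  m <- length(p)
  switch(method,
    bonferroni = p.adjust(p, "bonferroni"),
    holm       = p.adjust(p, "holm"),
    bh         = p.adjust(p, "BH"),
    sidak      = 1 - (1 - p)^m,
    qvalue     = storey_qvalue(p)
  )
}

# Storey q-values with pi0 estimated at a single lambda = 0.5 (no smoother:
# deterministic and appropriate at small m). q_i = pi0 * BH_i, which is the
# cumulative-min form min_{j >= rank(i)} pi0 * m * p_(j) / j.
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- mean(p > lambda) / (1 - lambda)
  pi0 <- min(1, max(pi0, .Machine$double.eps))
  pmin(1, pi0 * p.adjust(p, "BH"))
}
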