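test_that("two-sided exact p matches frozen enumeration values", {
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_p(3, 7, 7, 3), 0.178895408, tolerance = 1e-8)
  # degenerate margins carry no information
  expect_equal(fisher_exact_p(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_p(0, 0, 5, 5), 1)
  expect_error(fisher_exact_p(-1, 1, 1, 1), class = "snpload_validation_error")
})

test_that("exact p is invariant under row and column swaps and matches fisher.test", {
  set.seed(101)
  for (i in 1:50) {
    tb <- rpois(4, 20)
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
    p <- fisher_exact_p(a, b, c, d)
    expect_equal(fisher_exact_p(c, d, a, b), p, tolerance = 1e-12)  # row swap
    expect_equal(fisher_exact_p(b, a, d, c), p, tolerance = 1e-12)  # column swap
    if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
      expect_equal(p, fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                   tolerance = 1e-8)
    }
  }
})

test_that("exact p agrees with the brute-force oracle on small tables", {
  for (n in c(5L, 12L, 16L)) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[combos$a + combos$b + combos$c <= n, ]
    combos$d <- n - combos$a - combos$b - combos$c
    p_impl <- fisher_exact_p(combos$a, combos$b, combos$c, combos$d)
    p_oracle <- mapply(brute_fisher_p, combos$a, combos$b, combos$c, combos$d)
    expect_lt(max(abs(p_impl - p_oracle)), 1e-10)
  }
})

test_that("odds ratios use the Woolf interval with Haldane correction at zeros", {
  sym <- odds_ratio_ci(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  hz <- odds_ratio_ci(10, 0, 0, 10)
  expect_true(hz$haldane)
  expect_equal(hz$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))

  # independent hand computation of the Woolf interval for (20,80 / 40,60)
  wf <- odds_ratio_ci(20, 80, 40, 60)
  expect_equal(wf$odds_ratio, 0.375)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 40 + 1 / 60)
  expect_equal(wf$ci_low, exp(log(0.375) - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(wf$ci_high, exp(log(0.375) + qnorm(0.975) * se), tolerance = 1e-12)
  expect_true(wf$ci_low <= wf$odds_ratio && wf$odds_ratio <= wf$ci_high)
})

test_that("p-value corrections reproduce hand computations", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"), rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "sidak"),
               1 - (1 - c(0.01, 0.04))^2)
  # Storey q at lambda 0.5: pi0 = min(1, 2 * mean(p > 0.5)) then pi0 * BH
  ps <- c(0.01, 0.2, 0.6, 0.7, 0.8)
  pi0 <- min(1, mean(ps > 0.5) / 0.5)
  expect_equal(adjust_pvalues(ps, "qvalue"),
               pmin(1, pi0 * p.adjust(ps, "BH")))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), class = "snpload_validation_error")
})

test_that("correction orderings hold across random p-vectors", {
  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(2:40, 1))
    bh <- adjust_pvalues(p, "bh")
    holm <- adjust_pvalues(p, "holm")
    bonf <- adjust_pvalues(p, "bonferroni")
    sidak <- adjust_pvalues(p, "sidak")
    expect_true(all(p <= bh + 1e-12))
    expect_true(all(bh <= holm + 1e-12))
    expect_true(all(holm <= bonf + 1e-12))
    expect_true(all(sidak <= bonf + 1e-12))
    expect_true(all(c(bh, holm, bonf, sidak) >= 0 &
                      c(bh, holm, bonf, sidak) <= 1))
  }
})

test_that("pairwise scan produces one row per SNP per unordered pair", {
  scan <- suppressMessages(pairwise_scan(filtered_fixture()))
  expect_equal(nrow(scan), 15 * 21)
  expect_equal(dplyr::n_distinct(paste(scan$pop_a, scan$pop_b)), 15)
  # corrected p-values never fall below raw (the four FWER/FDR corrections)
  expect_true(all(scan$p_bonferroni >= scan$p_raw - 1e-12))
  expect_true(all(scan$p_holm >= scan$p_raw - 1e-12))
  expect_true(all(scan$p_sidak >= scan$p_raw - 1e-12))
  expect_true(all(scan$p_bh >= scan$p_raw - 1e-12))
  expect_true(all(scan$ci_low <= scan$odds_ratio + 1e-12 &
                    scan$odds_ratio <= scan$ci_high + 1e-12))
  # the monomorphic variant is degenerate and uninformative in every pair
  mono <- scan[scan$rsid == "rs79874540", ]
  expect_true(all(mono$p_raw == 1))
  expect_true(all(mono$degenerate))
  expect_true(all(is.finite(mono$odds_ratio)))
})

test_that("identical frequencies give p = 1 and a zero significance count", {
  p2 <- make_panel(list(P1 = c(.2, .5, .8), P2 = c(.2, .5, .8)))
  scan <- pairwise_scan(p2, sample_sizes = c(P1 = 100L, P2 = 100L))
  expect_true(all(scan$p_raw == 1))
  expect_false(any(scan$significant))

  counts0 <- significance_counts(scan, alpha = 0)
  expect_equal(counts0$n_significant, 0L)
  expect_equal(counts0$n_not_significant, 3L)
})

test_that("one extreme SNP among nulls is the only Bonferroni discovery", {
  freqs1 <- c(0.95, rep(0.5, 20))
  freqs2 <- c(0.05, rep(0.5, 20))
  pn <- make_panel(list(P1 = freqs1, P2 = freqs2))
  scan <- pairwise_scan(pn, sample_sizes = c(P1 = 100L, P2 = 100L))
  counts <- significance_counts(scan)
  expect_equal(counts$n_significant, 1L)
  expect_equal(counts$n_not_significant, 20L)
  expect_equal(counts$n_significant + counts$n_not_significant, nrow(pn))
})

test_that("scan errors without a sample size for each population", {
  expect_error(
    pairwise_scan(filtered_fixture(), sample_sizes = c(AFR = 661L)),
    class = "snpload_config_error"
  )
})

test_that("global correction family is more conservative than per-pair", {
  f <- filtered_fixture()
  per_pair <- suppressMessages(pairwise_scan(f))
  global <- suppressMessages(pairwise_scan(f, family = "global"))
  expect_true(all(global$p_bonferroni >= per_pair$p_bonferroni - 1e-12))
  expect_lte(sum(global$significant), sum(per_pair$significant))
})
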