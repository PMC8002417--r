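test_that("simulated panels respect bounds and are seed-deterministic", {
  p <- simulate_panel(21, c("AFR", "AMR", "EAS", "EUR", "TSI", "SAS"), seed = 42L)
  expect_equal(nrow(p), 21)
  fr <- as.matrix(dplyr::select(p, dplyr::starts_with("freq_")))
  expect_true(all(fr >= 0.05 & fr <= 0.95))
  expect_false(any(duplicated(p$rsid)))

  expect_identical(simulate_panel(10, c("A", "B"), seed = 1L),
                   simulate_panel(10, c("A", "B"), seed = 1L))
  expect_false(identical(simulate_panel(10, c("A", "B"), seed = 1L),
                         simulate_panel(10, c("A", "B"), seed = 2L)))
  expect_error(simulate_panel(5, "A", freq_range = c(0.9, 0.1)),
               class = "snpload_validation_error")

  # degenerate sampler: identical tables give p = 1 at equal sample sizes
  pd <- simulate_panel(5, c("A", "B"), freq_range = c(0.5, 0.5), seed = 3L)
  scan <- pairwise_scan(pd, sample_sizes = c(A = 100L, B = 100L))
  expect_true(all(scan$p_raw == 1))
})

test_that("genotype simulation matches HWE and its inbreeding perturbation", {
  p1 <- make_panel(list(P1 = 0.5))
  g <- simulate_genotypes(p1, "P1", 20000, inbreeding_f = 0, seed = 5L)
  het <- mean(g$dosage == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 20000))

  g1 <- simulate_genotypes(p1, "P1", 2000, inbreeding_f = 1, seed = 5L)
  expect_false(any(g1$dosage == 1))

  g0 <- simulate_genotypes(make_panel(list(P1 = 0)), "P1", 100, seed = 5L)
  expect_true(all(g0$dosage == 0))

  expect_error(simulate_genotypes(p1, "P1", 10, inbreeding_f = 2),
               class = "snpload_validation_error")
  expect_identical(simulate_genotypes(p1, "P1", 50, seed = 9L),
                   simulate_genotypes(p1, "P1", 50, seed = 9L))
})

test_that("a cohort round-trips bit-identically through VCF + panel files", {
  pn <- make_panel(list(P1 = c(0.3, 0.7)))
  g <- simulate_genotypes(pn, "P1", 3, seed = 13L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  smp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(g, panel = pn, vcf_path = vcf, panel_path = smp)

  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  rec <- strsplit(body[1], "\t")[[1]]
  expect_equal(rec[3], "rs1")
  expect_equal(rec[4], "G")  # REF = other allele
  expect_equal(rec[5], "A")  # ALT = associated allele

  back <- read_cohort(vcf, smp)
  expect_identical(back, g)

  est <- estimate_frequencies(back)
  man <- estimate_frequencies(g)
  expect_identical(est, man)
})

test_that("missing calls are written as ./. and excluded from denominators", {
  pn <- make_panel(list(P1 = c(0.5)))
  g <- simulate_genotypes(pn, "P1", 4, seed = 21L)
  g$dosage[2] <- NA
  vcf <- withr::local_tempfile(fileext = ".vcf")
  smp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(g, panel = pn, vcf_path = vcf, panel_path = smp)
  expect_true(any(grepl("\\./\\.", readLines(vcf))))
  back <- read_cohort(vcf, smp)
  expect_true(is.na(back$dosage[back$sample == g$sample[2]]))
  est <- estimate_frequencies(back)
  expect_equal(est$n_called, 3L)
  expect_equal(est$freq, sum(g$dosage, na.rm = TRUE) / 6)
})

test_that("a cohort at the published AFR frequencies recovers them within 3 SE", {
  f <- filtered_fixture()
  n <- 661L
  g <- simulate_genotypes(f, "AFR", n, seed = 29L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  smp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(g, panel = f, vcf_path = vcf, panel_path = smp)
  est <- estimate_frequencies(read_cohort(vcf, smp))
  est <- est[match(f$rsid, est$rsid), ]
  p <- f$freq_AFR
  se <- sqrt(p * (1 - p) / (2 * n))
  expect_true(all(abs(est$freq - p) <= 3 * se + 1e-12))
})

test_that("the end-to-end synthetic null keeps the scan's type-I error at bay", {
  # two populations simulated at identical frequencies; frequencies are
  # re-estimated from the cohort, rebuilt into a panel, and scanned
  base <- simulate_panel(150, "P1", seed = 31L)
  base$freq_P2 <- base$freq_P1
  attr(base, "populations") <- c("P1", "P2")
  g <- dplyr::bind_rows(
    simulate_genotypes(base, "P1", 100, seed = 37L),
    simulate_genotypes(base, "P2", 100, seed = 41L)
  )
  est <- estimate_frequencies(g) |>
    tidyr::pivot_wider(id_cols = "rsid", names_from = "population",
                       values_from = "freq", names_prefix = "freq_")
  panel2 <- dplyr::left_join(
    dplyr::select(base, "gene", "rsid", "allele1", "allele2", "associated_allele"),
    est, by = "rsid")
  panel2 <- snpload:::new_snp_panel(panel2, populations = c("P1", "P2"))
  scan <- pairwise_scan(panel2, sample_sizes = c(P1 = 100L, P2 = 100L))
  frac <- mean(scan$p_raw < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(scan)))
})
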