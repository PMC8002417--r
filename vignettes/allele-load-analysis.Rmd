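---
title: "Cross-population exact tests and the expected allele-load statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population exact tests and the expected allele-load statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpload)
```

## The question and the data

A recurring claim in behavioural genetics is that particular SNP alleles in
serotoninergic, dopaminergic and related pathways (genes such as *MAOA*,
*SLC6A4*, *TPH1/2*, *COMT*, *HTR1B/2A/2B*, *BDNF*, *DRD4*, *ApoE*, *NR3C2*)
predispose carriers to antisocial or aggressive behaviour. `snpload`
operationalises a two-part sanity check of such claims at the population
scale:

1. **Per-variant comparison.** Individually, candidate-allele frequencies
   differ strongly between continental populations — exactly as they do for
   arbitrary neutral variants, because populations are genetically distant.
2. **Aggregate comparison.** When the candidate alleles are pooled into a
   single per-person *expected allele load*, the populations are
   statistically indistinguishable: no population carries systematically
   more "risk" alleles than another.

The packaged input (`behaviour_snp_panel.tsv`) is a transcription of a
published 24-variant candidate panel with associated-allele frequencies, as
whole percentages, for six 1000 Genomes groupings: the AFR, AMR, EAS, EUR
and SAS super-populations plus TSI (Toscani in Italy) treated separately.
Three entries (rs1346551029, rs761010487, rs28363170 — structural/VNTR
polymorphisms) have no usable associated-allele frequency and carry the
`n.c.` sentinel; `filter_informative()` excludes them, leaving 21 variants.

Frequencies are taken as printed and never re-derived: the percent integers
divided by 100 *are* the analysis input. Two rows required a pinned
convention:

* **rs7322347, TSI.** The source row lists alleles C/T although the variant
  is T/A everywhere else in the row. We keep the row's two-allele structure
  and store the second-listed value (51%) as the associated-allele (A)
  frequency. The package does not guess the intended correction; it records
  the convention and warns every time the packaged panel is loaded with
  `behaviour_panel(warn = TRUE)`.
* **ApoE rs7412 / rs429358.** Both rows label T as the associated allele
  (annotated as the ε4 haplotype). Taken biologically, rs7412-T tags ε2
  rather than ε4, but the package implements the table exactly as printed;
  re-curating the haplotype assignment would change the input data, not the
  method.

A third convention: rs79874540 is monomorphic (associated allele A at 0%
in every population). Its frequency is *available* — it is zero — so the
variant is retained by `filter_informative()`, keeping the analysed count
at 21. In every pairwise test it yields an empty associated-allele margin,
which the exact test reports as `p = 1` with the `degenerate` flag set.

## From printed frequencies to exact tests

The original analysis tested genotype data; only the frequencies were
published. `allele_counts()` reconstructs allele counts as
`associated = round_half_up(2 * n * freq)` with deterministic half-up
rounding (platform-independent, unlike banker's rounding). Reconstruction
then inversion changes a frequency by at most `1/(2n)`, and every
downstream statistic is frequency-driven, so results are insensitive to
small errors in `n`. Default diploid sample sizes are the 1000 Genomes
phase-3 sizes for the populations analysed (AFR 661, AMR 347, EAS 504,
EUR 503, SAS 489, TSI 107); all are configurable.

For each of the `C(6,2) = 15` unordered population pairs and each retained
variant, `pairwise_scan()` forms the 2×2 table of associated/other allele
counts and computes:

* **Two-sided Fisher exact p.** Full enumeration of the hypergeometric
  distribution over the observed margins; the two-sided p-value is the sum
  of probabilities of all margin-consistent tables whose probability does
  not exceed the observed table's. Two-sided exact tests have several
  competing definitions; the probability-mass rule is pinned here because
  it is the convention of the major statistical environments, and the
  comparison uses a relative tolerance of `1e-7` so that ties in table
  probability are not broken by floating-point noise. A table whose margins
  contain a zero carries no information and is reported as `p = 1` with a
  flag rather than an error. The implementation is vectorized over tables;
  its agreement with an independent brute-force enumeration oracle (to
  `1e-10`, every table with total ≤ 40) and with `stats::fisher.test` is
  part of the test suite.
* **Allelic odds ratio.** The unconditional sample OR `(ad)/(bc)` with the
  Woolf log-normal confidence interval, applying the Haldane–Anscombe
  +0.5-to-every-cell correction whenever any cell is zero. The conditional
  MLE (what `fisher.test` estimates) is deliberately not used: the sample
  OR is the convention in frequency-comparison studies, and an exact CI is
  out of scope.
* **Five corrected p-values.** Bonferroni, Holm and Benjamini–Hochberg via
  `stats::p.adjust`; Šidák as `1 - (1-p)^m`; Storey q-values with the null
  proportion estimated at a single λ = 0.5
  (`π̂0 = min(1, mean(p > 0.5)/0.5)`, clamped away from zero). A λ-smoother
  would be noise at m = 21, so a fixed λ keeps the estimate deterministic.
  Note one structural fact: the four FWER/FDR corrections never fall below
  the raw p-value, but Storey q-values can (whenever `π̂0 < 1`, the largest
  p maps to `π̂0 · p < p`); tests therefore assert the ordering
  `raw ≤ BH ≤ Holm ≤ Bonferroni` and `Šidák ≤ Bonferroni` only.

The correction *family* defaults to each pair's own 21 tests, matching the
per-pair framing of the published comparison list; `family = "global"`
corrects across all 315 tests instead. The significance flag defaults to
Bonferroni at α = 0.05 — the most conservative choice, so any significance
claim survives the strictest correction.

## The expected allele-load statistic

Under Hardy–Weinberg equilibrium at associated-allele frequency `p`, the
genotype classes have frequencies `p²`, `2p(1-p)`, `(1-p)²` and the
expected number of associated-allele copies per individual is
`2p² + 2p(1-p) = 2p`. The population's **mean expected load** is the sum of
`2p` over retained variants — "weighted average" in the sense that genotype
classes are weighted by their HWE frequencies. `population_load()` computes
this closed form exactly; `simulate_individual_loads()` provides the
Monte-Carlo counterpart (per-SNP Binomial(2, p) draws), whose mean and
variance converge to `Σ2p` and `Σ2p(1−p)` — a convergence the test suite
checks at n = 10,000 under a fixed seed.

Two X-linked variants (*MAOA* rs6323 and rs1137070) are treated as
autosomal diploid, i.e. contribute `2p` like every other locus. At a 1:1
sex ratio a sex-aware expectation would be `1.5p` per person; the
2-alleles-per-person convention is the default because it is the one under
which the published 15.7–17.3 load band is recovered, and because the
frequency table carries no sex information.

On the packaged panel the six mean loads are 15.72 (TSI) to 17.52 (SAS)
alleles per person. The lower end reproduces the published floor of 15.7;
the upper end sits 0.2 above the published 17.3, which is the expected
consequence of whole-percent rounding in the printed frequencies (21 summed
frequencies, each rounded to ±0.5%, move the sum by up to ±0.21 alleles
after doubling). The acceptance checks therefore target the floor exactly
and bound the ceiling at 17.6 with a band width ≤ 2.0, rather than chasing
a digit the printed input cannot reproduce.

`compare_population_loads()` compares two populations by applying a Welch
two-sided t-test and a two-sided Wilcoxon rank-sum test to their per-SNP
expected-dosage vectors (n = 21 per group, unpaired). The published
analysis does not state what its test samples were; per-SNP dosage vectors
are the only published-data-derivable choice, and with it all 15 pairs come
out nonsignificant with p-values in qualitative agreement with the
published table (e.g. AMR–AFR 0.92/0.63 against the printed 0.95/0.67).
Digit-level agreement is not expected and not asserted. Because the same 21
loci appear in both groups, a paired variant (paired t, signed-rank) is
available via `paired = TRUE`; it is not the default because the published
p-values are clearly closer to the unpaired construction. The Wilcoxon test
uses the normal approximation with continuity correction throughout: the
dosage vectors contain ties, under which the exact null distribution is
undefined and R would silently fall back to the approximation anyway —
making it explicit keeps p-values deterministic.

## What the synthetic generator emulates — and what it does not

`simulate_panel()` (frequencies uniform on [0.05, 0.95] by default, the
range of a common, well-ascertained SNP), `simulate_genotypes()` and
`write_cohort()`/`read_cohort()` generate 1000-Genomes-shaped data: a panel
of biallelic SNPs with population-specific frequencies, diploid genotypes
drawn per-locus from HWE — optionally perturbed by an inbreeding
coefficient `f`, with class probabilities
`(p² + fpq, 2pq(1−f), q² + fpq)` — and a minimal VCF v4.2 (unphased GT,
`/` separator, ALT = associated allele so ALT dosage equals the
associated-allele count, `./.` for missing calls) plus an
`integrated_call_samples`-style sample panel. Every stochastic operation
takes an explicit seed (default 42) and restores the global RNG state, so
runs are exactly reproducible.

Deliberately absent: linkage disequilibrium between loci (the analysis
treats loci independently, so simulating LD would test nothing this package
computes), realistic chromosome coordinates, and sex-aware X-chromosome
simulation. Passing parameter-recovery and type-I-error tests on this
generator shows the pipeline is statistically sound under its own model
assumptions — it does not validate HWE, panel ascertainment, or the
behavioural associations themselves in real data.

## Numerical and design choices, in one place

* Exact-test p-values within `1e-12` of 1 are snapped to exactly 1 (the
  full-support sum accumulates ~1e-16 of float error; identical allele
  frequencies must give p = 1, not 0.9999999999999998).
* Half-up rounding for count reconstruction; ties in table probability
  resolved with the `1e-7` relative tolerance; both choices pinned for
  cross-platform determinism.
* Corrections are computed within an explicitly stated family (per-pair
  default); q-value π̂0 uses a single λ = 0.5.
* Degenerate tables (zero margin) are flagged, not dropped, so every pair
  reports exactly 21 rows and significance counts always sum to 21.
* The pipeline writes timestamp-free TSV/JSON, so identical configurations
  produce byte-identical outputs (verified in the test suite).
* Problem sizes in the test suite — 10,000 simulated individuals for load
  convergence, a 661-individual VCF cohort for parameter recovery, 1,000
  null tables for type-I calibration, and the exhaustive ≤ 40-total table
  sweep for the exact-test oracle — were chosen as the smallest sizes at
  which the 3-standard-error bounds are meaningfully tight.

## Limitations

The package analyses printed frequencies, not genotypes: confidence
intervals and p-values inherit the ±0.5% quantisation of the source table,
and genotype-level (3×2) tests are only derivable under the same HWE
assumption the load statistic already makes. Nothing here assesses whether
the candidate variants are genuinely associated with behaviour — the
aggregate-load result is informative precisely because it holds *even if*
they all were.
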