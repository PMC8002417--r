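#' Simulate a SNP panel with population-specific frequencies
#'
#' Draws associated-allele frequencies independently per SNP and
#' population, by default uniform on `[0.05, 0.95]`. rsids are synthetic
#' (`snp_0001`, ...) and unique; alleles are fixed A (associated) / G.
#'
#' @param n_snps Number of SNPs, `>= 1`.
#' @param populations Character vector of population labels.
#' @param freq_range Length-2 bounds of the uniform frequency sampler,
#'   within `[0, 1]`. Collapse the range (`c(0.5, 0.5)`) for a degenerate
#'   panel with identical frequencies everywhere.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A `snp_panel` tibble.
#' @examples
#' simulate_panel(5, c("POP1", "POP2"), seed = 42)
#' @export
simulate_panel <- function(n_snps, populations = PANEL_POPULATIONS,
                           freq_range = c(0.05, 0.95), seed = 42L) {
  stopifnot(n_snps >= 1, length(populations) >= 1)
  if (length(freq_range) != 2 || any(freq_range < 0 | freq_range > 1) ||
      freq_range[1] > freq_range[2]) {
    abort("freq_range must be increasing bounds within [0, 1]",
          class = "snpload_validation_error")
  }
  freqs <- withr::with_seed(seed, {
    matrix(runif(n_snps * length(populations), freq_range[1], freq_range[2]),
           nrow = n_snps, dimnames = list(NULL, paste0("freq_", populations)))
  })
  panel <- tibble::tibble(
    gene = paste0("GENE", seq_len(n_snps)),
    rsid = sprintf("snp_%04d", seq_len(n_snps)),
    allele1 = "A", allele2 = "G", associated_allele = "A"
  )
  panel <- dplyr::bind_cols(panel, tibble::as_tibble(freqs))
  validate_panel(new_snp_panel(panel, populations = populations))
  new_snp_panel(panel, populations = populations)
}

#' Simulate diploid genotypes for one population
#'
#' Draws each individual's genotype at each SNP from the inbreeding-
#' perturbed HWE distribution: with allele frequency `p` and inbreeding
#' coefficient `f`, classes (hom. associated, het, hom. other) have
#' probabilities `(p^2 + f*p*(1-p), 2*p*(1-p)*(1-f), (1-p)^2 + f*p*(1-p))`.
#' `f = 0` is exact HWE; `f = 1` removes heterozygotes (useful as a
#' negative control).
#'
#' @param panel A `snp_panel` covering `population`.
#' @param population Single population label.
#' @param n_individuals Number of individuals, `>= 1`.
#' @param inbreeding_f Inbreeding coefficient in `[0, 1]`.
#' @param seed Integer seed.
#' @return Genotype tibble with columns `sample`, `population`, `rsid`,
#'   `dosage` (0/1/2 copies of the associated allele), sample within SNP
#'   in panel order.
#' @export
simulate_genotypes <- function(panel, population, n_individuals,
                               inbreeding_f = 0, seed = 42L) {
  stopifnot(length(population) == 1, n_individuals >= 1)
  if (inbreeding_f < 0 || inbreeding_f > 1) {
    abort("inbreeding_f must be within [0, 1]", class = "snpload_validation_error")
  }
  panel <- ensure_informative(panel, population)
  p <- panel[[paste0("freq_", population)]]
  f <- inbreeding_f
  samples <- sprintf("%s_%04d", population, seq_len(n_individuals))
  dosages <- withr::with_seed(seed, {
    purrr::map(p, function(pi) {
      probs <- c(pi^2 + f * pi * (1 - pi),
                 2 * pi * (1 - pi) * (1 - f),
                 (1 - pi)^2 + f * pi * (1 - pi))
      sample(c(2L, 1L, 0L), n_individuals, replace = TRUE, prob = probs)
    })
  })
  tidyr::expand_grid(rsid = panel$rsid, sample = samples) |>
    dplyr::mutate(
      population = population,
      dosage = unlist(dosages)
    ) |>
    dplyr::select("sample", "population", "rsid", "dosage")
}

#' Write a genotype cohort as VCF + sample panel
#'
#' Emits a minimal VCF v4.2 (one biallelic record per SNP; REF = other
#' allele, ALT = associated allele, so the ALT dosage equals the
#' associated-allele count; unphased `GT` with `/`; missing calls `./.`;
#' synthetic 1-based coordinates on contig `1`) plus a 1000-Genomes-style
#' sample panel file with header `sample pop super_pop gender`.
#'
#' @param genotypes Genotype tibble (see [simulate_genotypes()]); `NA`
#'   dosages become missing calls.
#' @param panel The `snp_panel` the genotypes were drawn from (supplies
#'   allele labels; SNPs absent from the panel get REF N / ALT A).
#' @param vcf_path,panel_path Output paths.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(genotypes, panel = NULL, vcf_path, panel_path) {
  rsids <- unique(genotypes$rsid)
  samples <- unique(genotypes$sample)
  wide <- genotypes |>
    dplyr::select("rsid", "sample", "dosage") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "dosage") |>
    dplyr::arrange(match(.data$rsid, rsids))
  gt_code <- c("0/0", "0/1", "1/1")

  ref <- rep("N", length(rsids))
  alt <- rep("A", length(rsids))
  if (!is.null(panel)) {
    idx <- match(rsids, panel$rsid)
    hit <- !is.na(idx)
    assoc <- panel$associated_allele[idx[hit]]
    other <- ifelse(assoc == panel$allele1[idx[hit]],
                    panel$allele2[idx[hit]], panel$allele1[idx[hit]])
    ref[hit] <- other
    alt[hit] <- assoc
  }

  body <- vapply(seq_along(rsids), function(i) {
    dos <- unlist(wide[i, samples])
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
    paste(c("1", i * 1000L, rsids[i], ref[i], alt[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpload",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), vcf_path)

  pop_of <- genotypes |>
    dplyr::distinct(.data$sample, .data$population) |>
    dplyr::arrange(match(.data$sample, samples))
  readr::write_tsv(
    tibble::tibble(sample = pop_of$sample, pop = pop_of$population,
                   super_pop = pop_of$population, gender = "unknown"),
    panel_path, progress = FALSE
  )
  invisible(c(vcf = vcf_path, panel = panel_path))
}

#' Read a genotype cohort from VCF + sample panel
#'
#' Parses the VCF through `vcfR` and joins population labels from the
#' sample panel file, returning the long genotype tibble used throughout
#' the package. Dosage is the count of ALT (associated) alleles; `./.`
#' becomes `NA`.
#'
#' @param vcf_path,panel_path Paths written by [write_cohort()] (or any
#'   biallelic VCF with GT plus a `sample/pop` panel file).
#' @return Genotype tibble with columns `sample`, `population`, `rsid`,
#'   `dosage`.
#' @export
read_cohort <- function(vcf_path, panel_path) {
  for (p in c(vcf_path, panel_path)) {
    if (!file.exists(p)) {
      abort(paste0("cohort file not found: ", p), class = "snpload_io_error")
    }
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  pop_tbl <- readr::read_tsv(
    panel_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  dosage_of <- function(g) {
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(alleles, function(al) {
      if (any(al == ".") || length(al) != 2) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
  }
  tibble::tibble(
    rsid = rep(rownames(gt), times = ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    dosage = dosage_of(as.vector(gt))
  ) |>
    dplyr::left_join(
      dplyr::select(pop_tbl, sample = "sample", population = "pop"),
      by = "sample"
    ) |>
    dplyr::select("sample", "population", "rsid", "dosage") |>
    dplyr::arrange(match(.data$rsid, rownames(gt)), match(.data$sample, colnames(gt)))
  }
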