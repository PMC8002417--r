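#' Assemble a pipeline configuration
#'
#' @param panel_path Panel TSV; defaults to the packaged behaviour panel.
#' @param sample_sizes Named diploid sample sizes; see
#'   [default_sample_sizes()].
#' @param alpha Significance threshold in `(0, 1)`.
#' @param method Correction method for the significance flag.
#' @param family Correction family, `"pair"` or `"global"`.
#' @param paired Paired load comparison? Default unpaired.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (used only by the optional synthetic block).
#' @param synthetic Optional list `list(n_per_pop =, inbreeding_f =)`
#'   requesting a simulated cohort (VCF + sample panel) alongside the
#'   reports.
#' @return A `run_config` list.
#' @export
run_config <- function(panel_path = system.file("extdata", "behaviour_snp_panel.tsv",
                                                package = "snpload"),
                       sample_sizes = default_sample_sizes(),
                       alpha = 0.05,
                       method = "bonferroni",
                       family = "pair",
                       paired = FALSE,
                       out_dir = "snpload_out",
                       seed = 42L,
                       synthetic = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single number in (0, 1)", class = "snpload_config_error")
  }
  if (!method %in% c("bonferroni", "holm", "sidak", "bh", "qvalue")) {
    abort("method must be one of bonferroni, holm, sidak, bh, qvalue",
          class = "snpload_config_error")
  }
  if (!family %in% c("pair", "global")) {
    abort("family must be 'pair' or 'global'", class = "snpload_config_error")
  }
  structure(
    list(panel_path = panel_path, sample_sizes = sample_sizes, alpha = alpha,
         method = method, family = family, paired = paired, out_dir = out_dir,
         seed = as.integer(seed), synthetic = synthetic),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file falls back to the [run_config()]
#' default; `sample_sizes` is a named mapping of population to diploid
#' count.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "snpload_config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "snpload_config_error")
  }
  if (!is.null(raw$sample_sizes)) raw$sample_sizes <- unlist(raw$sample_sizes)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes panel loading, informativeness filtering, the pairwise exact-
#' test scan, per-pair significance counts, the per-population expected
#' allele load, and all pairwise load comparisons; writes
#' `association.tsv`, `significance_counts.tsv`, `population_load.tsv`,
#' `load_comparison.tsv` and a `run_summary.json` (counts, excluded
#' rsids, seed, config echo) under `config$out_dir`. With a `synthetic`
#' block, also simulates a cohort at the panel frequencies and writes
#' `cohort.vcf` / `cohort_samples.tsv`.
#'
#' Outputs are timestamp-free, so identical configs give byte-identical
#' files. Progress and warnings are reported via messages on stderr.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return Invisibly, a list with elements `panel`, `scan`, `sig_counts`,
#'   `load`, `load_comparison`, `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inform("stage panel: loading")
  panel <- read_panel(config$panel_path)
  filtered <- filter_informative(panel)
  excluded <- attr(filtered, "excluded")

  inform("stage scan: pairwise Fisher exact tests")
  scan <- pairwise_scan(filtered, sample_sizes = config$sample_sizes,
                        alpha = config$alpha, method = config$method,
                        family = config$family)
  sig <- significance_counts(scan)

  inform("stage load: expected allele load and comparisons")
  load_tbl <- population_load(filtered)
  cmp <- compare_all_loads(filtered, paired = config$paired)

  readr::write_tsv(scan, file.path(config$out_dir, "association.tsv"), progress = FALSE)
  readr::write_tsv(sig, file.path(config$out_dir, "significance_counts.tsv"), progress = FALSE)
  readr::write_tsv(load_tbl, file.path(config$out_dir, "population_load.tsv"), progress = FALSE)
  readr::write_tsv(cmp, file.path(config$out_dir, "load_comparison.tsv"), progress = FALSE)

  if (!is.null(config$synthetic)) {
    inform("stage simulate: synthetic cohort")
    n_per_pop <- config$synthetic$n_per_pop %||% 100L
    f <- config$synthetic$inbreeding_f %||% 0
    pops <- panel_populations(filtered)
    geno <- purrr::map_dfr(seq_along(pops), function(i) {
      simulate_genotypes(filtered, pops[i], n_per_pop, inbreeding_f = f,
                         seed = config$seed + i)
    })
    write_cohort(geno, panel = filtered,
                 vcf_path = file.path(config$out_dir, "cohort.vcf"),
                 panel_path = file.path(config$out_dir, "cohort_samples.tsv"))
  }

  summary <- list(
    n_variants_total = nrow(panel),
    n_variants_retained = nrow(filtered),
    excluded_rsids = as.list(excluded),
    n_pairs = nrow(sig),
    n_tests = nrow(scan),
    n_significant = sum(scan$significant),
    alpha = config$alpha, method = config$method, family = config$family,
    seed = config$seed,
    sample_sizes = as.list(config$sample_sizes)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(panel = filtered, scan = scan, sig_counts = sig,
                 load = load_tbl, load_comparison = cmp, summary = summary))
}
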