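#' Read a candidate-SNP panel from TSV
#'
#' A panel file is tab-separated with header
#' `gene rsid allele1 allele2 associated_allele freq_<POP>...`, one row per
#' variant. Frequencies are whole percentages of the *associated* allele
#' (e.g. `84` for 84%); empty fields are missing. `associated_allele` is
#' either one of the two alleles or the sentinel `"n.c."` (not considered)
#' for variants whose associated-allele frequencies are unavailable.
#'
#' @param path Path to a panel TSV file.
#' @return A `snp_panel` tibble with columns `gene`, `rsid`, `allele1`,
#'   `allele2`, `associated_allele` and one `freq_<POP>` column per
#'   population, frequencies converted to proportions in `[0, 1]`.
#'   Row order follows the file.
#' @examples
#' panel <- read_panel(system.file("extdata", "behaviour_snp_panel.tsv",
#'                                 package = "snpload"))
#' dplyr::count(panel, associated_allele == "n.c.")
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path), class = "snpload_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("gene", "rsid", "allele1", "allele2", "associated_allele")
  if (length(header) < 6L || !identical(header[1:5], fixed_cols) ||
      !all(startsWith(header[-(1:5)], "freq_"))) {
    abort(
      paste0("malformed panel header; expected `", paste(fixed_cols, collapse = "\t"),
             "` followed by freq_<POP> columns"),
      class = "snpload_format_error"
    )
  }
  pops <- sub("^freq_", "", header[-(1:5)])
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = readr::col_character(), rsid = readr::col_character(),
      allele1 = readr::col_character(), allele2 = readr::col_character(),
      associated_allele = readr::col_character(),
      .default = readr::col_double()
    ),
    na = "", progress = FALSE
  )
  pct <- dplyr::select(raw, dplyr::starts_with("freq_"))
  bad <- which(purrr::map_lgl(
    seq_len(nrow(pct)),
    function(i) any(!is.na(unlist(pct[i, ])) & (unlist(pct[i, ]) < 0 | unlist(pct[i, ]) > 100))
  ))
  if (length(bad) > 0) {
    abort(
      paste0("frequency outside [0, 100]% in row(s): ",
             paste(bad, collapse = ", "), " (rsid ",
             paste(raw$rsid[bad], collapse = ", "), ")"),
      class = "snpload_validation_error"
    )
  }
  panel <- dplyr::mutate(raw, dplyr::across(dplyr::starts_with("freq_"), ~ .x / 100))
  panel <- new_snp_panel(panel, populations = pops)
  validate_panel(panel)
  panel
}

new_snp_panel <- function(x, populations) {
  x <- tibble::as_tibble(x)
  attr(x, "populations") <- populations
  class(x) <- c("snp_panel", setdiff(class(x), "snp_panel"))
  x
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", nrow(x), " variants x ",
      length(panel_populations(x)), " populations (",
      paste(panel_populations(x), collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Population labels of a panel
#'
#' @param panel A `snp_panel` tibble (or any data frame with `freq_<POP>`
#'   columns).
#' @return Character vector of population labels.
#' @export
panel_populations <- function(panel) {
  attr(panel, "populations") %||%
    sub("^freq_", "", grep("^freq_", names(panel), value = TRUE))
}

#' Validate panel invariants
#'
#' Checks that rsids are unique, every present frequency lies in `[0, 1]`,
#' and each non-`"n.c."` associated allele is one of the variant's alleles.
#'
#' @param panel A `snp_panel` tibble.
#' @return The panel, invisibly; aborts with a `snpload_validation_error`
#'   on violation.
#' @export
validate_panel <- function(panel) {
  dup <- panel$rsid[duplicated(panel$rsid)]
  if (length(dup) > 0) {
    abort(paste0("duplicate rsid(s) in panel: ", paste(unique(dup), collapse = ", ")),
          class = "snpload_validation_error")
  }
  fr <- as.matrix(dplyr::select(panel, dplyr::starts_with("freq_")))
  if (any(!is.na(fr) & (fr < 0 | fr > 1))) {
    abort("panel frequencies must be proportions in [0, 1]",
          class = "snpload_validation_error")
  }
  informative <- panel$associated_allele != "n.c."
  ok <- panel$associated_allele == panel$allele1 |
    panel$associated_allele == panel$allele2
  if (any(informative & !ok)) {
    abort(
      paste0("associated allele not among the variant's alleles: ",
             paste(panel$rsid[informative & !ok], collapse = ", ")),
      class = "snpload_validation_error"
    )
  }
  invisible(panel)
}

#' Write a panel back to TSV
#'
#' Inverse of [read_panel()]: proportions are rescaled to whole-number-free
#' percentages and missing values become empty fields, so
#' `read_panel(write_panel(p, f))` reproduces `p`.
#'
#' @param panel A `snp_panel` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- dplyr::mutate(panel, dplyr::across(dplyr::starts_with("freq_"), ~ round(.x * 100, 9)))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' The packaged behaviour-associated SNP panel
#'
#' Loads the transcription of the published 24-variant candidate panel
#' (genes in serotoninergic, dopaminergic and related pathways) with
#' associated-allele frequencies for the AFR, AMR, EAS, EUR, TSI and SAS
#' populations of the 1000 Genomes Project.
#'
#' The source table's TSI entry for rs7322347 lists alleles C/T although the
#' variant is T/A in every other column of its row; the packaged value pins
#' the associated-allele (A) frequency to the row's second-listed figure
#' (51%). Both ApoE variants (rs7412, rs429358) carry T as associated
#' allele, exactly as printed. `warn = TRUE` surfaces the rs7322347
#' convention as a warning.
#'
#' @param warn Emit the transcription-convention warning? Default `TRUE`.
#' @return A `snp_panel` tibble with 24 variants and 6 populations.
#' @examples
#' panel <- behaviour_panel(warn = FALSE)
#' nrow(panel)
#' @export
behaviour_panel <- function(warn = TRUE) {
  path <- system.file("extdata", "behaviour_snp_panel.tsv", package = "snpload")
  panel <- read_panel(path)
  if (warn) {
    warn(paste0(
      "rs7322347 TSI: source row lists alleles C/T against the variant's T/A; ",
      "the associated-allele (A) frequency is pinned to the second-listed ",
      "value (51%)"), class = "snpload_transcription_warning")
  }
  panel
}

#' Keep variants informative for the frequency analysis
#'
#' Drops variants whose associated allele is the `"n.c."` sentinel and
#' variants missing a frequency for any requested population. Excluded
#' rsids are reported via a message. The operation is idempotent.
#'
#' @param panel A `snp_panel` tibble.
#' @param populations Populations that must be covered; defaults to all
#'   panel populations.
#' @return The filtered `snp_panel`, with the dropped rsids in the
#'   `"excluded"` attribute.
#' @examples
#' filtered <- filter_informative(behaviour_panel(warn = FALSE))
#' nrow(filtered)           # 21
#' attr(filtered, "excluded")
#' @export
filter_informative <- function(panel, populations = panel_populations(panel)) {
  cols <- paste0("freq_", populations)
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel has no column(s): ", paste(missing_cols, collapse = ", ")),
          class = "snpload_validation_error")
  }
  complete <- !apply(is.na(as.matrix(panel[, cols, drop = FALSE])), 1L, any)
  keep <- panel$associated_allele != "n.c." & complete
  excluded <- panel$rsid[!keep]
  if (length(excluded) > 0) {
    inform(paste0("excluding ", length(excluded),
                  " variant(s) without usable associated-allele frequencies: ",
                  paste(excluded, collapse = ", ")))
  }
  out <- new_snp_panel(panel[keep, , drop = FALSE], populations = populations)
  attr(out, "excluded") <- excluded
  out
}
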