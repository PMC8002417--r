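# Independent brute-force oracle for the two-sided Fisher exact p-value:
# closed-form hypergeometric pmf from binomial coefficients, full
# enumeration over the support, probability-mass two-sided rule.
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- choose(r1, support) * choose(n - r1, c1 - support) / choose(n, c1)
  p_obs <- prob[support == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# tiny hand-built panel: n_pop frequency columns supplied as a named list
make_panel <- function(freqs, associated = "A") {
  n <- length(freqs[[1]])
  base <- tibble::tibble(
    gene = paste0("G", seq_len(n)),
    rsid = paste0("rs", seq_len(n)),
    allele1 = "A", allele2 = "G",
    associated_allele = associated
  )
  for (pop in names(freqs)) base[[paste0("freq_", pop)]] <- freqs[[pop]]
  snpload:::new_snp_panel(base, populations = names(freqs))
}

fixture_panel <- function() {
  suppressWarnings(suppressMessages(behaviour_panel(warn = FALSE)))
}

filtered_fixture <- function() {
  suppressMessages(filter_informative(fixture_panel()))
}

strip_meta <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("tbl_df", "tbl", "data.frame")
  attributes(x)[setdiff(names(attributes(x)), c("names", "row.names", "class"))] <- NULL
  x
}
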