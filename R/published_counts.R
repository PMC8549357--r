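#' Published FDA-ARGOS benchmark filter counts
#'
#' Raw per-filter counts of biallelic TP and FP calls pooled across the 990
#' VCFs of the FDA-ARGOS six-species benchmarking experiment (166 pipelines
#' run on six bacterial samples), as printed in the source report: per
#' filter, the number of calls the filter is applicable to, the number it
#' removes, and the number only it removes, in each label stratum. The
#' `"any"` rows OR-combine all filters of the panel. Feeding these counts
#' through [efficacy_from_counts()] reproduces the published percentages
#' and value-added ratios at 2-decimal half-up rounding.
#'
#' @return `data.table` with columns `panel` (`SNP`/`INDEL`), `filter`,
#'   `applicable_fp`, `removed_fp`, `unique_fp`, `applicable_tp`,
#'   `removed_tp`.
#' @export
fdaargos_filter_counts <- function() {
  path <- system.file("extdata", "fdaargos_filter_counts.tsv",
                      package = "fpfilter", mustWork = TRUE)
  data.table::fread(path, sep = "\t", na.strings = "NA")
}

#' Published FDA-ARGOS call-set composition totals
#'
#' Total SNP and indel calls across the benchmark's 990 VCFs and how many
#' of each were false positives.
#'
#' @return `data.table` with columns `type`, `total_calls`, `fp_calls`.
#' @export
fdaargos_call_totals <- function() {
  path <- system.file("extdata", "fdaargos_call_totals.tsv",
                      package = "fpfilter", mustWork = TRUE)
  data.table::fread(path, sep = "\t")
}
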