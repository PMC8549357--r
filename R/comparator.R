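#' Label pipeline calls against a truth set
#'
#' Position/allele comparison on a haploid genome (calls are matched on the
#' exact key (chrom, pos, ref, alt) after normalization; no haplotype-graph
#' reconstruction). Counting follows benchmarking convention:
#' \itemize{
#'   \item only calls whose FILTER is `PASS` — or unset, since the FILTER
#'     column "if populated" must be PASS — are scored; others are ignored;
#'   \item calls whose reference footprint intersects the ambiguous
#'     positions are excluded from every count;
#'   \item TP = scored query key present in the truth set; FP = scored
#'     query key absent; FN = truth key not matched by any scored query
#'     key. FNs carry no call evidence and never enter the efficacy
#'     analysis.
#' }
#' Metrics are stratified by variant type (SNP vs indel); MNP/COMPLEX
#' query calls that survive normalization undecomposed are labeled but not
#' counted in either stratum. Each labeled call carries
#' `in_characterization_set`: labeled, from a biallelic record, SNP/INS/DEL
#' class, not MNP-derived, ACGT-only alleles.
#'
#' @param query a normalized [variant_calls()] table (extra columns, e.g.
#'   characteristics from [with_characteristics()], are preserved).
#' @param truth a [truth_set()].
#' @return list with `labeled` (the query table plus `label`
#'   (`"TP"`/`"FP"`/`NA`), `type`, and `in_characterization_set`),
#'   `metrics` (per-type [compute_metrics()] rows), and `fn` (unmatched
#'   truth variants).
#' @export
compare_calls <- function(query, truth) {
  stopifnot(inherits(truth, "truth_set"))
  missing <- setdiff(unique(query$chrom), names(truth$contig_lengths))
  if (length(missing)) {
    stop("compare_calls: query contig(s) absent from truth: ",
         paste(missing, collapse = ", "))
  }
  labeled <- data.table::copy(data.table::as.data.table(query))
  n <- nrow(labeled)
  pass <- labeled$filter_status %in% c("PASS", "unset")
  in_amb <- rep(FALSE, n)
  if (n > 0L && length(truth$ambiguous_positions)) {
    hits <- GenomicRanges::findOverlaps(.footprint_gr(labeled),
                                        truth$ambiguous_positions)
    in_amb[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  scored <- pass & !in_amb & !labeled$ambiguous
  truth_keys <- .call_key(truth$variants)
  query_keys <- .call_key(labeled)
  is_tp <- scored & query_keys %in% truth_keys
  labeled[, label := ifelse(scored, ifelse(is_tp, "TP", "FP"), NA_character_)]
  labeled[, type := .call_type(var_class)]
  labeled[, in_characterization_set :=
            !is.na(label) & biallelic_site & !mnp_derived &
            var_class %in% c("SNP", "INS", "DEL")]
  fn <- truth$variants[!truth_keys %in% query_keys[scored]]
  metrics <- data.table::rbindlist(lapply(c("SNP", "INDEL"), function(tt) {
    tp <- sum(is_tp & labeled$type %in% tt)
    fp <- sum(scored & !is_tp & labeled$type %in% tt)
    fn_n <- sum(.call_type(fn$var_class) %in% tt)
    cbind(data.table::data.table(type = tt),
          data.table::as.data.table(compute_metrics(tp, fp, fn_n)))
  }))
  data.table::setattr(labeled, "class", class(query))
  list(labeled = labeled[], metrics = metrics, fn = fn)
}

.call_key <- function(calls) paste(calls$chrom, calls$pos, calls$ref, calls$alt)

.call_type <- function(var_class) {
  ifelse(var_class %in% "SNP", "SNP",
         ifelse(var_class %in% c("INS", "DEL"), "INDEL", NA_character_))
}

#' Extract the characterization subset of labeled calls
#'
#' Restricts to calls with `in_characterization_set = TRUE` (biallelic,
#' SNP/INS/DEL, not MNP-derived, ACGT-only, scored in confident regions)
#' and splits by label and variant type.
#'
#' @param labeled the `labeled` table from [compare_calls()].
#' @return named list of four tables: `snp_tp`, `snp_fp`, `indel_tp`,
#'   `indel_fp`.
#' @export
characterization_subset <- function(labeled) {
  sub <- data.table::as.data.table(labeled)[in_characterization_set == TRUE]
  list(
    snp_tp   = sub[type == "SNP" & label == "TP"],
    snp_fp   = sub[type == "SNP" & label == "FP"],
    indel_tp = sub[type == "INDEL" & label == "TP"],
    indel_fp = sub[type == "INDEL" & label == "FP"]
  )
}

#' Precision, recall and F-score from TP/FP/FN counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F = 2 (precision * recall)/(precision + recall). Zero-denominator cases
#' are unavailable (`NA`), not 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`.
#' @export
#' @examples
#' compute_metrics(18, 2, 1)  # precision 0.9, recall ~0.947
compute_metrics <- function(tp, fp, fn) {
  stopifnot(length(tp) == 1L, length(fp) == 1L, length(fn) == 1L)
  if (tp < 0 || fp < 0 || fn < 0) stop("compute_metrics: counts must be >= 0")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       precision = precision, recall = recall, f_score = f)
}
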