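#' Efficacy percentages and value-added ratio from raw counts
#'
#' The arithmetic core shared by [compute_efficacy()] and by
#' report-reproduction workflows that start from printed counts. Each
#' percentage is `100 * count / denominator`, rounded half-up to `digits`
#' decimals; the value-added ratio is the quotient of the (rounded)
#' FP and TP removal percentages. Set `digits = NA` for unrounded values.
#'
#' @param applicable_fp,removed_fp,applicable_tp,removed_tp counts of
#'   FP/TP calls to which the filter applies, and removed by it.
#' @param unique_fp count of FPs removed by this filter and by no other
#'   applicable filter (`NA` for the OR-combined row).
#' @param digits decimals for half-up rounding of reported percentages
#'   (2 reproduces printed report precision); `NA` for no rounding.
#' @return one-row `data.table` with counts, percentages and
#'   `value_added_ratio`.
#' @export
#' @examples
#' efficacy_from_counts(1294894, 821144, NA, 23683336, 6558764)
efficacy_from_counts <- function(applicable_fp, removed_fp, unique_fp = NA_integer_,
                                 applicable_tp, removed_tp, digits = 2) {
  pct <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
    p <- 100 * num / den
    if (is.na(digits)) p else round_half_up(p, digits)
  }
  removed_fp_pct <- pct(removed_fp, applicable_fp)
  removed_tp_pct <- pct(removed_tp, applicable_tp)
  data.table::data.table(
    applicable_fp = applicable_fp, removed_fp = removed_fp,
    removed_fp_pct = removed_fp_pct,
    unique_fp = unique_fp, unique_fp_pct = pct(unique_fp, applicable_fp),
    applicable_tp = applicable_tp, removed_tp = removed_tp,
    removed_tp_pct = removed_tp_pct,
    value_added_ratio = value_added_ratio(removed_fp_pct, removed_tp_pct,
                                          digits = digits, prerounded = TRUE)
  )
}

#' Value-added ratio of a filter
#'
#' The ratio of the percentage of FP calls removed to the percentage of TP
#' calls also removed, counting only calls the filter applies to. Higher is
#' safer: the filter buys more FP removal per TP lost. In report mode
#' (`digits = 2`) both percentages are first rounded half-up to the printed
#' precision, since published tables compute the quotient from the rounded
#' values; `digits = NA` gives the exact quotient.
#'
#' @param removed_fp_pct,removed_tp_pct removal percentages (0-100).
#' @param digits rounding applied to the percentages (and the ratio);
#'   `NA` for none.
#' @param prerounded set `TRUE` when the inputs are already rounded to
#'   `digits`.
#' @return the ratio, or `NA` when the (rounded) TP percentage is 0.
#' @export
#' @examples
#' value_added_ratio(26.70, 1.19)  # 22.44
value_added_ratio <- function(removed_fp_pct, removed_tp_pct, digits = 2,
                              prerounded = FALSE) {
  if (is.na(removed_fp_pct) || is.na(removed_tp_pct)) return(NA_real_)
  stopifnot(removed_fp_pct >= 0, removed_tp_pct >= 0)
  if (!is.na(digits) && !prerounded) {
    removed_fp_pct <- round_half_up(removed_fp_pct, digits)
    removed_tp_pct <- round_half_up(removed_tp_pct, digits)
  }
  if (removed_tp_pct == 0) return(NA_real_)
  r <- removed_fp_pct / removed_tp_pct
  if (is.na(digits)) r else round_half_up(r, digits)
}

#' Per-filter and OR-combined efficacy table
#'
#' For each filter: counts and percentages of applicable FP/TP calls it
#' removes, the count/percentage of FPs removed by it and by no other
#' applicable filter (unique detection; denominator is the filter's own
#' applicable FP total), and the value-added ratio. The `"any"` row
#' OR-combines all filters: its denominators are the full label totals and
#' its removed counts the union of the per-filter removed sets.
#'
#' @param outcome a `filter_outcome` from [apply_filters_independent()]
#'   (Table-style reports assume independent mode) or
#'   [apply_filters_sequential()].
#' @param labels character vector of `"TP"`/`"FP"` (or `NA`) aligned with
#'   the outcome's rows; usually `labeled$label`.
#' @param digits report rounding (see [efficacy_from_counts()]).
#' @return `data.table`, one row per filter plus the leading `"any"` row.
#'   Empty call sets give an empty table.
#' @export
compute_efficacy <- function(outcome, labels, digits = 2) {
  stopifnot(inherits(outcome, "filter_outcome"))
  stopifnot(length(labels) == nrow(outcome$removed))
  if (length(labels) == 0L) {
    return(data.table::data.table(filter = character(0)))
  }
  is_fp <- !is.na(labels) & labels == "FP"
  is_tp <- !is.na(labels) & labels == "TP"
  rem <- outcome$removed
  app <- outcome$applicable
  n_removing <- rowSums(rem)
  rows <- list(cbind(
    data.table::data.table(filter = "any"),
    efficacy_from_counts(
      applicable_fp = sum(is_fp), removed_fp = sum(outcome$removed_by_any & is_fp),
      unique_fp = NA_integer_,
      applicable_tp = sum(is_tp), removed_tp = sum(outcome$removed_by_any & is_tp),
      digits = digits
    )
  ))
  for (k in seq_len(ncol(rem))) {
    uniq <- rem[, k] & n_removing == 1L
    rows[[k + 1L]] <- cbind(
      data.table::data.table(filter = colnames(rem)[k]),
      efficacy_from_counts(
        applicable_fp = sum(app[, k] & is_fp), removed_fp = sum(rem[, k] & is_fp),
        unique_fp = sum(uniq & is_fp),
        applicable_tp = sum(app[, k] & is_tp), removed_tp = sum(rem[, k] & is_tp),
        digits = digits
      )
    )
  }
  data.table::rbindlist(rows)
}

#' Two-panel (SNP and indel) efficacy report
#'
#' Convenience wrapper reproducing the standard report layout: restricts
#' labeled calls to the characterization subset, applies the SNP filter set
#' to SNP calls and the indel set to indel calls in independent mode, and
#' computes both efficacy panels.
#'
#' @param labeled labeled calls with characteristics (from
#'   [compare_calls()] on [with_characteristics()] output).
#' @param snp_specs,indel_specs filter lists; default the built-in sets.
#' @param digits report rounding.
#' @return named list of two efficacy tables: `snp`, `indel`.
#' @export
efficacy_table <- function(labeled, snp_specs = default_snp_filters(),
                           indel_specs = default_indel_filters(), digits = 2) {
  sub <- data.table::as.data.table(labeled)[in_characterization_set == TRUE]
  panel <- function(tt, specs) {
    calls <- sub[type == tt]
    out <- apply_filters_independent(calls, specs)
    compute_efficacy(out, calls$label, digits = digits)
  }
  list(snp = panel("SNP", snp_specs), indel = panel("INDEL", indel_specs))
}

#' Write an efficacy panel as TSV
#'
#' @param table an efficacy table from [compute_efficacy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_efficacy_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' Histograms of characteristics for TP vs FP calls
#'
#' Fixed-bin histograms of each characteristic, stratified by label (and
#' optionally by pipeline), emulating the TP/FP density comparison that
#' motivates the filter thresholds. Bin edges are shared between the TP and
#' FP strata of a characteristic so the distributions are directly
#' comparable.
#'
#' @param labeled labeled calls with characteristics; normally the
#'   characterization subset.
#' @param characteristics which characteristics to summarize.
#' @param n_bins number of equal-width bins over the pooled range.
#' @param by_pipeline also stratify by `pipeline_id`.
#' @return long `data.table`: `characteristic`, `label` (`pipeline_id`),
#'   `bin_left`, `bin_right`, `count`, `prop` (within stratum).
#' @export
summarize_distributions <- function(labeled, characteristics = characteristic_names(),
                                    n_bins = 30L, by_pipeline = FALSE) {
  dt <- data.table::as.data.table(labeled)[!is.na(label)]
  group_cols <- c("label", if (by_pipeline) "pipeline_id")
  out <- list()
  for (ch in characteristics) {
    if (!ch %in% names(dt)) next
    v <- dt[[ch]]
    ok <- !is.na(v)
    if (!any(ok)) next
    rng <- range(v[ok])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    sub <- dt[ok]
    bin <- pmin(pmax(findInterval(sub[[ch]], edges, rightmost.closed = TRUE), 1L), n_bins)
    tab <- data.table::data.table(sub[, ..group_cols], bin = bin)[
      , .(count = .N), by = c(group_cols, "bin")]
    tab[, prop := count / sum(count), by = group_cols]
    tab[, `:=`(characteristic = ch,
               bin_left = edges[bin], bin_right = edges[bin + 1L])]
    out[[ch]] <- tab[, c("characteristic", group_cols, "bin", "bin_left",
                         "bin_right", "count", "prop"), with = FALSE]
  }
  if (!length(out)) return(data.table::data.table())
  data.table::rbindlist(out)
}
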