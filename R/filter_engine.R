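#' Define a hard filter
#'
#' All hard filters in this framework are inclusive minimum-threshold
#' rules: a call is discarded when the characteristic is available and its
#' value is `<=` the threshold. A filter is *applicable* to a call only
#' when the call's type is in `applies_to` and the characteristic is
#' available; unavailable never counts as removed.
#'
#' @param name filter label (reported in efficacy tables and FILTER
#'   annotations).
#' @param characteristic one of [characteristic_names()].
#' @param threshold finite numeric discard threshold (value `<=` threshold
#'   discards).
#' @param applies_to character subset of `c("SNP", "INDEL")`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(name, characteristic, threshold,
                        applies_to = c("SNP", "INDEL")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!characteristic %in% characteristic_names()) {
    stop("filter_spec: unknown characteristic: ", characteristic)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  applies_to <- match.arg(applies_to, several.ok = TRUE)
  s <- list(name = name, characteristic = characteristic,
            threshold = threshold, applies_to = applies_to)
  class(s) <- "filter_spec"
  s
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s: discard %s <= %g (%s)\n",
              x$name, x$characteristic, x$threshold,
              paste(x$applies_to, collapse = "/")))
  invisible(x)
}

#' Default hard filters for SNP calls
#'
#' The nine empirically suggested SNP filters: variant-call quality <= 30,
#' quality by depth <= 1, variant allele frequency <= 0.95 (fraction, not
#' percent), read depth <= 5, variant-supporting reads <= 5, distance to
#' nearest SNP <= 3 bp, distance to nearest indel <= 10 bp, and <= 5 % of
#' variant-supporting reads on the least-covered strand or in the
#' least-covered direction. These thresholds are illustrative defaults, not
#' definitive guides; override per dataset.
#'
#' @return list of nine [filter_spec()]s with `applies_to = "SNP"`.
#' @export
default_snp_filters <- function() {
  mk <- function(name, ch, th) filter_spec(name, ch, th, applies_to = "SNP")
  list(
    mk("qual", "qual", 30),
    mk("qd", "qd", 1),
    mk("vaf", "vaf", 0.95),
    mk("depth", "depth", 5),
    mk("alt_reads", "alt_reads", 5),
    mk("dist_snp", "dist_snp", 3),
    mk("dist_indel", "dist_indel", 10),
    mk("strand_bias", "strand_min_pct", 5),
    mk("direction_bias", "direction_min_pct", 5)
  )
}

#' Default hard filters for indel calls
#'
#' Six filters; indels take a lower minimum call quality (20 rather than
#' the SNPs' 30) and a higher minimum read depth (10 rather than 5), and
#' no quality-by-depth, alt-read-count, or direction filter is applied
#' (their TP/FP distributions overlap too much to separate).
#'
#' @return list of six [filter_spec()]s with `applies_to = "INDEL"`.
#' @export
default_indel_filters <- function() {
  mk <- function(name, ch, th) filter_spec(name, ch, th, applies_to = "INDEL")
  list(
    mk("qual", "qual", 20),
    mk("vaf", "vaf", 0.95),
    mk("depth", "depth", 10),
    mk("dist_snp", "dist_snp", 3),
    mk("dist_indel", "dist_indel", 10),
    mk("strand_bias", "strand_min_pct", 5)
  )
}

#' Read filter specs from a config file
#'
#' TSV with header `name  characteristic  threshold  applies_to`, where
#' `applies_to` is `SNP`, `INDEL`, or `SNP,INDEL`.
#'
#' @param path path to the TSV.
#' @return list of [filter_spec()]s.
#' @export
read_filter_config <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  lapply(seq_len(nrow(dt)), function(i) {
    filter_spec(dt$name[i], dt$characteristic[i], dt$threshold[i],
                strsplit(dt$applies_to[i], ",", fixed = TRUE)[[1]])
  })
}

.spec_names <- function(specs) vapply(specs, `[[`, character(1), "name")

# evaluate one spec against a table that carries type + characteristic cols
.eval_spec <- function(tbl, spec, values = NULL) {
  if (!spec$characteristic %in% names(tbl)) {
    stop("apply_filters: calls lack characteristic column '",
         spec$characteristic, "' — run with_characteristics() first")
  }
  v <- if (is.null(values)) tbl[[spec$characteristic]] else values
  applicable <- tbl$type %in% spec$applies_to & !is.na(v)
  removed <- applicable & v <= spec$threshold
  list(applicable = applicable, removed = removed)
}

#' Apply hard filters independently
#'
#' Table-1 semantics: every filter is evaluated on the raw call set,
#' independently of the others. A call is removed by a filter iff the
#' filter is applicable (matching type, characteristic available) and the
#' value is `<=` the threshold.
#'
#' @param calls labeled calls carrying characteristic columns and a `type`
#'   column (output of [compare_calls()] on [with_characteristics()]
#'   input, or any table with those columns).
#' @param specs list of [filter_spec()]s.
#' @return object of class `filter_outcome`: list with logical matrices
#'   `applicable` and `removed` (one column per filter), vector
#'   `removed_by_any`, `stage` (per-filter, all 1 here), `specs`, `mode`.
#' @export
apply_filters_independent <- function(calls, specs) {
  calls <- .ensure_type(calls)
  nm <- .spec_names(specs)
  if (anyDuplicated(nm)) stop("apply_filters: duplicate filter names")
  n <- nrow(calls)
  applicable <- removed <- matrix(FALSE, n, length(specs), dimnames = list(NULL, nm))
  for (k in seq_along(specs)) {
    ev <- .eval_spec(calls, specs[[k]])
    applicable[, k] <- ev$applicable
    removed[, k] <- ev$removed
  }
  structure(list(applicable = applicable, removed = removed,
                 removed_by_any = rowSums(removed) > 0L,
                 stage = stats::setNames(rep(1L, length(specs)), nm),
                 specs = specs, mode = "independent"),
            class = "filter_outcome")
}

#' Apply hard filters with thinning last
#'
#' Recommended-practice (sequential) mode: stage 1 applies all
#' non-proximity filters; stage 2 recomputes distance-to-nearest on the
#' calls surviving stage 1 (per `pipeline_id`, i.e. within each VCF) and
#' only then applies the proximity (`dist_snp` / `dist_indel`) filters.
#' This minimizes true positives discarded because of a neighbouring false
#' positive that another filter already removed. With no stage-1 removals
#' the outcome equals independent mode.
#'
#' @inheritParams apply_filters_independent
#' @return a `filter_outcome` (see [apply_filters_independent()]) with
#'   `stage` marking each filter 1 or 2 and `mode = "sequential"`.
#' @export
apply_filters_sequential <- function(calls, specs) {
  calls <- .ensure_type(calls)
  nm <- .spec_names(specs)
  if (anyDuplicated(nm)) stop("apply_filters: duplicate filter names")
  prox <- vapply(specs, function(s) s$characteristic %in% c("dist_snp", "dist_indel"),
                 logical(1))
  n <- nrow(calls)
  applicable <- removed <- matrix(FALSE, n, length(specs), dimnames = list(NULL, nm))
  for (k in which(!prox)) {
    ev <- .eval_spec(calls, specs[[k]])
    applicable[, k] <- ev$applicable
    removed[, k] <- ev$removed
  }
  survives <- rowSums(removed[, !prox, drop = FALSE]) == 0L
  if (any(prox)) {
    new_dist <- data.table::data.table(dist_snp = rep(NA_real_, n),
                                       dist_indel = rep(NA_real_, n))
    surv_idx <- which(survives)
    if (length(surv_idx)) {
      sdt <- data.table::as.data.table(calls)[surv_idx]
      pid_col <- if ("pipeline_id" %in% names(sdt)) sdt$pipeline_id else
        rep("all", nrow(sdt))
      for (pid in unique(pid_col)) {
        sel <- which(pid_col == pid)
        o <- order(sdt$chrom[sel], sdt$pos[sel], method = "radix")
        d <- distances_to_nearest(sdt[sel][o])
        back <- order(o)  # sorted -> original row order
        new_dist[surv_idx[sel], `:=`(dist_snp = d$dist_snp[back],
                                     dist_indel = d$dist_indel[back])]
      }
    }
    for (k in which(prox)) {
      v <- new_dist[[specs[[k]]$characteristic]]
      ev <- .eval_spec(calls, specs[[k]], values = v)
      # proximity filters only ever act on stage-1 survivors
      applicable[, k] <- ev$applicable & survives
      removed[, k] <- ev$removed & survives
    }
  }
  structure(list(applicable = applicable, removed = removed,
                 removed_by_any = rowSums(removed) > 0L,
                 stage = stats::setNames(ifelse(prox, 2L, 1L), nm),
                 specs = specs, mode = "sequential"),
            class = "filter_outcome")
}

.ensure_type <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (!"type" %in% names(calls)) {
    if (!"var_class" %in% names(calls)) {
      stop("apply_filters: calls need a 'type' or 'var_class' column")
    }
    calls[, type := .call_type(var_class)]
  }
  calls
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat("<filter_outcome>", x$mode, "mode;", ncol(x$removed), "filters over",
      nrow(x$removed), "calls;", sum(x$removed_by_any), "removed by any\n")
  invisible(x)
}

#' Write a VCF annotated with failing filter names
#'
#' Calls removed by at least one filter get the semicolon-joined names of
#' the filters that removed them in the FILTER column; surviving calls get
#' `PASS`.
#'
#' @param calls the call table the outcome was computed from.
#' @param outcome a `filter_outcome` for those calls.
#' @param path output VCF path.
#' @param contig_lengths optional named vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(calls, outcome, path, contig_lengths = NULL) {
  stopifnot(nrow(calls) == nrow(outcome$removed))
  out <- data.table::copy(data.table::as.data.table(calls))
  fails <- apply(outcome$removed, 1L, function(r) {
    paste(colnames(outcome$removed)[r], collapse = ";")
  })
  out[, filter_status := ifelse(nzchar(fails), "non-PASS", "PASS")]
  out[, filter_detail := ifelse(nzchar(fails), fails, "PASS")]
  write_vcf(variant_calls(out), path, contig_lengths = contig_lengths)
}
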