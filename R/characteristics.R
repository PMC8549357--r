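#' Names of the nine positional characteristics
#'
#' @return character vector of the nine per-call statistics used for
#'   filtering: `qual`, `qd`, `vaf`, `depth`, `alt_reads`, `dist_snp`,
#'   `dist_indel`, `strand_min_pct`, `direction_min_pct`.
#' @export
characteristic_names <- function() {
  c("qual", "qd", "vaf", "depth", "alt_reads",
    "dist_snp", "dist_indel", "strand_min_pct", "direction_min_pct")
}

#' Extract the nine positional characteristics
#'
#' For each call, resolves the dialect's tag mappings and computes:
#' \describe{
#'   \item{qual}{the record's Phred-scaled QUAL.}
#'   \item{qd}{quality by depth: the dialect's QD-style tag when mapped,
#'     else the fallback `qual / alt_reads` (average quality per
#'     variant-supporting read) when both are available.}
#'   \item{vaf}{`alt_reads / depth` when both counts are available, else a
#'     dialect VAF tag, else unavailable.}
#'   \item{depth, alt_reads}{read counts from the mapped tags.}
#'   \item{strand_min_pct}{`100 * min(F, R) / (F + R)` over
#'     variant-supporting forward/reverse read counts; at most 50 by
#'     construction (50 = equal support on both strands).}
#'   \item{direction_min_pct}{same statistic over variant-supporting reads
#'     placed left/right (up-/downstream) of the call.}
#'   \item{dist_snp, dist_indel}{from [distances_to_nearest()].}
#' }
#' Unavailable is a first-class state (`NA`), distinct from zero: an
#' unmapped or absent tag never yields 0. Ambiguous-allele calls get all-`NA`
#' characteristics.
#'
#' @param calls a [variant_calls()] table (sorted; one call set / VCF).
#' @param dialect a [tag_dialect()]; defaults to the dialect attached by
#'   [parse_vcf()].
#' @return `data.table` with the nine characteristic columns plus
#'   `qd_source` (`"tag"`, `"fallback"`, or `NA`), row-aligned with `calls`.
#' @export
extract_characteristics <- function(calls, dialect = attr(calls, "dialect", exact = TRUE)) {
  if (is.null(dialect)) dialect <- tag_dialect("null")
  stopifnot(inherits(dialect, "tag_dialect"))
  n <- nrow(calls)
  m <- dialect$mapping
  num <- function(ref_str) {
    vapply(calls$tags, .tag_value, numeric(1), ref = ref_str)
  }
  depth <- num(m$depth)
  alt_reads <- num(m$alt_reads)
  bad <- !is.na(depth) & depth == 0 & !is.na(alt_reads) & alt_reads > 0
  if (any(bad)) {
    stop("tag inconsistency: depth == 0 with alt_reads > 0 at ",
         calls$chrom[which(bad)[1]], ":", calls$pos[which(bad)[1]])
  }
  vaf <- ifelse(!is.na(alt_reads) & !is.na(depth) & depth > 0,
                alt_reads / depth, num(m$vaf))
  qd_tag <- num(m$qd)
  qd_fallback <- ifelse(!is.na(calls$qual) & !is.na(alt_reads) & alt_reads > 0,
                        calls$qual / alt_reads, NA_real_)
  qd <- ifelse(!is.na(qd_tag), qd_tag, qd_fallback)
  qd_source <- ifelse(!is.na(qd_tag), "tag",
                      ifelse(!is.na(qd_fallback), "fallback", NA_character_))
  min_pct <- function(a, b) {
    tot <- a + b
    ifelse(!is.na(a) & !is.na(b) & tot > 0, 100 * pmin(a, b) / tot, NA_real_)
  }
  strand_min_pct <- min_pct(num(m$alt_fwd), num(m$alt_rev))
  direction_min_pct <- min_pct(num(m$alt_left), num(m$alt_right))
  dists <- distances_to_nearest(calls)
  chars <- data.table::data.table(
    qual = calls$qual, qd = qd, vaf = vaf, depth = depth,
    alt_reads = alt_reads,
    dist_snp = dists$dist_snp, dist_indel = dists$dist_indel,
    strand_min_pct = strand_min_pct, direction_min_pct = direction_min_pct,
    qd_source = qd_source
  )
  if (n > 0L && any(calls$ambiguous)) {
    for (col in names(chars)) {
      data.table::set(chars, which(calls$ambiguous), col,
                      if (col == "qd_source") NA_character_ else NA_real_)
    }
  }
  chars[]
}

#' Distance to the nearest SNP and indel call
#'
#' For each call, the distance in bp to the nearest *other* call of the
#' relevant class on the same contig at a distinct position: `dist_snp`
#' over SNP-class calls (including MNP-derived SNPs), `dist_indel` over
#' INS/DEL calls, both measured between anchor positions of the normalized
#' records. A call of the relevant class never counts itself, and calls
#' sharing its exact position (split alleles of one site) do not count as
#' neighbours, so distances are always >= 1 when available. `NA` when no
#' qualifying neighbour exists on the contig. Ambiguous-allele calls are
#' excluded from the neighbour sets.
#'
#' @param calls a [variant_calls()] table sorted by (chrom, pos).
#' @return `data.table(dist_snp, dist_indel)` row-aligned with `calls`.
#' @export
distances_to_nearest <- function(calls) {
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos, method = "radix")
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("distances_to_nearest: calls must be sorted by (chrom, pos)")
    }
  }
  dist_snp <- rep(NA_real_, nrow(calls))
  dist_indel <- rep(NA_real_, nrow(calls))
  if (nrow(calls) == 0L) {
    return(data.table::data.table(dist_snp = dist_snp, dist_indel = dist_indel))
  }
  amb <- if ("ambiguous" %in% names(calls)) calls$ambiguous else
    rep(FALSE, nrow(calls))
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    snp_pos <- sort(unique(calls$pos[idx][!amb[idx] &
                                          calls$var_class[idx] %in% "SNP"]))
    ind_pos <- sort(unique(calls$pos[idx][!amb[idx] &
                                          calls$var_class[idx] %in% c("INS", "DEL")]))
    dist_snp[idx] <- .nearest_distinct(calls$pos[idx], snp_pos)
    dist_indel[idx] <- .nearest_distinct(calls$pos[idx], ind_pos)
  }
  data.table::data.table(dist_snp = dist_snp, dist_indel = dist_indel)
}

# nearest |q - u| over sorted unique positions u, excluding u == q;
# findInterval gives the flanking candidates in O(log n) per query
.nearest_distinct <- function(q, u) {
  if (length(u) == 0L) return(rep(NA_real_, length(q)))
  i <- findInterval(q, u)
  at_u <- i >= 1L & i <= length(u) & u[pmax(i, 1L)] == q
  li <- ifelse(at_u, i - 1L, i)
  left <- ifelse(li >= 1L, q - u[pmax(li, 1L)], NA_real_)
  ri <- i + 1L
  right <- ifelse(ri <= length(u), u[pmin(ri, length(u))] - q, NA_real_)
  out <- pmin(left, right, na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Attach characteristics to a call table
#'
#' Convenience wrapper binding the [extract_characteristics()] columns onto
#' the call table, so downstream labeling and filtering operate on one
#' object.
#'
#' @inheritParams extract_characteristics
#' @return the call table with the nine characteristic columns appended.
#' @export
with_characteristics <- function(calls, dialect = attr(calls, "dialect", exact = TRUE)) {
  chars <- extract_characteristics(calls, dialect)
  out <- data.table::copy(calls)
  for (col in names(chars)) out[, (col) := chars[[col]]]
  data.table::setattr(out, "class", class(calls))
  data.table::setattr(out, "dialect", attr(calls, "dialect", exact = TRUE))
  out[]
}
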