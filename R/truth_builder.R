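#' Read a per-base pileup summary
#'
#' Expects a TSV with columns `chrom`, `pos` (1-based), `depth`,
#' `max_base_count` (count of the most common nucleotide at the position).
#'
#' @param path path to the TSV (header optional; columns in that order).
#' @return a `data.table` of pileup columns.
#' @export
read_pileup <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  data.table::setnames(dt, seq_len(4), c("chrom", "pos", "depth", "max_base_count"))
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            depth = as.integer(depth), max_base_count = as.integer(max_base_count))]
  dt[]
}

#' Mask low-quality assembly positions from pileup consensus
#'
#' A position is masked iff it has no coverage (depth 0) or the most common
#' nucleotide represents strictly less than `min_consensus` of the total
#' depth there (so a position at exactly 99 % consensus is NOT masked under
#' the default). Positions absent from `columns` imply depth 0 and are
#' masked when `contig_lengths` is supplied.
#'
#' @param columns pileup columns as from [read_pileup()]; at most one row
#'   per position.
#' @param min_consensus masking threshold on `max_base_count / depth`
#'   (strict `<`); default 0.99.
#' @param contig_lengths optional named vector; when given, uncovered
#'   positions (absent rows) are masked too.
#' @return a `GRanges` of masked intervals (1-based closed, reduced).
#' @export
mask_low_quality <- function(columns, min_consensus = 0.99, contig_lengths = NULL) {
  columns <- data.table::as.data.table(columns)
  if (anyDuplicated(columns[, .(chrom, pos)])) {
    stop("mask_low_quality: duplicate (chrom, pos) rows in pileup")
  }
  if (any(columns$max_base_count > columns$depth)) {
    stop("mask_low_quality: max_base_count exceeds depth")
  }
  masked <- columns[depth == 0L | (depth > 0L & max_base_count / depth < min_consensus)]
  gr <- if (nrow(masked)) .gr(masked$chrom, masked$pos, masked$pos) else
    GenomicRanges::GRanges()
  if (!is.null(contig_lengths)) {
    covered <- columns[depth > 0L]
    cov_gr <- if (nrow(covered)) .gr(covered$chrom, covered$pos, covered$pos) else
      GenomicRanges::GRanges()
    uncovered <- GenomicRanges::setdiff(.genome_gr(contig_lengths), cov_gr)
    gr <- GenomicRanges::union(gr, uncovered)
  }
  GenomicRanges::reduce(gr)
}

#' Extend a mask with discordant-call footprints
#'
#' Discordant calls (e.g. a negative-control caller detecting "variants"
#' when reads are mapped back to their own assembly) flag base-level
#' disagreements between read sets; their reference footprints are masked
#' in the same manner as low-quality positions.
#'
#' @param mask a `GRanges` mask (as from [mask_low_quality()]).
#' @param discordant_calls a normalized [variant_calls()] table.
#' @return the union mask as a reduced `GRanges`.
#' @export
mask_discordant <- function(mask, discordant_calls) {
  if (nrow(discordant_calls) == 0L) return(GenomicRanges::reduce(mask))
  GenomicRanges::reduce(GenomicRanges::union(mask, .footprint_gr(discordant_calls)))
}

#' Build a truth set from the consensus of alignment VCFs
#'
#' Whole-genome alignment under varied parameters yields n call sets;
#' variants present in all n (matched allele-aware on
#' (chrom, pos, ref, alt) after normalization) form the consensus truth
#' set, while variants called in at least one but not all VCFs are
#' parameter-sensitive and define the ambiguous positions. Confident
#' regions are the complement of the ambiguous reference footprints over
#' the genome. Consensus variants whose footprint nevertheless intersects
#' an ambiguous footprint (a discordant alternative allele at the same
#' site) are dropped, so every truth variant lies inside the confident
#' regions.
#'
#' @param vcfs list of two or more normalized [variant_calls()] tables.
#' @param contig_lengths named vector of contig lengths covering every
#'   contig seen in the calls.
#' @return an object of class `truth_set`: list with `variants`
#'   (consensus [variant_calls()]), `confident_regions` and
#'   `ambiguous_positions` (`GRanges` partitioning the genome),
#'   `contig_lengths`, and `n_input_vcfs`.
#' @export
build_consensus <- function(vcfs, contig_lengths) {
  if (!is.list(vcfs) || length(vcfs) < 2L) {
    stop("build_consensus: need a list of >= 2 input VCF call sets")
  }
  n <- length(vcfs)
  seen <- unique(unlist(lapply(vcfs, function(v) unique(v$chrom))))
  missing <- setdiff(seen, names(contig_lengths))
  if (length(missing)) {
    stop("build_consensus: contig(s) absent from contig_lengths: ",
         paste(missing, collapse = ", "))
  }
  keyed <- lapply(vcfs, function(v) {
    dt <- data.table::as.data.table(v)[!ambiguous | is.na(ambiguous)]
    unique(dt[, .(chrom, pos, ref, alt)])
  })
  all_keys <- data.table::rbindlist(keyed)[, .(n_vcfs = .N), by = .(chrom, pos, ref, alt)]
  consensus_keys <- all_keys[n_vcfs == n]
  ambiguous_keys <- all_keys[n_vcfs < n]
  amb_gr <- if (nrow(ambiguous_keys)) {
    GenomicRanges::reduce(.gr(ambiguous_keys$chrom, ambiguous_keys$pos,
                              ambiguous_keys$pos + nchar(ambiguous_keys$ref) - 1L))
  } else GenomicRanges::GRanges()
  conf_gr <- GenomicRanges::setdiff(.genome_gr(contig_lengths), amb_gr)
  first <- data.table::as.data.table(vcfs[[1]])
  variants <- first[consensus_keys, on = c("chrom", "pos", "ref", "alt"), nomatch = NULL]
  variants <- unique(variants, by = c("chrom", "pos", "ref", "alt"))
  # allele-aware consensus can coexist with positional ambiguity; keep the
  # truth inside confident regions
  if (nrow(variants) && length(amb_gr)) {
    hits <- GenomicRanges::findOverlaps(.footprint_gr(variants), amb_gr)
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) variants <- variants[-drop]
  }
  truth_set(variants = variant_calls(variants, pipeline_id = "truth"),
            confident_regions = conf_gr,
            ambiguous_positions = amb_gr,
            contig_lengths = contig_lengths,
            n_input_vcfs = n)
}

#' Construct a truth-set object
#'
#' @param variants consensus truth variants as a [variant_calls()] table.
#' @param confident_regions,ambiguous_positions `GRanges` partitioning the
#'   genome (disjoint; union covers every contig).
#' @param contig_lengths named vector of contig lengths.
#' @param n_input_vcfs number of alignment VCFs intersected (`NA` for
#'   synthetic truth).
#' @param reference optional named character vector of contig sequences
#'   (attached by the synthetic generator).
#' @return an object of class `truth_set`.
#' @export
truth_set <- function(variants, confident_regions, ambiguous_positions,
                      contig_lengths, n_input_vcfs = NA_integer_,
                      reference = NULL) {
  ts <- list(variants = variants,
             confident_regions = confident_regions,
             ambiguous_positions = ambiguous_positions,
             contig_lengths = contig_lengths,
             n_input_vcfs = n_input_vcfs,
             reference = reference)
  class(ts) <- "truth_set"
  ts
}

#' @export
print.truth_set <- function(x, ...) {
  cat("<truth_set>", nrow(x$variants), "variants (",
      sum(x$variants$var_class == "SNP"), "SNP /",
      sum(x$variants$var_class %in% c("INS", "DEL")), "indel ) over",
      length(x$contig_lengths), "contig(s);",
      length(x$ambiguous_positions), "ambiguous interval(s)\n")
  invisible(x)
}

#' Enumerate a whole-genome-alignment parameter sweep
#'
#' Documents/orchestrates the external alignment sweep whose per-parameter
#' VCFs feed [build_consensus()]. Each grid is `c(start, stop, step)`.
#' `mode = "cartesian"` (nucmer-style independent parameters) takes the
#' cartesian product of the grids; `mode = "lockstep"` (paftools-style,
#' e.g. -l tied to -L) advances all grids together and requires them to be
#' the same length.
#'
#' @param grids named list of `c(start, stop, step)` numeric triples.
#' @param mode `"cartesian"` or `"lockstep"`.
#' @return `data.frame` with one column per grid, one row per parameter
#'   tuple.
#' @export
#' @examples
#' nrow(enumerate_sweep(list(l = c(25, 200, 25)), mode = "lockstep"))  # 8
enumerate_sweep <- function(grids, mode = c("cartesian", "lockstep")) {
  mode <- match.arg(mode)
  stopifnot(is.list(grids), length(grids) >= 1L, !is.null(names(grids)))
  vals <- lapply(grids, function(g) {
    stopifnot(length(g) == 3L)
    if (g[3] <= 0) stop("enumerate_sweep: step must be positive")
    seq(g[1], g[2], by = g[3])
  })
  if (mode == "cartesian") {
    expand.grid(vals, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L) {
      stop("enumerate_sweep: lockstep grids must have equal lengths")
    }
    as.data.frame(vals)
  }
}
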