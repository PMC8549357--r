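#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when reproducing printed report
#' tables; base R's `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.675, 2)  # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge past binary-representation error before taking floor
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# GRanges from (chrom, start, end) vectors, 1-based closed coordinates
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

# full-genome GRanges from a named vector of contig lengths
.genome_gr <- function(contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths >= 1))
  .gr(names(contig_lengths), 1L, as.integer(contig_lengths))
}

# reference footprint of calls: anchor base through last reference base
.footprint_gr <- function(calls) {
  .gr(calls$chrom, calls$pos, calls$pos + nchar(calls$ref) - 1L)
}

#' Read a FASTA index (.fai)
#'
#' @param path path to a samtools-style `.fai` file.
#' @return named integer vector of contig lengths.
#' @export
read_fai <- function(path) {
  fai <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(fai[[2]]), as.character(fai[[1]]))
}

#' Write intervals as a BED file
#'
#' Emits 0-based half-open intervals (BED convention) from 1-based closed
#' genomic ranges.
#'
#' @param gr a `GRanges` of 1-based closed intervals.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based closed intervals
#'
#' @param path path to a 3+ column BED file (0-based half-open).
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  .gr(as.character(dt[[1]]), as.integer(dt[[2]]) + 1L, as.integer(dt[[3]]))
}
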