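#' Construct a variant-call table
#'
#' The package's working container for variant calls is a `data.table` of
#' class `variant_calls`, one row per (record, ALT allele). Columns:
#' `chrom`, `pos` (1-based anchor), `ref`, `alt`, `qual` (Phred QUAL, `NA`
#' when "."), `filter_status` (`"PASS"`, `"non-PASS"`, `"unset"`),
#' `var_class` (`"SNP"`, `"INS"`, `"DEL"`, `"MNP"`, `"COMPLEX"`, `NA` when
#' ambiguous), `ambiguous` (any non-ACGT character in either allele;
#' excluded from all downstream characterization), `biallelic_site`
#' (original record had exactly one ALT), `mnp_derived` (SNP produced by
#' decomposing an MNP), `pipeline_id`, and `tags` (list column of named
#' character vectors holding the raw INFO and `FMT/`-prefixed FORMAT
#' values).
#'
#' @param dt a `data.frame` with at least `chrom`, `pos`, `ref`, `alt`;
#'   missing bookkeeping columns are filled with defaults.
#' @param pipeline_id label used when `dt` lacks a `pipeline_id` column.
#' @return a `variant_calls` object, sorted by (chrom, pos).
#' @export
variant_calls <- function(dt, pipeline_id = "unknown") {
  dt <- data.table::as.data.table(dt)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(dt)))
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, ref := toupper(as.character(ref))]
  dt[, alt := toupper(as.character(alt))]
  if (nrow(dt) > 0L &&
      (any(dt$pos < 1L) || any(!nzchar(dt$ref)) || any(!nzchar(dt$alt)) ||
       any(dt$ref == dt$alt))) {
    stop("variant_calls: need pos >= 1, non-empty alleles, ref != alt")
  }
  if (!"qual" %in% names(dt)) dt[, qual := NA_real_]
  if (!"filter_status" %in% names(dt)) dt[, filter_status := "unset"]
  if (!"ambiguous" %in% names(dt)) dt[, ambiguous := !.acgt_only(ref) | !.acgt_only(alt)]
  if (!"var_class" %in% names(dt)) dt[, var_class := classify_variant(ref, alt)]
  if (!"biallelic_site" %in% names(dt)) dt[, biallelic_site := TRUE]
  if (!"mnp_derived" %in% names(dt)) dt[, mnp_derived := FALSE]
  if (!"pipeline_id" %in% names(dt)) dt[, pipeline_id := pipeline_id]
  if (!"tags" %in% names(dt)) dt[, tags := list(rep(list(character(0)), .N))]
  data.table::setorder(dt, chrom, pos)
  data.table::setattr(dt, "class", c("variant_calls", class(data.table::data.table())))
  dt[]
}

.acgt_only <- function(x) grepl("^[ACGT]+$", x)

#' Classify a variant by its alleles
#'
#' Pure function of the (normalized) REF/ALT pair: equal length 1 is a SNP,
#' equal length > 1 an MNP, a REF that is a proper prefix of ALT an
#' insertion, an ALT that is a proper prefix of REF a deletion, anything
#' else COMPLEX. Alleles containing ambiguity characters (non-ACGT) return
#' `NA`; such calls carry the `ambiguous` flag instead of a class.
#'
#' @param ref,alt character vectors of allele strings (recycled).
#' @return character vector of classes.
#' @export
#' @examples
#' classify_variant("A", "G")     # SNP
#' classify_variant("A", "ATT")   # INS
#' classify_variant("ACG", "TT")  # COMPLEX
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  out <- rep(NA_character_, n)
  ok <- .acgt_only(ref) & .acgt_only(alt)
  lr <- nchar(ref); la <- nchar(alt)
  out[ok & lr == 1L & la == 1L] <- "SNP"
  out[ok & lr > 1L & lr == la] <- "MNP"
  ins <- ok & lr < la & substr(alt, 1L, lr) == ref
  del <- ok & lr > la & substr(ref, 1L, la) == alt
  out[ins] <- "INS"
  out[del] <- "DEL"
  out[ok & is.na(out)] <- "COMPLEX"
  out
}

#' Parse a VCF file into a variant-call table
#'
#' Reads a VCF 4.x file (plain text or gzip/bgzip compressed) and returns
#' one call per ALT allele per record, in coordinate order. Multi-allelic
#' records are split, with all resulting calls flagged as non-biallelic
#' sites (`biallelic_site = FALSE`). FILTER is preserved as
#' `"PASS"` / `"non-PASS"` / `"unset"` ("."). Raw INFO values and the first
#' sample's FORMAT values (prefixed `FMT/`) are kept verbatim in the `tags`
#' list column for dialect-driven characteristic extraction.
#'
#' @param path path to the VCF file.
#' @param pipeline_id label of the producing pipeline.
#' @param dialect optional [tag_dialect()]; stored as the
#'   `"dialect"` attribute for later [extract_characteristics()] calls.
#' @return a [variant_calls()] table.
#' @export
parse_vcf <- function(path, pipeline_id = "unknown", dialect = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  body_at <- which(!startsWith(lines, "#"))
  rows <- vector("list", length(body_at))
  for (i in seq_along(body_at)) {
    ln <- body_at[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("malformed VCF record at line ", ln, " of ", path,
           ": expected >= 8 tab-separated fields, got ", length(f))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      stop("malformed VCF record at line ", ln, " of ", path,
           ": POS is not a positive integer")
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0L || !nzchar(f[4])) {
      stop("malformed VCF record at line ", ln, " of ", path,
           ": empty REF or ALT")
    }
    qual <- if (f[6] == ".") NA_real_ else suppressWarnings(as.numeric(f[6]))
    filt <- if (f[7] == "." || f[7] == "") "unset"
            else if (f[7] == "PASS") "PASS" else "non-PASS"
    tags <- .parse_tags(f)
    rows[[i]] <- data.table::data.table(
      chrom = f[1], pos = pos, ref = toupper(f[4]), alt = toupper(alts),
      qual = qual, filter_status = filt,
      biallelic_site = length(alts) == 1L,
      tags = rep(list(tags), length(alts))
    )
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  out <- variant_calls(dt, pipeline_id = pipeline_id)
  data.table::setattr(out, "dialect", dialect)
  out
}

# INFO "k=v;flag" plus first-sample FORMAT values as FMT/-prefixed entries
.parse_tags <- function(fields) {
  tags <- character(0)
  if (fields[8] != "." && nzchar(fields[8])) {
    kv <- strsplit(fields[8], ";", fixed = TRUE)[[1]]
    eq <- regexpr("=", kv, fixed = TRUE)
    keys <- ifelse(eq > 0, substr(kv, 1L, eq - 1L), kv)
    vals <- ifelse(eq > 0, substring(kv, eq + 1L), "TRUE")
    tags <- stats::setNames(vals, keys)
  }
  if (length(fields) >= 10L && nzchar(fields[9])) {
    keys <- strsplit(fields[9], ":", fixed = TRUE)[[1]]
    vals <- strsplit(fields[10], ":", fixed = TRUE)[[1]]
    n <- min(length(keys), length(vals))
    if (n > 0L) {
      tags <- c(tags, stats::setNames(vals[seq_len(n)],
                                      paste0("FMT/", keys[seq_len(n)])))
    }
  }
  tags
}

#' Normalize variant calls against a reference
#'
#' Emulates standard VCF pre-processing (left-shift plus decomposition):
#' indels are left-aligned by trimming shared suffix bases and extending
#' leftwards through repeats; alleles are reduced to minimal representation
#' with a single anchor base; MNPs are decomposed into per-base SNPs flagged
#' `mnp_derived`; length-discordant non-indel substitutions are kept as
#' single COMPLEX records. Ambiguous-allele calls pass through unchanged.
#' The operation is idempotent.
#'
#' @param calls a [variant_calls()] table.
#' @param reference named character vector (or `DNAStringSet`) of contig
#'   sequences covering every call locus.
#' @return a normalized, coordinate-sorted [variant_calls()] table.
#' @export
normalize_calls <- function(calls, reference) {
  reference <- .as_seq_vector(reference)
  if (nrow(calls) == 0L) return(calls)
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i]
    if (isTRUE(row$ambiguous)) {
      out[[i]] <- row
      next
    }
    seq <- reference[[row$chrom]]
    if (is.null(seq) || is.na(seq)) {
      stop("normalize_calls: contig not in reference: ", row$chrom)
    }
    if (substr(seq, row$pos, row$pos + nchar(row$ref) - 1L) != row$ref) {
      stop("normalize_calls: REF allele disagrees with reference at ",
           row$chrom, ":", row$pos)
    }
    na <- .left_align(row$pos, row$ref, row$alt, seq)
    if (nchar(na$ref) == nchar(na$alt) && nchar(na$ref) > 1L) {
      # MNP: one SNP per differing base, each flagged as MNP-derived
      rb <- strsplit(na$ref, "")[[1]]
      ab <- strsplit(na$alt, "")[[1]]
      d <- which(rb != ab)
      pieces <- lapply(d, function(k) {
        r <- data.table::copy(row)
        r[, `:=`(pos = na$pos + k - 1L, ref = rb[k], alt = ab[k],
                 var_class = "SNP", mnp_derived = TRUE)]
        r
      })
      out[[i]] <- data.table::rbindlist(pieces)
    } else {
      r <- data.table::copy(row)
      r[, `:=`(pos = na$pos, ref = na$ref, alt = na$alt,
               var_class = classify_variant(na$ref, na$alt))]
      out[[i]] <- r
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, pos)
  data.table::setattr(res, "class", class(calls))
  data.table::setattr(res, "dialect", attr(calls, "dialect", exact = TRUE))
  res[]
}

.as_seq_vector <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    stopifnot(is.character(reference), !is.null(names(reference)))
    toupper(reference)
  }
}

# vt-style normalization: trim shared suffix (extending left through the
# reference when an allele empties), then trim shared prefix down to one
# anchor base. Returns list(pos, ref, alt).
.left_align <- function(pos, ref, alt, seq) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L && (lr > 1L || la > 1L) &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos <= 1L) {
          stop(".left_align: cannot left-extend past contig start")
        }
        pos <- pos - 1L
        b <- substr(seq, pos, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write calls to a VCF 4.2 file
#'
#' One record per call (multi-allelic sites are written split, as held in
#' the table). Non-`FMT/` tags are written to INFO; `FMT/` tags to a single
#' sample column. FILTER is `PASS`, `.` (unset), or the stored string for
#' non-PASS (written as `FAIL` unless a `filter_detail` column is present).
#'
#' @param calls a [variant_calls()] table.
#' @param path output path.
#' @param contig_lengths optional named vector, emitted as `##contig` lines.
#' @param sample_name sample column name when FORMAT tags are present.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL, sample_name = "SAMPLE") {
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=fpfilter"),
              .vcf_meta_lines(calls, contig_lengths))
  has_fmt <- any(vapply(calls$tags, function(t) {
    length(t) > 0L && any(startsWith(names(t), "FMT/"))
  }, logical(1)))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_fmt) cols <- c(cols, "FORMAT", sample_name)
  recs <- vapply(seq_len(nrow(calls)), function(i) {
    row <- calls[i]
    t <- row$tags[[1]]
    is_fmt <- if (length(t)) startsWith(names(t), "FMT/") else logical(0)
    info <- t[!is_fmt]
    info_str <- if (length(info)) {
      paste(ifelse(info == "TRUE", names(info),
                   paste0(names(info), "=", info)), collapse = ";")
    } else "."
    filt <- switch(row$filter_status, PASS = "PASS", unset = ".",
                   `non-PASS` = if (!is.null(row$filter_detail)) row$filter_detail else "FAIL")
    fields <- c(row$chrom, row$pos, ".", row$ref, row$alt,
                if (is.na(row$qual)) "." else format(row$qual, trim = TRUE),
                filt, info_str)
    if (has_fmt) {
      fmt <- t[is_fmt]
      if (length(fmt)) {
        fields <- c(fields, paste(sub("^FMT/", "", names(fmt)), collapse = ":"),
                    paste(fmt, collapse = ":"))
      } else {
        fields <- c(fields, "GT", ".")
      }
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(cols, collapse = "\t"), recs), path)
  invisible(path)
}

.vcf_meta_lines <- function(calls, contig_lengths) {
  known_info <- c(
    DP = "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    AO = "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observations\">",
    AD = "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    QD = "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    SAF = "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt observations on forward strand\">",
    SAR = "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt observations on reverse strand\">",
    RPL = "##INFO=<ID=RPL,Number=A,Type=Integer,Description=\"Alt reads placed left of variant\">",
    RPR = "##INFO=<ID=RPR,Number=A,Type=Integer,Description=\"Alt reads placed right of variant\">"
  )
  known_fmt <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    DP = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  keys <- as.character(stats::na.omit(unique(unlist(lapply(calls$tags, names)))))
  info_keys <- keys[!startsWith(keys, "FMT/")]
  fmt_keys <- sub("^FMT/", "", keys[startsWith(keys, "FMT/")])
  lines <- character(0)
  if (!is.null(contig_lengths)) {
    lines <- c(lines, sprintf("##contig=<ID=%s,length=%d>",
                              names(contig_lengths), as.integer(contig_lengths)))
  }
  extra_info <- base::setdiff(info_keys, names(known_info))
  extra_fmt <- base::setdiff(fmt_keys, names(known_fmt))
  c(lines,
    unname(known_info[intersect(names(known_info), info_keys)]),
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"unmodelled tag\">", extra_info),
    unname(known_fmt[intersect(names(known_fmt), fmt_keys)]),
    sprintf("##FORMAT=<ID=%s,Number=.,Type=String,Description=\"unmodelled tag\">", extra_fmt))
}
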