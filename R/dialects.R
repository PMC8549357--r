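#' Define a caller tag dialect
#'
#' Variant callers differ in which INFO/FORMAT tags encode each positional
#' characteristic (and in what "depth" means). A dialect maps characteristics
#' to tag lookups. Tag references use the syntax `"DP"` (INFO tag),
#' `"FMT/AD"` (FORMAT tag, first sample), with an optional 1-based index
#' into comma-separated values, e.g. `"FMT/AD[2]"` for the first ALT's
#' allele depth. A characteristic with no mapping is reported as
#' unavailable, never as zero.
#'
#' @param dialect_id caller-family label.
#' @param depth tag holding total read depth at the locus.
#' @param alt_reads tag holding the count of variant-supporting reads.
#' @param qd tag holding a quality-by-depth statistic (e.g. GATK `QD`).
#' @param vaf tag holding a precomputed variant allele frequency; used only
#'   when the depth/alt-read counts are not both available.
#' @param alt_fwd,alt_rev tags holding forward/reverse-strand counts of
#'   variant-supporting reads (e.g. Freebayes `SAF`/`SAR`).
#' @param alt_left,alt_right tags holding counts of variant-supporting reads
#'   placed left/right of the call (e.g. Freebayes `RPL`/`RPR`).
#' @param depth_semantics `"absolute"` if the depth tag counts all mapped
#'   reads, `"filtered"` if the caller reports only internally retained
#'   reads. Recorded for provenance; not acted on.
#' @return an object of class `tag_dialect`.
#' @export
#' @examples
#' tag_dialect("freebayes", depth = "DP", alt_reads = "AO",
#'             alt_fwd = "SAF", alt_rev = "SAR",
#'             alt_left = "RPL", alt_right = "RPR")
tag_dialect <- function(dialect_id, depth = NULL, alt_reads = NULL, qd = NULL,
                        vaf = NULL, alt_fwd = NULL, alt_rev = NULL,
                        alt_left = NULL, alt_right = NULL,
                        depth_semantics = c("absolute", "filtered")) {
  stopifnot(is.character(dialect_id), length(dialect_id) == 1L)
  depth_semantics <- match.arg(depth_semantics)
  d <- list(
    dialect_id = dialect_id,
    mapping = list(depth = depth, alt_reads = alt_reads, qd = qd, vaf = vaf,
                   alt_fwd = alt_fwd, alt_rev = alt_rev,
                   alt_left = alt_left, alt_right = alt_right),
    depth_semantics = depth_semantics
  )
  class(d) <- "tag_dialect"
  d
}

#' @export
print.tag_dialect <- function(x, ...) {
  m <- x$mapping[!vapply(x$mapping, is.null, logical(1))]
  cat("<tag_dialect>", x$dialect_id, "\n")
  for (k in names(m)) cat("  ", k, "<-", m[[k]], "\n")
  cat("  depth semantics:", x$depth_semantics, "\n")
  invisible(x)
}

#' Built-in tag dialects
#'
#' Three dialects spanning the range of tag richness seen across callers:
#' `freebayes` (all nine characteristics derivable, including read-placement
#' counts), `gatk` (FORMAT-based depth/allele depth plus `QD`; no strand or
#' placement counts), and `minimal` (depth only).
#'
#' @return named list of [tag_dialect()] objects.
#' @export
default_dialects <- function() {
  list(
    freebayes = tag_dialect("freebayes",
      depth = "DP", alt_reads = "AO",
      alt_fwd = "SAF", alt_rev = "SAR",
      alt_left = "RPL", alt_right = "RPR"
    ),
    gatk = tag_dialect("gatk",
      depth = "FMT/DP", alt_reads = "FMT/AD[2]", qd = "QD",
      depth_semantics = "filtered"
    ),
    minimal = tag_dialect("minimal", depth = "DP")
  )
}

#' Read tag dialects from a config file
#'
#' The file is INI-like: one `[dialect_id]` section header per dialect,
#' followed by `key = value` lines where key is one of the [tag_dialect()]
#' mapping arguments (plus optional `depth_semantics`).
#'
#' @param path path to the config file.
#' @return named list of [tag_dialect()] objects.
#' @export
read_dialects <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  fields <- list()
  flush <- function() {
    if (is.null(cur)) return()
    out[[cur]] <<- do.call(tag_dialect, c(list(dialect_id = cur), fields))
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      fields <- list()
    } else {
      if (is.null(cur)) stop("dialect config: key before any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("dialect config: malformed line: ", ln)
      fields[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  flush()
  out
}

# Resolve one tag reference against a call's raw tag map.
# ref syntax: "TAG", "TAG[i]", "FMT/TAG", "FMT/TAG[i]". Returns numeric or NA.
.tag_value <- function(tags, ref) {
  if (is.null(ref) || is.null(tags)) return(NA_real_)
  idx <- 1L
  m <- regmatches(ref, regexec("^(.*)\\[([0-9]+)\\]$", ref))[[1]]
  if (length(m) == 3L) {
    ref <- m[2]
    idx <- as.integer(m[3])
  }
  val <- tags[[ref]]
  if (is.null(val) || is.na(val)) return(NA_real_)
  parts <- strsplit(val, ",", fixed = TRUE)[[1]]
  if (idx > length(parts)) return(NA_real_)
  suppressWarnings(as.numeric(parts[idx]))
}
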