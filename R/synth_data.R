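#' Pipeline profile for the synthetic generator
#'
#' Describes one simulated variant-calling pipeline: its tag dialect (which
#' INFO/FORMAT tags it emits), per-type recall, per-type FP rates, and the
#' parametric distributions of the characteristics for each call class
#' (TP, data-deficient FP, data-surfeit FP). Defaults model high-depth
#' haploid short-read sequencing: TP depth is negative binomial with mean
#' ~60; data-deficient FPs have Poisson(3) depth, quality spread around the
#' hard-filter thresholds, and allele frequency below 1; data-surfeit FPs
#' have depths several standard deviations above the TP mean with high
#' quality and allele frequency 1, so minimum-threshold filters cannot see
#' them.
#'
#' @param pipeline_id label.
#' @param dialect a [tag_dialect()] controlling emitted tags.
#' @param recall named numeric, per-type probability a truth variant is
#'   called (`SNP`, `INDEL`).
#' @param fp_rate named numeric, expected FPs per reference base per type.
#' @param tp list: `depth_mean`, `depth_size` (negative binomial),
#'   `qual_shape`, `qual_scale` (gamma).
#' @param deficient list: `depth_lambda` (Poisson, floored at 1),
#'   `qual_max` (quality ~ Uniform(0, qual_max)), `vaf_min`
#'   (VAF ~ Uniform(vaf_min, 1)), `strand_p` (per-read strand bias).
#' @param surfeit list: `depth_sigma` (depth ~ uniform over TP mean +
#'   sigma[1]..sigma[2] standard deviations), `qual_range`.
#' @return object of class `pipeline_profile`.
#' @export
pipeline_profile <- function(pipeline_id,
                             dialect = default_dialects()$freebayes,
                             recall = c(SNP = 0.95, INDEL = 0.90),
                             fp_rate = c(SNP = 5e-4, INDEL = 5e-5),
                             tp = list(depth_mean = 60, depth_size = 10,
                                       qual_shape = 4, qual_scale = 50),
                             deficient = list(depth_lambda = 3, qual_max = 40,
                                              vaf_min = 0.5, strand_p = 0.9),
                             surfeit = list(depth_sigma = c(4, 10),
                                            qual_range = c(500, 2000))) {
  stopifnot(inherits(dialect, "tag_dialect"),
            all(recall >= 0 & recall <= 1), all(fp_rate >= 0))
  p <- list(pipeline_id = pipeline_id, dialect = dialect, recall = recall,
            fp_rate = fp_rate, tp = tp, deficient = deficient,
            surfeit = surfeit)
  class(p) <- "pipeline_profile"
  p
}

#' Built-in pipeline profiles
#'
#' Three profiles differing in tag richness, emulating caller-dialect
#' variation: `fullinfo` (Freebayes-style INFO tags: all nine
#' characteristics derivable), `gatkish` (FORMAT DP/AD plus INFO QD; no
#' strand or placement counts), and `minimal` (INFO DP only).
#'
#' @return named list of [pipeline_profile()]s.
#' @export
default_pipeline_profiles <- function() {
  d <- default_dialects()
  list(
    fullinfo = pipeline_profile("fullinfo", dialect = d$freebayes),
    gatkish = pipeline_profile("gatkish", dialect = d$gatk),
    minimal = pipeline_profile("minimal", dialect = d$minimal)
  )
}

#' Simulation configuration
#'
#' The stated world of the synthetic experiment: a uniform-random haploid
#' reference, planted SNP/indel truth variants (densities default to the
#' middle of the benchmarked range, scaled to genome size), a random
#' ambiguous fraction of the genome, and per-pipeline call sets whose FPs
#' split into a data-deficient and a data-surfeit class, with deficient FPs
#' preferentially clustered near truth indels.
#'
#' @param seed mandatory integer seed; every generator draw derives from it.
#' @param contig_lengths named integer vector of contig lengths.
#' @param n_snps,n_indels planted truth variant counts.
#' @param ambiguous_fraction fraction of the genome marked ambiguous
#'   (excluded from scoring), drawn as random 50 bp intervals avoiding
#'   truth footprints.
#' @param fp_deficient_fraction fraction of FPs in the data-deficient
#'   class; the remainder are data-surfeit.
#' @param p_near probability a data-deficient FP is placed within
#'   `near_window` bp of a truth indel.
#' @param near_window clustering window in bp.
#' @param profiles list of [pipeline_profile()]s.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              contig_lengths = c(chr1 = 100000L),
                              n_snps = 300L, n_indels = 30L,
                              ambiguous_fraction = 0.01,
                              fp_deficient_fraction = 0.8,
                              p_near = 0.3, near_window = 10L,
                              profiles = default_pipeline_profiles()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("simulation_config: seed is mandatory")
  }
  stopifnot(n_snps >= 0, n_indels >= 0,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1,
            fp_deficient_fraction >= 0, fp_deficient_fraction <= 1,
            p_near >= 0, p_near <= 1)
  cfg <- list(seed = as.integer(seed), contig_lengths = contig_lengths,
              n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
              ambiguous_fraction = ambiguous_fraction,
              fp_deficient_fraction = fp_deficient_fraction,
              p_near = p_near, near_window = as.integer(near_window),
              profiles = profiles)
  class(cfg) <- "simulation_config"
  cfg
}

# run expr under a derived seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

#' Generate a uniform-random reference
#'
#' @param config a [simulation_config()].
#' @return named character vector of ACGT contig sequences; identical for
#'   identical seeds.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$contig_lengths < 1L)) {
    stop("generate_reference: zero-length contig")
  }
  .with_seed(config$seed, {
    vapply(config$contig_lengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Plant truth variants into a reference
#'
#' Draws `n_snps` SNPs and `n_indels` 1-10 bp indels at uniform positions
#' with non-overlapping reference footprints, normalizes them against the
#' reference (so planted indels are left-aligned), and carves a random
#' ambiguous fraction out of the genome, avoiding truth footprints so that
#' every truth variant lies in the confident regions.
#'
#' @param reference named character vector from [generate_reference()].
#' @param config a [simulation_config()].
#' @return a [truth_set()] carrying the reference.
#' @export
plant_truth <- function(reference, config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- nchar(reference)
  total <- config$n_snps + config$n_indels
  if (total * 12L > sum(L)) {
    stop("plant_truth: requested variants exceed available positions")
  }
  .with_seed(config$seed + 1L, {
    result <- NULL
    for (attempt in 1:50) {
      vars <- .draw_truth_variants(reference, config)
      if (is.null(vars)) next
      norm <- normalize_calls(variant_calls(vars, pipeline_id = "truth"), reference)
      fp <- .footprint_gr(norm)
      if (nrow(norm) == nrow(unique(data.table::as.data.table(norm),
                                    by = c("chrom", "pos", "ref", "alt"))) &&
          !any(GenomicRanges::countOverlaps(fp, fp) > 1L)) {
        amb <- .draw_ambiguous(config, fp)
        conf <- GenomicRanges::setdiff(.genome_gr(config$contig_lengths), amb)
        result <- truth_set(norm, conf, amb, config$contig_lengths,
                            n_input_vcfs = NA_integer_, reference = reference)
        break
      }
    }
    if (is.null(result)) {
      stop("plant_truth: could not place non-overlapping variants in 50 attempts")
    }
    result
  })
}

.draw_truth_variants <- function(reference, config) {
  rows <- list()
  taken <- GenomicRanges::GRanges()
  bases <- c("A", "C", "G", "T")
  for (chrom_i in seq_along(reference)) {
    chrom <- names(reference)[chrom_i]
    L <- nchar(reference[[chrom_i]])
    frac <- L / sum(nchar(reference))
    n_snp <- round(config$n_snps * frac)
    n_ind <- round(config$n_indels * frac)
    seqc <- reference[[chrom_i]]
    place <- function(n, width_fun, make_row) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:200) {
          w <- width_fun()
          pos <- sample.int(L - w - 1L, 1L) + 1L
          cand <- .gr(chrom, pos, pos + w - 1L)
          if (length(GenomicRanges::findOverlaps(cand, taken)) == 0L) {
            taken <<- c(taken, cand)
            out[[i]] <- make_row(pos, w)
            ok <- TRUE
            break
          }
        }
        if (!ok) return(NULL)
      }
      out
    }
    snps <- place(n_snp, function() 1L, function(pos, w) {
      ref <- substr(seqc, pos, pos)
      data.table::data.table(chrom = chrom, pos = pos, ref = ref,
                             alt = sample(setdiff(bases, ref), 1L))
    })
    if (is.null(snps)) return(NULL)
    indels <- place(n_ind, function() sample(2:11, 1L), function(pos, w) {
      if (runif(1) < 0.5) {
        # deletion: anchor plus w-1 deleted bases
        data.table::data.table(chrom = chrom, pos = pos,
                               ref = substr(seqc, pos, pos + w - 1L),
                               alt = substr(seqc, pos, pos))
      } else {
        ins <- paste(sample(bases, w - 1L, replace = TRUE), collapse = "")
        data.table::data.table(chrom = chrom, pos = pos,
                               ref = substr(seqc, pos, pos),
                               alt = paste0(substr(seqc, pos, pos), ins))
      }
    })
    if (is.null(indels)) return(NULL)
    rows <- c(rows, snps, indels)
  }
  if (!length(rows)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  }
  data.table::rbindlist(rows)
}

.draw_ambiguous <- function(config, truth_fp) {
  if (config$ambiguous_fraction <= 0) return(GenomicRanges::GRanges())
  out <- GenomicRanges::GRanges()
  for (chrom in names(config$contig_lengths)) {
    L <- config$contig_lengths[[chrom]]
    target <- config$ambiguous_fraction * L
    got <- 0
    guard <- 0L
    while (got < target && guard < 10000L) {
      guard <- guard + 1L
      start <- sample.int(max(L - 50L, 1L), 1L)
      cand <- .gr(chrom, start, min(start + 49L, L))
      if (length(GenomicRanges::findOverlaps(cand, truth_fp)) == 0L) {
        out <- GenomicRanges::reduce(c(out, cand))
        got <- sum(GenomicRanges::width(out[GenomicRanges::seqnames(out) == chrom]))
      }
    }
  }
  out
}

#' Simulate one pipeline's call set
#'
#' Emits each truth variant as a TP with probability `recall[type]`
#' (dropped variants are the implicit FNs), then places FPs: counts are
#' Poisson with mean `fp_rate[type] * genome length`. Data-deficient FPs
#' are placed within `near_window` bp of a truth indel with probability
#' `p_near` (uniformly otherwise); data-surfeit FPs are placed at least
#' `max(11, near_window + 1)` bp from every other call so that, as in real
#' data, no minimum-threshold filter (including the proximity filters) can
#' detect them. All calls land in confident regions at distinct, non-truth
#' positions. Characteristics are drawn per class from the profile's
#' distributions and emitted as tags according to the profile's dialect;
#' ground-truth labels go to a sidecar table, never into the VCF.
#'
#' @param truth a [truth_set()] from [plant_truth()] (carries the
#'   reference).
#' @param profile a [pipeline_profile()].
#' @param config the [simulation_config()].
#' @param seed_offset small integer distinguishing pipelines drawn from one
#'   config.
#' @return list with `calls` (a [variant_calls()] table with the profile's
#'   dialect attached) and `labels` (sidecar `data.table`: chrom, pos, ref,
#'   alt, label, fp_class).
#' @export
simulate_pipeline_vcf <- function(truth, profile, config, seed_offset = 0L) {
  stopifnot(inherits(truth, "truth_set"), inherits(profile, "pipeline_profile"))
  reference <- truth$reference
  if (is.null(reference)) {
    stop("simulate_pipeline_vcf: truth set carries no reference sequence")
  }
  .with_seed(config$seed + 1000L * (seed_offset + 2L), {
    tv <- data.table::as.data.table(truth$variants)
    tv[, type := .call_type(var_class)]
    keep <- runif(nrow(tv)) <= profile$recall[tv$type]
    tps <- tv[keep]

    genome_len <- sum(config$contig_lengths)
    n_fp <- stats::setNames(
      rpois(2, profile$fp_rate[c("SNP", "INDEL")] * genome_len),
      c("SNP", "INDEL"))
    fp_rows <- .place_fps(truth, config, n_fp, tps)

    tp_chars <- .draw_class_chars(nrow(tps), "TP", profile)
    fp_chars <- .draw_class_chars(nrow(fp_rows), fp_rows$fp_class, profile)

    calls_dt <- rbind(
      tps[, .(chrom, pos, ref, alt)][, fp_class := NA_character_],
      fp_rows[, .(chrom, pos, ref, alt, fp_class)]
    )
    chars <- rbind(tp_chars, fp_chars)
    calls_dt[, `:=`(qual = chars$qual, filter_status = "PASS")]
    calls_dt[, tags := .emit_tags(chars, profile$dialect)]
    labels <- calls_dt[, .(chrom, pos, ref, alt,
                           label = ifelse(is.na(fp_class), "TP", "FP"),
                           fp_class = fp_class)]
    data.table::setorder(labels, chrom, pos)
    calls <- variant_calls(calls_dt[, fp_class := NULL],
                           pipeline_id = profile$pipeline_id)
    data.table::setattr(calls, "dialect", profile$dialect)
    list(calls = calls, labels = labels)
  })
}

# draw FP positions/alleles; deficient FPs cluster near truth indels,
# surfeit FPs keep > near-window distance from every other call
.place_fps <- function(truth, config, n_fp, tps) {
  reference <- truth$reference
  bases <- c("A", "C", "G", "T")
  used <- .footprint_gr(truth$variants)
  conf <- truth$confident_regions
  indel_anchors <- data.table::as.data.table(
    truth$variants)[var_class %in% c("INS", "DEL"), .(chrom, pos)]
  w <- config$near_window
  rows <- list()
  # position admissible iff inside confident regions, clear of used footprints
  free_at <- function(chrom, pos, span = 1L, margin = 0L) {
    cand <- .gr(chrom, max(pos - margin, 1L),
                min(pos + span - 1L + margin, config$contig_lengths[[chrom]]))
    core <- .gr(chrom, pos, pos + span - 1L)
    length(GenomicRanges::findOverlaps(cand, used)) == 0L &&
      length(GenomicRanges::setdiff(core, conf)) == 0L
  }
  draw_pos <- function(near, span, margin) {
    for (try in 1:500) {
      if (near && nrow(indel_anchors)) {
        a <- indel_anchors[sample.int(nrow(indel_anchors), 1L)]
        chrom <- a$chrom
        pos <- a$pos + sample(c(-w:-1, 1:w), 1L)
      } else {
        chrom <- sample(names(config$contig_lengths), 1L,
                        prob = config$contig_lengths)
        pos <- sample.int(config$contig_lengths[[chrom]] - 12L, 1L) + 1L
      }
      if (pos < 2L || pos > config$contig_lengths[[chrom]] - span - 1L) next
      if (free_at(chrom, pos, span, margin)) {
        return(list(chrom = chrom, pos = pos))
      }
    }
    NULL
  }
  total <- sum(n_fp)
  classes <- sample(c("deficient", "surfeit"), total, replace = TRUE,
                    prob = c(config$fp_deficient_fraction,
                             1 - config$fp_deficient_fraction))
  types <- rep(names(n_fp), n_fp)
  # surfeit last so their isolation margin sees every other call
  ord <- order(classes == "surfeit")
  classes <- classes[ord]; types <- types[ord]
  if (config$p_near > 0 && nrow(indel_anchors) == 0L) {
    warning("simulate_pipeline_vcf: p_near > 0 but truth has no indels; ",
            "falling back to uniform FP placement")
  }
  for (i in seq_along(classes)) {
    is_def <- classes[i] == "deficient"
    near <- is_def && nrow(indel_anchors) > 0L && runif(1) < config$p_near
    span <- if (types[i] == "SNP") 1L else sample(2:4, 1L)
    margin <- if (is_def) 0L else max(11L, w + 1L)
    loc <- draw_pos(near, span, margin)
    if (is.null(loc)) next  # genome too crowded; drop this FP
    seqc <- reference[[loc$chrom]]
    if (types[i] == "SNP") {
      ref <- substr(seqc, loc$pos, loc$pos)
      row <- data.table::data.table(chrom = loc$chrom, pos = loc$pos, ref = ref,
                                    alt = sample(setdiff(bases, ref), 1L))
    } else if (runif(1) < 0.5) {
      row <- data.table::data.table(chrom = loc$chrom, pos = loc$pos,
                                    ref = substr(seqc, loc$pos, loc$pos + span - 1L),
                                    alt = substr(seqc, loc$pos, loc$pos))
    } else {
      anchor <- substr(seqc, loc$pos, loc$pos)
      ins <- paste(sample(bases, span - 1L, replace = TRUE), collapse = "")
      row <- data.table::data.table(chrom = loc$chrom, pos = loc$pos,
                                    ref = anchor, alt = paste0(anchor, ins))
    }
    # left-align; re-draw rather than emit if the shifted key collides
    norm <- .left_align(row$pos, row$ref, row$alt, seqc)
    row[, `:=`(pos = norm$pos, ref = norm$ref, alt = norm$alt)]
    if (!free_at(row$chrom, row$pos, nchar(row$ref), margin)) next
    row[, fp_class := classes[i]]
    used <- c(used, .gr(row$chrom, row$pos, row$pos + nchar(row$ref) - 1L))
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  fp_class = character()))
  }
  data.table::rbindlist(rows)
}

# per-class characteristic draws; returns qual/depth/alt/strand/placement
.draw_class_chars <- function(n, classes, profile) {
  if (length(classes) == 1L) classes <- rep(classes, n)
  stopifnot(length(classes) == n)
  tp <- profile$tp; def <- profile$deficient; sur <- profile$surfeit
  depth <- alt <- qual <- fwd <- lft <- integer(n)
  sd_tp <- sqrt(tp$depth_mean + tp$depth_mean^2 / tp$depth_size)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "TP") {
      d <- max(1L, rnbinom(1, mu = tp$depth_mean, size = tp$depth_size))
      a <- d
      q <- rgamma(1, shape = tp$qual_shape, scale = tp$qual_scale)
      p_strand <- 0.5
    } else if (cl == "deficient") {
      d <- max(1L, rpois(1, def$depth_lambda))
      a <- max(1L, round(runif(1, def$vaf_min, 1) * d))
      q <- runif(1, 0, def$qual_max)
      p_strand <- def$strand_p
    } else { # surfeit
      lo <- tp$depth_mean + sur$depth_sigma[1] * sd_tp
      hi <- tp$depth_mean + sur$depth_sigma[2] * sd_tp
      d <- round(runif(1, lo, hi))
      a <- d
      q <- runif(1, sur$qual_range[1], sur$qual_range[2])
      p_strand <- 0.5
    }
    depth[i] <- d; alt[i] <- a; qual[i] <- q
    fwd[i] <- rbinom(1, a, p_strand)
    lft[i] <- rbinom(1, a, p_strand)
  }
  data.table::data.table(qual = round(qual, 2), depth = depth, alt_reads = alt,
                         alt_fwd = fwd, alt_rev = alt - fwd,
                         alt_left = lft, alt_right = alt - lft)
}

# materialize tag maps per the dialect's vocabulary
.emit_tags <- function(chars, dialect) {
  id <- dialect$dialect_id
  lapply(seq_len(nrow(chars)), function(i) {
    r <- chars[i]
    if (id == "freebayes") {
      c(DP = as.character(r$depth), AO = as.character(r$alt_reads),
        SAF = as.character(r$alt_fwd), SAR = as.character(r$alt_rev),
        RPL = as.character(r$alt_left), RPR = as.character(r$alt_right))
    } else if (id == "gatk") {
      c(QD = as.character(round(r$qual / max(r$depth, 1L), 2)),
        `FMT/GT` = "1/1",
        `FMT/DP` = as.character(r$depth),
        `FMT/AD` = paste(r$depth - r$alt_reads, r$alt_reads, sep = ","))
    } else {
      c(DP = as.character(r$depth))
    }
  })
}

#' Write a complete fixture suite to disk
#'
#' Generates reference, truth and per-pipeline call sets for `config` and
#' writes them in standard formats: `reference.fasta` (+ `.fai`),
#' `truth.vcf`, `confident.bed`, `ambiguous.bed`, one `<pipeline>.vcf` and
#' `<pipeline>_labels.tsv` (the ground-truth sidecar) per profile.
#' Deterministic for a given seed.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly; also returns the
#'   in-memory objects in the `objects` element.
#' @export
make_fixture_suite <- function(config, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("make_fixture_suite: cannot create ", dir)
  }
  reference <- generate_reference(config)
  truth <- plant_truth(reference, config)
  paths <- list(
    fasta = file.path(dir, "reference.fasta"),
    fai = file.path(dir, "reference.fasta.fai"),
    truth_vcf = file.path(dir, "truth.vcf"),
    confident_bed = file.path(dir, "confident.bed"),
    ambiguous_bed = file.path(dir, "ambiguous.bed")
  )
  .write_fasta_fai(reference, paths$fasta, paths$fai)
  write_vcf(truth$variants, paths$truth_vcf, contig_lengths = config$contig_lengths)
  write_bed(truth$confident_regions, paths$confident_bed)
  write_bed(truth$ambiguous_positions, paths$ambiguous_bed)
  sims <- list()
  for (k in seq_along(config$profiles)) {
    prof <- config$profiles[[k]]
    sim <- simulate_pipeline_vcf(truth, prof, config, seed_offset = k)
    vcf_path <- file.path(dir, paste0(prof$pipeline_id, ".vcf"))
    lab_path <- file.path(dir, paste0(prof$pipeline_id, "_labels.tsv"))
    write_vcf(sim$calls, vcf_path, contig_lengths = config$contig_lengths)
    data.table::fwrite(sim$labels, lab_path, sep = "\t")
    paths[[paste0("vcf_", prof$pipeline_id)]] <- vcf_path
    paths[[paste0("labels_", prof$pipeline_id)]] <- lab_path
    sims[[prof$pipeline_id]] <- sim
  }
  paths$objects <- list(reference = reference, truth = truth, sims = sims)
  invisible(paths)
}

.write_fasta_fai <- function(reference, fasta_path, fai_path, width = 70L) {
  dss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dss, fasta_path, width = width)
  offsets <- integer(length(reference))
  off <- 0L
  lens <- nchar(reference)
  for (i in seq_along(reference)) {
    off <- off + nchar(names(reference)[i]) + 2L  # ">name\n"
    offsets[i] <- off
    nlines <- ceiling(lens[i] / width)
    off <- off + lens[i] + nlines  # sequence bytes + newlines
  }
  fai <- data.table::data.table(names(reference), lens, offsets, width, width + 1L)
  data.table::fwrite(fai, fai_path, sep = "\t", col.names = FALSE)
  invisible(fai_path)
}
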