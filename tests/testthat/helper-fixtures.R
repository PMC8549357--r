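# fixture builders and independent oracles shared across test files

# minimal call table from parallel vectors
make_calls <- function(chrom, pos, ref, alt, ..., pipeline_id = "test") {
  variant_calls(data.table::data.table(chrom = chrom, pos = pos,
                                       ref = ref, alt = alt, ...),
                pipeline_id = pipeline_id)
}

# write a small VCF from raw lines (records given as list of field vectors)
write_vcf_text <- function(path, records, header = character(0),
                           samples = character(0)) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  lines <- c("##fileformat=VCFv4.2", header, paste(cols, collapse = "\t"),
             vapply(records, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# O(n^2) all-pairs oracle for distance-to-nearest, mirroring the contract:
# nearest other call of the class on the same chrom at a distinct position
oracle_distances <- function(calls) {
  n <- nrow(calls)
  ds <- di <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || calls$chrom[j] != calls$chrom[i]) next
      if (isTRUE(calls$ambiguous[j]) || calls$pos[j] == calls$pos[i]) next
      d <- abs(calls$pos[j] - calls$pos[i])
      if (calls$var_class[j] == "SNP" && (is.na(ds[i]) || d < ds[i])) ds[i] <- d
      if (calls$var_class[j] %in% c("INS", "DEL") &&
          (is.na(di[i]) || d < di[i])) di[i] <- d
    }
  }
  data.table::data.table(dist_snp = ds, dist_indel = di)
}

# first-principles set-algebra oracle for one efficacy row
oracle_efficacy_row <- function(applicable, removed, lab, k, digits = 2) {
  fp <- which(lab == "FP")
  tp <- which(lab == "TP")
  rem_sets <- lapply(seq_len(ncol(removed)), function(j) which(removed[, j]))
  app_fp <- intersect(which(applicable[, k]), fp)
  rem_fp <- intersect(rem_sets[[k]], fp)
  others <- Reduce(union, rem_sets[-k], integer(0))
  uniq_fp <- setdiff(rem_fp, others)
  app_tp <- intersect(which(applicable[, k]), tp)
  rem_tp <- intersect(rem_sets[[k]], tp)
  pct <- function(a, b) if (length(b) == 0) NA_real_ else
    round_half_up(100 * length(a) / length(b), digits)
  list(applicable_fp = length(app_fp), removed_fp = length(rem_fp),
       removed_fp_pct = pct(rem_fp, app_fp),
       unique_fp = length(uniq_fp), unique_fp_pct = pct(uniq_fp, app_fp),
       applicable_tp = length(app_tp), removed_tp = length(rem_tp),
       removed_tp_pct = pct(rem_tp, app_tp))
}

# random labeled fixture with characteristics, for efficacy/filter oracles
random_labeled_fixture <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(50 * n, n))
  dt <- data.table::data.table(
    chrom = "chr1", pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = NA_character_,
    type = "SNP", var_class = "SNP",
    label = sample(c("TP", "FP"), n, TRUE, prob = c(0.7, 0.3)),
    qual = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0, 100)),
    qd = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 5)),
    vaf = ifelse(runif(n) < 0.1, NA_real_, runif(n, 0.3, 1)),
    depth = ifelse(runif(n) < 0.1, NA_real_, sample(1:60, n, TRUE)),
    alt_reads = sample(1:40, n, TRUE),
    dist_snp = ifelse(runif(n) < 0.1, NA_real_, sample(1:30, n, TRUE)),
    dist_indel = ifelse(runif(n) < 0.3, NA_real_, sample(1:40, n, TRUE)),
    strand_min_pct = runif(n, 0, 50),
    direction_min_pct = ifelse(runif(n) < 0.5, NA_real_, runif(n, 0, 50)),
    pipeline_id = "fix"
  )
  dt[, alt := vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")]
  dt
}

# small deterministic simulation config for fast tests
test_config <- function(seed = 7, ...) {
  simulation_config(seed = seed, contig_lengths = c(chr1 = 60000L),
                    n_snps = 150L, n_indels = 20L, ...)
}
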