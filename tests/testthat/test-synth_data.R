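test_that("generate_reference is seeded, sized, and near-uniform", {
  cfg <- simulation_config(seed = 123, contig_lengths = c(chr1 = 100000L))
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  expect_equal(nchar(r1[["chr1"]]), 100000L)
  # each base 25% within binomial sampling error (5 sigma ~ 0.68%)
  freq <- table(strsplit(r1[["chr1"]], "")[[1]]) / 100000
  expect_true(all(abs(freq - 0.25) < 0.007))
  expect_error(generate_reference(
    simulation_config(seed = 1, contig_lengths = c(chr1 = 0L))), "zero-length")
  expect_error(simulation_config(), "seed is mandatory")
})

test_that("plant_truth plants the requested variants in clean footprints", {
  cfg <- simulation_config(seed = 9, contig_lengths = c(chr1 = 50000L),
                           n_snps = 19L, n_indels = 13L,
                           ambiguous_fraction = 0)
  truth <- plant_truth(generate_reference(cfg), cfg)
  expect_equal(nrow(truth$variants), 32L)  # 19 + 13, none lost to overlap
  expect_equal(sum(truth$variants$var_class == "SNP"), 19L)
  expect_equal(sum(truth$variants$var_class %in% c("INS", "DEL")), 13L)
  # non-overlapping footprints (oracle: pairwise interval check)
  v <- truth$variants
  s <- v$pos
  e <- v$pos + nchar(v$ref) - 1L
  for (i in seq_len(nrow(v))) {
    overlaps <- sum(s <= e[i] & e >= s[i])
    expect_equal(overlaps, 1L)  # only itself
  }
  # with ambiguous_fraction 0 the confident regions cover the genome
  expect_equal(sum(GenomicRanges::width(truth$confident_regions)), 50000L)

  empty_cfg <- simulation_config(seed = 2, contig_lengths = c(chr1 = 5000L),
                                 n_snps = 0L, n_indels = 0L,
                                 ambiguous_fraction = 0)
  empty <- plant_truth(generate_reference(empty_cfg), empty_cfg)
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(sum(GenomicRanges::width(empty$confident_regions)), 5000L)

  expect_error(plant_truth(
    generate_reference(simulation_config(seed = 3, contig_lengths = c(chr1 = 100L))),
    simulation_config(seed = 3, contig_lengths = c(chr1 = 100L),
                      n_snps = 50L, n_indels = 50L)),
    "exceed")
})

test_that("truth variants always lie inside confident regions", {
  for (s in 1:3) {
    cfg <- test_config(seed = s, ambiguous_fraction = 0.05)
    truth <- plant_truth(generate_reference(cfg), cfg)
    fp <- GenomicRanges::GRanges(truth$variants$chrom,
      IRanges::IRanges(truth$variants$pos,
                       truth$variants$pos + nchar(truth$variants$ref) - 1L))
    hits <- GenomicRanges::findOverlaps(fp, truth$ambiguous_positions)
    expect_equal(length(hits), 0L)
    # partition of the genome
    expect_equal(sum(GenomicRanges::width(truth$confident_regions)) +
                   sum(GenomicRanges::width(truth$ambiguous_positions)),
                 sum(cfg$contig_lengths))
  }
})

test_that("a perfect pipeline reproduces the truth key set exactly", {
  cfg <- test_config(seed = 4)
  truth <- plant_truth(generate_reference(cfg), cfg)
  perfect <- pipeline_profile("perfect",
                              recall = c(SNP = 1, INDEL = 1),
                              fp_rate = c(SNP = 0, INDEL = 0))
  sim <- simulate_pipeline_vcf(truth, perfect, cfg, 1)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  expect_setequal(key(sim$calls), key(truth$variants))
  expect_true(all(sim$labels$label == "TP"))
})

test_that("the comparator recovers the generator's sidecar labels exactly", {
  cfg <- test_config(seed = 12)
  truth <- plant_truth(generate_reference(cfg), cfg)
  for (prof in default_pipeline_profiles()) {
    sim <- simulate_pipeline_vcf(truth, prof, cfg, 2)
    expect_equal(nrow(sim$labels), nrow(sim$calls))  # sidecar bookkeeping
    res <- compare_calls(sim$calls, truth)
    merged <- merge(res$labeled[, .(chrom, pos, ref, alt, label)],
                    sim$labels, by = c("chrom", "pos", "ref", "alt"))
    expect_equal(nrow(merged), nrow(sim$calls))
    expect_equal(merged$label.x, merged$label.y)
  }
})

test_that("data-deficient FPs look data-deficient and cluster near indels", {
  cfg <- test_config(seed = 33, fp_deficient_fraction = 1, p_near = 0.8)
  truth <- plant_truth(generate_reference(cfg), cfg)
  prof <- default_pipeline_profiles()$fullinfo
  sim <- simulate_pipeline_vcf(truth, prof, cfg, 1)
  chars <- extract_characteristics(sim$calls, prof$dialect)
  fp_idx <- which(sim$labels$fp_class == "deficient")
  expect_gt(length(fp_idx), 20L)
  # depth ~ max(1, Poisson(3)): P(depth <= 5) ~ 0.916; allow binomial noise
  expect_gt(mean(chars$depth[fp_idx] <= 5), 0.75)
  # ~80% of deficient FPs within the 10 bp window of a truth indel
  ind_pos <- truth$variants[truth$variants$var_class %in% c("INS", "DEL")]$pos
  near <- vapply(sim$labels$pos[fp_idx],
                 function(p) any(abs(ind_pos - p) <= cfg$near_window),
                 logical(1))
  expect_gt(mean(near), 0.6)
  expect_lt(mean(near), 0.97)
})

test_that("two seeds give different call sets; one seed is reproducible", {
  cfg1 <- test_config(seed = 101)
  cfg2 <- test_config(seed = 102)
  t1 <- plant_truth(generate_reference(cfg1), cfg1)
  t2 <- plant_truth(generate_reference(cfg2), cfg2)
  prof <- default_pipeline_profiles()$minimal
  s1 <- simulate_pipeline_vcf(t1, prof, cfg1, 1)
  s1b <- simulate_pipeline_vcf(t1, prof, cfg1, 1)
  s2 <- simulate_pipeline_vcf(t2, prof, cfg2, 1)
  expect_identical(as.data.frame(s1$calls), as.data.frame(s1b$calls))
  expect_false(identical(as.data.frame(s1$calls), as.data.frame(s2$calls)))
})

test_that("p_near without truth indels warns and falls back to uniform", {
  cfg <- simulation_config(seed = 8, contig_lengths = c(chr1 = 20000L),
                           n_snps = 40L, n_indels = 0L, p_near = 0.5)
  truth <- plant_truth(generate_reference(cfg), cfg)
  expect_warning(
    simulate_pipeline_vcf(truth, default_pipeline_profiles()$fullinfo, cfg, 1),
    "no indels")
})

test_that("make_fixture_suite writes a parseable, deterministic suite", {
  cfg <- simulation_config(seed = 55, contig_lengths = c(chr1 = 30000L),
                           n_snps = 60L, n_indels = 10L,
                           profiles = default_pipeline_profiles()[c("fullinfo", "gatkish")])
  dir <- withr::local_tempdir()
  paths <- make_fixture_suite(cfg, dir)
  # reference round-trips through FASTA + fai
  fasta <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(as.character(fasta[["chr1"]]), paths$objects$reference[["chr1"]])
  fai <- read_fai(paths$fai)
  expect_equal(fai, c(chr1 = 30000L))
  # truth VCF and BEDs parse and agree with the in-memory objects
  truth_calls <- parse_vcf(paths$truth_vcf)
  expect_equal(nrow(truth_calls), nrow(paths$objects$truth$variants))
  conf <- read_bed(paths$confident_bed)
  expect_equal(sum(GenomicRanges::width(conf)),
               sum(GenomicRanges::width(paths$objects$truth$confident_regions)))
  # pipeline VCFs parse; sidecar row counts match record counts
  for (pid in c("fullinfo", "gatkish")) {
    calls <- parse_vcf(paths[[paste0("vcf_", pid)]], pipeline_id = pid,
                       dialect = default_dialects()[[
                         if (pid == "fullinfo") "freebayes" else "gatk"]])
    labels <- data.table::fread(paths[[paste0("labels_", pid)]])
    expect_equal(nrow(calls), nrow(labels))
    expect_equal(nrow(calls), nrow(paths$objects$sims[[pid]]$calls))
    # characteristics extract cleanly from the written tags
    ch <- extract_characteristics(calls)
    expect_true(all(!is.na(ch$depth)))
  }
  # determinism: regenerate into a second directory and compare VCF bytes
  dir2 <- withr::local_tempdir()
  make_fixture_suite(cfg, dir2)
  expect_identical(readLines(file.path(dir, "fullinfo.vcf")),
                   readLines(file.path(dir2, "fullinfo.vcf")))
})

test_that("a written gatk-dialect VCF yields QD and AD characteristics", {
  cfg <- simulation_config(seed = 21, contig_lengths = c(chr1 = 20000L),
                           n_snps = 30L, n_indels = 5L,
                           profiles = default_pipeline_profiles()["gatkish"])
  dir <- withr::local_tempdir()
  paths <- make_fixture_suite(cfg, dir)
  calls <- parse_vcf(paths$vcf_gatkish, dialect = default_dialects()$gatk)
  ch <- extract_characteristics(calls)
  expect_true(all(!is.na(ch$qd)))
  expect_true(all(!is.na(ch$alt_reads)))
  expect_true(all(is.na(ch$strand_min_pct)))  # gatk dialect has no strand tags
})
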