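test_that("parse_vcf maps records, splits multi-allelics, flags ambiguity", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, list(
    c("chr1", 100, ".", "A", "G", 50, "PASS", "DP=20"),
    c("chr1", 200, ".", "C", "G,T", 99, "PASS", "DP=30"),
    c("chr1", 300, ".", "N", "A", 10, "PASS", "."),
    c("chr1", 400, ".", "T", "A", ".", "q10", "DP=5;AO=2"),
    c("chr1", 500, ".", "G", "C", 12, ".", ".")
  ))
  calls <- parse_vcf(path, pipeline_id = "p1")
  expect_s3_class(calls, "variant_calls")
  expect_equal(nrow(calls), 6L)  # the G,T record splits in two

  snp <- calls[calls$pos == 100L]
  expect_equal(snp$var_class, "SNP")
  expect_equal(snp$filter_status, "PASS")
  expect_equal(snp$qual, 50)
  expect_equal(snp$tags[[1]][["DP"]], "20")

  multi <- calls[calls$pos == 200L]
  expect_equal(multi$alt, c("G", "T"))
  expect_false(any(multi$biallelic_site))

  amb <- calls[calls$pos == 300L]
  expect_true(amb$ambiguous)
  expect_true(is.na(amb$var_class))

  expect_equal(calls[calls$pos == 400L]$filter_status, "non-PASS")
  expect_true(is.na(calls[calls$pos == 400L]$qual))
  expect_equal(calls[calls$pos == 500L]$filter_status, "unset")
})

test_that("parse_vcf reads FORMAT tags and errors name the bad line", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(path, list(
    c("chr1", 10, ".", "A", "T", 60, "PASS", "QD=12.5", "GT:DP:AD", "1/1:40:5,35")
  ), samples = "S1")
  calls <- parse_vcf(path)
  t <- calls$tags[[1]]
  expect_equal(t[["QD"]], "12.5")
  expect_equal(t[["FMT/DP"]], "40")
  expect_equal(t[["FMT/AD"]], "5,35")

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t50\tPASS\tDP=9",
               "chr1\tnot_a_number"), bad)
  expect_error(parse_vcf(bad), "line 4")
})

test_that("classify_variant follows the allele-shape rules", {
  expect_equal(classify_variant("A", "G"), "SNP")
  expect_equal(classify_variant("A", "ATT"), "INS")
  expect_equal(classify_variant("ATT", "A"), "DEL")
  expect_equal(classify_variant("AT", "GC"), "MNP")
  expect_equal(classify_variant("ACG", "TT"), "COMPLEX")
  expect_equal(classify_variant("AC", "TACG"), "COMPLEX")  # no prefix match
  expect_true(is.na(classify_variant("N", "A")))
  # vectorized
  expect_equal(classify_variant(c("A", "A"), c("G", "AG")), c("SNP", "INS"))
})

test_that("normalize_calls decomposes MNPs and left-aligns indels", {
  ref <- c(chr1 = "CAAATGGCTAGCATGCATGC")
  # MNP decomposition
  mnp <- make_calls("chr1", 7L, "GC", "CA")
  norm <- normalize_calls(mnp, ref)
  expect_equal(norm$pos, c(7L, 8L))
  expect_equal(norm$ref, c("G", "C"))
  expect_equal(norm$alt, c("C", "A"))
  expect_true(all(norm$mnp_derived))
  expect_equal(norm$var_class, c("SNP", "SNP"))

  # homopolymer insertion shifts to the contig-start anchor
  ins <- make_calls("chr1", 4L, "A", "AA")
  norm_ins <- normalize_calls(ins, ref)
  expect_equal(norm_ins$pos, 1L)
  expect_equal(norm_ins$ref, "C")
  expect_equal(norm_ins$alt, "CA")
  expect_equal(norm_ins$var_class, "INS")

  # already-minimal SNP unchanged
  snp <- make_calls("chr1", 6L, "G", "T")
  expect_equal(as.data.frame(normalize_calls(snp, ref)[, .(pos, ref, alt)]),
               data.frame(pos = 6L, ref = "G", alt = "T"))

  # REF disagreement is a consistency error
  expect_error(normalize_calls(make_calls("chr1", 6L, "A", "T"), ref),
               "disagrees")
})

test_that("normalize_calls is idempotent on random indels", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  ref <- c(chr1 = paste(sample(bases, 500, TRUE), collapse = ""))
  rows <- lapply(1:40, function(i) {
    pos <- sample(20:480, 1)
    w <- sample(1:6, 1)
    if (runif(1) < 0.5) {
      data.table::data.table(chrom = "chr1", pos = pos,
                             ref = substr(ref, pos, pos + w),
                             alt = substr(ref, pos, pos))
    } else {
      data.table::data.table(chrom = "chr1", pos = pos,
                             ref = substr(ref, pos, pos),
                             alt = paste0(substr(ref, pos, pos),
                                          paste(sample(bases, w, TRUE), collapse = "")))
    }
  })
  calls <- variant_calls(data.table::rbindlist(rows))
  calls <- calls[ref != alt]
  once <- normalize_calls(calls, ref)
  twice <- normalize_calls(once, ref)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("extract_characteristics computes the nine statistics per dialect", {
  d <- default_dialects()$freebayes
  calls <- make_calls("chr1", c(100L, 103L, 150L),
                      c("A", "C", "G"), c("G", "T", "GTT"),
                      qual = c(300, 40, 25))
  calls$tags <- list(
    c(DP = "50", AO = "48", SAF = "1", SAR = "19", RPL = "10", RPR = "38"),
    c(DP = "20", AO = "20", SAF = "10", SAR = "10", RPL = "0", RPR = "20"),
    c(DP = "8", AO = "6", SAF = "3", SAR = "3", RPL = "3", RPR = "3")
  )
  ch <- extract_characteristics(calls, d)
  expect_equal(ch$vaf[1], 48 / 50)
  expect_equal(ch$strand_min_pct[1], 5)           # min(1,19)/20
  expect_equal(ch$direction_min_pct[2], 0)        # 0 of 20 upstream
  expect_equal(ch$qd[1], 300 / 48)                # fallback qual/alt_reads
  expect_equal(ch$qd_source[1], "fallback")
  expect_equal(ch$dist_snp[1], 3)                 # SNP at 103
  expect_equal(ch$dist_indel[1], 50)              # indel at 150
  expect_equal(ch$depth, c(50, 20, 8))

  # dialect without strand tags: unavailable, never zero
  ch_min <- extract_characteristics(calls, default_dialects()$minimal)
  expect_true(all(is.na(ch_min$strand_min_pct)))
  expect_true(all(is.na(ch_min$alt_reads)))
  expect_equal(ch_min$depth, c(50, 20, 8))  # depth still mapped

  # QD-style tag takes precedence over the fallback
  gat <- make_calls("chr1", 10L, "A", "G", qual = 300)
  gat$tags <- list(c(QD = "2.5", `FMT/DP` = "40", `FMT/AD` = "10,30"))
  chg <- extract_characteristics(gat, default_dialects()$gatk)
  expect_equal(chg$qd, 2.5)
  expect_equal(chg$qd_source, "tag")
  expect_equal(chg$alt_reads, 30)
  expect_equal(chg$vaf, 0.75)
})

test_that("characteristic availability is monotone in dialect richness", {
  calls <- make_calls("chr1", c(5L, 9L), c("A", "T"), c("G", "C"),
                      qual = c(10, 20))
  calls$tags <- list(c(DP = "30", AO = "15", SAF = "7", SAR = "8"),
                     c(DP = "12", AO = "6", SAF = "1", SAR = "5"))
  poor <- tag_dialect("poor", depth = "DP")
  rich <- tag_dialect("rich", depth = "DP", alt_reads = "AO",
                      alt_fwd = "SAF", alt_rev = "SAR")
  ch_poor <- extract_characteristics(calls, poor)
  ch_rich <- extract_characteristics(calls, rich)
  for (col in characteristic_names()) {
    expect_true(all(is.na(ch_poor[[col]]) | !is.na(ch_rich[[col]])),
                info = col)
  }
})

test_that("strand shares conserve to 100 percent", {
  set.seed(3)
  f <- sample(0:50, 50, TRUE)
  r <- sample(1:50, 50, TRUE)
  minp <- 100 * pmin(f, r) / (f + r)
  maxp <- 100 * pmax(f, r) / (f + r)
  expect_equal(minp + maxp, rep(100, 50))
  expect_true(all(minp <= 50))
})

test_that("depth zero with alt reads is a tag inconsistency", {
  calls <- make_calls("chr1", 5L, "A", "G", qual = 10)
  calls$tags <- list(c(DP = "0", AO = "3"))
  expect_error(extract_characteristics(calls, default_dialects()$freebayes),
               "inconsistency")
})

test_that("distances_to_nearest matches the spec examples and the brute force", {
  calls <- make_calls("chr1", c(100L, 103L, 150L),
                      c("A", "C", "G"), c("G", "T", "GTT"))
  d <- distances_to_nearest(calls)
  expect_equal(d$dist_snp, c(3, 3, 47))
  expect_equal(d$dist_indel, c(50, 47, NA))

  lone <- make_calls("chr1", 42L, "A", "G")
  expect_true(all(is.na(distances_to_nearest(lone))))

  expect_error(
    distances_to_nearest(structure(
      data.table::data.table(chrom = "chr1", pos = c(5L, 2L),
                             ref = "A", alt = "G", ambiguous = FALSE,
                             var_class = "SNP"),
      class = c("variant_calls", "data.table", "data.frame"))),
    "sorted")

  # 100 random calls across two contigs vs the O(n^2) oracle
  set.seed(99)
  rnd <- variant_calls(data.table::data.table(
    chrom = sample(c("chr1", "chr2"), 100, TRUE),
    pos = sample.int(2000, 100),
    ref = "A",
    alt = sample(c("G", "AGG", "T"), 100, TRUE)
  ))
  rnd <- unique(rnd, by = c("chrom", "pos"))
  got <- distances_to_nearest(rnd)
  expect_equal(as.data.frame(got), as.data.frame(oracle_distances(rnd)))
})

test_that("nearest-SNP distances are symmetric bounds", {
  set.seed(5)
  calls <- variant_calls(data.table::data.table(
    chrom = "chr1", pos = sample.int(5000, 80), ref = "C", alt = "T"))
  calls <- unique(calls, by = "pos")
  d <- distances_to_nearest(calls)$dist_snp
  # if A's nearest SNP is B at distance d, B's nearest-SNP distance <= d
  for (i in seq_len(nrow(calls))) {
    j <- which(abs(calls$pos - calls$pos[i]) == d[i] & seq_len(nrow(calls)) != i)
    expect_true(all(d[j] <= d[i]))
  }
})

test_that("variant_calls validates its invariants", {
  expect_error(make_calls("chr1", 0L, "A", "G"), "pos >= 1")
  expect_error(make_calls("chr1", 5L, "A", "A"), "ref != alt")
  expect_error(make_calls("chr1", 5L, "", "A"))
})
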