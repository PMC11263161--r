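# Signature extraction from CIGAR runs, split alignments and BAM records.

test_that("CIGAR deletion runs become DEL signatures at the right span", {
  # 100M 200D 100M mapped at 0-based 1000: the D run spans [1100, 1300)
  s <- extract_cigar_signatures("chr1", 1001, "100M200D100M", "r1", 1L,
                                min_sv_size = 30)
  expect_equal(nrow(s), 1L)
  expect_equal(s$sv_type, "DEL")
  expect_equal(s$left, 1100)
  expect_equal(s$right, 1300)
  expect_equal(s$length, 200)
  expect_equal(s$haplotype, 1L)
  expect_equal(s$source, "cigar")
})

test_that("sub-threshold runs yield nothing", {
  s <- extract_cigar_signatures("chr1", 1001, "100M10D100M", "r1", 0L,
                                min_sv_size = 30)
  expect_equal(nrow(s), 0L)
})

test_that("nearby same-type runs chain into one signature with summed length", {
  # D runs at [50,90) and [110,150) relative to start; gap 20 < merge_gap
  s <- extract_cigar_signatures("chr1", 1, "50M40D20M40D50M", "r1", 2L,
                                min_sv_size = 30, merge_gap = 100)
  expect_equal(nrow(s), 1L)
  expect_equal(s$length, 80)
  expect_equal(s$left, 50)
  expect_equal(s$right, s$left + s$length)  # DEL span always equals length
  # with a gap threshold below the 20 bp separation the runs stay apart
  s2 <- extract_cigar_signatures("chr1", 1, "50M40D20M40D50M", "r1", 2L,
                                 min_sv_size = 30, merge_gap = 20)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$length, c(40, 40))
})

test_that("insertion runs anchor at a point and chain too", {
  s <- extract_cigar_signatures("chr1", 1, "100M60I40M", "r1", 0L)
  expect_equal(s$sv_type, "INS")
  expect_equal(s$left, 100)
  expect_equal(s$right, 100)
  expect_equal(s$length, 60)
  # two 20 bp I runs 30 bp apart chain to a 40 bp insertion
  s2 <- extract_cigar_signatures("chr1", 1, "100M20I30M20I40M", "r1", 0L,
                                 min_sv_size = 30, merge_gap = 100)
  expect_equal(s2$sv_type, "INS")
  expect_equal(s2$length, 40)
  expect_equal(s2$left, 100)
})

test_that("no signature below min_sv_size is ever emitted", {
  cigars <- c("10M40D10M5I10M", "30M31D5M29D30M", "50M29I50M", "100M")
  for (ms in c(30, 50, 100)) {
    for (cg in cigars) {
      s <- extract_cigar_signatures("chr1", 1, cg, "r", 0L, min_sv_size = ms)
      if (nrow(s)) expect_true(all(s$length >= ms))
      validate_signatures(s)
    }
  }
})

test_that("split segments with a reference gap give a DEL breakpoint", {
  alns <- data.frame(
    qname = "r1", flag = c(0L, 2048L), chrom = "chr1",
    pos = c(1, 2001), strand = "+",
    cigar = c("1000M2000S", "1000S1000M1000S"),
    haplotype = 1L, is_supplementary = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  s <- extract_split_signatures(alns, min_sv_size = 30)
  expect_equal(nrow(s), 1L)
  expect_equal(s$sv_type, "DEL")
  expect_equal(s$left, 1000)
  expect_equal(s$right, 2000)
  expect_equal(s$length, 1000)
  expect_equal(s$haplotype, 1L)
  expect_equal(s$source, "split")
})

test_that("opposite-strand adjacency gives an INV over the minus segment", {
  alns <- data.frame(
    qname = "r1", flag = c(0L, 2064L), chrom = "chr1",
    pos = c(4001, 5001), strand = c("+", "-"),
    cigar = c("1000M1000S", "1000M1000S"),
    haplotype = 2L, is_supplementary = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  s <- extract_split_signatures(alns, min_sv_size = 30)
  expect_equal(s$sv_type, "INV")
  expect_equal(s$left, 5000)
  expect_equal(s$right, 6000)
  expect_equal(s$length, 1000)
})

test_that("a backward reference jump gives a DUP over the overlap", {
  # read: ref [0,500) then jumps back to 300 -> overlap [300,500)
  alns <- data.frame(
    qname = "r1", flag = c(0L, 2048L), chrom = "chr1",
    pos = c(1, 301), strand = "+",
    cigar = c("500M500S", "500S500M"),
    haplotype = 0L, is_supplementary = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  s <- extract_split_signatures(alns, min_sv_size = 30)
  expect_equal(s$sv_type, "DUP")
  expect_equal(s$left, 300)
  expect_equal(s$right, 500)
  expect_equal(s$length, 200)
})

test_that("a lone primary alignment yields no split signatures", {
  alns <- data.frame(qname = "r1", flag = 0L, chrom = "chr1", pos = 1,
                     strand = "+", cigar = "1000M", haplotype = 0L,
                     is_supplementary = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(extract_split_signatures(alns)), 0L)
})

test_that("BAM loading honors HP tags, skips secondaries, measures coverage", {
  rec <- data.frame(
    qname = c("a", "b", "c", "d", "e"),
    flag = c(0L, 0L, 256L, 0L, 0L),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(1L, 101L, 201L, 1L, 5001L),
    cigar = c("1000M", "500M", "500M", "5000M", "5000M"),
    tags = c("HP:i:1", "", "HP:i:2", "HP:i:2", "HP:i:1"),
    stringsAsFactors = FALSE)
  bam <- write_test_bam(rec, c(chr1 = 10000L, chr2 = 10000L))
  alns <- load_tagged_alignments(bam)
  expect_false("c" %in% alns$qname)        # secondary dropped
  expect_equal(alns$haplotype[alns$qname == "a"], 1L)
  expect_equal(alns$haplotype[alns$qname == "b"], 0L)  # untagged convention
  expect_equal(alns$haplotype[alns$qname == "d"], 2L)
  # coverage: chr1 has 1000+500 aligned bp over 10 kb; chr2 two 5 kb reads
  expect_equal(chromosome_coverage(bam, "chr1")$cov, 0.15)
  expect_equal(chromosome_coverage(bam, "chr2")$cov, 1.0)
  expect_error(chromosome_coverage(bam, "chrX"), "not in BAM header")
  # region restriction
  expect_equal(sort(unique(load_tagged_alignments(bam, "chr2")$qname)),
               c("d", "e"))
})

test_that("an HP tag outside {1,2} is treated as untagged with a warning", {
  rec <- data.frame(qname = "a", flag = 0L, chrom = "chr1", pos = 1L,
                    cigar = "100M", tags = "HP:i:3", stringsAsFactors = FALSE)
  bam <- write_test_bam(rec, c(chr1 = 1000L))
  expect_warning(alns <- load_tagged_alignments(bam), "outside")
  expect_equal(alns$haplotype, 0L)
})

test_that("empty chromosome has zero coverage and a missing BAM is fatal", {
  rec <- data.frame(qname = "a", flag = 0L, chrom = "chr1", pos = 1L,
                    cigar = "100M", tags = "", stringsAsFactors = FALSE)
  bam <- write_test_bam(rec, c(chr1 = 1000L, chr2 = 1000L))
  expect_equal(chromosome_coverage(bam, "chr2")$cov, 0)
  expect_error(load_tagged_alignments("/nonexistent.bam"), "not found")
})

test_that("extraction is independent of record order", {
  rec <- data.frame(
    qname = c("a", "b"), flag = 0L, chrom = "chr1", pos = c(1L, 51L),
    cigar = c("100M60D100M", "100M80D100M"),
    tags = c("HP:i:1", "HP:i:2"), stringsAsFactors = FALSE)
  b1 <- write_test_bam(rec, c(chr1 = 1000L))
  b2 <- write_test_bam(rec[2:1, ], c(chr1 = 1000L))
  s1 <- extract_signatures(b1)
  s2 <- extract_signatures(b2)
  key <- function(s) s[order(s$read_id), ]
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)
})
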