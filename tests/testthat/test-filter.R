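# Scoring, haplotype-quality-scaled filtering, genotyping and refinement.

mk_cluster <- function(lens, haps, lefts = NULL, type = "DEL",
                       reads = sprintf("r%02d", seq_along(lens))) {
  if (is.null(lefts)) lefts <- rep(1000, length(lens))
  do.call(rbind, Map(function(l, h, p, r) sig_row(p, l, sv_type = type,
                                                  hap = h, read = r),
                     lens, haps, lefts, reads))
}

test_that("consistent score is 1 - popSD/max", {
  expect_equal(consistent_score(c(100, 100, 100)), 1.0)
  expect_equal(consistent_score(c(80, 120)), 1 - 20 / 120)
  expect_equal(consistent_score(150), 1.0)
  cl <- mk_cluster(c(80, 120), c(1L, 2L))
  expect_equal(consistent_score(cl), 1 - 20 / 120)
})

test_that("haplotype scale follows its three branches", {
  fp <- filter_params(H0 = 0.8, HR0 = 0.8, HomoSF = 0.1, HomoSR = 0.5,
                      NonHomoSF = 0.2, NonHomoSR = 0.5,
                      LowHRF = 0.1, LowHRR = 0.5)
  st <- function(N, M, H1, H2) list(N = N, M = M, H1 = H1, H2 = H2)
  # (a) fully tagged, one haplotype: relaxed
  expect_equal(haplotype_scale(st(10, 10, 10, 0), fp), 1 - (0.1 + 0.5 * 0.2))
  # (b) fully tagged, mixed haplotypes: the NonHomo parameters apply
  expect_equal(haplotype_scale(st(10, 10, 5, 5), fp), 1 - (0.2 + 0.5 * 0.2))
  # (c) untagged: tightened
  expect_equal(haplotype_scale(st(10, 0, 0, 0), fp), 1 + (0.1 + 0.5 * 0.8))
  # H == H0 exactly falls in the low-tagging branch
  expect_equal(haplotype_scale(st(10, 8, 8, 0), fp), 1 + 0.1)
  # neutral parameters give SC = 1 in every branch
  neutral <- filter_params(HomoSF = 0, HomoSR = 0, NonHomoSF = 0,
                           NonHomoSR = 0, LowHRF = 0, LowHRR = 0)
  for (s in list(st(10, 10, 10, 0), st(10, 10, 5, 5), st(10, 0, 0, 0),
                 st(4, 3, 2, 1)))
    expect_equal(haplotype_scale(s, neutral), 1.0)
})

test_that("scale is affine and non-increasing in H within the homozygous branch", {
  fp <- filter_params(HomoSF = 0.05, HomoSR = 0.25)
  H <- seq(0.82, 1, by = 0.02)
  sc <- vapply(H, function(h) {
    m <- round(h * 100)
    haplotype_scale(list(N = 100L, M = m, H1 = m, H2 = 0L), fp)
  }, numeric(1))
  expect_true(all(diff(sc) <= 1e-12))
  slopes <- diff(sc) / diff(round(H * 100) / 100)
  expect_true(all(abs(slopes - (-fp$HomoSR)) < 1e-9))
})

test_that("support and score thresholds combine as specified", {
  neutral <- filter_params(set_a = list(FF = 2, FR = 0.2, FS = 0.55),
                           set_b = list(FF = 2, FR = 0.2, FS = 0.55),
                           HomoSF = 0, HomoSR = 0, NonHomoSF = 0,
                           NonHomoSR = 0, LowHRF = 0, LowHRR = 0)
  # support 10 >= 2 + 0.2*20 = 6, identical lengths: pass
  cl <- mk_cluster(rep(100, 10), rep(0L, 10))
  expect_true(apply_filter(cl, 20, neutral)$passed)
  # support 3 < 6 under both sets: fail
  cl3 <- mk_cluster(rep(100, 3), rep(0L, 3))
  expect_false(apply_filter(cl3, 20, neutral)$passed)
  # SC = 0.8 lowers the threshold 6 to 4.8; support 5 passes
  relax <- filter_params(set_a = list(FF = 2, FR = 0.2, FS = 0.55),
                         set_b = list(FF = 2, FR = 0.2, FS = 0.55),
                         H0 = 0.8, HR0 = 0.8, HomoSF = 0.1, HomoSR = 0.5,
                         LowHRF = 0, LowHRR = 0)
  cl5 <- mk_cluster(rep(100, 5), rep(1L, 5))  # H = 1, HR = 1 -> SC = 0.8
  res <- apply_filter(cl5, 20, relax)
  expect_equal(res$sc, 0.8)
  expect_true(res$passed)
  expect_false(apply_filter(cl5, 20, neutral)$passed)  # SC = 1 needs 6
})

test_that("a cluster passing one set passes overall, and SC*FS is clamped", {
  fp <- filter_params(set_a = list(FF = 100, FR = 1, FS = 0.99),
                      set_b = list(FF = 1, FR = 0, FS = 0.75),
                      HomoSF = 0, HomoSR = 0, NonHomoSF = 0, NonHomoSR = 0,
                      LowHRF = 0.2, LowHRR = 0.5)
  cl <- mk_cluster(rep(100, 4), rep(0L, 4))   # untagged: SC = 1.6
  res <- apply_filter(cl, 2, fp)
  # set b: support 4 >= 1.6 * 1, score 1 >= min(1, 1.6 * 0.75) = 1
  expect_true(res$passed)
  expect_equal(res$set_id, "b")
})

test_that("passing is monotone in support", {
  fp <- filter_params()
  passes <- vapply(2:12, function(n)
    apply_filter(mk_cluster(rep(100, n), rep(0L, n)), 20, fp)$passed,
    logical(1))
  expect_true(all(diff(passes) >= 0))  # once passing, stays passing
})

test_that("genotyping follows haplotype counts, then allele fraction", {
  fp <- filter_params(H0 = 0.8)
  both <- mk_cluster(rep(100, 20), c(rep(1L, 10), rep(2L, 9), 0L))
  expect_equal(genotype_call(both, 20, fp), "1/1")
  one <- mk_cluster(rep(100, 10), rep(1L, 10))
  expect_equal(genotype_call(one, 20, fp), "0/1")
  untagged <- mk_cluster(rep(100, 10), rep(0L, 10))
  expect_equal(genotype_call(untagged, 20, fp), "0/1")   # 10/20 = 0.5
  expect_equal(genotype_call(untagged, 12, fp), "1/1")   # 10/12 >= 0.75
  expect_equal(genotype_call(untagged, 100, fp), "./.")  # 0.1 < 0.2
  # allele-fraction mode ignores the tags
  expect_equal(genotype_call(one, 20, fp, mode = "allele_fraction"), "0/1")
  # cov 0: only the haplotype rule can decide
  expect_equal(genotype_call(one, 0, fp), "0/1")
  expect_equal(genotype_call(untagged, 0, fp), "./.")
})

test_that("refinement takes rounded means with half-away-from-zero ties", {
  cl <- mk_cluster(c(100, 102), c(1L, 1L), lefts = c(1000, 1002))
  call <- refine_call(cl)
  expect_equal(call$pos, 1002)      # mean 1001 (0-based) -> 1002 1-based
  expect_equal(call$svlen, -101)
  expect_equal(call$end, 1103)
  # mean length 100.5 rounds to 101, not round-half-even's 100
  cl2 <- mk_cluster(c(100, 101), c(1L, 1L))
  expect_equal(abs(refine_call(cl2)$svlen), 101)
  ins <- sig_row(500, 300, sv_type = "INS", hap = 0L, read = "a")
  call3 <- refine_call(ins)
  expect_equal(call3$pos, 501)
  expect_equal(call3$svlen, 300)
  expect_equal(call3$end, 501)
})

test_that("VCF output round-trips and enforces sorted input", {
  calls <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(1002, 5000),
    sv_type = c("DEL", "INS"), svlen = c(-101, 250), end = c(1103, 5000),
    support = c(12L, 8L), gt = c("0/1", "1/1"),
    hap_f = c(0.95, 0.5), hap_maj = c(1, 0.6), hap_sc = c(0.92, 1.1),
    stringsAsFactors = FALSE)
  contigs <- data.frame(name = "chr1", length = 10000L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls, vcf, contigs)
  back <- read_sv_vcf(vcf)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$sv_type, calls$sv_type)
  expect_equal(back$svlen, calls$svlen)
  expect_equal(back$end, calls$end)
  expect_equal(back$support, calls$support)
  expect_equal(back$gt, calls$gt)
  expect_equal(back$hap_f, calls$hap_f, tolerance = 1e-4)
  # empty call set: valid header-only VCF
  vcf0 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls[0, ], vcf0, contigs)
  expect_equal(nrow(read_sv_vcf(vcf0)), 0L)
  # out-of-order calls error before writing
  expect_error(write_sv_vcf(calls[2:1, ], vcf, contigs), "sorted")
  # unknown contig errors
  bad <- calls; bad$chrom <- "chrZ"
  expect_error(write_sv_vcf(bad, vcf, contigs), "contig")
})

test_that("REF bases come from the reference when supplied", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  calls <- data.frame(chrom = "chr1", pos = 3, sv_type = "DEL", svlen = -60,
                      end = 63, support = 5L, gt = "0/1",
                      stringsAsFactors = FALSE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls, vcf, data.frame(name = "chr1", length = 10L),
               reference = ref, hap_annotations = FALSE)
  rec <- strsplit(vcf_body(vcf), "\t")[[1]]
  expect_equal(rec[4], "G")
  expect_equal(rec[5], "<DEL>")
})
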