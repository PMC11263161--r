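# Self-contained synthetic diploid data: a random reference, planted SVs with
# haplotype assignment, and a haplotype-tagged BAM of constructed alignments.
# Alignments are written directly (no read simulator or aligner involved):
# a read spanning a planted SV carries it as the corresponding CIGAR run or
# split-alignment pair, which is exactly the evidence the caller consumes.

#' Simulation configuration
#'
#' @param genome_length total genome size in bp (split evenly over
#'   `n_chroms`).
#' @param n_chroms number of chromosomes.
#' @param counts named integer vector of planted SVs per type
#'   (DEL/INS/DUP/INV).
#' @param size_range named list of c(min, max) SV sizes per type (bp,
#'   >= 50).
#' @param het_fraction fraction of SVs that are heterozygous (haplotype drawn
#'   uniformly); the remainder are homozygous.
#' @param depth total fold coverage (split evenly over the two haplotypes).
#' @param read_length read length in bp (constant).
#' @param pos_jitter_sd per-read SD of the SV position in its alignment (bp).
#' @param len_jitter_sd per-read SD of the SV length in its alignment (bp).
#' @param tag_rate probability that a read carries an HP tag.
#' @param mistag_rate probability that a tagged read is tagged with the wrong
#'   haplotype.
#' @param flank minimum alignment anchor on each side of a represented SV
#'   (bp).
#' @param spacing minimum gap between planted SVs (bp); the default of one
#'   read length guarantees a read overlaps at most one SV and satisfies the
#'   jitter/merge-window separation requirement.
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @return a list with class `hapsv_sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_chroms = 1,
                       counts = c(DEL = 10, INS = 10, DUP = 10, INV = 10),
                       size_range = list(DEL = c(60, 400), INS = c(60, 400),
                                         DUP = c(60, 400), INV = c(60, 400)),
                       het_fraction = 0.5, depth = 20, read_length = 10000,
                       pos_jitter_sd = 0, len_jitter_sd = 0,
                       tag_rate = 1, mistag_rate = 0,
                       flank = 200, spacing = read_length, seed = 1) {
  stopifnot(genome_length >= 1, n_chroms >= 1,
            all(names(counts) %in% SV_TYPES), all(counts >= 0),
            het_fraction >= 0, het_fraction <= 1, depth > 0,
            read_length >= 200, pos_jitter_sd >= 0, len_jitter_sd >= 0,
            tag_rate >= 0, tag_rate <= 1, mistag_rate >= 0, mistag_rate <= 1,
            flank >= 0, spacing >= 0)
  for (t in names(counts)) {
    r <- size_range[[t]]
    if (is.null(r) || length(r) != 2L || r[1] < 50 || r[2] < r[1])
      stop("size_range for ", t, " must be c(min, max) with min >= 50",
           call. = FALSE)
  }
  structure(list(genome_length = genome_length, n_chroms = n_chroms,
                 counts = counts, size_range = size_range,
                 het_fraction = het_fraction, depth = depth,
                 read_length = read_length, pos_jitter_sd = pos_jitter_sd,
                 len_jitter_sd = len_jitter_sd, tag_rate = tag_rate,
                 mistag_rate = mistag_rate, flank = flank, spacing = spacing,
                 seed = seed),
            class = "hapsv_sim_config")
}

#' Simulate a reference and planted SV truth set
#'
#' Draws a random nucleotide reference and places the configured SVs with at
#' least `spacing` bp between any two (so same-haplotype variants never
#' overlap and, at the default spacing, no read spans two variants).
#' Heterozygous SVs are assigned haplotype 1 or 2 uniformly.
#'
#' @param config a [sim_config()] object.
#' @return list: `reference` (`DNAStringSet`), `truth` (data.frame with
#'   chrom, pos (1-based), sv_type, svlen (signed, negative DEL), gt
#'   ("0/1"/"1/1"), hap (1/2 for het, NA for hom)).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "hapsv_sim_config"))
  set.seed(config$seed)
  chrom_len <- config$genome_length %/% config$n_chroms
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  reference <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""), character(1)))
  names(reference) <- chroms
  types <- rep(names(config$counts), config$counts)
  n <- length(types)
  if (n == 0L)
    return(list(reference = reference,
                truth = data.frame(chrom = character(), pos = numeric(),
                                   sv_type = character(), svlen = numeric(),
                                   gt = character(), hap = integer(),
                                   stringsAsFactors = FALSE)))
  types <- sample(types)
  sizes <- vapply(types, function(t) {
    r <- config$size_range[[t]]
    sample(seq(r[1], r[2]), 1L)
  }, numeric(1))
  chrom_of <- chroms[rep_len(seq_len(config$n_chroms), n)]
  rows <- list()
  for (ci in seq_len(config$n_chroms)) {
    idx <- which(chrom_of == chroms[ci])
    if (!length(idx)) next
    need <- sum(sizes[idx]) + (length(idx) + 1) * config$spacing
    if (need > chrom_len)
      stop("genome too small for requested SVs: chromosome ", chroms[ci],
           " needs ", need, " bp but has ", chrom_len, call. = FALSE)
    slack <- chrom_len - need
    cuts <- sort(stats::runif(length(idx), 0, slack))
    extra <- diff(c(0, cuts))
    pos0 <- numeric(length(idx))
    cur <- 0
    for (k in seq_along(idx)) {
      cur <- cur + config$spacing + extra[k]
      pos0[k] <- floor(cur)
      cur <- cur + sizes[idx[k]]
    }
    het <- stats::runif(length(idx)) < config$het_fraction
    hap <- ifelse(het, sample(1:2, length(idx), replace = TRUE), NA_integer_)
    rows[[ci]] <- data.frame(
      chrom = chroms[ci], pos = pos0 + 1,
      sv_type = types[idx],
      svlen = ifelse(types[idx] == "DEL", -sizes[idx], sizes[idx]),
      gt = ifelse(het, "0/1", "1/1"), hap = hap,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(reference = reference, truth = truth)
}

# one read's SAM rows: represents at most one SV (guaranteed by spacing)
.read_rows <- function(qname, chrom, chrom_len, start, L, sv, config, hp_str) {
  plain <- function() data.frame(
    qname = qname, flag = 0L, chrom = chrom, pos = start + 1,
    cigar = sprintf("%dM", L), tags = hp_str, stringsAsFactors = FALSE)
  if (is.null(sv)) return(plain())
  s0 <- sv$pos - 1
  len <- abs(sv$svlen)
  jp <- round(stats::rnorm(1, 0, config$pos_jitter_sd))
  jl <- round(stats::rnorm(1, 0, config$len_jitter_sd))
  s0 <- s0 + jp
  len <- len + jl
  fl <- config$flank
  ok <- len >= 1 && s0 >= start + fl && s0 + len <= start + L - fl
  if (!ok) return(plain())
  a <- s0 - start
  if (sv$sv_type == "DEL") {
    if (start + L + len > chrom_len) return(plain())
    return(data.frame(qname = qname, flag = 0L, chrom = chrom, pos = start + 1,
                      cigar = sprintf("%dM%dD%dM", a, len, L - a),
                      tags = hp_str, stringsAsFactors = FALSE))
  }
  if (sv$sv_type == "INS") {
    if (a + len > L - fl) return(plain())
    return(data.frame(qname = qname, flag = 0L, chrom = chrom, pos = start + 1,
                      cigar = sprintf("%dM%dI%dM", a, len, L - a - len),
                      tags = hp_str, stringsAsFactors = FALSE))
  }
  if (sv$sv_type == "INV") {
    # primary: left flank on +; supplementary: the inverted interval on -
    return(data.frame(
      qname = qname, flag = c(0L, 2064L), chrom = chrom,
      pos = c(start + 1, s0 + 1),
      cigar = c(sprintf("%dM%dS", a, L - a),
                sprintf("%dS%dM%dS", L - a - len, len, a)),
      tags = hp_str, stringsAsFactors = FALSE))
  }
  # DUP (tandem): first copy ends the primary segment; the supplementary
  # segment jumps back to the duplication start (reference overlap = len)
  w1 <- a + len
  return(data.frame(
    qname = qname, flag = c(0L, 2048L), chrom = chrom,
    pos = c(start + 1, s0 + 1),
    cigar = c(sprintf("%dM%dS", w1, L - w1),
              sprintf("%dS%dM", w1, L - w1)),
    tags = hp_str, stringsAsFactors = FALSE))
}

#' Simulate a haplotype-tagged BAM of constructed alignments
#'
#' Samples reads uniformly per haplotype to depth/2 each. A read spanning a
#' planted SV (with at least `flank` bp anchor on both sides) carries it in
#' its alignment: DEL as a D CIGAR run, INS as an I run, INV as a
#' primary/supplementary pair on opposite strands, DUP as a split pair with a
#' backward reference jump. Per-read position and length jitter are
#' Normal(0, sd), rounded. Each read is HP-tagged with its haplotype of
#' origin with probability `tag_rate`; a tagged read gets the wrong haplotype
#' with probability `mistag_rate`. Output is coordinate-sorted and indexed.
#'
#' @param reference `DNAStringSet` from [simulate_truth()].
#' @param truth truth data.frame from [simulate_truth()].
#' @param config a [sim_config()] object.
#' @param out_prefix output path prefix; `<out_prefix>.bam` (+ `.bai`) is
#'   created.
#' @param drop_tags write no HP tags regardless of `tag_rate` (used to
#'   compare against a haplotype-unaware run on identical alignments).
#' @return path to the BAM file.
#' @export
simulate_tagged_bam <- function(reference, truth, config, out_prefix,
                                drop_tags = FALSE) {
  stopifnot(inherits(config, "hapsv_sim_config"))
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  L <- config$read_length
  rows <- list()
  for (chrom in names(reference)) {
    chrom_len <- Biostrings::width(reference[names(reference) == chrom])
    tchr <- truth[truth$chrom == chrom, , drop = FALSE]
    for (h in 1:2) {
      on_h <- tchr[tchr$gt == "1/1" | (!is.na(tchr$hap) & tchr$hap == h), ,
                   drop = FALSE]
      n_reads <- ceiling(config$depth / 2 * chrom_len / L)
      starts <- sample.int(chrom_len - L + 1L, n_reads, replace = TRUE) - 1L
      for (ri in seq_len(n_reads)) {
        start <- starts[ri]
        qname <- sprintf("r%s_h%d_%06d", sub("^chr", "", chrom), h, ri)
        # spacing >= read_length: at most one SV can be fully inside
        inside <- which(on_h$pos - 1 >= start + config$flank &
                        on_h$pos - 1 + abs(on_h$svlen) * (on_h$sv_type != "INS") <=
                          start + L - config$flank)
        sv <- if (length(inside)) on_h[inside[1], ] else NULL
        # the RNG stream must not depend on drop_tags, so that the tagged
        # and tag-stripped BAMs hold byte-identical alignments
        hp <- NA_integer_
        if (stats::runif(1) < config$tag_rate) {
          hp <- if (stats::runif(1) < config$mistag_rate) 3L - h else h
        }
        if (drop_tags) hp <- NA_integer_
        hp_str <- if (is.na(hp)) "" else sprintf("\tHP:i:%d", hp)
        rows[[length(rows) + 1L]] <-
          .read_rows(qname, chrom, chrom_len, start, L, sv, config, hp_str)
      }
    }
  }
  alns <- do.call(rbind, rows)
  alns <- alns[order(match(alns$chrom, names(reference)), alns$pos), ,
               drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
                 alns$qname, alns$flag, alns$chrom, alns$pos, alns$cigar,
                 alns$tags)
  sam <- paste0(out_prefix, ".sam")
  con <- file(sam, "wb")
  writeLines(c(hdr, rec), con, sep = "\n")
  close(con)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Write the planted truth set as a VCF
#'
#' VCF 4.2 with SVTYPE/SVLEN/END INFO and a GT column distinguishing 0/1 from
#' 1/1, parseable by the benchmarking engine.
#'
#' @param truth truth data.frame from [simulate_truth()] (sorted).
#' @param out_path output path.
#' @param contigs data.frame with columns name, length.
#' @param reference optional `DNAStringSet` for REF bases.
#' @return `out_path`, invisibly.
#' @export
write_truth_vcf <- function(truth, out_path, contigs, reference = NULL) {
  calls <- data.frame(chrom = truth$chrom, pos = truth$pos,
                      sv_type = truth$sv_type, svlen = truth$svlen,
                      end = ifelse(truth$sv_type == "INS", truth$pos,
                                   truth$pos + abs(truth$svlen)),
                      support = rep(0L, nrow(truth)), gt = truth$gt,
                      stringsAsFactors = FALSE)
  write_sv_vcf(calls, out_path, contigs, reference = reference,
               hap_annotations = FALSE, sample = "TRUTH")
}

#' Simulate a complete dataset on disk
#'
#' Convenience wrapper: reference FASTA, haplotype-tagged BAM (+ index) and
#' truth VCF in `out_dir`.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @return list of paths (`fasta`, `bam`, `truth_vcf`) plus the truth
#'   data.frame.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_truth(config)
  fasta <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, fasta)
  bam <- simulate_tagged_bam(sim$reference, sim$truth, config,
                             file.path(out_dir, "reads"))
  contigs <- data.frame(name = names(sim$reference),
                        length = Biostrings::width(sim$reference),
                        stringsAsFactors = FALSE)
  truth_vcf <- file.path(out_dir, "truth.vcf")
  write_truth_vcf(sim$truth, truth_vcf, contigs, reference = sim$reference)
  list(fasta = fasta, bam = bam, truth_vcf = truth_vcf, truth = sim$truth)
}
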