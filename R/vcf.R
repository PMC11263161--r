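# VCF 4.2 output of SV calls (symbolic ALT alleles) and parsing of SV VCFs
# for benchmarking and round-trip checks.

.vcf_sv_header <- function(contigs, hap_annotations, sample) {
  h <- c("##fileformat=VCFv4.2",
         "##source=hapsv",
         sprintf("##contig=<ID=%s,length=%d>", contigs$name, as.integer(contigs$length)),
         '##ALT=<ID=DEL,Description="Deletion">',
         '##ALT=<ID=INS,Description="Insertion">',
         '##ALT=<ID=DUP,Description="Duplication">',
         '##ALT=<ID=INV,Description="Inversion">',
         '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
         '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant">',
         '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
         '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Number of supporting reads">')
  if (hap_annotations)
    h <- c(h,
           '##INFO=<ID=HAPF,Number=1,Type=Float,Description="Fraction of cluster signatures from haplotype-tagged reads (H)">',
           '##INFO=<ID=HAPMAJ,Number=1,Type=Float,Description="Majority-haplotype fraction of tagged signatures (HR)">',
           '##INFO=<ID=HAPSC,Number=1,Type=Float,Description="Haplotype-tagging-quality filter scale (SC)">')
  c(h,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
}

#' Write SV calls to a VCF 4.2 file
#'
#' Emits one record per call with symbolic ALT (<DEL>, <INS>, <DUP>, <INV>),
#' INFO fields SVTYPE/SVLEN/END/SUPPORT (plus HAPF/HAPMAJ/HAPSC haplotype
#' annotations unless disabled) and a single-sample GT column. The REF base
#' at POS is taken from `reference` when given, else "N".
#'
#' @param calls data.frame with columns chrom, pos (1-based), sv_type, svlen,
#'   end, support, gt, and (if `hap_annotations`) hap_f, hap_maj, hap_sc.
#'   Must be sorted by (chrom, pos); an error is raised before writing
#'   otherwise.
#' @param out_path output path.
#' @param contigs data.frame with columns name, length (header contigs).
#' @param reference optional `Biostrings::DNAStringSet` (or path to a FASTA)
#'   supplying REF bases.
#' @param hap_annotations include the haplotype-quality INFO fields. Disable
#'   for output byte-compatible with a haplotype-unaware run.
#' @param sample sample name for the genotype column.
#' @return `out_path`, invisibly.
#' @export
write_sv_vcf <- function(calls, out_path, contigs, reference = NULL,
                         hap_annotations = TRUE, sample = "SAMPLE") {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, pos)", call. = FALSE)
    if (!all(calls$chrom %in% contigs$name))
      stop("call chromosome absent from contig table", call. = FALSE)
  }
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (!is.null(reference))
    names(reference) <- sub("\\s.*$", "", names(reference))
  lines <- .vcf_sv_header(contigs, hap_annotations, sample)
  if (nrow(calls)) {
    ref_base <- rep("N", nrow(calls))
    if (!is.null(reference)) {
      for (i in seq_len(nrow(calls))) {
        if (!calls$chrom[i] %in% names(reference))
          stop("call chromosome absent from reference: ", calls$chrom[i],
               call. = FALSE)
        ref_base[i] <- as.character(Biostrings::subseq(
          reference[[calls$chrom[i]]], calls$pos[i], calls$pos[i]))
      }
    }
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPPORT=%d",
                    calls$sv_type, as.integer(calls$svlen),
                    as.integer(calls$end), as.integer(calls$support))
    if (hap_annotations)
      info <- sprintf("%s;HAPF=%.4f;HAPMAJ=%.4f;HAPSC=%.4f", info,
                      calls$hap_f, calls$hap_maj, calls$hap_sc)
    lines <- c(lines, paste(
      calls$chrom, as.integer(calls$pos),
      sprintf("hapsv.%s.%d", calls$sv_type, seq_len(nrow(calls))),
      ref_base, sprintf("<%s>", calls$sv_type), ".", "PASS", info,
      "GT", calls$gt, sep = "\t"))
  }
  con <- file(out_path, "wb")  # binary mode: LF line endings on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(out_path)
}

#' Read an SV VCF into a call table
#'
#' Parses CHROM/POS/INFO (SVTYPE, SVLEN, END, SUPPORT, HAPF/HAPMAJ/HAPSC when
#' present) and the first sample's GT. SVTYPE falls back to the symbolic ALT
#' when the INFO key is missing.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame with columns chrom, pos, id, sv_type, svlen, end,
#'   support, gt, hap_f, hap_maj, hap_sc (NA where absent).
#' @export
read_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  empty <- data.frame(chrom = character(), pos = numeric(), id = character(),
                      sv_type = character(), svlen = numeric(), end = numeric(),
                      support = numeric(), gt = character(), hap_f = numeric(),
                      hap_maj = numeric(), hap_sc = numeric(),
                      stringsAsFactors = FALSE)
  body_lines <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (body_lines == 0L) return(empty)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(v@fix) == 0L) return(empty)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  num_info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  chr_info <- function(key) as.character(vcfR::extract.info(v, element = key))
  sv_type <- chr_info("SVTYPE")
  alt_type <- sub("^<(.+)>$", "\\1", fix$ALT)
  sv_type[is.na(sv_type)] <- alt_type[is.na(sv_type)]
  gt <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2L) {
    g <- vcfR::extract.gt(v, element = "GT")
    gt <- as.character(g[, 1])
  }
  data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS), id = fix$ID,
             sv_type = sv_type, svlen = num_info("SVLEN"),
             end = num_info("END"), support = num_info("SUPPORT"),
             gt = gt, hap_f = num_info("HAPF"), hap_maj = num_info("HAPMAJ"),
             hap_sc = num_info("HAPSC"), stringsAsFactors = FALSE)
}
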