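# Shared fixture builders: signature rows, random signature sets, and tiny
# BAMs assembled from hand-written SAM records at test time.

sig_row <- function(left, length, sv_type = "DEL", hap = 0L, read = "r1",
                    chrom = "chr1", right = NULL, source = "cigar") {
  if (is.null(right))
    right <- if (sv_type == "INS") left else left + length
  sv_signatures(chrom = chrom, left = left, right = right, length = length,
                sv_type = sv_type, read_id = read, haplotype = hap,
                source = source)
}

# random signature set concentrated enough that clusters actually form
random_sigs <- function(n, span = 20000, types = c("DEL", "INS"),
                        max_len = 800) {
  type <- sample(types, n, replace = TRUE)
  left <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len - 30, n, replace = TRUE) + 30
  sv_signatures(chrom = "chr1", left = left,
                right = ifelse(type == "INS", left, left + len),
                length = len, sv_type = type,
                read_id = sprintf("r%03d", seq_len(n)),
                haplotype = sample(0:2, n, replace = TRUE),
                source = "cigar")
}

# canonical form of a clustering result for set comparison
partition_key <- function(clusters) {
  sort(vapply(clusters, function(cl)
    paste(sort(paste(cl$read_id, cl$left, cl$length, sep = ":")),
          collapse = "|"), character(1)))
}

# build an indexed BAM from a data.frame of SAM records
# (qname, flag, chrom, pos, cigar, tags; tags like "HP:i:1" or "")
write_test_bam <- function(records, targets, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamfix")
    dir.create(dir)
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), unname(targets)))
  records <- records[order(match(records$chrom, names(targets)), records$pos), ,
                     drop = FALSE]
  tags <- ifelse(nzchar(records$tags), paste0("\t", records$tags), "")
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*%s",
                 records$qname, records$flag, records$chrom, records$pos,
                 records$cigar, tags)
  sam <- file.path(dir, "fixture.sam")
  con <- file(sam, "wb"); writeLines(c(hdr, rec), con, sep = "\n"); close(con)
  Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                   indexDestination = TRUE)
}

vcf_body <- function(path) grep("^#", readLines(path), invert = TRUE, value = TRUE)
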