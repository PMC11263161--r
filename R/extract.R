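# Reading haplotype-tagged alignments and turning them into SV signatures.
#
# Evidence comes from two places: large I/D runs inside one alignment's CIGAR
# (intra-read), and breakpoint patterns between the primary and supplementary
# alignments of one read (inter-read). Haplotype labels are per-read HP aux
# tags in the WhatsHap convention (1/2; absent = untagged).

#' Load haplotype-tagged alignments from a BAM file
#'
#' Reads primary and supplementary alignments (unmapped and secondary records
#' are skipped) and attaches the integer HP tag as a haplotype label,
#' 0 when the tag is absent. HP values outside \{1, 2\} are treated as
#' untagged with a warning.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param region optional chromosome name to restrict to.
#' @return data.frame with columns qname, flag, chrom, pos (1-based leftmost),
#'   strand, cigar, haplotype, is_supplementary.
#' @export
load_tagged_alignments <- function(bam_path, region = NULL) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path, call. = FALSE)
  bf <- Rsamtools::BamFile(bam_path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "cigar")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, tag = "HP")
  } else {
    hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
    if (!region %in% names(hdr))
      stop("chromosome not in BAM header: ", region, call. = FALSE)
    gr <- GenomicRanges::GRanges(region, IRanges::IRanges(1, hdr[[region]]))
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, tag = "HP",
                                     which = gr)
  }
  res <- Rsamtools::scanBam(bf, param = param)
  # with `which`, scanBam returns one list element per range; concatenate
  pull <- function(field) do.call(c, lapply(res, function(x) x[[field]]))
  qname <- pull("qname")
  hp <- do.call(c, lapply(res, function(x) {
    v <- x$tag$HP
    if (is.null(v)) rep(NA_integer_, length(x$qname)) else as.integer(v)
  }))
  hp[is.na(hp)] <- 0L
  bad <- !(hp %in% 0:2)
  if (any(bad)) {
    warning(sum(bad), " alignment(s) with HP tag outside {1,2}; treated as untagged")
    hp[bad] <- 0L
  }
  fl <- pull("flag")
  data.frame(qname = qname, flag = fl,
             chrom = as.character(pull("rname")),
             pos = pull("pos"),
             strand = as.character(pull("strand")),
             cigar = pull("cigar"),
             haplotype = hp,
             is_supplementary = bitwAnd(fl, 2048L) > 0L,
             stringsAsFactors = FALSE)
}

# Chain same-type events (0-based start, length) whose reference gap is
# < merge_gap, then emit one signature per chain with length = sum of event
# lengths. For DEL the emitted span is [first start, first start + total
# length) so the span always equals the length; for INS the anchor point is
# the first event's position.
.chain_events <- function(starts, lens, ends, merge_gap) {
  o <- order(starts)
  starts <- starts[o]; lens <- lens[o]; ends <- ends[o]
  grp <- cumsum(c(1, (starts[-1] - cummax(ends[-length(ends)])) >= merge_gap))
  list(start = tapply(starts, grp, min),
       length = tapply(lens, grp, sum))
}

#' Extract intra-read CIGAR signatures from one alignment
#'
#' Deletion (D) runs yield DEL signatures spanning their reference interval;
#' insertion (I) runs yield INS signatures anchored at their reference
#' position. Same-type runs separated by less than `merge_gap` reference bp
#' are chained into a single signature whose length is the sum of the run
#' lengths; the `min_sv_size` threshold is applied to the chained signature.
#'
#' @param chrom chromosome name.
#' @param pos 1-based leftmost mapped position.
#' @param cigar CIGAR string.
#' @param read_id read name.
#' @param haplotype haplotype label in \{0, 1, 2\}.
#' @param min_sv_size minimum emitted signature length (bp).
#' @param merge_gap chaining distance (bp).
#' @return signature data.frame (possibly empty).
#' @export
extract_cigar_signatures <- function(chrom, pos, cigar, read_id, haplotype,
                                     min_sv_size = 30, merge_gap = 500) {
  ops <- tryCatch(GenomicAlignments::explodeCigarOps(cigar)[[1]],
                  error = function(e) NULL)
  if (is.null(ops)) {
    warning("malformed CIGAR for read ", read_id, "; skipped")
    return(.empty_signatures())
  }
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_consumes <- ops %in% c("M", "D", "N", "=", "X")
  ref_before <- pos - 1 + cumsum(c(0, lens[-length(lens)] * ref_consumes[-length(lens)]))
  out <- list()
  for (kind in c("D", "I")) {
    sel <- ops == kind
    if (!any(sel)) next
    ev_start <- ref_before[sel]
    ev_len <- lens[sel]
    ev_end <- if (kind == "D") ev_start + ev_len else ev_start
    ch <- .chain_events(ev_start, ev_len, ev_end, merge_gap)
    keep <- ch$length >= min_sv_size
    if (!any(keep)) next
    st <- as.numeric(ch$start[keep]); ln <- as.numeric(ch$length[keep])
    out[[kind]] <- sv_signatures(
      chrom = chrom, left = st,
      right = if (kind == "D") st + ln else st,
      length = ln, sv_type = if (kind == "D") "DEL" else "INS",
      read_id = read_id, haplotype = haplotype, source = "cigar")
  }
  if (!length(out)) .empty_signatures() else do.call(rbind, unname(out))
}

# per-segment geometry of one alignment: reference span and the query
# interval in the original read orientation (derived from soft/hard clips)
.segment_geometry <- function(alns) {
  ops <- GenomicAlignments::explodeCigarOps(alns$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(alns$cigar)
  n <- nrow(alns)
  g <- data.frame(chrom = alns$chrom, strand = alns$strand,
                  rs = alns$pos - 1, re = NA_real_, qs = NA_real_,
                  qe = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    op <- ops[[i]]; ln <- lens[[i]]
    g$re[i] <- g$rs[i] + sum(ln[op %in% c("M", "D", "N", "=", "X")])
    qtot <- sum(ln[op %in% c("M", "I", "S", "H", "=", "X")])
    lead <- if (op[1] %in% c("S", "H")) ln[1] else 0
    trail <- if (op[length(op)] %in% c("S", "H")) ln[length(ln)] else 0
    qs <- lead
    qe <- qtot - trail
    if (alns$strand[i] == "-") { tmp <- qs; qs <- qtot - qe; qe <- qtot - tmp }
    g$qs[i] <- qs; g$qe[i] <- qe
  }
  g[order(g$qs), , drop = FALSE]
}

#' Extract inter-read (split-alignment) signatures for one read
#'
#' Adjacent same-strand segments on one read imply a DEL (reference gap with
#' no unaligned read sequence), an INS (unaligned read sequence with no
#' reference gap) or a DUP (backward reference jump, i.e. reference overlap).
#' An adjacent opposite-strand pair implies an INV spanning the reference
#' interval of the minus-strand segment.
#'
#' @param alns data.frame of all primary/supplementary alignments of one read
#'   (as returned by [load_tagged_alignments()], filtered to one qname).
#' @param min_sv_size minimum emitted signature length (bp).
#' @return signature data.frame (possibly empty).
#' @export
extract_split_signatures <- function(alns, min_sv_size = 30) {
  if (nrow(alns) < 2L) return(.empty_signatures())
  stopifnot(length(unique(alns$qname)) == 1L)
  hap <- alns$haplotype[!alns$is_supplementary]
  hap <- if (length(hap)) hap[1] else alns$haplotype[1]
  read_id <- alns$qname[1]
  g <- .segment_geometry(alns)
  out <- list()
  for (i in seq_len(nrow(g) - 1L)) {
    a <- g[i, ]; b <- g[i + 1L, ]
    if (a$chrom != b$chrom) next
    read_gap <- b$qs - a$qe
    if (a$strand == b$strand) {
      if (a$strand == "+") {
        ref_gap <- b$rs - a$re; lo <- a$re; hi <- b$rs
        dup_lo <- b$rs; dup_hi <- a$re
      } else {
        ref_gap <- a$rs - b$re; lo <- b$re; hi <- a$rs
        dup_lo <- a$rs; dup_hi <- b$re
      }
      if (-ref_gap >= min_sv_size) {
        out[[length(out) + 1L]] <- sv_signatures(
          chrom = a$chrom, left = dup_lo, right = dup_hi, length = -ref_gap,
          sv_type = "DUP", read_id = read_id, haplotype = hap, source = "split")
      } else if (ref_gap >= min_sv_size && read_gap < min_sv_size) {
        out[[length(out) + 1L]] <- sv_signatures(
          chrom = a$chrom, left = lo, right = hi, length = ref_gap,
          sv_type = "DEL", read_id = read_id, haplotype = hap, source = "split")
      } else if (read_gap >= min_sv_size && abs(ref_gap) < min_sv_size) {
        out[[length(out) + 1L]] <- sv_signatures(
          chrom = a$chrom, left = lo, right = lo, length = read_gap,
          sv_type = "INS", read_id = read_id, haplotype = hap, source = "split")
      }
    } else {
      m <- if (a$strand == "-") a else b
      if (m$re - m$rs >= min_sv_size) {
        out[[length(out) + 1L]] <- sv_signatures(
          chrom = a$chrom, left = m$rs, right = m$re, length = m$re - m$rs,
          sv_type = "INV", read_id = read_id, haplotype = hap, source = "split")
      }
    }
  }
  if (!length(out)) .empty_signatures() else do.call(rbind, out)
}

#' Mean read depth of a chromosome
#'
#' Coverage is the summed reference span of primary alignments on the
#' chromosome divided by the chromosome length; it scales the
#' coverage-proportional support threshold of filtering.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param chrom chromosome name (must be in the BAM header).
#' @return list with elements `chrom` and `cov` (fold coverage, >= 0).
#' @export
chromosome_coverage <- function(bam_path, chrom) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(hdr))
    stop("chromosome not in BAM header: ", chrom, call. = FALSE)
  chrom_len <- hdr[[chrom]]
  alns <- load_tagged_alignments(bam_path, region = chrom)
  alns <- alns[!alns$is_supplementary, , drop = FALSE]
  if (!nrow(alns)) return(list(chrom = chrom, cov = 0))
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(alns$cigar)
  list(chrom = chrom, cov = sum(as.numeric(widths)) / chrom_len)
}

#' Extract all SV signatures from a BAM file
#'
#' Runs CIGAR extraction on every primary/supplementary alignment and split
#' extraction on every read with supplementary alignments.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param region optional chromosome restriction.
#' @param min_sv_size,merge_gap see [extract_cigar_signatures()].
#' @param dup_as_ins also emit an INS view of each DUP signature (used when a
#'   duplication lacks split support downstream).
#' @return signature data.frame.
#' @export
extract_signatures <- function(bam_path, region = NULL, min_sv_size = 30,
                               merge_gap = 500, dup_as_ins = FALSE) {
  alns <- load_tagged_alignments(bam_path, region = region)
  if (!nrow(alns)) return(.empty_signatures())
  sigs <- list()
  # chained signature length per type is bounded by the summed op lengths,
  # so alignments whose D and I totals are both below threshold cannot emit
  ops_all <- GenomicAlignments::explodeCigarOps(alns$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(alns$cigar)
  candidate <- vapply(seq_len(nrow(alns)), function(i) {
    op <- ops_all[[i]]; ln <- lens_all[[i]]
    sum(ln[op == "D"]) >= min_sv_size || sum(ln[op == "I"]) >= min_sv_size
  }, logical(1))
  for (i in which(candidate)) {
    s <- extract_cigar_signatures(alns$chrom[i], alns$pos[i], alns$cigar[i],
                                  alns$qname[i], alns$haplotype[i],
                                  min_sv_size = min_sv_size,
                                  merge_gap = merge_gap)
    if (nrow(s)) sigs[[length(sigs) + 1L]] <- s
  }
  supp_reads <- unique(alns$qname[alns$is_supplementary])
  for (q in supp_reads) {
    s <- extract_split_signatures(alns[alns$qname == q, , drop = FALSE],
                                  min_sv_size = min_sv_size)
    if (nrow(s)) sigs[[length(sigs) + 1L]] <- s
  }
  out <- if (!length(sigs)) .empty_signatures() else do.call(rbind, sigs)
  if (dup_as_ins && nrow(out)) {
    dup <- out[out$sv_type == "DUP", , drop = FALSE]
    if (nrow(dup)) {
      dup$sv_type <- "INS"
      dup$right <- dup$left
      out <- rbind(out, dup)
    }
  }
  rownames(out) <- NULL
  out
}
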