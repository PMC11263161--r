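# Cluster scoring, haplotype-tagging-quality-scaled filtering, genotyping and
# refinement into VCF-ready calls.

#' Length-consistency score of a cluster
#'
#' 1 - SD(lengths) / max(lengths), with the population SD; 1 when all lengths
#' are identical (and for a singleton).
#'
#' @param cluster signature data.frame of one cluster (N >= 1), or a numeric
#'   vector of lengths.
#' @return real in (0, 1].
#' @export
consistent_score <- function(cluster) {
  lens <- if (is.data.frame(cluster)) cluster$length else cluster
  stopifnot(length(lens) >= 1L)
  1 - pop_sd(lens) / max(lens)
}

#' Haplotype-tagging-quality scale
#'
#' Computes the factor SC multiplying the filtering thresholds of a cluster,
#' from H = M/N (fraction of signatures from tagged reads) and
#' HR = max(H1, H2)/M (majority-haplotype fraction; 0 when M = 0):
#' \itemize{
#'   \item H > H0 and HR > HR0: SC = 1 - (HomoSF + HomoSR * (H - H0)) —
#'     a well-tagged, single-haplotype cluster; thresholds are relaxed.
#'   \item H > H0 and HR <= HR0: SC = 1 - (NonHomoSF + NonHomoSR * (H - H0)) —
#'     well-tagged but mixed haplotypes; the signed parameters relax or
#'     tighten as configured.
#'   \item H <= H0: SC = 1 + (LowHRF + LowHRR * (H0 - H)) — poorly tagged;
#'     thresholds are tightened.
#' }
#'
#' @param stats list from [cluster_stats()] (fields N, M, H1, H2 used).
#' @param params a [filter_params()] object.
#' @return positive real SC.
#' @export
haplotype_scale <- function(stats, params) {
  stopifnot(stats$N >= 1L)
  H <- stats$M / stats$N
  HR <- if (stats$M >= 1L) max(stats$H1, stats$H2) / stats$M else 0
  if (H > params$H0) {
    if (HR > params$HR0) {
      1 - (params$HomoSF + params$HomoSR * (H - params$H0))
    } else {
      1 - (params$NonHomoSF + params$NonHomoSR * (H - params$H0))
    }
  } else {
    1 + (params$LowHRF + params$LowHRR * (params$H0 - H))
  }
}

#' Filter a cluster on support and length consistency
#'
#' Under condition set s in \{a, b\} a cluster passes iff its distinct-read
#' support is >= SC * (FF_s + FR_s * cov) and its consistent score is
#' >= min(1, SC * FS_s); it passes overall iff it passes at least one set.
#' SC is the haplotype-tagging-quality scale ([haplotype_scale()]).
#'
#' @param cluster signature data.frame of one cluster.
#' @param cov chromosome fold coverage (>= 0).
#' @param params a [filter_params()] object.
#' @return list: passed (logical), set_id ("a", "b" or NA), sc, score,
#'   support, H, HR.
#' @export
apply_filter <- function(cluster, cov, params) {
  stopifnot(cov >= 0)
  st <- cluster_stats(cluster)
  sc <- haplotype_scale(st, params)
  score <- consistent_score(cluster)
  pass_set <- function(s) {
    st$support >= sc * (s$FF + s$FR * cov) && score >= min(1, sc * s$FS)
  }
  set_id <- NA_character_
  if (pass_set(params$set_a)) set_id <- "a"
  else if (pass_set(params$set_b)) set_id <- "b"
  list(passed = !is.na(set_id), set_id = set_id, sc = sc, score = score,
       support = st$support,
       H = st$M / st$N,
       HR = if (st$M >= 1L) max(st$H1, st$H2) / st$M else 0)
}

#' Genotype a passing cluster
#'
#' With good haplotype tagging (H > H0) the genotype is read off the
#' per-haplotype signature counts: both haplotypes holding >= 20% of tagged
#' signatures is homozygous 1/1; one haplotype holding >= 80% is heterozygous
#' 0/1. Otherwise (or in `allele_fraction` mode) the supporting-read fraction
#' support/cov decides: >= 0.75 is 1/1, >= 0.2 is 0/1, below that `./.`.
#' At cov = 0 only the haplotype rule can apply.
#'
#' @param cluster signature data.frame of one cluster.
#' @param cov chromosome fold coverage.
#' @param params a [filter_params()] object (H0 threshold).
#' @param mode "haplotype" (default) or "allele_fraction" (fallback rule only).
#' @return genotype string: "1/1", "0/1" or "./.".
#' @export
genotype_call <- function(cluster, cov, params, mode = c("haplotype", "allele_fraction")) {
  mode <- match.arg(mode)
  st <- cluster_stats(cluster)
  H <- st$M / st$N
  if (mode == "haplotype" && H > params$H0 && st$M >= 1L) {
    f1 <- st$H1 / st$M
    f2 <- st$H2 / st$M
    if (f1 >= 0.2 && f2 >= 0.2) return("1/1")
    if (max(f1, f2) >= 0.8) return("0/1")
  }
  if (cov > 0) {
    af <- st$support / cov
    if (af >= 0.75) return("1/1")
    if (af >= 0.2) return("0/1")
  }
  "./."
}

#' Refine a cluster into a VCF-ready call
#'
#' POS is the rounded mean of signature left positions (1-based in the
#' output); SVLEN is the rounded mean signature length, negated for DEL;
#' END = POS + |SVLEN| for DEL/DUP/INV and POS for INS. Rounding is
#' half-away-from-zero. Support is the distinct read count.
#'
#' @param cluster signature data.frame of one cluster.
#' @return one-row data.frame: chrom, pos, sv_type, svlen, end, support.
#' @export
refine_call <- function(cluster) {
  st <- cluster_stats(cluster)
  type <- cluster$sv_type[1]
  pos <- round_half_away(st$mean_pos) + 1
  len <- round_half_away(st$mean_len)
  svlen <- if (type == "DEL") -len else len
  end <- if (type == "INS") pos else pos + len
  data.frame(chrom = cluster$chrom[1], pos = pos, sv_type = type,
             svlen = svlen, end = end, support = st$support,
             stringsAsFactors = FALSE)
}
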