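# The end-to-end caller: extract -> cluster -> disunite -> filter ->
# genotype -> refine -> VCF, plus the simulate and bench entry points the
# command-line interface delegates to.

#' Call structural variants from a haplotype-tagged BAM
#'
#' Runs the full pipeline per chromosome: signature extraction (CIGAR and
#' split-alignment), haplotype-conditioned clustering, per-haplotype cluster
#' disunion, haplotype-tagging-quality-scaled filtering, genotyping and
#' refinement. A BAM without HP tags runs in degraded mode: all pair
#' multipliers are 1, no cluster can disunite, and the low-tagging filter
#' branch applies.
#'
#' @param bam_path coordinate-sorted, indexed BAM (HP tags optional).
#' @param out_vcf output VCF path.
#' @param reference optional FASTA path or `DNAStringSet` for REF bases.
#' @param params a [caller_params()] object.
#' @param region optional chromosome restriction.
#' @param genotype_mode "haplotype" or "allele_fraction"
#'   (see [genotype_call()]).
#' @param hap_annotations write the HAPF/HAPMAJ/HAPSC INFO fields.
#' @param sample sample name in the VCF.
#' @return invisibly, the data.frame of emitted calls.
#' @export
sv_call <- function(bam_path, out_vcf, reference = NULL,
                    params = caller_params(), region = NULL,
                    genotype_mode = c("haplotype", "allele_fraction"),
                    hap_annotations = TRUE, sample = "SAMPLE") {
  stopifnot(inherits(params, "hapsv_params"))
  genotype_mode <- match.arg(genotype_mode)
  targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  chroms <- if (is.null(region)) names(targets) else region
  contigs <- data.frame(name = names(targets), length = unname(targets),
                        stringsAsFactors = FALSE)
  calls <- list()
  for (chrom in chroms) {
    sigs <- extract_signatures(bam_path, region = chrom,
                               min_sv_size = params$min_sv_size,
                               merge_gap = params$merge_gap,
                               dup_as_ins = params$dup_as_ins)
    if (!nrow(sigs)) next
    if (all(sigs$haplotype == 0L))
      message("hapsv: no HP tags on ", chrom,
              "; running haplotype-unaware (neutral multipliers)")
    cov <- chromosome_coverage(bam_path, chrom)$cov
    clusters <- cluster_signatures(sigs, params)
    if (params$split_enabled)
      clusters <- do.call(c, lapply(clusters, split_by_haplotype))
    for (cl in clusters) {
      if (!nrow(cl)) next
      fp <- params$filter[[cl$sv_type[1]]]
      flt <- apply_filter(cl, cov, fp)
      if (!flt$passed) next
      call <- refine_call(cl)
      if (abs(call$svlen) < params$min_svlen_out) next
      call$gt <- genotype_call(cl, cov, fp, mode = genotype_mode)
      call$hap_f <- flt$H
      call$hap_maj <- flt$HR
      call$hap_sc <- flt$sc
      call$filter_set <- flt$set_id
      calls[[length(calls) + 1L]] <- call
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), pos = numeric(), sv_type = character(),
               svlen = numeric(), end = numeric(), support = integer(),
               gt = character(), hap_f = numeric(), hap_maj = numeric(),
               hap_sc = numeric(), filter_set = character(),
               stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  write_sv_vcf(calls, out_vcf, contigs, reference = reference,
               hap_annotations = hap_annotations, sample = sample)
  invisible(calls)
}

#' Simulate a dataset (CLI entry point)
#'
#' Delegates to [simulate_dataset()].
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory.
#' @return list of output paths and the truth table.
#' @export
sv_simulate <- function(config, out_dir) {
  simulate_dataset(config, out_dir)
}

#' Benchmark and report (CLI entry point)
#'
#' Runs [sv_benchmark()], prints the overall and per-type table, and
#' optionally writes the full result as JSON.
#'
#' @param calls_vcf,truth_vcf VCF paths.
#' @param bed optional BED restriction.
#' @param out_json optional JSON report path.
#' @param ... passed to [sv_benchmark()].
#' @return the benchmark result list, invisibly.
#' @export
sv_bench <- function(calls_vcf, truth_vcf, bed = NULL, out_json = NULL, ...) {
  res <- sv_benchmark(calls_vcf, truth_vcf, bed = bed, ...)
  print_benchmark(res)
  if (!is.null(out_json))
    jsonlite::write_json(res, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(res)
}
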