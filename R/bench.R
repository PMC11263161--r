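# Sequence-free benchmarking of SV calls against a truth set: one-to-one
# matching by position distance and size ratio (the semantics of truvari run
# with sequence comparison disabled), then presence and genotype
# precision/recall/F1, overall and per SV type.

#' Match calls against truth records
#'
#' A call can match a truth entry iff the SV types are equal (optionally
#' allowing DUP to pair with INS), the start distance is <= `refdist`, and
#' min(|len|)/max(|len|) >= `pctsize`. Candidate pairs are assigned greedily,
#' best size similarity first (ties broken by distance), each call and truth
#' entry matching at most once. A matched pair is additionally a genotype
#' match when the GT strings are identical.
#'
#' @param calls data.frame with columns chrom, pos, sv_type, svlen, gt (as
#'   from [read_sv_vcf()]), sorted by (chrom, pos).
#' @param truth data.frame with the same columns, sorted by (chrom, pos).
#' @param refdist maximum start distance in bp.
#' @param pctsize minimum size ratio.
#' @param dup_ins_match allow DUP and INS records to match each other.
#' @return list: `pairs` (data.frame call_idx, truth_idx, gt_match),
#'   `call_matched`, `truth_matched` (logical vectors), and the inputs.
#' @export
match_calls <- function(calls, truth, refdist = 500, pctsize = 0.7,
                        dup_ins_match = FALSE) {
  for (d in list(calls, truth)) {
    if (nrow(d) && !identical(order(d$chrom, d$pos), seq_len(nrow(d))))
      stop("calls and truth must be sorted by (chrom, pos)", call. = FALSE)
  }
  nc <- nrow(calls); nt <- nrow(truth)
  pairs <- data.frame(call_idx = integer(), truth_idx = integer(),
                      gt_match = logical())
  if (nc && nt) {
    type_ok <- function(a, b) {
      a == b | (dup_ins_match & ((a == "DUP" & b == "INS") |
                                 (a == "INS" & b == "DUP")))
    }
    ci <- rep(seq_len(nc), each = nt)
    ti <- rep(seq_len(nt), times = nc)
    la <- abs(calls$svlen[ci]); lb <- abs(truth$svlen[ti])
    dist <- abs(calls$pos[ci] - truth$pos[ti])
    ratio <- pmin(la, lb) / pmax(la, lb)
    keep <- calls$chrom[ci] == truth$chrom[ti] &
      type_ok(calls$sv_type[ci], truth$sv_type[ti]) &
      dist <= refdist & ratio >= pctsize
    cand <- data.frame(call_idx = ci[keep], truth_idx = ti[keep],
                       ratio = ratio[keep], dist = dist[keep])
    cand <- cand[order(-cand$ratio, cand$dist, cand$call_idx, cand$truth_idx), ,
                 drop = FALSE]
    call_used <- logical(nc); truth_used <- logical(nt)
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      a <- cand$call_idx[k]; b <- cand$truth_idx[k]
      if (!call_used[a] && !truth_used[b]) {
        call_used[a] <- TRUE; truth_used[b] <- TRUE; sel[k] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    pairs <- data.frame(call_idx = cand$call_idx, truth_idx = cand$truth_idx,
                        gt_match = !is.na(calls$gt[cand$call_idx]) &
                          !is.na(truth$gt[cand$truth_idx]) &
                          calls$gt[cand$call_idx] == truth$gt[cand$truth_idx])
  }
  call_matched <- logical(nc); call_matched[pairs$call_idx] <- TRUE
  truth_matched <- logical(nt); truth_matched[pairs$truth_idx] <- TRUE
  list(pairs = pairs, call_matched = call_matched,
       truth_matched = truth_matched, calls = calls, truth = truth)
}

#' Precision, recall and F1 from match counts
#'
#' precision = TP_call/(TP_call + FP_call), recall = TP_base/(TP_base +
#' FN_base), F1 = 2PR/(P + R); a 0/0 ratio is defined as 0.
#'
#' @param TP_call,FP_call correct and incorrect detections among the calls.
#' @param TP_base,FN_base covered and missed truth records.
#' @return list(precision, recall, f1).
#' @export
sv_metrics <- function(TP_call, FP_call, TP_base, FN_base) {
  stopifnot(TP_call >= 0, FP_call >= 0, TP_base >= 0, FN_base >= 0)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(TP_call, TP_call + FP_call)
  r <- safe_div(TP_base, TP_base + FN_base)
  list(precision = p, recall = r, f1 = safe_div(2 * p * r, p + r))
}

# presence- or GT-level counts for a subset of calls/truth
.level_counts <- function(matching, level, call_sel, truth_sel) {
  pairs <- matching$pairs
  good <- if (level == "gt") pairs$gt_match else rep(TRUE, nrow(pairs))
  tp_call <- sum(good & call_sel[pairs$call_idx])
  tp_base <- sum(good & truth_sel[pairs$truth_idx])
  list(TP_call = tp_call, FP_call = sum(call_sel) - tp_call,
       TP_base = tp_base, FN_base = sum(truth_sel) - tp_base)
}

.bench_block <- function(matching, call_sel, truth_sel) {
  out <- list()
  for (level in c("presence", "gt")) {
    cnt <- .level_counts(matching, level, call_sel, truth_sel)
    out[[level]] <- c(cnt, sv_metrics(cnt$TP_call, cnt$FP_call,
                                      cnt$TP_base, cnt$FN_base))
  }
  out
}

#' Benchmark summary from a matching
#'
#' Presence-level metrics credit any matched pair; GT-level metrics require
#' the genotype to agree as well (a matched pair with discordant GT counts
#' as FP and FN at the GT level). Per-type blocks partition calls and truth
#' by their own SV type; totals sum to the overall counts.
#'
#' @param matching result of [match_calls()].
#' @return list with `overall` and `by_type`, each containing `presence` and
#'   `gt` blocks of counts and metrics.
#' @export
stratify_matches <- function(matching) {
  nc <- nrow(matching$calls); nt <- nrow(matching$truth)
  overall <- .bench_block(matching, rep(TRUE, nc), rep(TRUE, nt))
  by_type <- lapply(stats::setNames(SV_TYPES, SV_TYPES), function(t)
    .bench_block(matching, matching$calls$sv_type == t,
                 matching$truth$sv_type == t))
  list(overall = overall, by_type = by_type)
}

#' Benchmark a calls VCF against a truth VCF
#'
#' Loads both VCFs, optionally restricts to a BED region (a record counts if
#' its POS lies inside a half-open 0-based interval), matches, and computes
#' presence and GT precision/recall/F1 overall and per SV type.
#'
#' @param calls_vcf,truth_vcf VCF paths.
#' @param bed optional BED path restricting the comparison.
#' @param refdist,pctsize,dup_ins_match see [match_calls()].
#' @return list as from [stratify_matches()], plus `n_calls`, `n_truth`.
#' @export
sv_benchmark <- function(calls_vcf, truth_vcf, bed = NULL, refdist = 500,
                         pctsize = 0.7, dup_ins_match = FALSE) {
  calls <- read_sv_vcf(calls_vcf)
  truth <- read_sv_vcf(truth_vcf)
  if (!is.null(bed)) {
    reg <- rtracklayer::import(bed, format = "BED")
    inside <- function(d) {
      if (!nrow(d)) return(logical(0))
      gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
      IRanges::overlapsAny(gr, reg)
    }
    calls <- calls[inside(calls), , drop = FALSE]
    truth <- truth[inside(truth), , drop = FALSE]
  }
  matching <- match_calls(calls, truth, refdist = refdist, pctsize = pctsize,
                          dup_ins_match = dup_ins_match)
  res <- stratify_matches(matching)
  res$n_calls <- nrow(calls)
  res$n_truth <- nrow(truth)
  res
}

#' Print a benchmark report table
#'
#' @param bench result of [sv_benchmark()] / [stratify_matches()].
#' @return the formatted table data.frame, invisibly; prints it as a side
#'   effect.
#' @export
print_benchmark <- function(bench) {
  fmt_row <- function(name, block) {
    data.frame(scope = name,
               level = c("presence", "gt"),
               TP_call = c(block$presence$TP_call, block$gt$TP_call),
               FP_call = c(block$presence$FP_call, block$gt$FP_call),
               TP_base = c(block$presence$TP_base, block$gt$TP_base),
               FN_base = c(block$presence$FN_base, block$gt$FN_base),
               precision = round(c(block$presence$precision, block$gt$precision), 4),
               recall = round(c(block$presence$recall, block$gt$recall), 4),
               f1 = round(c(block$presence$f1, block$gt$f1), 4),
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(list(fmt_row("ALL", bench$overall)),
                          lapply(SV_TYPES, function(t)
                            fmt_row(t, bench$by_type[[t]]))))
  print(tab, row.names = FALSE)
  invisible(tab)
}
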