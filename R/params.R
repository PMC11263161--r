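# Tunable parameters of the caller, grouped per SV type, plus the flat
# key-value configuration file they round-trip through.

#' Supported SV types
#' @export
SV_TYPES <- c("DEL", "INS", "DUP", "INV")

#' Clustering parameters for one SV type
#'
#' `F` (bp) and `CR` (dimensionless) are the absolute-position and relative
#' merge tolerances of signature clustering. When two signatures carry
#' haplotype tags, both tolerances are multiplied by `SR` (same haplotype,
#' stricter, in \[0,1\]) or `DR` (different haplotypes, more permissive, >= 1);
#' pairs involving an untagged signature are left unscaled.
#'
#' @param F position tolerance in bp (> 0).
#' @param CR relative tolerance, dimensionless (> 0).
#' @param SR same-haplotype multiplier in \[0, 1\].
#' @param DR different-haplotype multiplier (>= 1).
#' @return a list with class `hapsv_cluster_params`.
#' @export
cluster_params <- function(F = 500, CR = 0.3, SR = 0.8, DR = 1.3) {
  p <- list(F = F, CR = CR, SR = SR, DR = DR)
  for (k in names(p)) if (!.is_num1(p[[k]])) .stop_param(k, "must be a finite number")
  if (p$F <= 0) .stop_param("F", "must be > 0")
  if (p$CR <= 0) .stop_param("CR", "must be > 0")
  if (p$SR < 0 || p$SR > 1) .stop_param("SR", "must be in [0, 1]")
  if (p$DR < 1) .stop_param("DR", "must be >= 1")
  structure(p, class = "hapsv_cluster_params")
}

#' Filtering parameters for one SV type
#'
#' A cluster passes filtering if it passes at least one of two condition sets
#' (`a` and `b`). Under set s the cluster needs distinct-read support
#' >= SC * (FF_s + FR_s * Cov) and consistent score >= min(1, SC * FS_s),
#' where Cov is the chromosome coverage and SC the haplotype-tagging-quality
#' scale computed by [haplotype_scale()] from H = M/N (tagged fraction) and
#' HR = max(H1, H2)/M (majority-haplotype fraction):
#'   H > H0, HR > HR0 : SC = 1 - (HomoSF + HomoSR * (H - H0))
#'   H > H0, HR <= HR0: SC = 1 - (NonHomoSF + NonHomoSR * (H - H0))
#'   H <= H0          : SC = 1 + (LowHRF + LowHRR * (H0 - H))
#'
#' `HomoR` is accepted for configuration compatibility but enters no formula.
#'
#' @param set_a,set_b lists with elements FF (fixed support floor, reads),
#'   FR (coverage-proportional support rate) and FS (minimum consistent score).
#' @param H0 tagged-fraction threshold in \[0, 1\].
#' @param HR0 majority-haplotype-fraction threshold in \[0, 1\].
#' @param HomoSF,HomoSR,LowHRF,LowHRR reals in \[0, 1\].
#' @param NonHomoSF,NonHomoSR reals in \[-1, 1\].
#' @param HomoR accepted but unused, in \[0, 1\].
#' @return a list with class `hapsv_filter_params`.
#' @export
filter_params <- function(set_a = list(FF = 2, FR = 0.2, FS = 0.55),
                          set_b = list(FF = 1, FR = 0.1, FS = 0.75),
                          H0 = 0.8, HR0 = 0.8,
                          HomoSF = 0.05, HomoSR = 0.25,
                          NonHomoSF = 0, NonHomoSR = 0.1,
                          LowHRF = 0.05, LowHRR = 0.25,
                          HomoR = 0.5) {
  for (s in list(a = set_a, b = set_b)) {
    if (!all(c("FF", "FR", "FS") %in% names(s)))
      .stop_param("set_a/set_b", "must contain FF, FR and FS")
    if (!.is_num1(s$FF) || s$FF < 0) .stop_param("FF", "must be >= 0")
    if (!.is_num1(s$FR) || s$FR < 0) .stop_param("FR", "must be >= 0")
    if (!.is_num1(s$FS) || s$FS < 0 || s$FS > 1) .stop_param("FS", "must be in [0, 1]")
  }
  unit <- list(H0 = H0, HR0 = HR0, HomoSF = HomoSF, HomoSR = HomoSR,
               LowHRF = LowHRF, LowHRR = LowHRR, HomoR = HomoR)
  for (k in names(unit))
    if (!.is_num1(unit[[k]]) || unit[[k]] < 0 || unit[[k]] > 1)
      .stop_param(k, "must be in [0, 1]")
  for (k in c("NonHomoSF", "NonHomoSR")) {
    v <- get(k)
    if (!.is_num1(v) || v < -1 || v > 1) .stop_param(k, "must be in [-1, 1]")
  }
  structure(c(list(set_a = set_a, set_b = set_b), unit,
              list(NonHomoSF = NonHomoSF, NonHomoSR = NonHomoSR)),
            class = "hapsv_filter_params")
}

#' Full caller configuration
#'
#' Bundles extraction thresholds, per-SV-type clustering and filtering
#' parameters, and pipeline switches. Per-type entries supplied through
#' `cluster` / `filter` override the defaults for the named types only.
#' Default tolerances: F = 500 bp (600 bp for INV), CR = 0.3, SR = 0.8,
#' DR = 1.3.
#'
#' @param min_sv_size minimum signature length retained at extraction (bp).
#' @param merge_gap maximum reference gap for chaining same-type CIGAR events
#'   of one read into a single signature (bp).
#' @param min_svlen_out minimum |SVLEN| of an emitted call (bp); calls below
#'   it are dropped as sub-SV indels.
#' @param split_enabled apply the per-haplotype cluster disunion stage.
#' @param dup_as_ins additionally re-type DUP signatures lacking split support
#'   as insertions at the duplication locus.
#' @param cluster named list of [cluster_params()] per SV type (partial).
#' @param filter named list of [filter_params()] per SV type (partial).
#' @return a list with class `hapsv_params`.
#' @export
caller_params <- function(min_sv_size = 30, merge_gap = 500, min_svlen_out = 50,
                          split_enabled = TRUE, dup_as_ins = FALSE,
                          cluster = list(), filter = list()) {
  if (!.is_num1(min_sv_size) || min_sv_size < 1) .stop_param("min_sv_size", "must be >= 1")
  if (!.is_num1(merge_gap) || merge_gap < 0) .stop_param("merge_gap", "must be >= 0")
  if (!.is_num1(min_svlen_out) || min_svlen_out < 0) .stop_param("min_svlen_out", "must be >= 0")
  if (!is.logical(split_enabled) || length(split_enabled) != 1L)
    .stop_param("split_enabled", "must be TRUE or FALSE")
  if (!is.logical(dup_as_ins) || length(dup_as_ins) != 1L)
    .stop_param("dup_as_ins", "must be TRUE or FALSE")
  cl <- list(DEL = cluster_params(F = 500), INS = cluster_params(F = 500),
             DUP = cluster_params(F = 500), INV = cluster_params(F = 600))
  fl <- stats::setNames(lapply(SV_TYPES, function(t) filter_params()), SV_TYPES)
  for (t in names(cluster)) {
    if (!t %in% SV_TYPES) .stop_param(t, "unknown SV type in 'cluster'")
    stopifnot(inherits(cluster[[t]], "hapsv_cluster_params"))
    cl[[t]] <- cluster[[t]]
  }
  for (t in names(filter)) {
    if (!t %in% SV_TYPES) .stop_param(t, "unknown SV type in 'filter'")
    stopifnot(inherits(filter[[t]], "hapsv_filter_params"))
    fl[[t]] <- filter[[t]]
  }
  structure(list(min_sv_size = min_sv_size, merge_gap = merge_gap,
                 min_svlen_out = min_svlen_out, split_enabled = split_enabled,
                 dup_as_ins = dup_as_ins, cluster = cl, filter = fl),
            class = "hapsv_params")
}

#' Haplotype-neutral caller configuration
#'
#' Returns a [caller_params()] object in which the haplotype-aware layer is
#' inert: SR = DR = 1 (no tag-conditioned merge tolerances), all six filter
#' scale parameters 0 (SC = 1 in every branch), and cluster disunion
#' disabled. Together with `genotype_mode = "allele_fraction"` and
#' `hap_annotations = FALSE` in [sv_call()], a run on a tagged BAM is
#' byte-identical to the run on the same BAM with HP tags stripped —
#' the haplotype-aware layer cleanly contains the vanilla caller.
#'
#' @param split_enabled keep the disunion stage (it is tag-driven, so TRUE
#'   breaks the strict reduction on tagged input).
#' @return a [caller_params()] object.
#' @export
neutral_caller_params <- function(split_enabled = FALSE) {
  cl <- lapply(stats::setNames(SV_TYPES, SV_TYPES), function(t)
    cluster_params(F = if (t == "INV") 600 else 500, SR = 1, DR = 1))
  fl <- lapply(stats::setNames(SV_TYPES, SV_TYPES), function(t)
    filter_params(HomoSF = 0, HomoSR = 0, NonHomoSF = 0, NonHomoSR = 0,
                  LowHRF = 0, LowHRR = 0))
  caller_params(split_enabled = split_enabled, cluster = cl, filter = fl)
}

# ---- configuration file (flat key-value text with per-SV-type sections) ----

#' Write a caller configuration file
#'
#' Flat `key = value` text with one `[TYPE]` section per SV type; chosen for
#' diff-friendliness. [read_caller_config()] restores an identical object.
#'
#' @param params a [caller_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_caller_config <- function(params, path) {
  stopifnot(inherits(params, "hapsv_params"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c("# hapsv caller configuration",
             paste("min_sv_size =", fmt(params$min_sv_size)),
             paste("merge_gap =", fmt(params$merge_gap)),
             paste("min_svlen_out =", fmt(params$min_svlen_out)),
             paste("split_enabled =", params$split_enabled),
             paste("dup_as_ins =", params$dup_as_ins))
  for (t in SV_TYPES) {
    cp <- params$cluster[[t]]
    fp <- params$filter[[t]]
    lines <- c(lines, paste0("[", t, "]"),
               paste("F =", fmt(cp$F)), paste("CR =", fmt(cp$CR)),
               paste("SR =", fmt(cp$SR)), paste("DR =", fmt(cp$DR)),
               paste("FF_a =", fmt(fp$set_a$FF)), paste("FR_a =", fmt(fp$set_a$FR)),
               paste("FS_a =", fmt(fp$set_a$FS)),
               paste("FF_b =", fmt(fp$set_b$FF)), paste("FR_b =", fmt(fp$set_b$FR)),
               paste("FS_b =", fmt(fp$set_b$FS)),
               paste("H0 =", fmt(fp$H0)), paste("HR0 =", fmt(fp$HR0)),
               paste("HomoSF =", fmt(fp$HomoSF)), paste("HomoSR =", fmt(fp$HomoSR)),
               paste("NonHomoSF =", fmt(fp$NonHomoSF)), paste("NonHomoSR =", fmt(fp$NonHomoSR)),
               paste("LowHRF =", fmt(fp$LowHRF)), paste("LowHRR =", fmt(fp$LowHRR)),
               paste("HomoR =", fmt(fp$HomoR)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a caller configuration file
#'
#' @param path file written by [write_caller_config()] (or edited by hand).
#'   Unknown keys raise an error naming the offending key.
#' @return a [caller_params()] object.
#' @export
read_caller_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  section <- ""
  global <- list()
  per_type <- stats::setNames(vector("list", length(SV_TYPES)), SV_TYPES)
  for (ln in raw) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% SV_TYPES)
        stop("unknown section [", section, "] in config", call. = FALSE)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- if (val %in% c("TRUE", "FALSE")) as.logical(val) else suppressWarnings(as.numeric(val))
    if (is.na(parsed)) stop("non-numeric value for key '", key, "'", call. = FALSE)
    if (section == "") global[[key]] <- parsed else per_type[[section]][[key]] <- parsed
  }
  known_global <- c("min_sv_size", "merge_gap", "min_svlen_out", "split_enabled", "dup_as_ins")
  bad <- setdiff(names(global), known_global)
  if (length(bad)) stop("unknown config key: ", bad[1], call. = FALSE)
  cl <- list(); fl <- list()
  for (t in SV_TYPES) {
    kv <- per_type[[t]]
    if (is.null(kv) || !length(kv)) next
    known <- c("F", "CR", "SR", "DR", "FF_a", "FR_a", "FS_a", "FF_b", "FR_b",
               "FS_b", "H0", "HR0", "HomoSF", "HomoSR", "NonHomoSF",
               "NonHomoSR", "LowHRF", "LowHRR", "HomoR")
    bad <- setdiff(names(kv), known)
    if (length(bad)) stop("unknown config key '", bad[1], "' in [", t, "]", call. = FALSE)
    carg <- kv[intersect(names(kv), c("F", "CR", "SR", "DR"))]
    cl[[t]] <- do.call(cluster_params, carg)
    farg <- list()
    if (any(c("FF_a", "FR_a", "FS_a") %in% names(kv)))
      farg$set_a <- list(FF = kv$FF_a, FR = kv$FR_a, FS = kv$FS_a)
    if (any(c("FF_b", "FR_b", "FS_b") %in% names(kv)))
      farg$set_b <- list(FF = kv$FF_b, FR = kv$FR_b, FS = kv$FS_b)
    for (k in c("H0", "HR0", "HomoSF", "HomoSR", "NonHomoSF", "NonHomoSR",
                "LowHRF", "LowHRR", "HomoR"))
      if (!is.null(kv[[k]])) farg[[k]] <- kv[[k]]
    fl[[t]] <- do.call(filter_params, farg)
  }
  args <- c(global, list(cluster = cl, filter = fl))
  do.call(caller_params, args)
}
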