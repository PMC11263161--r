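# Haplotype-conditioned single-linkage clustering of SV signatures, and the
# per-haplotype disunion of clusters that mix two length-distinct variants.

#' Haplotype pair multiplier
#'
#' Merge tolerances between two signatures are scaled by `SR` when both carry
#' the same haplotype tag (stricter: no inter-haplotype interference is
#' possible), by `DR` when they carry different tags (more permissive), and
#' left unscaled when either is untagged.
#'
#' @param hap1,hap2 haplotype labels in \{0, 1, 2\} (vectorised).
#' @param params a [cluster_params()] object.
#' @return numeric multiplier(s).
#' @export
haplotype_multiplier <- function(hap1, hap2, params) {
  ifelse(hap1 != 0L & hap2 != 0L,
         ifelse(hap1 == hap2, params$SR, params$DR),
         1)
}

#' Signature pair merge test
#'
#' Two signatures are mergeable when either condition holds with m the
#' haplotype multiplier:
#'   max(|dLeft|, |dRight|) < F * m, or
#'   max(|dLeft|, |dRight|, |dLength|) / min(length1, length2) < CR * m.
#' Inequalities are strict. All arguments after the first two are vectorised.
#'
#' @param s1,s2 single-row signature data.frames (or vector components via
#'   `pair_mergeable_vec`).
#' @param params a [cluster_params()] object for the shared SV type.
#' @return logical.
#' @export
pair_mergeable <- function(s1, s2, params) {
  stopifnot(s1$chrom == s2$chrom, s1$sv_type == s2$sv_type)
  pair_mergeable_vec(s1$left, s1$right, s1$length, s1$haplotype,
                     s2$left, s2$right, s2$length, s2$haplotype, params)
}

#' @rdname pair_mergeable
#' @param l1,r1,len1,h1,l2,r2,len2,h2 vectors of left/right/length/haplotype.
#' @export
pair_mergeable_vec <- function(l1, r1, len1, h1, l2, r2, len2, h2, params) {
  m <- haplotype_multiplier(h1, h2, params)
  dpos <- pmax(abs(l1 - l2), abs(r1 - r2))
  eq1 <- dpos < params$F * m
  minlen <- pmin(len1, len2)
  eq2 <- minlen > 0 & pmax(dpos, abs(len1 - len2)) / minlen < params$CR * m
  eq1 | eq2
}

# minimal union-find find (no compression; cluster windows are small)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster signatures by transitive merge closure
#'
#' Within each (chromosome, SV type) group, returns the partition equal to the
#' transitive closure of [pair_mergeable()] over single signatures
#' (single-linkage). Candidate pairs are restricted to a sliding window over
#' signatures sorted by left position: a pair at left distance d can only be
#' mergeable if d < max(F * DR, CR * DR * min(length)), so comparing each
#' signature to its successors within max(F * DR, CR * DR * length_i) bp
#' preserves the closure exactly. The result is independent of input order.
#'
#' @param sigs signature data.frame.
#' @param params a [caller_params()] object (per-type tolerances are taken
#'   from it), or a single [cluster_params()] applied to all types.
#' @return list of clusters, each a signature data.frame; within each cluster
#'   rows are ordered by (left, right, length, read_id) for determinism.
#' @export
cluster_signatures <- function(sigs, params = caller_params()) {
  if (!nrow(sigs)) return(list())
  validate_signatures(sigs)
  get_cp <- function(type) {
    if (inherits(params, "hapsv_cluster_params")) params else params$cluster[[type]]
  }
  out <- list()
  for (key in unique(paste(sigs$chrom, sigs$sv_type))) {
    grp <- sigs[paste(sigs$chrom, sigs$sv_type) == key, , drop = FALSE]
    cp <- get_cp(grp$sv_type[1])
    grp <- grp[order(grp$left, grp$right, grp$length, grp$read_id), , drop = FALSE]
    n <- nrow(grp)
    parent <- seq_len(n)
    if (n > 1L) {
      win <- pmax(cp$F * cp$DR, cp$CR * cp$DR * grp$length)
      for (i in seq_len(n - 1L)) {
        j <- i + 1L
        while (j <= n && grp$left[j] - grp$left[i] < win[i]) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
          if (ri != rj &&
              pair_mergeable_vec(grp$left[i], grp$right[i], grp$length[i],
                                 grp$haplotype[i], grp$left[j], grp$right[j],
                                 grp$length[j], grp$haplotype[j], cp)) {
            parent[max(ri, rj)] <- min(ri, rj)
          }
          j <- j + 1L
        }
      }
    }
    roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
    for (r in sort(unique(roots)))
      out[[length(out) + 1L]] <- grp[roots == r, , drop = FALSE]
  }
  lapply(out, function(cl) { rownames(cl) <- NULL; cl })
}

#' Brute-force reference clustering
#'
#' O(n^2) transitive closure of [pair_mergeable()] over all pairs, used as the
#' independent oracle for the windowed implementation in tests.
#'
#' @inheritParams cluster_signatures
#' @return list of clusters in the same normalised order as
#'   [cluster_signatures()].
#' @export
cluster_signatures_bruteforce <- function(sigs, params = caller_params()) {
  if (!nrow(sigs)) return(list())
  get_cp <- function(type) {
    if (inherits(params, "hapsv_cluster_params")) params else params$cluster[[type]]
  }
  out <- list()
  for (key in unique(paste(sigs$chrom, sigs$sv_type))) {
    grp <- sigs[paste(sigs$chrom, sigs$sv_type) == key, , drop = FALSE]
    cp <- get_cp(grp$sv_type[1])
    grp <- grp[order(grp$left, grp$right, grp$length, grp$read_id), , drop = FALSE]
    n <- nrow(grp)
    adj <- outer(seq_len(n), seq_len(n), function(i, j)
      pair_mergeable_vec(grp$left[i], grp$right[i], grp$length[i], grp$haplotype[i],
                         grp$left[j], grp$right[j], grp$length[j], grp$haplotype[j],
                         cp))
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    comp <- match(comp, unique(comp))
    for (r in sort(unique(comp)))
      out[[length(out) + 1L]] <- grp[comp == r, , drop = FALSE]
  }
  lapply(out, function(cl) { rownames(cl) <- NULL; cl })
}

#' Length-difference significance between haplotypes
#'
#' Per-haplotype mean signature lengths are considered significantly different
#' when |M1 - M2| > max(SD1, SD2) (population SDs).
#'
#' @param M1,SD1 mean and SD of haplotype-1 signature lengths (bp).
#' @param M2,SD2 mean and SD of haplotype-2 signature lengths (bp).
#' @return logical.
#' @export
significantly_different <- function(M1, SD1, M2, SD2) {
  abs(M1 - M2) > pmax(SD1, SD2)
}

#' Per-haplotype cluster statistics
#'
#' @param cluster signature data.frame of one cluster (all rows share chrom
#'   and sv_type).
#' @return list with N (signatures), M (tagged), H1, H2 (per-haplotype
#'   counts), M1, M2, SD1, SD2 (per-haplotype length mean/SD, NA when the
#'   haplotype is absent), mean_pos, mean_len (over all signatures), and
#'   support (distinct read count).
#' @export
cluster_stats <- function(cluster) {
  stopifnot(nrow(cluster) >= 1L)
  len1 <- cluster$length[cluster$haplotype == 1L]
  len2 <- cluster$length[cluster$haplotype == 2L]
  list(N = nrow(cluster),
       M = length(len1) + length(len2),
       H1 = length(len1), H2 = length(len2),
       M1 = if (length(len1)) mean(len1) else NA_real_,
       M2 = if (length(len2)) mean(len2) else NA_real_,
       SD1 = if (length(len1)) pop_sd(len1) else NA_real_,
       SD2 = if (length(len2)) pop_sd(len2) else NA_real_,
       mean_pos = mean(cluster$left),
       mean_len = mean(cluster$length),
       support = length(unique(cluster$read_id)))
}

#' Disunite a cluster by haplotype
#'
#' When a cluster contains signatures from both haplotypes and the
#' per-haplotype mean lengths are significantly different
#' ([significantly_different()]), the cluster is split into a haplotype-1 and
#' a haplotype-2 cluster; each untagged signature joins the side whose mean
#' length is nearer to its own length (ties go to haplotype 1). Otherwise the
#' cluster is returned unchanged. Signature count is conserved.
#'
#' @param cluster signature data.frame of one cluster.
#' @return list of one or two signature data.frames.
#' @export
split_by_haplotype <- function(cluster) {
  st <- cluster_stats(cluster)
  if (st$H1 < 1L || st$H2 < 1L ||
      !significantly_different(st$M1, st$SD1, st$M2, st$SD2))
    return(list(cluster))
  side <- integer(nrow(cluster))
  side[cluster$haplotype == 1L] <- 1L
  side[cluster$haplotype == 2L] <- 2L
  untagged <- cluster$haplotype == 0L
  if (any(untagged)) {
    d1 <- abs(cluster$length[untagged] - st$M1)
    d2 <- abs(cluster$length[untagged] - st$M2)
    side[untagged] <- ifelse(d1 <= d2, 1L, 2L)
  }
  list(cluster[side == 1L, , drop = FALSE],
       cluster[side == 2L, , drop = FALSE])
}
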