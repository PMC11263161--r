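---
title: "hapsv: haplotype-aware structural variant calling from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hapsv: haplotype-aware structural variant calling from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsv)
```

## The problem

Structural variants (SVs) — deletions, insertions, duplications and
inversions of at least 50 bp — are called from long-read alignments by
collecting per-read evidence ("signatures"), grouping signatures that
describe the same underlying variant, and filtering the groups by read
support. Long reads from Oxford Nanopore routinely span heterozygous sites,
so a phasing step (SNV calling plus read tagging, e.g. Clair3 + WhatsHap)
can label each read with its parental haplotype, stored as the integer `HP`
aux tag (1 or 2; untagged reads carry no tag). `hapsv` consumes such a
tagged BAM and exploits the labels at three points of the calling process:
when deciding whether two signatures describe the same variant, when
recognising that one signature cluster actually mixes two distinct nearby
variants from opposite haplotypes, and when setting the support thresholds a
cluster must clear. Haplotype tagging itself is out of scope: the package
expects the conventional upstream recipe (Clair3 with an ONT model, then
`whatshap haplotag --ignore-read-groups`) to have produced the BAM.

## Signature extraction

Two evidence channels are used. Intra-read: every deletion (`D`) or
insertion (`I`) CIGAR run contributes an event; same-type events of one
alignment closer than `merge_gap` (default 500 bp) on the reference are
chained into a single signature whose length is the sum of the event
lengths, and the `min_sv_size` threshold (default 30 bp) is applied to the
chained signature, so a variant fragmented into nearby sub-events by the
aligner is still recovered. A chained deletion is recorded with its span
equal to its total length, anchored at the first event. Inter-read: for the
ordered segments of a split-aligned read, a reference gap with no unaligned
read sequence is a deletion, unaligned read sequence with no reference gap
is an insertion, a backward reference jump (overlap) is a duplication, and
an adjacent opposite-strand pair is an inversion spanning the minus-strand
segment. Signatures inherit the `HP` label of their read; an `HP` value
outside {1, 2} is treated as untagged with a warning. All internal
coordinates are 0-based half-open; VCF output is 1-based.

The final VCF drops calls under 50 bp (`min_svlen_out`); extraction keeps
signatures from 30 bp so that a cluster whose mean length straddles the
50 bp boundary is estimated from all of its evidence.

## Haplotype-conditioned clustering

Signatures $S_1, S_2$ of one type on one chromosome are mergeable when
either condition holds:

$$\max(|\Delta \mathrm{left}|, |\Delta \mathrm{right}|) < F \cdot m
\quad\text{or}\quad
\frac{\max(|\Delta \mathrm{left}|, |\Delta \mathrm{right}|,
|\Delta \mathrm{length}|)}{\min(L_1, L_2)} < CR \cdot m ,$$

with strict inequalities, $F$ and $CR$ per-type tolerances, and $m$ the
haplotype multiplier: $SR \le 1$ when both signatures carry the same tag
(reads of one haplotype face no inter-haplotype interference, so the
condition can afford to be stricter), $DR \ge 1$ when they carry different
tags, and $1$ when either is untagged (the neutral choice for a case the
merge rule does not otherwise specify). Both tolerances are scaled by $m$.
Clusters are the transitive closure (single linkage) of this relation.

Defaults are $F = 500$ bp (600 for INV, whose breakpoints are noisier),
$CR = 0.3$, $SR = 0.8$, $DR = 1.3$ — near the position/size tolerances
common in long-read callers; they are deliberately configurable per type.

The implementation sorts by left position and only tests pairs inside a
sliding window, which preserves the closure exactly: a mergeable pair at
left distance $d$ satisfies $d < F \cdot m \le F \cdot DR$ (first
condition) or $d < CR \cdot m \cdot \min(L_1, L_2) \le CR \cdot DR \cdot
L_i$ (second condition), so comparing each signature to successors within
$\max(F \cdot DR,\, CR \cdot DR \cdot L_i)$ bp loses no edge. A brute-force
$O(n^2)$ closure (built on an adjacency matrix and graph components) ships
as `cluster_signatures_bruteforce()` and the test suite checks equality of
the two on 1,000 randomized signature sets.

## Disunion of mixed clusters

Two nearby variants of the same type and similar size on opposite
haplotypes tend to fall into one cluster. With tags this is detectable: let
$M_i$, $SD_i$ be the mean and standard deviation of signature lengths from
haplotype $i$ within a cluster. When both haplotypes are present and

$$|M_1 - M_2| > \max(SD_1, SD_2),$$

the cluster is disunited into its haplotype-1 and haplotype-2 parts.
Untagged signatures follow the side whose mean length is nearer their own
(ties to haplotype 1) — a nearest-mean rule chosen because length is the
quantity the significance test itself uses. Population standard deviations
(divide by $n$, singleton SD 0) keep the test well-defined for minimal
clusters; disunion is applied once per cluster after clustering, not
recursively.

## Filtering scaled by tagging quality

For a cluster of $N$ signatures, $M$ from tagged reads, $H_1$/$H_2$ per
haplotype, define $H = M/N$ and $HR = \max(H_1, H_2)/M$ ($HR = 0$ when
$M = 0$). The tagging fraction acts as a proxy for the local alignment
quality, so the support thresholds are scaled by

* $H > H_0$, $HR > HR_0$: $SC = 1 - (\mathrm{HomoSF} + \mathrm{HomoSR}(H - H_0))$ — relaxed;
* $H > H_0$, $HR \le HR_0$: $SC = 1 - (\mathrm{NonHomoSF} + \mathrm{NonHomoSR}(H - H_0))$ — the signed parameters encode whether a well-tagged but haplotype-mixed region should be trusted more or less;
* $H \le H_0$: $SC = 1 + (\mathrm{LowHRF} + \mathrm{LowHRR}(H_0 - H))$ — tightened.

$SC$ is affine in $H$ within each branch and equals 1 when all six scale
parameters are 0. $H = H_0$ exactly falls in the third branch (strict
inequalities). A `HomoR` parameter is accepted in configuration for
compatibility but enters no formula. The cluster then passes if, for at
least one of two condition sets $(FF, FR, FS)$, its distinct-read support
is $\ge SC\,(FF + FR \cdot \mathrm{Cov})$ **and** its consistent score

$$1 - \frac{SD(\mathrm{lengths})}{\max(\mathrm{lengths})}$$

is $\ge \min(1, SC \cdot FS)$ — the clamp keeps the score condition
satisfiable when $SC > 1$. Cov is the chromosome's mean depth (summed
reference span of primary alignments over chromosome length). Defaults
($FF{=}2, FR{=}0.2, FS{=}0.55$ / $FF{=}1, FR{=}0.1, FS{=}0.75$;
$H_0 = HR_0 = 0.8$; HomoSF 0.05, HomoSR 0.25, NonHomoSF 0, NonHomoSR 0.1,
LowHRF 0.05, LowHRR 0.25) keep the scale within a few percent of 1 across
realistic $H$, so the haplotype adjustment perturbs rather than replaces
the coverage-proportional filter.

## Genotyping and refinement

Calls report POS and SVLEN as the rounded means of the cluster's signature
positions and lengths (half-away-from-zero, so a mean of 100.5 becomes
101; SVLEN negated for deletions; END = POS + |SVLEN| except for
insertions). Genotype: with $H > H_0$, both haplotypes holding $\ge 20\%$
of tagged signatures is `1/1` and one haplotype holding $\ge 80\%$ is
`0/1`; otherwise the supporting-read fraction support/Cov decides
($\ge 0.75$ `1/1`, $\ge 0.2$ `0/1`, else `./.`). The 20%/80% cuts tolerate
a few mistagged reads while keeping the two configurations separable at
typical depths; `genotype_mode = "allele_fraction"` forces the fallback
rule and exists mainly to quantify what the haplotype rule adds. The VCF
also carries $H$, $HR$ and $SC$ as `HAPF`/`HAPMAJ`/`HAPSC` INFO fields
unless `hap_annotations = FALSE`.

## The synthetic diploid generator

`simulate_truth()` and `simulate_tagged_bam()` build test data with no
external aligner, reference download or read simulator: a random
nucleotide reference, planted SVs (heterozygous on a random haplotype or
homozygous), and constructed alignments written directly as a sorted,
indexed BAM. A read covering a planted SV with at least `flank` (200 bp)
anchor on both sides carries it in its alignment — DEL as a `D` run, INS
as an `I` run, INV as a forward/reverse primary–supplementary pair, DUP as
a split pair whose second segment jumps back by the duplicated length (the
canonical tandem-duplication signature; representing duplications as
insertion runs would make them indistinguishable from insertions at the
signature level and defeat per-type evaluation). Per-read position and
length jitter are normal with configurable SDs; reads are HP-tagged with
their haplotype of origin at `tag_rate`, mistagged at `mistag_rate`. The
random stream consumed per read is identical whether or not tags are
written, so `drop_tags = TRUE` yields byte-identical alignments minus the
tags — the basis of the neutrality comparison below.

Planted SVs are spaced at least one read length apart by default, so every
read supports at most one variant and same-haplotype variants never
overlap; overlapping-haplotype scenarios are built by passing a hand-made
truth table to `simulate_tagged_bam()`. What the simulator does **not**
model: base-level sequencing errors and small indel noise (signature-level
jitter subsumes their effect on SV evidence), alignment artifacts around
repeats, SNVs, and realistic ONT length distributions (reads are
constant-length). Passing tests on this generator therefore demonstrates
the correctness of the signature-to-call machinery under controlled
evidence, not calling accuracy on real ONT data.

## Benchmarking

`sv_benchmark()` mirrors sequence-free truvari matching: a call matches a
truth record iff types agree (DUP–INS cross-matching is off by default,
available as a flag), start distance $\le$ 500 bp and size ratio
$\ge 0.7$; assignment is greedy one-to-one by size similarity then
distance — a documented simplification of truvari's ranking, adequate for
synthetic data. Precision $= TP_{call}/(TP_{call}+FP_{call})$, recall
$= TP_{base}/(TP_{base}+FN_{base})$, $F1 = 2PR/(P+R)$, with $0/0$ defined
as 0. Presence metrics ignore genotypes; GT metrics additionally require
GT equality, so GT-F1 $\le$ presence F1 always. An optional BED restricts
both sets to records whose POS falls in a half-open interval.

## Neutrality: containing the vanilla caller

Setting $SR = DR = 1$ and the six scale parameters to 0 removes the
haplotype influence on clustering and filtering. Two components consume
tags directly and are controlled separately: disunion (disabled in
`neutral_caller_params()`) and the genotyping rule
(`genotype_mode = "allele_fraction"`). With those settings plus
`hap_annotations = FALSE` (the annotations report tag fractions and
necessarily differ), a run on a tagged BAM is byte-identical to the run on
the same alignments with tags stripped — verified in the test suite. This
is the design guarantee that the haplotype-aware layer strictly contains
the vanilla caller.

## Numerical and scale choices

Problem sizes in the tests were chosen so the full suite runs in about a
minute: a 2 Mb single-chromosome genome with 40 planted SVs (10 per type,
50% heterozygous) at depth 20 for end-to-end checks, 1,000 randomized sets
of up to 100 signatures for the clustering oracle, and five seeds of a
noisy configuration (position jitter SD 30 bp, length jitter SD 15 bp, tag
rate 0.85, mistag rate 0.02) for robustness. At depth 20 a heterozygous
variant is supported by roughly Poisson(10) reads; the second filter set
($FF{=}1, FR{=}0.1$) keeps variants with as few as 3 supporting reads, so
clean-data recall is limited only by the far tail of that distribution.
Ties and degenerate cases are fixed explicitly: strict merge inequalities,
population SDs, singleton SD 0, untagged-pair multiplier 1, disunion ties
to haplotype 1, rounding half-away-from-zero, metric $0/0 \to 0$.

## Limitations

Breakpoints are cluster means, not consensus-refined; genotypes are
unphased (`0/1`, never `0|1` with a PS); breakend notation, multi-sample
output and likelihood-based clustering are out of scope. The filter-scale
branch for well-tagged, haplotype-mixed clusters exposes signed parameters
rather than a fitted policy; their defaults are mild. Accuracy figures
from the synthetic generator should be read as upper bounds: real ONT data
adds alignment noise modes the simulator deliberately omits.
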