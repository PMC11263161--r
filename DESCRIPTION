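Package: hapsv
Title: Haplotype-Aware Structural Variant Calling from Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls structural variants (deletions, insertions, duplications,
    inversions >= 50 bp) from coordinate-sorted long-read alignments that carry
    per-read haplotype tags (integer HP aux field, WhatsHap convention).
    SV signatures are extracted from CIGAR operations and split alignments,
    clustered with haplotype-conditioned merge tolerances, disunited when one
    cluster mixes two length-distinct variants from opposite haplotypes, and
    filtered with support thresholds scaled by the haplotype-tagging quality of
    each cluster before genotyped VCF output. The package also ships a
    self-contained synthetic diploid read simulator that writes haplotype-tagged
    BAMs with planted variants, and a sequence-free benchmarking engine
    computing presence and genotype precision/recall/F1 against a truth VCF.
License: MIT
Encoding: UTF-8
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Biostrings,
    vcfR,
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
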