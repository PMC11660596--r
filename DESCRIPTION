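Package: ailhap
Title: Ancestral-Haplotype Mapping in Advanced Intercross Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haplotype-block analysis of admixed advanced intercross line
    (AIL) populations. Partitions phased genotypes into fixed-width SNP
    blocks, computes haplotype diversity (H12/H123/H1234) and
    between-population dissimilarity statistics, infers per-haplotype local
    ancestry against founder panels, builds SNP-, ancestry- and
    haplotype-based relationship matrices, and runs mixed-linear-model
    association scans in SNP, haplotype-combination and ancestral-dosage
    modes. Includes block-wise BLUP estimation of haplotype-allele effects
    with ancestral labels, an ancestry-based dominance scan (Kruskal-Wallis
    with Steel-Dwass post-hoc tests), gene-overlap annotation from GTF, and
    a gene-dropping AIL simulator that provides ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
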