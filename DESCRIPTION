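Package: sdrkit
Title: Detection and Dating of Recombination-Suppressed Sex-Determining Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics and population-genetics toolkit for studying
    deeply conserved sex-determining regions (SDRs) such as the ~200-kbp grape
    SDR. Implements collinear gene block detection between annotated haplotypes
    (MCScanX-style anchor chaining), fixed-size gene-window conservation scoring
    with clade-wise rank normalization, SNP hard filtering, pairwise r2 linkage
    disequilibrium with Hill-Weir decay fitting and 1-kbp LD landscapes,
    homozygous/heterozygous call ratio contrasts, Kimura two-parameter and
    Nei-Gojobori (NG86) synonymous divergence with molecular-clock dating of
    inversions and LTR insertions, promoter extraction with position-weight
    matrix scanning for allele-group-specific binding sites, and synthetic-data
    generators that emulate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
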