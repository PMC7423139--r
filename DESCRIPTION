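Package: hetscope
Title: Detecting Regional Expansion and Collapse in Heterozygous Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diagnostics for de novo genome assemblies of heterozygous
    diploid samples. Allelic regions that the assembler fails to merge
    inflate assembly length and depress read-mapping coverage and apparent
    SNP heterozygosity, while collapsed repeat copies do the opposite.
    hetscope computes whole-assembly summary statistics (N50, length
    cutoffs, genome-wide heterozygosity), quantifies sequence missing from
    and expanded within a test assembly relative to a reference from
    pairwise alignment tables, derives per-region heterozygosity, coverage
    and unique-length ratios against matched reference regions, classifies
    region sets as expanded, collapsed or mixed, and tallies fragmentation
    versus allelic duplication among predicted proteins. A synthetic
    diploid-genome generator with injectable expansion, collapse and
    bubble-fragmentation artifacts provides fully ground-truthed inputs
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
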