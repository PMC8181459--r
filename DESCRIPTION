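Package: ystrpopgen
Title: Forensic Statistics and Population Genetics for Y-STR Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of
    Y-chromosomal short tandem repeat (Y-STR) haplotype tables such as
    PowerPlex Y23 profiles. Computes per-locus allele frequencies and gene
    diversity, haplotype-level forensic parameters (haplotype diversity,
    match probability, discrimination capacity, fraction of unique
    haplotypes), pairwise population R_ST by analysis of molecular
    variance (AMOVA) with permutation p-values, allele-frequency PCA and
    classical multidimensional scaling, neighbor-joining trees from
    distance matrices, and nearest-neighbor Y-haplogroup prediction
    against labeled reference panels. Includes a stepwise-mutation-model
    simulator and generators for haplotype tables realizing prescribed
    occurrence spectra.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
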