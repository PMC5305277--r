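Package: snvauth
Title: Cell Line Authentication from RNA-Seq Variant Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Authenticates cell lines from RNA-seq data by building filtered
    expressed single-nucleotide-variant (SNV) profiles out of annotated
    variant calls and comparing their genotypes against reference (COSMIC
    style) cell-line mutation profiles. Implements the strand-bias /
    quality-by-depth / SNV-cluster / allelic-depth filtering stack,
    coverage and concordance authentication statistics, contaminant
    profile screening, SNP genotyping panel checks, pairwise
    transcriptome-scale profile comparisons, match/mismatch annotation
    characterisation, allele-specific read classification at two proximal
    variant sites, robustness assessment under binomial depth
    subsampling, and a synthetic data generator with controlled ground
    truth for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    Rsamtools,
    GenomicAlignments,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
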