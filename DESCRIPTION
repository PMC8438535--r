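Package: bsascan
Title: Bulked-Segregant Sequencing Scans for Mapping a Dominant Fertility-Restorer Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked-segregant analysis (BSA-seq) of an
    F2 population segregating a single dominant locus, modelled on the mapping
    of a Brassica napus fertility-restorer gene. Computes per-site SNP/InDel
    indices from pooled allele depths, applies the low-index quality filter,
    averages indices in sliding windows, and calls candidate intervals where
    the delta(SNP-index) between sterile and fertile pools exceeds a detection
    threshold. Includes a simulator of F2 bulked-segregant sequencing
    experiments (Haldane recombination, phenotype-selected bulks, Poisson
    depth and binomial allele sampling with sequencing error), chi-square
    segregation-ratio testing with Yates continuity correction, and
    recombinant-count linkage-distance estimation for fine mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
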