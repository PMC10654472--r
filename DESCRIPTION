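Package: domescan
Title: Farmed-Versus-Wild Differentiation Analysis for Gene-Level and
    Pool-Seq Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-track analysis of domestication signatures in farmed and
    wild fish populations, motivated by gilthead seabream and European
    seabass. The gene-level track compares per-population allele and
    genotype frequencies at candidate-gene SNPs (Wilcoxon rank-sum tests,
    exact Hardy-Weinberg checks, binomial logistic models with stepwise
    AIC selection over origin and collection-period factors) and
    calibrates the false-positive rate of farmed-versus-wild tests under
    a Wright-Fisher bottleneck null. The chromosome-level track ingests
    pooled-sequencing base counts, merges technical replicates, calls
    biallelic SNPs under read-depth and minor-allele-frequency filters,
    and scans for differentiated regions with pooled nucleotide-diversity
    FST, Fisher exact and Cochran-Mantel-Haenszel tests,
    Benjamini-Hochberg adjustment, rolling-average tracks and
    gene-neighbourhood annotation. A synthetic-data generator with known
    ground truth makes every stage testable offline, including the
    read-depth resampling simulation used to justify the minimum-depth
    threshold for pooled genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml,
    zoo
Config/testthat/edition: 3
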