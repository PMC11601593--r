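Package: xqtlgxe
Title: Bulk-Segregant X-QTL Mapping and Genotype-by-Environment Analysis of
    Ubiquitin-Proteasome System Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci (QTLs) from pooled
    sequencing of phenotypically extreme segregant pools (X-QTL bulk segregant
    analysis) and for classifying genotype-by-environment interactions (GxE) at
    individual loci. Includes quantification of ubiquitin-proteasome system
    activity from tandem-fluorescent-timer flow cytometry events (forward-scatter
    gating, loess time-detrending of the -log2(RFP/GFP) ratio, mixed-model GxE
    tests), ingestion of pooled allele counts from VCF or TSV, loess-smoothed
    allele-frequency difference tracks, a kernel-weighted binomial
    likelihood-ratio LOD scan with an effective-pool-size information cap,
    2-LOD support intervals, replicate reconciliation, rule-based classification
    of presence/absence and sign-change GxE, and a synthetic-data generator for
    recombinant haploid segregant pools and cytometry events so the whole
    pipeline can be exercised and calibrated in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
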