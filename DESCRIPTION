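Package: rhizogwas
Title: Quantitative Genetics of the Rhizosphere Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking host genetic variation to rhizosphere
    microbial community composition in a diversity panel. Provides broad-sense
    heritability screening of amplicon sequence variants (ASVs) from replicated
    field trials, a mixed-linear-model association engine (EMMA-style
    eigen-rotated REML with P3D Wald scans) shared by GWAS, expression GWAS and
    transcriptome-wide association studies, linkage-disequilibrium based QTL
    interval construction with distant-eQTL hotspot detection, multi-kernel
    cross-validated genomic prediction of ionome traits, Mantel covariation
    tests, and assembly of the ASV-QTL-gene regulatory network. Ships a
    synthetic-data generator emulating the statistical structure of a
    175-genotype replicated field study so the full pipeline runs end-to-end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
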