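Package: gwasoverlap
Title: Cross-Trait Genetic Overlap from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the shared genetic architecture of two traits
    from genome-wide association study (GWAS) summary statistics and a
    linkage-disequilibrium (LD) reference panel.  Implements covariate-adjusted
    per-variant association with standard variant quality control, greedy LD
    clumping into independent significant, lead, and candidate variants and
    merged genomic risk loci, conditional quantile-quantile enrichment curves,
    conditional and conjunctional false discovery rates for cross-trait
    discovery, SNP heritability by average-information REML on a genomic
    relationship matrix, heritability and genetic correlation by LD-score
    regression with block jackknife errors, replication concordance reports,
    and covariate-adjusted case-control volume contrasts with
    Benjamini-Hochberg correction.  A seeded synthetic-data generator produces
    block-LD genotype panels, paired summary statistics under a bivariate
    causal mixture with tunable shared-causal fraction and effect-direction
    concordance, phenotypes with target heritability, and clinical cohorts
    with per-diagnosis volume offsets, so the whole pipeline can be exercised
    end to end without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
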