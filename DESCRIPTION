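Package: insolubilome
Title: Differential Protein Insolubility Analysis for Paired Insoluble-Fraction Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of SDS-insoluble fraction proteomics from paired
    case/control designs, as used to study amyloid-driven and age-related
    protein insolubility in C. elegans. Provides paired t-test differential
    insolubility calling with Storey q-value correction and peptide-count
    and fold-change filters, exact Fisher/hypergeometric protein-set overlap
    testing and core insoluble proteome construction, gene-set
    over-representation with a gene-count times FDR enrichment score,
    a per-protein chronic age-related disease GO biological process sharing
    statistic with Kruskal-Wallis/Dunn group comparisons, biophysical score
    distribution comparisons including supersaturation fold ratios, and
    Spearman-based aging expression trend classification. A synthetic data
    generator with known ground truth (spiked insolubility, planted disease
    sharing, shifted score distributions, planted expression trends) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression,
    GeneSetEnrichment, Software
RoxygenNote: 7.3.3
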