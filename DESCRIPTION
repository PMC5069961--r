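Package: sulfurlim
Title: Dual-Omics Analysis of Sulfur Limitation in Batch Cultures of
    'Ca. Pelagibacter ubique'
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for batch-culture sulfur-limitation
    studies of 'Candidatus Pelagibacter ubique': growth-phase classification
    from a ribosomal marker-gene "growth state" score, transcriptome and
    proteome differential expression with fold-change/significance filters,
    peptide-to-protein fold-change rollup with detection sentinels, per-gene
    mRNA-protein correlation across a time course, and a per-cell sulfur-quota
    mass balance for dimethylsulfoniopropionate (DMSP). Ships a synthetic-data
    generator emulating the study design (nutrient-quota logistic growth,
    condition-by-phase multiplicative expression effects, peptide multiplicity,
    lognormal noise, detection dropout) so every stage is testable end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
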