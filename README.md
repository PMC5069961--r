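# sulfurlim

Dual-omics analysis of sulfur limitation in batch cultures of
*Candidatus* Pelagibacter ubique.

SAR11 bacteria such as *Ca.* P. ubique cannot reduce sulfate and meet their
sulfur quota from reduced organosulfur compounds, chiefly
dimethylsulfoniopropionate (DMSP). `sulfurlim` is a tidyverse-style R package
for the computational side of a batch-culture sulfur-limitation experiment in
this organism — nine cultures on 100 nM (limiting) or 1 µM (control) DMSP,
harvested in exponential, transitioning and stationary phase for simultaneous
transcriptomics and peptide-level proteomics — and for synthetic studies with
the same structure. It is aimed at microbial physiologists and computational
biologists who need a tested, reusable implementation of the analysis rather
than one-off scripts.

## What it computes

* **Growth-state classification.** Per sample, the mean of min–max-normalized
  log2 expression of 21 ribosomal-protein/elongation-factor genes,

  score(s) = mean_g [ (log2 x_gs − min_s log2 x_gs) / (max_s log2 x_gs − min_s log2 x_gs) ],

  clustered into three phases by the exact SSE-optimal 1-D 3-partition and
  used to re-assign mislabelled harvests (`growth_state()`).
* **Differential expression on both layers.** Fold change = ratio of
  arithmetic group means (treatment/reference); two-sided Welch t tests on
  log2 abundances; Benjamini–Hochberg correction per (contrast × layer)
  family; the sixfold any-condition filter, the fourfold stationary-contrast
  filter, and the fivefold-box exponential scatter
  (`diff_expression()`, `table1_filter()`, `table2_filter()`, `fig2_scatter()`).
* **Peptide→protein rollup.** Peptide group means → peptide fold changes
  (with `Inf`/`1/Inf` detection sentinels and `ND` for never-detected
  proteins) → arithmetic mean protein fold change; one-sample t of per-peptide
  log2 folds (`protein_quant()`, `nd_census()`).
* **mRNA–protein correlation.** Per-gene Pearson r of log2 series across one
  culture's five-point time course, stratified by transcript fold-change
  magnitude (`correlate_layers()`, `magnitude_correlation_summary()`).
* **DMSP mass balance.** consumed [nM] = density × 10³ × quota(amol) × 10⁻¹⁸ × 10⁹
  with the 6.67 amol/cell sulfur quota; unaccounted = dose − consumed
  (`consumed_sulfur()`, `unaccounted_dmsp()`, `sulfur_budget()`).
* **A synthetic study generator** (`simulate_study()`) emulating the design:
  nutrient-quota logistic growth, 29 samples over 9 cultures, published
  condition×phase effect sizes, peptide multiplicity, lognormal noise,
  detection dropout. All randomness is seed-driven and the generator's ground
  truth is returned with the study, so parameter recovery is testable.

Results come back as tibbles or as small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods, so everything chains with the pipe.

## Worked example

```r
library(sulfurlim)
library(dplyr)

study <- simulate_study(seed = 1)   # 9 cultures, 29 samples, 1354 loci
fit   <- growth_state(study)        # marker-gene phase classification
glance(fit)
#> # A tibble: 1 × 5
#>   n_samples n_exponential n_transitioning n_stationary n_reclassified
#> 1        29             7              13            9              2

de <- diff_expression(study, state = fit)
tidy(de) %>% filter(locus == "SAR11_1172", comparison == "LE")
#>   locus      layer   comparison  fold sentinel   p_value significant_raw
#> 1 SAR11_1172 mRNA    LE         37.8  finite   0.0000275 TRUE
#> 2 SAR11_1172 protein LE          4.01 finite   0.00487   TRUE

length(table1_filter(de))  # loci with >= sixfold change, p <= 0.05, any condition
#> [1] 19
length(table2_filter(de))  # >= fourfold in the stationary contrast
#> [1] 15

magnitude_correlation_summary(correlate_layers(study))
#>   stratum          n median_r
#> 1 large_change     6  0.838
#> 2 small_change  1342  0.00287
```

The two reclassified samples are the limited cultures harvested late for
their "exponential" time point — the classifier moves them to transitioning.
The planted osmC (SAR11_1172) exponential-phase effect is 50-fold on the mRNA
layer and 4.5-fold on the protein layer; a single 3-vs-4-sample study
estimates them with considerable spread (37.8 and 4.0 here), while averaging
over many generator seeds recovers them to within a few percent. Genes with
large transcript changes correlate strongly with their proteins
(median r 0.84); the rest scatter around zero. Filter counts fluctuate
around the planted 23 and 15 because several published effects sit exactly
on the fold gates; with noise turned off (`noise_model(cv_mrna = 0,
cv_protein = 0, peptide_efficiency_sd = 0, dropout_rate = 0)`) both sets are
recovered exactly.

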