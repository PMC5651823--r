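# nattriad

Analysis of three-condition bulk RNA-seq designs in cancer: healthy tissue
(**H**, from a non-cancer donor cohort), histologically normal tissue
adjacent to a tumor (**A**, NAT) and the tumor itself (**T**), across
multiple tissue types. NAT is routinely used as the "normal" control in
cancer studies, yet it sits in a molecular state between healthy tissue and
tumor; analyzing all three conditions jointly — across cohorts that were
sequenced separately — requires dedicated normalization, batch handling and
statistics. `nattriad` provides that pipeline end to end, together with a
synthetic-data generator with recorded ground truth so that every stage can
be validated.

## What it computes

- **Preprocessing**: abundance filtering (≥10 reads in ≥2 samples),
  upper-quartile CPM normalization, estimation of unwanted-variation
  factors from housekeeping (negative-control) genes by SVD on the
  control-gene residuals, factor removal, and RLE diagnostics.
- **Cross-cohort comparability**: assignment of samples to tissues by
  Pearson correlation with median healthy profiles, and housekeeping-gene
  concordance between cohorts (Pearson on median log2 levels, Spearman on
  per-gene SDs).
- **Differential expression**: per-gene negative-binomial log-linear model
  (variance μ + φμ²) with group indicator, unwanted-variation covariates
  and effective-library-size offset; likelihood-ratio test; a gene is
  called up (U) or down (D) only when Bonferroni p < 0.05, |log2 FC| > 1
  and average log2 CPM > 3, otherwise stable (S).
- **Nine expression models**: the A:H status crossed with the T:A status
  (SS, SU, SD, US, DS, UU, DD, UD, DU). UD — up in NAT vs healthy *and*
  down in tumor vs NAT — is tumor-adjacent specific activation (TASA).
  Within-tissue model enrichment uses observed/expected counts under
  independence with Poisson upper-tail p-values
  P(Pois(λ = expected) ≥ observed).
- **Cross-tissue sharing**: the chance a gene carries a model in ≥ k of T
  tissues under independence is the exact Poisson–Binomial tail
  (dynamic programming over the per-tissue rates q_t); λ = G·tail, and the
  observed shared count is tested against Pois(λ) — the Poisson
  approximation of the Binomial over genes.
- **Signature scoring**: rank-based single-sample enrichment (ssGSEA,
  integrated-difference statistic, weight (N−i+1)^α with α = 0.25) for the
  shared TASA set; preranked GSEA (ES/NES, gene-tag permutation null, FDR)
  for gene-set collections; Mann–Whitney score comparisons with Bonferroni
  correction; Spearman ranking of tumor-side genes against matched NAT TASA
  scores to nominate upstream regulators.
- **Deconvolution**: the tumor-similarity fraction of each sample as the
  exact solution of min ‖x − (1−f)·h − f·t‖² with 0 ≤ f ≤ 1 against the
  per-tissue healthy/tumor mean references.
- **Control comparison**: how tumor DE conclusions change when the control
  is healthy tissue (T:H) versus NAT (T:A) — fold-change correlation, DEG
  counts, overlaps and discordant calls.

The methods vignette (`vignettes/nattriad-methods.Rmd`) documents the
models, parameter choices and the generator's scope.

## Worked example

Simulate a three-tissue triad with planted two-fold effects and 10 shared
TASA genes, run the differential-expression and model stages, and score the
recovered signature:

```r
library(nattriad)

cf <- simulation_config(n_genes = 1000, n_tissues = 3,
                        samples_per_condition = c(H = 20, A = 20, T = 20),
                        n_shared_tasa = 10, min_shared_tissues = 2,
                        effect_log2fc = 2, seed = 42)
sim <- simulate_triad(cf)
counts <- filter_low_abundance(sim$matrix)
counts
#> ExpressionMatrix: 1000 genes x 180 samples [counts]
#>           condition
#> tissue      A  H  T
#>   tissue01 20 20 20
#>   tissue02 20 20 20
#>   tissue03 20 20 20

hk <- sim$truth$housekeeping          # negative-control genes
tissues <- unique(counts$samples$tissue)
deAH <- lapply(setNames(tissues, tissues), function(tt)
  de_contrast(counts, tt, c("H", "A"), controls = hk, k = 1))
deTA <- lapply(setNames(tissues, tissues), function(tt)
  de_contrast(counts, tt, c("A", "T"), controls = hk, k = 1))

models <- assign_models(deAH, deTA)
table(models$model[models$tissue == "tissue01"])
#>  DD  DS  DU  SD  SS  SU  UD  US  UU
#>  20  30  10  10 860  11  10  30  19

model_enrichment(models, "tissue01")[8:9, ]
#>   model observed expected     fold            p
#> 8    UD       10     2.36 4.237288 0.0001765351
#> 9    DU       10     2.40 4.166667 0.0002015413
```

The NAT-specific models are ~4-fold enriched over the independence
expectation: genes significant in both contrasts cluster in the UD/DU
cells rather than spreading over the nine models. Sharing across tissues is
far beyond the Poisson–Binomial null, and the recovered TASA signature
scores highest in NAT:

```r
tasa <- shared_genes(models, "UD", min_tissues = 2)
sharing_summary(models, "UD", thresholds = 2:3)
#>   k observed lambda       fold            p
#> 1 2       10  0.298   33.55705 1.161127e-12
#> 2 3        4  0.001 4000.00000 4.163335e-14

cpm <- uq_cpm(counts)
score <- ssgsea_score(cpm, tasa)
idx <- cpm$samples$tissue == "tissue01"
tapply(score[idx], cpm$samples$condition[idx], median)
#>        A        H        T
#> 346.7136 238.9957 246.3771

sel <- idx & cpm$samples$condition %in% c("A", "H")
compare_scores(score[sel],
               factor(cpm$samples$condition[sel], levels = c("H", "A")),
               correction_factor = 6)
#>   statistic        p_raw       p_bonf significant
#> 1         0 1.450889e-11 8.705333e-11        TRUE
```

The per-tissue medians show the TASA score elevated specifically in NAT
(A) relative to both healthy and tumor, and the Mann–Whitney comparison is
significant after Bonferroni correction for the six per-tissue
comparisons.

`run_pipeline(pipeline_config(...))` chains all stages (including
deconvolution, the T:H vs T:A control comparison and the comparability
checks) and writes TSV/JSON/GMT outputs plus a run manifest; configurations
can live in YAML files via `read_pipeline_config()`.

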