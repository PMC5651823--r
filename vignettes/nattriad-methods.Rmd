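---
title: "Methods: triad analysis of healthy, tumor-adjacent and tumor transcriptomes"
author: "nattriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triad analysis of healthy, tumor-adjacent and tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nattriad)
```

## The problem

Histologically normal tissue adjacent to a tumor (NAT) is routinely used as
the control in cancer transcriptomics, yet NAT is molecularly distinct from
tissue taken from donors without cancer. Quantifying that distinction
requires integrating two cohorts that were sequenced separately — a
healthy-donor cohort and a tumor-project cohort contributing both NAT and
tumor samples — which brings pronounced library-size differences and latent
batch structure that must be handled before any biology can be read out.

`nattriad` implements the complete analysis for such a three-condition
("triad") design across multiple tissue types: normalization and removal of
unwanted variation anchored on negative-control (housekeeping) genes,
negative-binomial differential expression with hard significance gates,
classification of genes into nine expression models, cross-tissue sharing
statistics under an independence null, extraction and single-sample scoring
of the tumor-adjacent specific activation (TASA) signature, two-reference
expression deconvolution, and a head-to-head comparison of tumor
differential expression using healthy versus NAT controls. Every stage is
exercised against a synthetic-data generator that plants known truth.

## Notation and conditions

Within each tissue, samples carry one of three condition labels: `H`
(healthy, from the first cohort), `A` (NAT) and `T` (tumor, both from the
second cohort). Contrasts are directional: `A:H` is NAT over healthy, `T:A`
tumor over NAT, `T:H` tumor over healthy. A gene's status in a contrast is
`U` (up), `D` (down) or `S` (stable); the pair of `A:H` and `T:A` statuses
defines its expression model (`SS` … `UD`), where `UD` — up in NAT relative
to healthy *and* down in tumor relative to NAT — marks TASA and `DU` the
mirrored repression.

## Preprocessing

**Filtering.** Only genes with at least 10 reads in at least 2 samples
enter any analysis. The operation is idempotent and refuses non-count
input.

**Upper-quartile CPM.** Counts per million with a per-sample scale factor:
the 75th percentile (linear interpolation, `quantile` type 7) of the
sample's *non-zero count fractions* (count / library size), normalized to
mean 1 across samples. Computing the quantile on fractions — rather than on
raw counts — makes the normalization invariant to rescaling a sample's
counts by a positive constant; the factors then capture composition
differences only, while the library size itself is divided out once. The
log variant uses `log2(CPM + 1)`; the pseudocount of 1 is a convention
choice and is exposed as an argument.

**Unwanted variation.** Housekeeping genes are assumed free of condition
effects but *not* free of technical structure. Each control gene's log2 CPM
is centered across samples and the first $k$ left singular vectors of the
sample × control-gene matrix are taken as factor scores (orthonormal by
construction). Two uses are supported, and the pipeline deliberately keeps
them distinct:

* as covariates inside the count model of the differential-expression test
  (the default path — it preserves the count-model variance structure);
* subtracted from the log2 matrix (`remove_unwanted`) for diagnostics and
  signature scoring only.

$k$ defaults to 1 — the dominant unwanted factor in a two-cohort
integration is the cohort itself — and is a configuration parameter.
Normalization and factor estimation are performed per tissue and per
condition pair, so each two-group test sees factors estimated on exactly
the samples it compares. The relative log expression (RLE) summary (per
sample: median and IQR of log2 expression minus the gene's median) is the
diagnostic for residual global distortion.

The average log2 CPM used by the abundance gate is computed on UQ-CPM
before factor removal; computing it after removal would make a gate that is
meant to measure raw detectability depend on the estimated factors.

## Differential expression

Per gene, a log-linear negative-binomial model with variance
$\mu + \phi\mu^2$:

$$\log \mu_{gj} = \beta_{0g} + \beta_{1g}\,x_j + \gamma_g^\top w_j + \log(\hat L_j),$$

with $x_j$ the group indicator, $w_j$ the optional unwanted-variation
scores and $\hat L_j$ the upper-quartile–adjusted effective library size.
The group coefficient is tested by a likelihood-ratio test (1 df); the
reported log2 fold-change is $\beta_{1g}/\log 2$, so it is exactly the
quantity the model tested, with no pseudocount. Fitting is iteratively
reweighted least squares vectorized across genes (all genes share one
design matrix), with step-halving on deviance increases and closed-form
solves for designs of up to three columns.

**Dispersion** is estimated by method of moments on library-size-adjusted
counts, pooled across the two groups, floored at zero, and shrunk toward
the 10%-trimmed mean of all per-gene estimates with a prior weight of 30
degrees of freedom. The strong default moderation is deliberate: with a
weak prior the per-gene estimator's sampling variance leaks into the
extreme tail of the likelihood-ratio statistic and inflates the family-wise
error of Bonferroni-gated calls, which this pipeline relies on. With the
prior at 30 df the Bonferroni calls are family-wise calibrated on null
simulations while recovery of two-fold planted effects is unaffected. The
prior weight is a configuration parameter.

**Gates.** A gene is called `U`/`D` only if all three hold: Bonferroni
p-value < 0.05, |log2 fold-change| > 1 (strictly — a planted fold of
exactly 2 sits on the gate boundary), and average log2 CPM > 3. Everything
else is `S`. Bonferroni multiplies by the number of tested genes in that
contrast.

## Nine models, sharing and TASA

Model labels concatenate the `A:H` and `T:A` statuses. Within a tissue,
the expected count of model $XY$ under independence of the two contrasts is
$G\,(n_X/G)(n_Y/G)$; enrichment is reported as observed/expected with a
Poisson upper-tail p-value $P(\mathrm{Pois}(\lambda = \text{expected}) \ge
\text{observed})$.

Cross-tissue sharing uses the per-tissue membership rates $q_t$ on the
common tested-gene universe. The probability that a single gene is a member
in at least $k$ of $T$ tissues is the exact Poisson–Binomial tail, computed
by dynamic programming over the success-count distribution (verified in the
tests against exhaustive $2^T$ enumeration and the Binomial closed form).
The expected number of shared genes is $\lambda = G \cdot \text{tail}$, and
the observed count gets fold $= \text{obs}/\lambda$ and a Poisson
upper-tail p-value — the Poisson approximation of the Binomial over genes.
All Poisson p-values use the upper-tail convention $P(X \ge \text{obs})$.

The shared TASA set is `shared_genes(models, "UD", min_tissues = 3)`;
the threshold is a parameter, with sharing summaries also reported at
$\ge 2$ and $\ge 4$.

Directional consistency of a shared set is the fraction of genes whose
`A:H` log2 fold-change has the same sign in *every* tissue, significance
not required.

## Signature scoring

**ssGSEA.** Per sample, genes are ranked by descending abundance (ties
broken by gene order, which is stable); the score integrates the difference
between the weighted in-set cumulative distribution (steps proportional to
$(N - i + 1)^\alpha$, the descending rank weight, $\alpha = 0.25$) and the
uniform out-of-set cumulative distribution. Using ranks makes the score
invariant to any strictly monotone per-sample transform, so it can be
computed on CPM or log CPM interchangeably. The integrated-difference (sum)
statistic is used, not the maximum deviation — that is the single-sample
convention; an optional across-sample min–max rescaling exists and is off
by default. Per-patient baseline alignment of scores is likewise exposed as
an option rather than imposed.

**Preranked enrichment.** The enrichment score is the maximum deviation of
the running sum with hit increments $|s|^p/\sum_{\text{set}}|s|^p$
($p = 1$) and miss increments $1/(N - n_{\text{set}})$. The null is
gene-tag permutation: `n_perm` random same-size sets (default 1000,
seeded); NES divides by the mean same-sign null |ES|; nominal p-values use
the same-sign tail with a +1 correction (so $p \ge 1/(n_\text{perm}+1)$);
FDR follows the standard pooled positive/negative-null procedure, gated at
1%.

**Group comparisons** of scores use the two-sided Mann–Whitney test with an
explicit Bonferroni correction factor (the number of comparisons in the
family) and a corrected significance threshold of 0.001.

**Regulator ranking.** For subject-matched NAT/tumor pairs, every
tumor-side gene is correlated (Spearman) with the matched NAT TASA scores
and ranked by the coefficient; constant genes are excluded with a warning,
unmatched samples dropped with a warning, and fewer than three pairs is an
error.

## Deconvolution

Each sample profile $x$ is decomposed against a two-column reference (per
tissue: the mean healthy and mean tumor profile on the linear normalized
scale, over the filtered gene universe) as
$\min_f \lVert x - (1-f)\,h - f\,t\rVert^2$ subject to $0 \le f \le 1$.
With two references the quadratic program reduces to one variable and has
the closed-form solution $f = \langle x - h,\, t - h\rangle / \lVert t -
h\rVert^2$ projected onto $[0, 1]$ — exact, deterministic, no iterative
solver. Linear abundance is used because mixing of cell populations is
additive on that scale; identical reference columns are rejected as
unidentifiable. No additional high-variance gene filtering and no quantile
pre-normalization are applied (both are documented toggles of the
surrounding workflow rather than silent defaults).

## The synthetic-data generator

`simulate_triad()` draws negative-binomial counts
($\mathrm{Var} = \mu + \phi\mu^2$, per-gene $\phi$ uniform on
$[0.05, 0.5]$ by default) with:

* per-gene, per-tissue baselines uniform on $[3, 10]$ log2 CPM-like units
  — independent across tissues, which separates tissue profiles by roughly
  2 log2 units SD and makes correlation-based tissue assignment
  well-posed;
* two source cohorts with log-normal library sizes (defaults: meanlog
  $\log 5\times10^6$ vs $\log 2\times10^7$, sdlog 0.25) — healthy samples
  from the first, NAT/tumor from the second, reproducing the confounding
  of cohort with condition that motivates control-gene factor removal;
* latent factors loading on **all** genes (loadings $N(0, 0.3)$ per log2
  unit, scores $N(0, 1)$ with a configurable mean shift between cohorts):
  housekeeping genes are clean of condition effects only, exactly the
  negative-control contract the factor estimation exploits;
* housekeeping genes with a single baseline across tissues (stably
  expressed by definition) and no condition effect anywhere;
* planted condition effects on the log2-mean scale, symmetric for U/D,
  distributed over the eight non-null models at configurable per-tissue
  proportions, restricted to genes with baseline ≥ 5.5 so that planted
  signal lies in the regime the abundance gate declares detectable;
* a set of shared TASA genes planted as UD in at least `min_shared_tissues`
  tissues each;
* per-NAT-sample mixing fractions $m_s$ (uniform on $[0.35, 0.65]$) that
  place gradient-model (UU/DD) and null genes at the convex combination
  $(1-m_s)\log_2\mu_H + m_s\log_2\mu_T$ of the healthy and tumor log2
  means. Interpolating on the log scale keeps the two planted contrasts
  symmetric — a *linear* mixture is asymmetric in fold-change (a strongly
  down-regulated tumor component moves the mixture by barely
  $\log_2(1-m)$), which would make planted DD labels systematically
  unrecoverable under the fold gate. NAT-specific (UD/DU) and one-sided
  (US/DS/SU/SD) models are planted directly so their truth labels stay
  exact and TASA genes are not diluted by construction.

`simulate_matched_pairs()` is the single-tissue variant with
subject-matched NAT/tumor samples: one well-expressed null gene is the
designated driver; its tumor-side log2 mean varies by a subject effect
$z_i \sim N(0,1)$, and the subject's NAT-side TASA effect sizes are scaled
by $\max(0,\, 1 + \text{driver\_effect}\cdot z_i)$, so the tumor driver
level linearly modulates the NAT TASA signature.

Reproducibility: one global stream keyed by the seed draws the shared
quantities (gene roles, loadings, dispersions), then per-tissue
sub-streams are derived deterministically from it, so identical
configurations are bitwise reproducible.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: read-level artifacts (no FASTQ, no mapping
bias), gene–gene correlation beyond the shared latent factors, GC/length
effects, isoform switching, outlier samples, cell-type composition shifts
(NAT "intermediacy" here is a mean-expression property, not a mixture of
cell populations), and microarray noise for external validation cohorts.
Effect-size distributions of real DEGs are unknown; the planted default of
$|\mathrm{log_2 FC}| \in [1, 3]$ is an implementer's choice and is
config-exposed.

## Numerical choices and degenerate inputs

* Upper-quartile on non-zero fractions, `quantile` type 7 — bit
  reproducible.
* Strict inequalities on both the fold-change and abundance gates
  (borderline genes are `S`).
* IRLS: deviance-based convergence ($10^{-10}$ relative), maximum 50
  iterations, $\eta$ clamped to $[-30, 700]$ to keep separated genes
  finite, step-halving on deviance increase.
* Ties in tissue assignment break on panel order with a warning; ties in
  ranks use stable gene order; Spearman uses average ranks for tied values.
* Constant genes: excluded from co-expression and regulator ranking with a
  warning (correlation undefined), reported as NA rows where a matrix shape
  must be preserved.
* Zero-expected model cells with positive observed counts report infinite
  fold with a flag instead of failing.
* All-zero samples, empty gene-set intersections, singular designs
  (covariate collinear with the group) and insufficient matched pairs are
  errors with actionable messages.

## Problem sizes used by the test suite

The suite validates statistical properties at desk scale: 2000 genes, four
tissues, 30 samples per condition for recovery and scoring properties; 2000
genes, 20 per group, $\phi = 0.2$ for null calibration (20 seeds for the
family-wise check); 200 matched subjects for driver ranking (20 seeds, plus
50 small-scale null seeds); 100 replicates for enrichment-fold calibration.
These sizes give the Monte-Carlo bands stated in the tests while keeping
the default run in minutes.

## Known limitations

* The likelihood-ratio $\chi^2$ approximation is slightly liberal at small
  group sizes; the strong dispersion moderation compensates in the
  Bonferroni tail, but exact small-sample NB tests and quasi-likelihood
  F-tests are out of scope.
* Factor estimation assumes the unwanted structure is visible in the
  control genes; an artifact orthogonal to the controls will not be
  removed.
* The deconvolution is two-component by design; it estimates similarity to
  the tumor mean profile, not cell-type composition.
* Sharing statistics assume independence across tissues under the null;
  genes co-regulated across tissues for reasons other than the planted
  signal will inflate the fold.
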