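---
title: "Screening DNA methylation for epigenetic supersimilarity and systemic interindividual variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening DNA methylation for epigenetic supersimilarity and systemic interindividual variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essiv)
```

## The biological model

Most interindividual variation in CpG methylation is either tissue-specific
or driven by local genotype. A distinct class of loci -- metastable
epialleles -- acquires its methylation state *stochastically in the
cleavage-stage embryo* and maintains that state systemically through
differentiation. Two array-scale signatures identify such loci, and this
package implements the screens for both:

* **Epigenetic supersimilarity (ESS).** Monozygotic (MZ) twins split from a
  single zygote *after* such a state is established, so they share it;
  dizygotic (DZ) twins arise from two zygotes and do not. If methylation
  were purely genetically determined, DZ twins (identical by descent at half
  their haplotypes) should be at most twice as discordant as MZ twins.
  Probes where MZ concordance exceeds that genetic bound are
  "epigenetically supersimilar".
* **Systemic interindividual variation (SIV).** At the same loci, unrelated
  individuals differ substantially in methylation, but the different germ
  layers of one individual do not -- the state was set before gastrulation.

## The statistics, stage by stage

**Twin concordance (`ess_screen`).** Discordance of a pair set at probe
$i$ is the mean squared error from the line of identity,
$\mathrm{MSE}_i = \frac{1}{n}\sum_{j=1}^{n} (\beta_{ijA} - \beta_{ijB})^2$.
MZ and DZ MSEs are normalized by the MSE of randomized pseudo-pairs (RZ)
drawn from the pooled twin population, which represents the discordance of
unrelated individuals. A probe is classified ESS when

* normalized DZ MSE / normalized MZ MSE $> 2$ (strictly; this is the
  genetic bound),
* the interindividual $\beta$ range (max $-$ min over the pooled
  population) $> 0.4$ (probes below that are typically unmethylated
  everywhere and uninformative), and
* normalized MZ MSE $\le 0.5$ (probes discordant even within MZ pairs are
  excluded).

A probe with zero MZ MSE but discordant DZ pairs has an infinite ratio and
is maximal ESS; a probe with zero MSE in both classes carries no signal and
is not flagged. `mse_distribution_stats()` quantifies the population-level
signature: normalized DZ MSEs are approximately normal, while an excess of
probes far *below* the MZ mean (left skew, tested one-sided with the
moment-based D'Agostino transformation) marks supersimilarity. Note that a
perfectly symmetric sample gives $p = 0.5$ under this one-sided test --
absence of evidence for left skew, not evidence of symmetry.

**SIV screen (`siv_screen`).** On an individuals $\times$ tissues panel,
interindividual variation is the range of per-individual cross-tissue mean
$\beta$, and tissue-specific variation the range of per-tissue means. A
probe is SIV when interindividual variation $> 0.2$ (strictly) and
tissue-specific variation is $< 1/3$ of it. Negative controls
(`select_negative_controls`) invert the logic: comparable interindividual
range ($> 0.4$) but MZ/RZ MSE $> 0.5$ and tissue variation at least twice
the interindividual variation. The targeted validation call
(`intertissue_correlation_call`) declares a region systemic when the
inter-tissue Pearson correlations across individuals give $R^2 > 0.50$; by
default *all* tissue pairs must pass, because "systemic" semantically
requires concordance across every germ layer (an `all_pairs = FALSE`
relaxation is provided, since a single-pair reading is also defensible).

**Enrichment (`enrich_test`).** All probe-set enrichment uses an explicit
caller-supplied background -- there is no implicit universe. The
chi-squared (no continuity correction; intended uses have large counts) and
Fisher tests always partition the background into set and non-set probes.
The fold can be taken against that complement ("relative to all other
probes passing the filter") or against the whole background ("relative to
all probes on the array"); both conventions are standard and the choice is
explicit via `fold_base`.

**Genotype association (`mqtl_regression`, `variance_heterogeneity`).**
Methylation QTL are assessed by ordinary least squares on additive allele
counts; the model $R^2$ estimates the fraction of methylation variance
explained by the SNP. Genotype effects on *variance* -- the signature of
genotype-dependent metastability, where one haplotype pins the epigenotype
and the other permits the stochastic draw -- are tested with Bartlett's
test, by default across whichever classes are supplied (the pipeline
convention is to compare the two homozygote classes). Externally estimated
variance-explained values are consumed as `beta_snp` and flagged
"substantial" when strictly $> 0.33$; the internal $R^2$ is labelled
distinctly so the two are never conflated.

**Season-of-conception EWAS (`soc_scan`).** Conception season is assigned
from conception dates (or birth dates minus a configurable 280-day
gestation): February--April is the peak dry season, July--September the
peak rainy season, all else excluded. Each probe is fit by Huber
M-estimation (tuning constant $1.345 \times$ the MAD-based scale, the
standard 95%-efficiency choice; via `MASS::rlm` with tolerance $10^{-8}$
and up to 50 iterations) of $\beta$ on season plus the covariate columns of
the design (sex, methylation principal components, cell-type proportions --
the package consumes these as columns and does not compute PCA or
deconvolution). Coefficient p-values use a normal reference on the robust
t-statistics. Benjamini--Hochberg FDR is applied across all tested probes
and probes with $q < 0.10$ are season-of-conception differentially
methylated probes (SoC-DMPs).

**Cluster-level cancer-risk framework (`cluster_permutation_test`).**
Probes are chained into clusters when consecutive positions are within 500
bp (inclusive), keeping chains of at least two. Per probe, M-values
($M = \log_2 \beta/(1-\beta)$) are rank-normalized in ascending order
(plain average-tie ranks, no quantile mapping) and associated with case
status by conditional logistic regression on the 1:1 matched pairs --
equivalently, intercept-free logistic regression of a constant positive
outcome on within-pair (case $-$ control) differences; covariates constant
within every pair drop out of the conditional likelihood. Two cluster
events are assessed: (i) the number $N$ of probes significant at
$p < 0.05$ with concordant coefficient signs (operationalized as the larger
same-sign count) together with the minimum probe $p$; and (ii) the
recurrence -- the number of cancer types with $N \ge 2$ -- across types.
The null distribution keeps the pairing but independently swaps each
pair's case/control labels with probability $\tfrac12$ (a sign flip of that
pair's difference row); p-values use the add-one estimator
$(r+1)/(n_{\mathrm{perm}}+1)$, which never returns zero. Significance is
declared by BH FDR $< 0.25$ across the ten most CpG-rich clusters, within
each cancer type.

### Why the permutation engine uses the score test

The Wald test of the conditional-logistic MLE is undefined under
separation -- and separation is *routine* exactly where the framework
should fire: a strongly affected cluster in a modest number of pairs can
make every within-pair difference one-signed, sending the MLE to infinity.
Treating those probes as missing would silently erase the strongest
signals from the cluster events. The permutation engine therefore scores
probe-level significance (observed and permuted assignments alike) with
the Rao score test of the same conditional likelihood, with nuisance
covariates profiled out under the null: it is always defined,
asymptotically equivalent to the Wald test away from separation, and --
because the permutation p-value compares like with like -- exact under the
within-pair exchangeability null regardless of the statistic's small-sample
calibration. It is also what makes 20,000 permutations cheap: with no
covariates the information is invariant under sign flips and all
permutations reduce to one matrix product; with covariates each permutation
costs one small Newton fit plus closed-form algebra. The exported
regression interface (`clr_fit`, `probe_associations`) still reports the
Wald fit, with separation flagged and `NA` estimates, since that is the
natural contract for a regression.

## The synthetic cohorts

Every stage is validated against generators that embody the establishment
model; their defaults are the package's study conditions.

* `simulate_twin_cohort()`: loci draw states from a trimodal distribution
  (`{0.1, 0.5, 0.9}` with weights `{1/4, 1/2, 1/4}` -- the three-state
  pattern a bistable epiallele shows in a two-allele population).
  `EARLY_STOCHASTIC` loci draw once per zygote; `LATE_STOCHASTIC` per
  individual; `GENETIC` loci map allele count additively onto the state
  range, with DZ co-twins sharing each haplotype independently with
  probability 1/2 (per-locus, ignoring linkage -- the screens are
  per-probe); `GENETIC_METASTABLE` loci behave stochastically except that
  the major-allele homozygote is pinned at the top state (one genotype
  suppresses metastability). Measurement noise is additive Gaussian on the
  beta scale, sd 0.03 by default (pyrosequencing-scale technical error),
  clipped to $[0,1]$. Establishment is treated as perfectly maintained;
  all within-class noise is measurement noise.
* `simulate_multitissue_panel()`: 4 individuals $\times$ 3 tissues by
  default; systemic loci assign individuals evenly spaced offsets spanning
  `effect` (default 0.4) so the parameter *is* the noise-free
  interindividual range, tissue-specific loci do the same across tissues,
  and noise is sd 0.02.
* `simulate_soc_cohort()`: 128 children, half conceived in each season;
  affected loci gain `seasonal_delta` (default 0.05) in rainy-conceived
  samples. The residual sd defaults to 0.08: unrelated individuals at
  variably methylated CpGs differ far more than array noise alone, and this
  scale gives the 0.05 design realistic rather than degenerate power. Sex
  and two continuous nuisance covariates are generated with small per-locus
  effects so the adjustment is exercised.
* `simulate_matched_casecontrol()`: 1:1 matched pairs over 10 three-probe
  clusters; affected clusters shift cases by `delta` (default 1) on the
  latent M scale, concordantly across the cluster. BMI, smoking, alcohol
  and six leukocyte proportions are generated per sample with nuisance
  effects on methylation, so the conditional model has real confounding to
  remove; the six proportions sum to one and the fitter drops the
  dependent column of their within-pair differences automatically.

What the generators deliberately do **not** emulate: array batch and probe
chemistry artifacts, linkage disequilibrium across loci, cell-composition
shifts correlated with exposure, and imperfect somatic maintenance of the
established state. Passing the recovery tests therefore demonstrates that
the statistics recover the model's structure at realistic noise levels --
not that the pipeline is robust to every failure mode of real array data,
whose preprocessing is out of scope here.

## Numerical choices and degenerate inputs

* $\beta$ values of exactly 0 or 1 are clamped to $[\varepsilon,
  1-\varepsilon]$, $\varepsilon = 10^{-6}$, before the M-transform
  (configurable; disabling clamping makes boundary values an error).
  Out-of-range values beyond $10^{-9}$ always raise -- nothing is silently
  clipped on input.
* Missingness: a pair contributes to a probe only when both members are
  observed; probes with fewer than 10 complete pairs in a twin class are
  flagged low-support. The tissue panel excludes probes with any missing
  value by default (an option averages over available tissues instead).
* Variance ranking uses the population (divide-by-$n$) variance over the
  pooled twin samples; ties in the top-fraction cut are broken by probe ID
  so the selection is deterministic. The beta range is likewise computed on
  the pooled MZ+DZ population, and the top-variance cut is computed on the
  same pooled population as the ranges.
* One RZ pairing is the default normalization (a single randomization,
  seeded); `k_rz` averages several re-pairings for variance reduction.
* Constant responses in `robust_fit()` return zero slopes with `NA`
  p-values rather than erroring; non-convergence is flagged per probe and
  the probe keeps an `NA` p.
* Conditional-logistic fits standardize columns internally (Newton-Raphson
  is affine-equivariant, so estimates are unchanged) and detect separation
  scale-freely from the fitted probabilities.
* `classify_ess`/`classify_siv` treat `NA` records as negative calls, never
  as errors, so screens run to completion on partially missing tables.

## Problem sizes used by the test suite

The suite validates parameter recovery at the design scale of the screens:
a 1000-locus twin cohort of 100 MZ + 160 DZ pairs, the default 4 x 3
tissue panel with 500 loci, a 128-child seasonal cohort of 1000 loci with
50 affected, and matched case-control studies of 8-50 pairs with 20,000
permutations for the exhaustive-enumeration comparison and 399 per seed
for the 50-seed null calibration. These sizes keep every oracle comparison
(brute-force MSE, hypergeometric enumeration, exhaustive 256-assignment
permutation) exact while the whole suite completes in about a minute.

## Known limitations

* The ESS screen's genetic bound (DZ/MZ $\le 2$ under pure genetic
  determination) fails in additive-model regimes with very small
  measurement noise: a perfectly heritable locus has near-zero MZ MSE and
  the ratio diverges. The simulator exposes this -- `GENETIC` loci are
  routinely classified ESS at low noise -- which is why mQTL filtering
  (`flag_substantial_mqtl`) is a required companion step before calling a
  probe a candidate metastable epiallele.
* Permutation p-values are bounded below by $1/(n_{\mathrm{perm}}+1)$;
  with 20,000 permutations and FDR 0.25 over ten clusters this is ample,
  but rank-based selection among many clusters needs more permutations.
* BH FDR control is a statement about the *expectation* of the false
  discovery proportion. At $q < 0.10$ with ~50 discoveries, a handful of
  false DMPs is the expected behaviour of a correctly calibrated scan, not
  a defect; single-digit false-positive counts fluctuate accordingly from
  seed to seed.
* The SoC model consumes covariates as given; principal components and
  cell-type proportions must be computed upstream.
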