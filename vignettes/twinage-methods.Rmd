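---
title: "Models and methods behind twinage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twinage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinage)
```

## The scientific problem

Chronological age reshapes the transcriptome in several distinct ways: the
*mean* expression of a gene can drift up or down; the *population variance*
of its expression can widen or narrow; and genetically identical
(monozygotic, MZ) co-twins — who also share their age — can become more or
less *discordant*, which isolates non-shared environmental causes. On top
of these marginal changes, the *genetic regulation* of expression can
itself be age-dependent (genotype-by-age, GxAge, interactions at cis
eQTLs), as can the coupling between promoter methylation and expression.

A twin cohort is the one design in which these strands can be separated:
the MZ/DZ covariance contrast identifies additive-genetic (A),
common-environment (C) and unique-environment (E) variance; co-twins
sampled at the same visit share their exact age; and within-MZ-pair
differences are environmental by construction. `twinage` implements the
full analysis path for such a cohort, together with a synthetic cohort
generator carrying known ground truth, so that every stage is verifiable
without access to controlled individual-level data.

## Input model and normalization

Expression arrives as a feature-by-sample count matrix (features are exons
or splicing links; every feature maps to one gene) with a BED-like
annotation carrying the gene, strand and TSS. Genes whose count entries
are more than 10% zero are flagged and removed; columns are scaled to a
common library size (default $10^7$ reads); each feature is then mapped
through the rank-based inverse-normal transform
$$x_i \mapsto \Phi^{-1}\!\left(\frac{r_i - 1/2}{n}\right),$$
with average ranks for ties. The offset $1/2$ is symmetric and keeps the
extremes finite; the exact offset convention is exposed as an argument.
Coordinates are 0-based half-open internally; VCF positions are converted
at the boundary.

## The twin mixed-model engine

All mean-level inference runs through a linear mixed model whose
covariance is block-diagonal over families. We work with the marginal
form: each sample has variance $\sigma^2$, and co-twins are correlated
with $r_{MZ}$ or $r_{DZ}$ according to zygosity (this is the marginal
equivalent of family plus MZ-pair random intercepts; technical grouping
factors such as primer index can be added through the generic crossed
random-intercept engine `fit_lmm()`). For fixed correlations the fixed
effects and $\sigma^2$ have closed-form profiled estimates via the
within-pair sum/difference rotation, so the likelihood is a function of
one or two correlations only; these are optimised by Nelder–Mead on
logistic-transformed parameters with a relative-tolerance of $10^{-8}$
and deterministic starting values ($r = 0.2$). The block likelihood is
tested against a dense multivariate-normal evaluation (agreement to
$10^{-8}$) and against `lme4` on the same data (log-likelihood agreement
to $10^{-5}$).

Age effects on the mean are tested by maximum likelihood: the model with
and without age is fitted, and $2\Delta\ell$ is referred to
$\chi^2_1$ (negative values are clipped to zero). Under a fully null
simulated cohort the statistic is indistinguishable from $\chi^2_1$
(Kolmogorov–Smirnov).

Two residual types serve the downstream analyses:

* **conditional residuals** remove the fixed effects *and* the BLUP of
  the pair-shared component — used where family structure must be gone
  from the values themselves (the interaction scans);
* **marginal residuals** remove only the GLS fixed effects, with the
  familial covariance used to weight the fit — used by the variance
  analysis (next section).

Conditional residuals of any mixed model carry negative within-pair
correlation (the BLUP over-subtracts the shared part), which is why the
interaction scans pair them with twin-aware permutations rather than
sample-level ones.

## Permutation-based multiple testing

Genes with many exons get more chances to produce an extreme statistic.
The empirical adjustment therefore works at the gene level: the observed
gene statistic is the maximum over the gene's features; ages are permuted
while keeping twin pairs together (pairs exchange ages only with pairs,
singletons with singletons, so co-twins always keep identical ages); per
permutation the same gene-level maxima are recomputed; and nulls are
pooled within (up to) 16 quantile strata of exons-per-gene, with
$$p_{adj} = \frac{1 + \#\{\text{pooled null} \ge \text{observed}\}}
                 {1 + \text{pool size}}.$$
Defaults: 100 permutations, $\alpha = 0.05$, features inherit their
gene's call. Under the null, one-exon and thirty-exon genes reject at
the same rate — the point of the stratification.

## Age effects on expression variance

The dispersion statistic is deliberately simple: a LOESS curve (span
0.75, degree 2) of the expression residuals on age absorbs any smooth
age trend in the mean; $d_i = \sqrt{|e_i - \widehat{loess}(age_i)|}$ is
a variance-stabilised distance from the trend; and the two-sided
Spearman correlation of $d$ with age measures dispersion change, its
sign giving the direction. Because only ranks of $d$ and age enter, the
statistic is invariant to residual shifts and to affine transformations
of age. A mean-only age trend does not trigger it.

The input residuals are **marginal**: the technical covariates are
removed by GLS under the twin covariance, but the pair-shared component
is *not* subtracted. Subtracting its BLUP would remove almost exactly
the pair-shared dispersion changes this analysis exists to find — the
retained fraction of a shared component after BLUP removal is
$\left(\tfrac{1-r}{1+r}\right)^2$, essentially zero at realistic twin
correlations. Familial dependence is instead handled where it matters
for inference: the permutation null moves twin pairs as units, so the
adjusted p-values are calibrated in cohorts with strong family effects.

## MZ co-twin discordance

For complete MZ pairs and each feature, the two co-twin residuals
(technical covariates removed; family structure deliberately retained —
the within-pair contrast is the signal) are ordered into
$(\max_i, \min_i)$, and we fit
$$\max_i = \alpha + \beta\,\min_i + \gamma\,age_i +
           \delta\,(\min_i \times age_i) + \varepsilon_i .$$
$\gamma$ asks whether the max/min relationship is conditional on age —
whether co-twins drift apart (or together) as they grow older. Two
refinements keep $\gamma$ specific to *non-shared* divergence:

* the $\min \times age$ interaction absorbs changes in the max-on-min
  *slope*, which arise when a pair-shared component changes variance
  with age (without the term, those changes leak into $\gamma$ through
  the nonzero mean of $\min$);
* the t-statistic uses an HC3 sandwich standard error, because shared
  variance trends make the regression residual variance a function of
  age.

$\min$ enters uncentred; centring moves the evaluation point of the age
main effect into a region where the two known residual artifacts (see
*Limitations*) reinforce instead of cancel. Multiple testing uses
pair-level age permutations with the same stratified pooling as above.
On simulations, divergence injected into the non-shared component is
detected with high power, while the same variance trajectory injected
as pair-shared shifts is not called — while the variance test still
fires — reproducing the design logic that within-MZ-pair differences
must have an environmental, non-shared cause.

## ACE(+age) variance decomposition

Per feature, REML over the twin-block covariance with MZ within-pair
covariance $\sigma^2_A + \sigma^2_C$, DZ
$\tfrac{1}{2}\sigma^2_A + \sigma^2_C$ and total
$\sigma^2_A + \sigma^2_C + \sigma^2_E$, with age as a fixed effect. The
fit is performed on the correlation scale and mapped back
($\sigma^2_A = 2(r_{MZ} - r_{DZ})\sigma^2$, etc.); when the
unconstrained optimum implies a negative component the model is
refitted on the corresponding boundary ($r_{MZ} = r_{DZ}$ for
$A = 0$; $r_{DZ} = r_{MZ}/2$ for $C = 0$), so components are
non-negative by construction. The age share is put on the same scale as
the ACE components via
$\sigma^2_{age} = \hat\beta^2_{age}\,\mathrm{Var}(age)$;
$h^2 = \sigma^2_A / \text{total}$ and
$PVE_{age} = \sigma^2_{age} / \text{total}$. Both zygosities must be
present (a single zygosity cannot separate A from C). Note that the
constrained REML estimate differs from moment-based (Falconer)
estimates by $O(n^{-1/2})$ even at thousands of pairs, because the model
pools one total variance across zygosity groups while per-group
correlations standardise separately; the two agree asymptotically but
not digit-for-digit in finite samples.

## Interaction scans

**GxAge.** For each eligible feature (those with an age effect on mean,
variance or discordance), all variants within TSS $\pm$ 1 Mb (boundary
included) and MAF $\ge 0.05$ are tested with
$y = \beta_0 + \beta_1 g + \beta_2\,age + \beta_3\,g \times age$ on
conditional residuals. Significance of $\beta_3$ is assessed against a
residual-permutation null: per (feature, variant), the main-effects
model's residuals are permuted (10 times by default) and refitted with
the interaction model. Two aspects of the permutation are deliberate:
the *same* index permutations are applied to every pair (preserving the
dependence between tests that share a feature or gene), and the
permutations move twin pairs as blocks (preserving the within-pair
correlation of conditional residuals). Nulls are pooled per gene across
its feature–variant pairs with exon-count stratification; a
Benjamini–Hochberg step across features gives the final 5% FDR call.
With only 10 permutations, resolution comes from the pooling, not the
permutation count.

**Methylation-by-age.** For genes passing a variance-age prescreen
(nominal $p < 0.1$ by default), each probe mapped to the gene is tested
with $y = \beta_0 + \beta_1 m + \beta_2\,age + \beta_3\,m \times age$
on residualized expression and methylation; the interaction is called
significant when $p < 10^{-4}$ — a fixed Bonferroni-style threshold,
strict inequality, taken as configurable rather than re-derived.

## Cross-tissue sharing (Storey's $\pi_1$)

Features significant in a discovery tissue have their nominal p-values
extracted in a replication tissue;
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))$ is computed on
$\lambda = 0.05, 0.10, \ldots, 0.95$, smoothed with a cubic smoothing
spline (df = 3) and evaluated at the largest $\lambda$; $\pi_1 = 1 -
\hat\pi_0$, clipped to $[0, 1]$. A bootstrap-MSE selector is available
as an alternative. The resulting discovery-by-replication matrix is
directional and need not be symmetric. When the alternative p-value
distribution has mass near 1 (e.g. weak signals), $\pi_1$ is biased
slightly towards zero — inherent to the estimator, not the
implementation.

## The synthetic cohort generator

`simulate_cohort()` produces the study conditions every verification
runs under: female twin pairs with ages drawn uniformly on 39–85 years,
co-twins sampled at identical ages (same visit), an MZ:DZ ratio of
roughly 1:1.5 (default 84 + 130 pairs, a half-scale registry), and
per-gene effect profiles with:

* an ACE-structured latent signal (MZ covariance
  $\sigma^2_A + \sigma^2_C$, DZ $\sigma^2_A/2 + \sigma^2_C$), exons of
  a gene sharing the gene-level signal plus exon-level unique noise;
* a linear age effect on the mean (`beta_age`, sd units per year,
  centred at the range midpoint);
* `var_slope`: a multiplicative change of the *pair-shared*
  environmental sd per year — population variance changes with age
  without separating co-twins;
* `discordance_slope`: non-shared noise whose sd grows linearly from
  the youngest age — separates co-twins *and* adds variance;
* optional cis SNP main and SNP-by-age effects, with genotypes
  transmitted through simulated parental haplotypes (MZ co-twins share
  genotypes exactly; DZ co-twins share each parental allele with
  probability 1/2, giving the exact IBD distribution);
* optional methylation probes (Beta(2,2) marginals) with
  methylation-by-age interaction effects.

Counts are produced by mapping the latent Gaussian signal through
`exp()`, scaling columns to the library size and Poisson sampling;
technical covariates (insert size, GC content, batch) shift the count
scale and are removed again by the pipeline. The noise-free latent
matrix is kept in the ground truth. Because library scaling divides out
per-sample common factors, a mean-age shift applied to *every* gene
largely cancels — as in real data, cohort-wide shifts are not
identifiable from relative counts — so power simulations embed effect
genes in a null background.

What the generator does **not** emulate: read-level sampling (no
FASTQ), isoform structure behind splicing links, linkage
disequilibrium between variants, realistic batch confounding,
non-Gaussian environmental shocks, or population stratification.
Passing the verification suite therefore demonstrates statistical
correctness and calibration of the machinery under the twin design —
not robustness to every artefact of a real sequencing study.

## Numerical choices and degenerate inputs

* Every stochastic step takes a seed; the same seed reproduces results
  bit-for-bit, and seeded code restores the caller's RNG state.
* Constant features are dropped with a message (the rank transform is
  undefined); monomorphic variants are skipped and counted; exact
  linear fits return a zero statistic rather than dividing by a zero
  variance; non-identifiable variance components in the generic engine
  are set to the zero boundary by an explicit likelihood tie-break.
* Validation errors name the offending file, sample or field; readers
  reject rather than coerce.

The verification suite uses cohorts of 100+100 pairs with 200 genes for
calibration checks, 1000 single-exon genes for the LRT distribution,
1000+1000 pairs for the ACE decomposition, n = 600 for the
power simulations, and 500 one-exon plus 500 thirty-exon genes for the
stratification fairness check — sizes chosen so the full suite runs on
a laptop-class single core in minutes while leaving Monte-Carlo noise
well inside the asserted tolerances.

## Known limitations

* **Rank transform vs marginal variance growth.** The inverse-normal
  transform fixes the marginal distribution per feature. When the
  population variance grows with age, old samples occupy the tails of
  the mixture, where the transform's slope is small — so within-pair
  distances shrink slightly at old ages on the analysis scale. Under
  extreme pair-shared variance growth this can leak a small
  *decreasing*-discordance signal; the interaction term and robust SE
  reduce but cannot fully remove it.
* **BLUP attenuation.** Conditional residuals attenuate any signal that
  is itself family-shared — including the cis-genetic component probed
  by the GxAge scan (MZ co-twins share dosage). Estimated interaction
  effects are therefore conservative in magnitude.
* **Estimator differences.** REML variance components and moment-based
  twin estimates (Falconer) agree asymptotically but differ at
  realistic sample sizes (see above).
* The LOESS span/degree are fixed defaults (0.75 / 2), exposed as
  arguments; very small cohorts (n < 30, or < 10 distinct ages) are
  rejected rather than smoothed.

## A minimal run

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(
  n_mz_pairs = 25, n_dz_pairs = 25, n_genes = 20, seed = 1))
res <- run_all(co, run_config(n_perm = 50, min_mz_pairs = 10, seed = 1),
               out_dir = tempfile("twinage_run"))
res$age_mean
res$heritability[1:3, c("feature_id", "h2", "pve_age")]
```
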