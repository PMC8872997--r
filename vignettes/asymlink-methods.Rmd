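---
title: "Linking polygenic risk to multivariate brain asymmetry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking polygenic risk to multivariate brain asymmetry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

asymlink implements a complete analysis chain for asking whether common
genetic liability to a psychiatric disorder, summarized per person as a
polygenic risk score (PRS), is associated with the multivariate pattern of
left--right structural brain asymmetry — and whether two such risks share a
pattern, whether either pattern resembles average sex differences, and what
else in a deep phenome the scores relate to. This vignette explains each
statistical component, the assumptions behind it, and the design choices
the package makes where more than one reasonable implementation exists.

```{r setup, message = FALSE}
library(asymlink)
library(dplyr)
```

## The asymmetry index and its preprocessing

For each paired regional measure (cortical surface area, cortical
thickness, subcortical volume) the laterality of individual $i$ in region
$j$ is the normalized difference

$$\mathrm{AI}_{ij} = \frac{L_{ij} - R_{ij}}{(L_{ij} + R_{ij})/2},$$

which is dimensionless, antisymmetric under swapping hemispheres, invariant
to rescaling both sides, and bounded in $(-2, 2)$ for positive measures.
Positive values mean leftward asymmetry. The reference configuration
carries 42 indexes: 28 surface-area, 8 thickness and 6 subcortical-volume
regions.

`prepare_asymmetry_matrix()` applies, in order:

1. **Outlier removal** at 6 SDs from the mean, computed once per column
   (not iterated), on each *unilateral* raw measure; an index becomes
   missing if either side is removed. The threshold and an alternative
   mode that filters the indexes themselves (`outliers_on = "ai"`) are
   exposed, because either reading of "per measure" is defensible; the
   unilateral reading is the default.
2. **Rank-based inverse normal transformation**,
   $x \mapsto \Phi^{-1}\!\big((r - c)/(m - 2c + 1)\big)$ with Blom's
   offset $c = 3/8$ (van der Waerden and Tukey offsets are available).
   Ties share average ranks. The offset choice is immaterial for any
   downstream correlation but is recorded in provenance.
3. **Covariate residualization** by ordinary least squares against age,
   $(\mathrm{age}-\overline{\mathrm{age}})^2$ (the mean taken on the
   analysis sample at preprocessing time), ten genetic principal
   components, scanner x/y/z position, T1 signal- and contrast-to-noise,
   assessment centre and genotyping array (treatment-coded with the most
   frequent level as reference), and sex — except in the sex-difference
   analysis, where sex is deliberately left in the data. A brain-size
   column can be appended for the sensitivity analysis.

Missing entries are handled per column: each index is residualized on its
own complete cases, and the multivariate statistics below use complete
rows, reporting the analysis $n$ explicitly.

## Scalar-target canonical correlation

With a single standardized score $s$ on one side, canonical correlation
analysis against the index matrix $X$ has exactly one canonical pair, and
the canonical correlation equals the multiple correlation of $s$ on $X$:

$$r_c = \max_{w}\ \mathrm{cor}(s,\, Xw) = \sqrt{R^2_{s \sim X}},
\qquad w \propto \Sigma_{XX}^{-1}\Sigma_{Xs}.$$

`scalar_cca()` solves the covariance system directly (Cholesky), scales
the canonical variate to unit sample variance, and orients it so its
correlation with the score is non-negative — making "positive loading =
leftward shift with increasing risk" well defined. **Loadings** are the
per-region correlations between each index and the canonical variate and
are the primary interpretive output; raw and per-SD weights are also
reported. The equivalence with multiple regression is not only the
implementation shortcut but also the test oracle: the suite checks
`canonical_r` against an independent `lm()` fit to $10^{-10}$ on random
instances.

Because the target is scalar, the null distribution of $r_c^2$ is that of
a regression $R^2$, so the parametric p-value uses the exact F statistic

$$F = \frac{r_c^2}{1 - r_c^2}\cdot\frac{n - p - 1}{p} \sim F_{p,\,n-p-1},$$

exact under Gaussian errors. The reference literature for this design does
not name its test, so the F test is adopted as the exact choice for the
one-pair case; Bartlett's $\chi^2$ approximation is implemented as a
cross-check mode and agrees within a factor of two at biobank-scale $n$.

## Comparing two loading patterns

The similarity of the two risks' association patterns is the Pearson
correlation of their loading vectors across the $p$ regions. Its null
distribution is built by permutation with two within-subject structures
preserved: the pair of scores is shuffled *jointly* against the fixed
index matrix, so the score--score correlation is retained exactly in every
permutation while all score--brain association is destroyed. Both CCAs are
re-fit per permutation (via a precomputed Cholesky factor of
$\Sigma_{XX}$, which the suite verifies is numerically identical to a
from-scratch re-fit) and the loading-vector correlation is recorded.

The empirical p-value uses the add-one rule
$p = (1 + \#\{|r^\ast| \ge |r_{\mathrm{obs}}|\})/(1 + B)$, two-sided by
default (the sidedness is configurable; the magnitude rule is consistent
with the reference analysis reporting a high p for a near-zero observed
correlation). Regions are classified **concordant** when both loadings
exceed $+0.2$ or both fall below $-0.2$, **discordant** when they cross
the thresholds in opposite directions; the 0.2 threshold is a reporting
convention, not a test.

## Sex-difference map

Sex differences of asymmetry are summarized per region by a two-sample
pooled-variance t statistic (identical to the OLS slope t of index on
sex) on indexes residualized *without* sex; with females coded 1, positive
t means leftward shift in females. The correlation of this t-vector with a
risk's loading vector is tested by shuffling sex labels and recomputing
the whole t-vector each time while holding the loading vector at its
observed value: the stated null randomizes sex, not the score. Whether the
loading vector should *also* be re-derived under permuted sex covariates is
ambiguous in the source procedure; both behaviours are implemented
(`refit = "tmap_only"` is the default and the reported one,
`refit = "full"` re-residualizes and re-fits the CCA per permutation).

## Handedness contrasts

Three logistic regressions per score — left vs right, mixed vs right, and
non-right (left $\cup$ mixed) vs right — with the same covariates as the
main analysis; six models in the two-score configuration. Coefficients are
log-odds per SD of score. Fits are maximum likelihood (IRLS, tolerance
$10^{-8}$); quasi-separation is flagged in the result rather than
penalized away, and categories outside the three recognized ones are
treated as missing.

## Phenome-wide scan

`run_phewas()` dispatches on variable type: continuous phenotypes are
inverse-normal transformed and fit linearly; binary by logistic; ordered
categorical by proportional odds; unordered categorical by
baseline-category multinomial logistic with a likelihood-ratio p for the
score. A declared codebook type always overrides the automatic
classifier, which is a deliberately simple cascade (two values = binary;
non-numeric = unordered; integer-coded with at most 10 levels = ordered;
otherwise continuous): the scientific content here is the four-model
dispatch with per-score Benjamini--Hochberg control at $q = 0.05$, not any
particular biobank field heuristic. Phenotypes that fail to converge are
excluded from the adjustment with the reason logged, so $m$ always equals
the number of tested phenotypes. Columns used to build the indexes, the
covariates, sex, handedness and the scores themselves are excluded by
default.

## The synthetic cohort generator

Because the motivating data are access-controlled, every stage is
exercised on simulated cohorts whose defaults are fixed at the study's
conditions: $n = 32{,}256$ with 52.6% females; two scores with
correlation 0.08 and a +0.04 SD female shift (back-derived from the
reported two-sample t at the study's group sizes); planted canonical
correlations 0.03 and 0.04 on an orthonormal pair of loading patterns
(so the planted patterns share nothing, matching the null similarity
finding); a sex-difference pattern of amplitude 0.03 SD on a third
orthogonal direction; handedness base rates (0.890, 0.095, 0.015) with
mixed-vs-right log-odds 0.14 and left-vs-right 0.04 for the first score;
and a small typed phenotype panel with planted cognition effects for the
second score.

Asymmetry is planted on the AI scale and inverted exactly:
$L = s(1 + a/2)$, $R = s(1 - a/2)$ around a log-normal bilateral size
$s$, so the index computation recovers the latent $a$ to machine
precision — giving an analytic round-trip test. Latent values implying a
non-positive side are clipped with a warning and counted; with the
default AI scale of 0.15 this essentially never happens. The marginal
distribution of raw unilateral measures is not identified by the source
material; log-normal sizes are an explicit assumption recorded in the
cohort metadata.

Signal calibration uses the identity that with planted directions the
target canonical correlation is the multiple correlation of the score on
the index matrix. For orthogonal patterns and uncorrelated scores the
coefficient is the closed form $\alpha = r/\sqrt{1-r^2}$ (in noise-SD
units); correlated scores or overlapping patterns couple the two
equations, which are then solved numerically from the closed-form start
and validated to $10^{-6}$ in correlation units. Outliers, when enabled,
replace unilateral measures with values 7--10 SDs from their column mean:
far enough to trip the 6 SD rule deterministically, close enough to keep
rank structure intact.

What the generator does *not* emulate: spatial correlation among regions
beyond the planted low-rank structure, realistic covariate--brain
confounding strength, non-Gaussian measurement noise, and missingness
mechanisms other than completely-at-random. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
generative model, not robustness to every feature of real imaging data.

## Reproducibility and numerical choices

Each cohort is a pure function of its configuration (including the seed);
pipeline stages draw child seeds derived as `seed * 11 + stage_index`, so
any stage can be re-run in isolation. Reports serialize deterministically:
a rerun with the same configuration is byte-identical. Degenerate inputs
fail loudly: non-positive measures, constant columns under the rank
transform, rank-deficient designs (with the collinear columns named),
empty handedness groups and constant predictors are all errors rather
than silent coercions.

The test suite runs the method at reduced but honest problem sizes chosen
to keep the full run comfortable on a laptop: the regression-oracle check
uses 100 random instances at $n = 500$, permutation calibration 200
datasets at $n = 2{,}000$ with 200 permutations, parameter recovery 20
seeds at $n = 30{,}000$, handedness coverage 100 replicates at
$n = 10^5$, FDR control 60 replicates of 200 null phenotypes at
$n = 10^4$, and one end-to-end run at the full $n = 32{,}256$ with 1,000
permutations.

## A short worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_individuals = 5000, seed = 7),
                       n_perm = 500, seed = 7)
report <- run_pipeline(cfg)
report
glance(report$cca$score_asd)
tidy(report$comparison) |> arrange(desc(abs(loading_a)))
autoplot(report$comparison)
```

## Known limitations

- The scalar CCA is exactly the one-pair case; no multi-dimensional or
  regularized CCA is provided, by scope.
- The permutation null assumes exchangeable rows (no family or site
  clustering structure).
- The proportional-odds and multinomial models report score effects on
  their native latent scales, which are not directly comparable across
  phenotype types.
- Separation in the handedness models is reported, not corrected; with
  rare categories and strong covariates a penalized fit would be the
  next step.
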