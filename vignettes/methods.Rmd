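---
title: "From receptor signaling assays to variance explained: the models behind mc4rbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From receptor signaling assays to variance explained: the models behind mc4rbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mc4rbias)
```

## The scientific problem

Nonsynonymous variants in the melanocortin 4 receptor (MC4R), a brain-expressed
Gαs-coupled GPCR central to energy homeostasis, span the full range from
loss of function (LoF) to gain of function (GoF). Because MC4R signals through
at least two pathways — canonical cAMP production and β-arrestin recruitment —
the question of *which* pathway carries the receptor's effect on body weight
can be asked statistically: characterize each variant's maximal efficacy
(E~max~) in both pathways in cells, estimate each variant's association with
BMI in a large cohort, and ask how much of the between-variant variance in BMI
effects each in-vitro measure explains.

`mc4rbias` implements that chain end to end:

1. **Assay quantification** — time-resolved luminescence traces to normalized
   E~max~ (% of wild type) and LoF/WT-like/GoF calls;
2. **Bias statistics** — geometric-mean ratio of β-arrestin to cAMP maximal
   activity;
3. **Genetic association** — per-variant and carrier-group regressions,
   fixed-effect pooling, obesity case-control definitions, a phenome-style
   scan;
4. **Meta-inference** — random-effects meta-regression of per-variant BMI
   effects on ln E~max~ with REML heterogeneity and percent variance
   explained;
5. **Synthetic data** — a fully seeded generator reproducing the statistical
   structure all of the above assumes, so the complete pipeline runs and is
   testable without individual-level cohort data.

## Assay quantification

A well's readout is a luminescence time series: a flat pre-stimulation
baseline followed by an agonist-induced rise. Quantification is deliberately
simple and assumption-light:

- **AUC**: the baseline is the arithmetic mean of the pre-stimulation window
  (at least two points); the response is the trapezoidal integral of
  signal − baseline over the post-stimulation points, on the sampled grid
  with no interpolation or smoothing. Adding any constant to a trace leaves
  its AUC unchanged.
- **Two-point normalization**: within each replicate plate and pathway, the
  mock-transfected well anchors 0% and the wild-type well anchors 100%,
  so `pct = 100 (AUC − AUC_mock) / (AUC_WT − AUC_mock)`. Normalizing within
  plate removes plate-level scale and offset (the function is invariant to
  affine transforms of all its inputs); equal mock and wild-type anchors are
  a hard error naming the plate. The same operation serves ERK western-blot
  normalization (unstimulated wild type 0%, maximally stimulated wild type
  100%).
- **Testing**: per-variant, per-pathway, the per-experiment normalized values
  are compared to 100% with a two-sided single-sample t test at α = 0.05.
  LoF means significantly below 100%, GoF above, otherwise WT-like. A
  zero-variance sample away from 100% is flagged degenerate: the class is
  assigned by sign and the p-value reported at the machine floor rather than
  zero.
- **Overall category**: LoF in either pathway ⇒ LoF; GoF in either ⇒ GoF;
  discordant directions (GoF one pathway, LoF the other) ⇒ *opposing*;
  both WT-like ⇒ WT-like. Truncating (nonsense/frameshift) variants are not
  assayed and are LoF by rule.

Dose-response curves are fit as a sigmoid with variable slope and the bottom
fixed at zero — `top / (1 + 10^(hill (log10EC50 − log10[L])))` — which is the
only three-parameter reading of a variable-slope logistic. Fitting is
least squares (Levenberg–Marquardt) with multi-start initialization from
data-derived guesses plus a deterministic grid of perturbed starts; an
all-zero response returns a degenerate flat fit rather than an error.

## Signaling bias

Bias is quantified on maximal efficacy only: the ratio of geometric means of
per-experiment β-arrestin and cAMP activities,
`exp(mean(ln barr) − mean(ln cAMP))`, tested against ratio = 1 with an
unpaired two-sample t test on the log scale. The classic pooled-variance test
is the default because that is the unqualified reading of "unpaired two-sample
t test"; Welch is available as a flag. The 95% CI is the exponentiated
t-interval for the difference of log-means, so the CI excludes 1 exactly when
p < 0.05, and a tie at p = α is non-significant. The bias analysis set is
variants that are GoF in *at least one* pathway — overall GoF plus opposing
variants with a GoF arm.

Operational-model bias factors (ΔΔlog(τ/K~A~)) and potency-based bias are out
of scope by design: the statistic here is the E~max~ ratio.

## Genetic association

Associations are plain covariate-adjusted regressions: OLS for BMI, logistic
IRLS for binary outcomes, both Wald-inferred, adjusted for age, sex and
genotyping array. Mixed-model kinship adjustment is deliberately not
implemented: the synthetic cohorts are unrelated by construction, so
covariate-adjusted OLS/IRLS estimates the same quantity the cohort analysis
targets. Complete or quasi-complete separation and rank-deficient designs are
explicit failures naming the offending column; p-values are floored at the
smallest positive double rather than reported as 0.

Obesity phenotypes are BMI-threshold case-control definitions (obesity
≥ 30 kg/m², severe obesity ≥ 40 kg/m², controls < 25 kg/m², in-between
excluded). Carrier-group analysis sums allele counts over a variant set — a
compound heterozygote counts as two copies — and contrasts 1-copy and
≥2-copy carriers against noncarriers with indicator coding (additive coding
available). An empty carrier class yields an "unavailable" row, not an
exception. The phenome-style scan tests every binary outcome with more than
`min_cases` cases (default 500) and Bonferroni-corrects at α/m for the m
outcomes actually tested.

## Random-effects meta-regression

The core model, per variant $v$ with estimated BMI effect $\hat\beta_v$ and
known sampling SE $s_v$:

$$\hat\beta_v = \gamma_0 + \gamma_1 x_v + u_v + e_v,
\qquad u_v \sim N(0, \tau^2),\; e_v \sim N(0, s_v^2),$$

with moderator $x_v = \ln(E_{\max,v}/100)$, the log relative efficacy.
$\tau^2$ is estimated by REML — Fisher scoring on the restricted likelihood
with step-halving, truncation at zero every iteration, and convergence when
$|\Delta\tau^2| < 10^{-10}$ — with DerSimonian–Laird method-of-moments as a
selectable alternative and cross-check. Coefficients are weighted least
squares with weights $1/(s_v^2 + \hat\tau^2)$ and Wald z inference
(Knapp–Hartung t inference available as a flag). The headline quantity is

$$R^2 = 100 \times \max\!\left(0, \frac{\hat\tau^2_{\varnothing} -
\hat\tau^2_{x}}{\hat\tau^2_{\varnothing}}\right),$$

the percent reduction in *between-variant* variance when the moderator enters,
computed against the intercept-only fit on the same rows and truncated to
[0, 100]. This is the standard meta-regression R² analog; the alternative that
includes sampling variance in the denominator was considered and not adopted,
because the scientific claim concerns between-variant variance. Both estimator
choices are exposed; REML plus the between-variance definition is the default.

Truncating variants have no measured efficacy; where a sensitivity analysis
includes them, their moderator is substituted at 1% of wild type
(`x = ln(0.01)`). Other sensitivity tools: leave-one-out refits, rare-only
filtering (allele frequency < 0.5%), ultra-rare exclusion (< 0.001%),
cluster-plot quality-score thresholds, category subsets, and a categorical
moderator mode (LoF/WT-like/GoF dummies against a WT-like reference).

The tests verify the REML estimate against two independent routes: a
brute-force profile-restricted-likelihood grid search over τ² (step 10⁻⁴) and
the `metafor` package, both agreeing to well under the documented tolerances.

## The synthetic-data generator

The generator's defaults describe the data-generating conditions the pipeline assumes:

- **Variant panel**: 60 variants; allele frequencies log-uniform on
  [10⁻⁶, 0.02] — the 0.0001%–2% span reported for MC4R variants in UK
  Biobank, log-uniform so ultra-rare
  variants are represented; category mix 77% LoF / 8% WT-like / 15% GoF
  (the reported 47/3/9 of 61 MC4R variants, with the two opposing variants
  folded into rounding); 12/61 of variants truncating. True efficacies per category:
  LoF uniform on (0, 0.8), WT-like normal around 1 (SD 0.03), GoF uniform on
  (1.1, 1.5) — no empirical distribution for these is available, so
  the uniform ranges are a modeling convenience, chosen once.
- **Effects**: `beta_v = gamma0 + gamma1 ln(Emax_barr,v) + u_v` with defaults
  γ₀ = 0, γ₁ = −0.55, τ² = 0.04125. At unit moderator variance this puts the
  moderator-attributable share of between-variant variance at
  γ₁²/(γ₁² + τ²) = 88%, the generating condition the acceptance analysis
  recovers.
- **Genotypes**: independent Binomial(2, f) draws per variant — Hardy-Weinberg,
  no linkage disequilibrium, matching the panel's pairwise R² < 0.01.
- **Phenotypes**: BMI 27 ± 4.7 kg/m² plus additive genetic and small
  age/sex/array covariate terms; binary outcomes Bernoulli with logit linear
  in BMI (baseline log-odds −3, slope 0.1 per kg/m²) — genotype acts on
  disease only through BMI (full mediation) by default, since the source
  analysis does not model mediation.
- **Traces**: `baseline + plateau_scale × E × (1 − e^{−kt})` after the
  stimulation time, flat before, with i.i.d. Gaussian noise per point
  (baseline 1000, plateau 5000, k = 0.002 s⁻¹, noise SD 40, 110 points every
  30 s, 600 s baseline window, 4 replicate experiments). A saturating
  exponential is used because only the AUC is consumed downstream and this
  form has a closed-form integral for oracle testing; any monotone saturating
  shape with plateau ∝ E~max~ would serve. Every replicate plate carries its
  own mock and wild-type anchors.

One run seed drives everything, with per-stage sub-seeds derived
deterministically, so a dataset is byte-identical under the same
configuration.

### What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes: rare HWE
genotypes, additive moderator-driven BMI effects with between-variant
heterogeneity, BMI-mediated disease risk, and plates whose normalized AUC
recovers the generating efficacy exactly in the noiseless limit. It does not
emulate population structure, relatedness, imputation error, genotyping
error, or LD — all quality-control concerns upstream of the statistics
implemented here.

Two desk-scale artifacts deserve note. First, with only within-trace photon
noise, AUC averaging over ~90 post-stimulation points makes per-experiment
E~max~ extremely precise, so the single-sample t test calls even 3% deviations
from wild type significant: synthetic plates yield fewer WT-like calls than
real experiments, where between-experiment variability dominates. Passing
classification tests therefore demonstrate correctness of the decision rules,
not realistic assay power. Second, at desk-scale cohort sizes (tens of
thousands rather than half a million), per-variant sampling variances are
large relative to τ², so the moderated REML τ̂² is often truncated at zero and
R² reaches 100%; the 88% figure is recovered in the replicate-panel analysis
at biobank-scale precision (SEs of 0.05–0.15 kg/m² per allele), which is
what `scripts/acceptance.R` computes.

Ultra-rare variants (frequency near 10⁻⁶) can have fewer than two carriers at
desk scale; their single-variant associations are reported as unavailable and
excluded from pooling and meta-regression with a logged count, rather than
estimated from degenerate designs.

## Numerical choices

- REML: Fisher scoring with step-halving on the restricted likelihood;
  negative variance estimates truncated at zero at every iteration;
  non-convergence after 100 iterations is an error naming the count.
- Logistic IRLS: deviance tolerance 10⁻¹², 100 iterations max; separation
  detected via the fitted-probability warning plus a diverging coefficient.
- Dose-response: best of multi-start Levenberg–Marquardt fits by residual sum
  of squares; non-convergence of all starts returns `converged = FALSE`
  rather than an error.
- Ties: bias and pathway classifications treat p = α as non-significant.
- Printed percentages round half away from zero.
- p-values are never exactly zero; they are floored at the smallest positive
  representable double.

## Reported problem sizes

The bundled analysis scripts run a 50,000-individual, 60-variant cohort with
4 replicate experiments per assay — a desk-scale configuration chosen so the
entire workflow, test suite and acceptance analysis complete in minutes on a
single CPU. The replicate-panel acceptance analysis uses 500 panels of 49
variants, matching the reported missense analysis set size.
Parameter-recovery tests
use 30 pipeline replicates at 6,000 individuals with frequencies drawn at the
top of the simulated frequency range so every variant is estimable.

## Known limitations

- The assay model has no between-experiment variance component (see above).
- Carrier-group conventions for compound heterozygotes across different
  variants are assumed (two copies); the source convention is not stated.
- The single-sample tests are applied to per-experiment normalized values,
  and GoF/LoF calls use raw p < 0.05 per pathway without multiplicity
  correction across variants — both assumptions, not documented facts about
  the original analysis.
- Disease outcomes are fully BMI-mediated by default; direct genotype effects
  on disease are configurable but off.
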