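# mc4rbias

Linking cell-based measurements of melanocortin 4 receptor (MC4R) signaling
to population genetic association estimates for BMI and obesity-related
disease.

## The problem

MC4R is a brain-expressed Gαs-coupled GPCR central to body-weight regulation.
Naturally occurring nonsynonymous variants range from loss of function (LoF)
to gain of function (GoF), and the receptor signals through two measurable
pathways: canonical cAMP production and β-arrestin recruitment. For anyone
studying which pathway carries the receptor's effect on body weight — or
using human variation to anticipate the consequences of pathway-biased
agonists — the key quantity is how much of the between-variant variance in
BMI associations each in-vitro efficacy measure explains.

`mc4rbias` implements the full analysis chain as a tested R package:

1. **Assay quantification**: time-resolved luminescence traces →
   baseline-corrected trapezoidal AUC → two-point normalization within each
   replicate plate (mock = 0%, wild type = 100%) → single-sample t tests
   against the 100% wild-type level → LoF / WT-like / GoF / opposing calls.
   Also: variable-slope dose-response fits with bottom fixed at 0, and the
   flow-cytometry percent-internalization formula.
2. **Signaling bias**: ratio of geometric means of β-arrestin to cAMP maximal
   activity with a log-scale two-sample t test against ratio = 1.
3. **Genetic association**: covariate-adjusted OLS/logistic regression per
   variant, carrier-group contrasts (1 copy, ≥2 copies vs noncarriers),
   BMI-threshold obesity phenotypes, fixed-effect inverse-variance pooling
   with Cochran Q / I², Wald-ratio OR rescaling per kg/m², and a
   phenome-style scan with case-count filtering and Bonferroni control.
4. **Meta-inference**: random-effects meta-regression of per-variant BMI
   effects on ln(relative E<sub>max</sub>), with τ² by REML (Fisher scoring;
   DerSimonian–Laird as an alternative) and variance explained reported as
   the percent reduction in τ²:

   β̂<sub>v</sub> = γ₀ + γ₁·ln(E<sub>max,v</sub>) + u<sub>v</sub> + e<sub>v</sub>,  u<sub>v</sub> ~ N(0, τ²), e<sub>v</sub> ~ N(0, se<sub>v</sub>²)

   R² = 100 · (τ̂²<sub>intercept-only</sub> − τ̂²<sub>moderated</sub>) / τ̂²<sub>intercept-only</sub>

   plus leave-one-out, rare-only, quality-score and multivariable sensitivity
   analyses, and the 1%-of-wild-type moderator substitution for truncating
   variants.
5. **Synthetic data**: a fully seeded generator for variant panels (allele
   frequencies log-uniform over 0.0001%–2%), Hardy-Weinberg genotypes,
   additive BMI phenotypes with BMI-mediated binary outcomes, and saturating
   luminescence plates whose plateau scales with each variant's true
   efficacy — so the whole pipeline runs with no individual-level data.

See `vignettes/methods.Rmd` for the models, assumptions and numerical
choices.

## Worked example

```r
library(mc4rbias)

cfg <- simulation_config(seed = 1, n_individuals = 20000, n_variants = 40,
                         freq_range = c(0.001, 0.02))
run <- run_full_pipeline(cfg)
print(run)
#> Pipeline run (seed 1): 40 variants, 20000 individuals
#>   categories: LoF 35 (88%), GoF 4 (10%), opposing 1 (3%), WT-like 0 (0%)
#>   any functional consequence: 100%
#>   meta-regression: gamma1 = -0.687 (p = 5.8e-18), tau2 = 0.0925, R2 = 87.5%
```

The report says: of 40 simulated variants, 35 were called LoF, 4 GoF and 1
opposing from the synthetic plates; regressing each variant's estimated BMI
effect on its measured ln E<sub>max</sub> for β-arrestin recruitment gives a
strongly negative moderator coefficient (higher recruitment → lower BMI), and
the moderator removes 87.5% of the between-variant variance in this run.

The bias statistic on per-experiment activities:

```r
b <- compute_bias(barr_pct = c(190, 205, 210, 198),
                  camp_pct = c(102, 97, 104, 99))
sprintf("ratio %.2f (95%% CI %.2f-%.2f), p = %.2g", b$ratio, b$ci95[1], b$ci95[2], b$p)
#> "ratio 2.00 (95% CI 1.87-2.13), p = 2.2e-07"
```

— a variant recruiting β-arrestin at twice its cAMP activity is called
β-arrestin-biased.

## The analysis workflow

The numbered drivers under `analysis/` run the desk-scale study
(50,000 individuals, 60 variants, 4 replicate experiments per assay) and
write their tables under `results/` (bulky regenerable inputs under
`scratch/`):

```sh
Rscript analysis/01_simulate.R    # cohort, variant panel, assay plates
Rscript analysis/02_quantify.R    # E_max profiles and functional categories
Rscript analysis/03_bias.R        # bias ratios for GoF variants
Rscript analysis/04_associate.R   # per-variant, pooled and carrier-group associations
Rscript analysis/05_metareg.R     # meta-regression + sensitivity analyses
```

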