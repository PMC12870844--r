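# sexseldiv

Does stronger sexual selection drive replicate populations apart in their
reproductive traits and reproductive-gene expression? `sexseldiv` is an R
package for analysing replicated experimental-evolution designs that
contrast a strong (SSS) and a weak (WSS) sexual-selection regime — for
example seed-beetle lines evolving under polyandry versus enforced early
monandry. It packages three linked analyses, each behind a
data-frame-in/tibble-out interface with broom-style `tidy()`/`glance()`
methods and `autoplot()` figures, plus a synthetic-data generator with
recorded ground truth so every estimator can be checked by parameter
recovery.

## What it computes

**1. Strength of sexual selection** from mating-population assays (one row
per individual: lifetime matings *m*, lifetime reproductive success *w*):

- opportunity for sexual selection *I*<sub>s</sub> = Var(*m*/*m̄*), with a
  percentile bootstrap CI;
- Bateman gradient *β*<sub>B</sub>: REML mixed-model slope of relative *w*
  on absolute *m* with a random intercept per replicate line;
- Jones index *s*′<sub>max</sub> = √*I*<sub>s</sub> · *β*<sub>ss</sub>,
  where *β*<sub>ss</sub> is the OLS slope of relative *w* on relative *m*;
- a Z-test of equal Bateman slopes between regimes,
  *Z* = (*b*₁ − *b*₂)/√(se₁² + se₂²).

**2. Divergent male–female coevolution** from a fully crossed line × line
double-mating design scoring last-male paternity P2 = hatched/eggs:
a quasi-binomial logit GLM per regime (sequential male line, female line,
male × female terms; Pearson-χ²/df dispersion; F tests; predicted mean P2;
interaction η²), and three complementary routes comparing the male × female
interaction between regimes — a fixed-dispersion binomial GLMM (PQL)
variance component, a weighted arcsine-√P2 mixed-model variance-ratio test,
and a residual cell-mean bootstrap with BCa intervals, variance-ratio F and
Bartlett tests — plus within- vs between-line rank-sum comparisons.

**3. Expression divergence ratios** from a gene × sample matrix (2 sexes ×
2 regimes × 4 replicate lines): per gene, the mean absolute deviation of
replicate expression around the regime mean, the SSS/WSS ratio (1 = equally
divergent), bootstrap-median set summaries with BCa CIs, KS and gated
one-sided Mann–Whitney tests of reproductive-protein sets (SFP, FRP)
against the transcriptome background, and a deterministic ≥90%-identity
lowest-e-value best-hit filter that builds those sets from BLAST
tabular (outfmt 6) homology output.

## Worked example

```r
library(sexseldiv)

truth <- synthetic_truth()        # the generator's study conditions
cfg   <- run_config(seed = 1, n_bootstrap = 500)

rec <- simulate_mating_assays(truth, seed = 1)
sx  <- sexsel_estimates(rec, cfg)
dplyr::select(tidy(sx), sex, regime, n_used, I_s, beta_B, beta_B_se, s_max)
#> # A tibble: 4 × 7
#>   sex    regime n_used   I_s beta_B beta_B_se  s_max
#>   <chr>  <chr>   <int> <dbl>  <dbl>     <dbl>  <dbl>
#> 1 male   WSS        14 0.337 0.136     0.0176 0.134
#> 2 male   SSS        14 0.226 0.317     0.0165 0.387
#> 3 female WSS        43 0.287 0.0774    0.0388 0.0618
#> 4 female SSS        55 0.324 0.390     0.0145 0.489
glance(sx)
#> # A tibble: 2 × 3
#>   sex        z  p_value
#>   <chr>  <dbl>    <dbl>
#> 1 female  7.55 4.22e-14
#> 2 male    7.48 7.35e-14
```

Reading: in both sexes the Bateman gradient (`beta_B`, fitness gain per
additional mating) is several times steeper under strong sexual selection,
and the equal-slopes Z test rejects equality; the Jones index `s_max`
(maximum standardized strength of sexual selection) is correspondingly
larger. The generator was built with slopes 0.1 (WSS) vs 0.4 (SSS), which
is what the estimates recover.

```r
dm <- simulate_double_matings(truth, seed = 1)
sc <- spermcomp_analysis(dm, cfg)
dplyr::select(glance(sc), regime, predicted_mean_p2,
              eta_squared_interaction, interaction_varcomp, lmm_share_percent)
#> # A tibble: 2 × 5
#>   regime predicted_mean_p2 eta_squared_interaction interaction_varcomp
#>   <chr>              <dbl>                   <dbl>               <dbl>
#> 1 WSS                0.503                   0.108               0.139
#> 2 SSS                0.572                   0.199               0.205
#> # ℹ 1 more variable: lmm_share_percent <dbl>  (10.6 for WSS, 20.6 for SSS)
```

Reading: overall last-male paternity is higher under SSS, and the
male × female interaction — the signature of idiosyncratic coevolution —
carries roughly twice the effect size and variance share under SSS.

```r
ed <- simulate_expression(truth, n_genes = 18000,
                          geneset_spec = c(SFP = 50, FRP = 96), seed = 1)
dv <- expression_divergence(ed, ed$gene_sets, cfg)
glance(dv)[, c("set", "n_genes", "boot_mean_median", "ci_lower", "ci_upper")]
#> # A tibble: 4 × 5
#>   set        n_genes boot_mean_median ci_lower ci_upper
#>   <chr>        <int>            <dbl>    <dbl>    <dbl>
#> 1 all_male     18000             1.00    0.989     1.01
#> 2 all_female   18000             1.00    0.993     1.02
#> 3 SFP             50             1.41    1.19      1.69
#> 4 FRP             96             1.29    1.11      1.49
```

Reading: the transcriptome-wide divergence ratio sits at 1 (equal
divergence between regimes), while the designated reproductive-protein
sets — generated with 1.5× larger between-replicate SD under SSS — show
clearly elevated ratios (1.41 and 1.29 here; set-level sampling noise at
50–96 genes) with BCa intervals excluding 1.

A command-line wrapper covers the same stages
(`inst/scripts/sexseldiv simulate|sexsel|spermcomp|expdiv ...`), writing
delimited result tables and a configuration log.

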