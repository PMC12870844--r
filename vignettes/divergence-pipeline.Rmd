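---
title: "Quantifying sexual selection and reproductive divergence across replicate lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sexual selection and reproductive divergence across replicate lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexseldiv)
library(dplyr)
```

## The scientific problem

Sexual selection is predicted to drive divergent coevolution of male and
female reproductive traits between isolated populations, even without any
environmental differences. `sexseldiv` implements a three-part analysis of
that prediction for replicated experimental-evolution lines kept under a
strong (SSS) or weak (WSS) sexual-selection regime, such as seed-beetle
lines evolving under polyandry versus enforced early monandry:

1. **How strong is sexual selection in each regime?** Estimated from
   mating-population assays via the opportunity for sexual selection, the
   Bateman gradient, and the Jones index.
2. **Have replicate lines diverged in the traits that decide sperm
   competition?** Assessed from a fully crossed line-by-line double-mating
   design: if lines coevolve idiosyncratically, the male-line-by-female-line
   interaction in last-male paternity (P2) should be stronger under strong
   sexual selection.
3. **Is the expression of reproductive genes more divergent between
   strong-selection replicates?** Quantified by per-gene divergence ratios
   of between-replicate expression variability, comparing designated
   reproductive-protein sets (seminal-fluid proteins, SFP; female
   reproductive-tract proteins, FRP) against the transcriptome background.

A synthetic-data generator with a recorded ground truth emulates all three
data types, so each estimator is testable by parameter recovery without any
external download.

## Sexual-selection metrics

Let $m_i$ be individual $i$'s lifetime mating count and $w_i$ its lifetime
reproductive success. Within each sex-by-regime group (optionally per
mating population), relative values are obtained by dividing by the group
mean, so relative values average exactly 1. The three metrics are:

* **Opportunity for sexual selection** $I_s = \mathrm{Var}(m_i / \bar m)$,
  the sample variance (divisor $n-1$) of relative mating success. The
  divisor is a deliberate choice: the $n-1$ form is the standard unbiased
  estimator for selection-opportunity statistics. A nonparametric
  percentile bootstrap over individuals provides its CI.
* **Bateman gradient** $\beta_B$: the slope of relative reproductive
  success on *absolute* mating count, fitted by REML in a linear mixed
  model with a random intercept per replicate line (the lines within a
  regime are assumed to share a common gradient). With a single line, or
  when the estimated line variance collapses to zero (singular fit), the
  fit degrades to ordinary least squares — the slope is then identical and
  the Wald SE remains defined.
* **Jones index** $s'_{max} = \sqrt{I_s}\,\beta_{ss}$, with $\beta_{ss}$
  the ordinary least-squares slope of relative reproductive success on
  relative mating success. $\beta_{ss}$ is plain OLS by design: it is a
  standardized selection differential, not a hierarchical estimate.

Individuals with zero matings (hence zero reproductive success) are
excluded before estimation: they carry no information about how fitness
accumulates over successive matings, and their inclusion biases the
gradient. The excluded count is always reported.

Regimes are compared per sex with a two-independent-estimates Z test,
$Z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$, with a two-sided normal p.

```{r sexsel-demo}
rec <- simulate_mating_assays(synthetic_truth(), seed = 1)
fit <- sexsel_estimates(rec, run_config(seed = 1, n_bootstrap = 500))
tidy(fit) |> select(sex, regime, n_used, I_s, beta_B, beta_B_se, s_max)
glance(fit)
```

## The crossed sperm-competition analysis

Each female is mated first to a sterilized male of her own line and then to
a fertile focal male from one of the regime's lines; hatched eggs are
attributable to the second male, so P2 = hatched / eggs laid. Only females
where two ejaculates demonstrably competed are analysed: both matings must
have occurred and at least one egg must have hatched (P2 = 0 cannot be
distinguished from a failed ejaculate transfer).

The core model, fitted per regime, is a quasi-binomial GLM of hatched
counts with the egg total as binomial denominator, logit link, and
sequential terms male line, female line, male x female. The dispersion
$\hat\phi$ is the Pearson $\chi^2$ over residual df — the standard
empirical dispersion estimate for overdispersed proportions; each term's F
is $(\Delta D/\Delta df)/\hat\phi$. Three
deliberate conventions:

* The deviance decomposition is sequential (type I) in the order male
  line, female line, interaction — matching the canonical deviance-table
  layout; the order of the two main effects is configurable, and the
  interaction term is invariant to it in a balanced design.
* The interaction effect size $\eta^2$ is the interaction deviance over
  the total (all terms + residual = null) deviance. Deviance additivity of
  the sequential decomposition makes the denominator well defined.
* The predicted regime-mean P2 is the inverse logit of the average cell
  linear predictor with a delta-method CI — an estimate of the typical
  cell rather than the raw pooled proportion.

If a design cell is saturated (every egg hatched, or none), the fitted
probability is pinned to the boundary; the fit then proceeds on counts
shrunk by half an egg in each direction, with a warning — a lightweight
penalization that keeps the dispersion finite.

### Comparing the interaction between regimes

A larger and significant interaction in one regime does not by itself show
the interactions differ, so three complementary routes compare them
directly:

1. **Binomial GLMM variance component.** The same model with male line,
   female line and their interaction as *random* effects, intercept fixed,
   and the dispersion *fixed* at $\hat\phi$ from the fixed-effects fit.
   Estimation is penalized quasi-likelihood, iterating a weighted working
   response through an REML linear mixed model. The loop uses half-step
   damping (PQL is prone to a two-cycle oscillation of the linear
   predictor) and converges on the relative change of the linear predictor
   at $10^{-5}$; the fit is deterministic. The reported quantity is the
   logit-scale variance of the male-by-female random effect. Its SE comes
   from the curvature (numeric Hessian) of the profiled REML criterion at
   convergence, transferred to the variance scale by the delta method with
   the profiled residual scale held fixed — an approximation that ignores
   the residual-scale uncertainty, adequate for the effect-comparison
   purpose it serves here. The loop runs at the female level: with a free
   residual scale, female-level binomial sampling noise identifies the
   cell-level variance, and any misfit of the fixed dispersion is absorbed
   by the residual scale instead of biasing the component. A deterministic
   `method = "moments"` fallback fits the same random-effect structure to
   empirical logits.
2. **Weighted arcsine-square-root LMM.** $y = \arcsin\sqrt{P2}$ weighted
   by the egg total. The fixed-effects two-way ANOVA supplies the
   interaction mean squares, compared between regimes by
   $F = MS_{SSS}/MS_{WSS}$ on the two interaction df, one-sided for the
   directional prediction that the interaction is stronger under strong
   sexual selection (a two-sided p is also reported). The interaction's
   percentage share of total variance comes from the corresponding
   random-effects fit; weights are rescaled to mean 1 so the residual
   variance refers to an average-weight female and the share denominator
   (line + line + interaction + residual variances) is on one scale.
3. **Residual cell means.** The additive (no-interaction) model's
   per-female residual hatched counts, averaged per design cell, measure
   each cell's deviation from additivity. The statistic is the sample
   variance of the 16 cell means. Females are resampled with replacement
   *within cells* — the resampling unit is a deliberate choice that
   preserves the crossed design — and the additive model is refitted on
   every resample; the bootstrap yields an average variance and a BCa
   interval. Regimes are compared by a variance-ratio F on
   (cells - 1, cells - 1) df (one-sided, same directional prediction) and
   by Bartlett's homogeneity test on the two groups of cell means.

A rank-sum comparison of within-line versus between-line crosses (per
regime and pooled) checks for consistent directionality: exact p-values
for small tie-free samples, the tie-corrected normal approximation
otherwise; completely tied samples return p = 1.

```{r spermcomp-demo}
dm <- simulate_double_matings(synthetic_truth(), seed = 1)
sc <- spermcomp_analysis(dm, run_config(seed = 1, n_bootstrap = 500))
glance(sc) |> select(regime, predicted_mean_p2, eta_squared_interaction,
                     interaction_varcomp, lmm_share_percent)
```

## Expression divergence ratios

For one sex, each regime contributes one sample per replicate line. For
every gene, the divergence within a regime is the mean absolute deviation
of the replicate values around the regime mean; the divergence ratio is
$d_{SSS}/d_{WSS}$, equal to 1 in expectation when expression evolution is
equally divergent under both regimes. Ratios are scale-invariant and
location-invariant per gene; genes with $d_{WSS} = 0$ have an undefined
ratio, are excluded from summaries, and are counted in the report.

Transcripts count as expressed when cpm (count / library size x $10^6$,
computed on raw counts) is strictly greater than the threshold (default 2)
in **every** sample of the relevant sex — the filter scope is per sex by
default, a deliberate reading of "all compared samples", since sets are
evaluated within one sex. Normalization is a plug-in point: the built-in
default is $\log_2(\mathrm{cpm} + 0.5)$, and `precomputed` mode accepts an
externally variance-stabilized matrix unchanged. The divergence-ratio
method itself is transformation-agnostic; the absolute ratio values shift
mildly with the transform.

Set summaries use the mean of 9,999 bootstrap medians with a BCa interval
for the median: bias correction $z_0$ from the proportion of bootstrap
statistics below the observed value, acceleration from the jackknife
skewness over genes (the leave-one-out medians are computed in closed form
from the order statistics). "Mean bootstrap median" is implemented as the
mean of the bootstrap median distribution — one of two readings of that
phrase; the observed median is also reported so either summary is
available. Sets are compared to the background by a two-sample KS test
and, gated on KS rejection, a one-sided Mann-Whitney U test of the
prediction that reproductive proteins diverge more; both raw p-values are
always stored. The background includes the set members by default (the
comparison is "set versus all transcripts of that sex"); an option
excludes them.

Reproductive-protein sets are defined from tabular homology-search output:
hits below 90% identity are dropped ($\geq$ retains), then each query
keeps its single lowest-e-value hit, ties broken by higher bit score, then
lexicographic subject id — fully deterministic. Distinct queries may map
to one subject; they are not collapsed.

## The synthetic-data generator

The generator's defaults encode the study conditions the analyses assume;
they are fixed once and are not tuning knobs.

| Parameter | Default | Basis |
|---|---|---|
| female mating rate | 1.0 (WSS), 2.1 (SSS) | observed regime means |
| Bateman slope (relative scale) | 0.1 (WSS), 0.4 (SSS) | recovery calibration |
| baseline P2 | 0.44 (WSS), 0.61 (SSS) | observed regime means |
| interaction variance (logit) | 0.222 (WSS), 0.633 (SSS) | observed GLMM components |
| hatch intra-female correlation $\rho$ | 0.15 | see below |
| line-effect SD | 0.3 | a realistic modest line effect |
| eggs per female | Poisson(40) | typical clutch totals |
| replicate expression SD | 0.5; designated sets 1.5x under SSS | recovery calibration |

Specifics worth knowing:

* **Mating counts are plain Poisson** with the regime rate, so the regime
  mean equals the stated rate exactly (a zero-truncated law cannot reach a
  mean of 1.0, since its mean always exceeds its rate and 1). Zero-mating
  individuals arise naturally and are handled by the documented exclusion
  rule, as in the assays the generator emulates.
* **Reproductive success** has expectation linear in mating count with the
  regime's Bateman slope expressed on the relative-fitness scale (the
  design constant `mean_rs` sets the offspring scale: 100 for males, who
  aggregate five females' output, 30 for females), an additive
  line effect, and Poisson noise around the linear predictor floored at
  zero — integer offspring with realistic mean-variance coupling.
* **Hatched counts are beta-binomial** with intra-class correlation
  $\rho$: $\mathrm{Var} = n p (1-p)(1 + (n-1)\rho)$. With clutches near 40
  eggs, $\rho = 0.15$ reproduces residual dispersions around 7, the order
  observed in hatch-count models of this kind. The male-by-female cell
  effect is drawn once per cell on the logit scale.
* **Expression** is simulated directly on the normalized scale: per gene,
  a fixed baseline plus Normal line deviations whose SD depends on
  (regime, gene set). Because the mean absolute deviation of a Normal is
  proportional to $\sigma$, the expected divergence ratio of a set equals
  its SD ratio — the lever all recovery tests use.
* All draws flow from one top-level seed through named substreams, one per
  stage, so adding a stage never perturbs another stage's draws, and equal
  (truth, sizes, seed) gives byte-identical tables.

What the generator does **not** emulate: mating-sequence dynamics and
sperm-level mechanics; count-level expression noise is optional rather than
default (ratios are defined on normalized values); expression baselines are
independent across genes, so gene-gene correlation structure in real
transcriptomes is absent. Passing recovery tests therefore shows the
estimators invert the generator's statistical structure — not that real
data meet these assumptions.

## Calibration results and a known limitation

The test suite (problem sizes chosen as a deliberate compromise between
Monte-Carlo error and desk-scale runtimes) verifies at 200 replicates
each: nominal size of the crossed-GLM interaction F test and of both
variance-ratio routes under a null truth (4x4 lines, 5 females/cell,
Poisson(20) clutches); uniformity of the KS set-versus-background p under
equal replicate SDs (1,000 genes, set of 50); recovery of a logit-scale
interaction variance of 0.6 within 15% (8x8 lines, 20 females/cell); and
recovery of a set divergence-ratio of 1.5 within 10% (set of 100).

Two calibration limits are documented rather than hidden.

First, the headline variance-ratio test of the residual route uses
(cells - 1, cells - 1) degrees of freedom — the conventional reference for
a ratio of variances of 16 values. But the cell means of additive-model
residuals are not free: with equal cell sizes they are orthogonal to both
line margins and span only the $(I-1)(J-1) = 9$-dimensional interaction
subspace, so the ratio behaves like $F_{9,9}$, and the $F_{15,15}$
reference over-rejects (about 11% at nominal 5% in the null simulations —
numerically consistent with $P(F_{9,9} > q^{F_{15,15}}_{0.95})$). The
result table therefore carries both rows: the conventional
`variance_ratio_one_sided` at (15, 15) df and
`variance_ratio_interaction_df` at the effective (9, 9) df, which is the
calibrated one. Users quoting a p-value from this route should prefer the
effective-df row.

Second, Wald coverage of
the Bateman gradient is nominal (93-97%) where the gradient is shallow
(the weak regime, slope 0.1), but drops to roughly 89% at the steep slope
of 0.4 under Poisson reproductive-success noise. The cause is structural:
Poisson noise couples the variance to the mean, so the residual variance
grows along the mating-count axis, and the homoscedastic REML/OLS Wald SE
is anticonservative. The effect is scale-free — it depends only on
$(1 - \beta\lambda)/\beta$ — so no sample size or offspring scale removes
it. Users comparing steep gradients should treat Wald CIs as approximate
or bootstrap the slope.

## Degenerate inputs and numerical conventions

* Relativization refuses groups with mean zero, naming the group.
* `I_s` requires at least two values; the Bateman fit requires variance in
  mating counts.
* BCa intervals collapse to percentile (or point) limits when the
  bootstrap distribution is degenerate; $z_0$ is clamped away from
  $\pm\infty$ at $1/(2B)$.
* Bootstrap quantiles use the continuous type-6 rule.
* Regime labels are a closed vocabulary (`WSS`/`SSS`); anything else is
  rejected, never guessed. The same holds for sex labels.
* Two runs with equal configuration and inputs produce byte-identical
  output files; the determinism is asserted by checksum in the tests.
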