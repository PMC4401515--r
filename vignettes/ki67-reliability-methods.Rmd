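---
title: "Methods: simultaneous inter- and intra-observer reliability for Ki-67 scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous inter- and intra-observer reliability for Ki-67 scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The Ki-67 labelling index — the percentage of tumour-cell nuclei staining
positive for the Ki-67 proliferation antigen — guides chemotherapy decisions
in moderately differentiated (G2) breast carcinoma, yet its reproducibility
between and within pathologists is notoriously weak exactly in that midrange
group. Agreement studies therefore compare competing assessment strategies
(regional averaging, dark-nuclei counting, hotspot reading, visual
estimation, digital image analysis) by having several pathologists score the
same tumour sections repeatedly under each strategy, and then ranking the
strategies by how reliable their readings are.

`ki67agree` implements the full analysis pipeline for such a study design:
`n` tumour samples scored by `k` raters under each assessment method, with
`m` repeated rounds separated in time.

## The crossed random-effects model

All estimators assume the balanced two-way crossed model with replicates

$$Y_{ijl} = \mu + s_i + r_j + (sr)_{ij} + e_{ijl},$$

with independent zero-mean normal subject effects $s_i$
(variance $\sigma^2_s$), rater effects $r_j$ ($\sigma^2_r$), subject-by-rater
interaction $(sr)_{ij}$ ($\sigma^2_{sr}$), and replicate error $e_{ijl}$
($\sigma^2_e$). Writing $T$ for the total variance, the two coefficients
estimated *simultaneously from the same data* are

$$\rho_\text{inter} = \frac{\sigma^2_s}{T}, \qquad
  \rho_\text{intra} = \frac{\sigma^2_s + \sigma^2_r + \sigma^2_{sr}}{T}
  = 1 - \frac{\sigma^2_e}{T},$$

so $\rho_\text{inter} \le \rho_\text{intra}$ by construction: disagreement
between raters (the rater and interaction components) erodes inter-observer
reliability but not a rater's agreement with herself or himself.

Estimation is classical method-of-moments: `anova_decompose()` computes the
balanced two-way ANOVA with replicates, `estimate_components()` inverts the
expected mean squares

$$\hat\sigma^2_e = MS_E,\quad
  \hat\sigma^2_{sr} = \frac{MS_{SR} - MS_E}{m},\quad
  \hat\sigma^2_r = \frac{MS_R - MS_{SR}}{nm},\quad
  \hat\sigma^2_s = \frac{MS_S - MS_{SR}}{km},$$

truncating negative estimates at zero (the standard fix; it keeps both
coefficients inside $[0, 1]$, at the price of a small upward bias when a
component is near zero). On balanced data these estimates coincide with the
REML fit of the same model, which the test suite uses as an independent
cross-check (`lme4`), alongside an explicit loop-based summation oracle.

## Hypothesis tests and one-sided bounds

Both coefficients are tested one-sidedly against the prespecified
qualification threshold, $H_0: \rho \le \rho_0$ with $\rho_0 = 0.6$ by
default, at $\alpha = 0.05$. No multiple-testing correction is applied; the
per-method results are exploratory.

**Intra-observer.** Collapsing the design to a one-way layout over the
$nk$ subject–rater cells with $m$ replicates gives the classical exact
interval for a one-way intraclass correlation:
$F_\text{obs} = MS_\text{between}/MS_E$ on $(nk-1,\ nk(m-1))$ df,
$F_L = F_\text{obs} / F_{1-\alpha}$, lower bound $(F_L - 1)/(F_L + m - 1)$,
and the dual p-value $P\{F > F_\text{obs}/\theta_0\}$ with
$\theta_0 = 1 + m\rho_0/(1-\rho_0)$. The p-value crosses $\alpha$ exactly
when the bound crosses $\rho_0$ (verified as a property test).

*Known limitation.* The collapse treats the $nk$ cell effects as
independent, but in the crossed model they share subject and rater effects.
When subject variance dominates — as it does in any usable reliability
study — the between-cell mean square has effective degrees of freedom closer
to $n$ than to $nk$, so the nominal 95% bound under-covers somewhat: in our
coverage simulation (500 crossed-model studies at $n=50$, $k=4$, $m=3$,
$\rho_\text{inter}=0.6$, $\rho_\text{intra}=0.8$) the intra bound covered
90% rather than 92–98%. The construction is retained because it is exact for
the one-way model it states, simple, and deterministic; users who need
calibrated intra bounds at small $n$ should treat it as approximate.

**Inter-observer.** No exact pivot exists for $\sigma^2_s/T$. The package
uses a seeded parametric percentile bootstrap: fit the variance components,
draw `B` synthetic studies of the same dimensions from the fitted normal
model, re-estimate $\rho_\text{inter}$ on each, and take the empirical
$\alpha$-quantile as the lower bound. The p-value is the add-one-smoothed
fraction of bootstrap estimates at or below $\rho_0$,
$(\#\{\hat\rho^* \le \rho_0\} + 1)/(B + 1)$. Coverage of this bound is
validated by simulation (93% at the configuration above, inside the 92–98%
acceptance band). Defaults: $B = 2000$, seed mandatory — there is no silent
nondeterminism anywhere in the package.

## Fleiss' kappa at clinical cut-offs

Clinical use dichotomizes the labelling index at established cut-offs (14%
and 20% by default); a value exactly at the cut-off is "low" (the boundary
is inclusive). Agreement on the dichotomized scale is Fleiss' kappa with
$r$ rating occasions per subject. By default all $k \times m$
rater-repetition occasions are pooled ($r = 12$ in a 4-rater, 3-repetition
study) — the paper-style design does not dictate this, so a single
repetition can be selected instead via the `repetition` argument.

Inference resamples *subjects* with replacement (`B` = 2000 by default) and
applies the bias-corrected (BC) percentile construction: with
$z_0 = \Phi^{-1}(\#\{\kappa^* < \hat\kappa\}/B)$, the one-sided lower bound
at level $\alpha$ is the bootstrap quantile at
$\Phi(2 z_0 + z_\alpha)$. No acceleration term is used (plain BC, not BCa).
The p-value against $\kappa \le 0.6$ is the smallest level whose BC lower
bound exceeds 0.6, found by inverting the bound over a 2001-point level
grid. Resampled tables in which every rating falls in one category leave
kappa undefined; such replicates are dropped and counted, and more than 20%
of them aborts the analysis as unstable rather than silently imputing.

## Weighted ranking, qualification and interpretation

Methods are ranked by the prespecified weighted sum
$0.6\,\rho_\text{inter} + 0.4\,\rho_\text{intra}$ (weights configurable,
must sum to 1). Rank 1 is the best method; ties break toward the higher
inter-observer coefficient, then by method code. A method *qualifies* for
further validation when its weighted sum strictly exceeds 0.6. Coefficients
are labelled on the conventional verbal scales: for ICC-type coefficients
poor (< 0.4), fair good ([0.4, 0.76)), excellent ([0.76, 1]); for kappa the
Landis–Koch ladder (poor ≤ 0, slight to 0.20, fair to 0.40, moderate to
0.60, substantial to 0.80, almost perfect to 1). The printed kappa scale
starts at 0.01, leaving (0, 0.01) uncovered; the slight band is extended
down to 0 for continuity.

Bland–Altman summaries (bias, SD of differences, limits of agreement
bias ± 1.96·SD) are emitted in two views, since a per-method plot does not
dictate the pairing: rater versus rater on per-subject cell means (the inter
view) and repetition versus repetition within each rater (the intra view).

`build_report()` runs the whole pipeline per method, records per-method
failures (e.g., a method with constant readings) without aborting the
others, and `write_report()` serialises the result to JSON with a stable key
order, rounding at serialisation only (3 decimals by default; all internal
computation is double precision).

## Rater dropout

Balanced-design extraction applies an all-or-nothing rule per method: any
rater missing at least one (sample, repetition) cell — relative to the full
grid of samples and repetitions seen for that method — is excluded entirely,
mirroring a five-pathologist study in which one expert's missing assessments
led to analysing four. Partial imputation is deliberately rejected: the
estimators above assume a balanced crossed design. The generalisation to
per-method dropout is ours; with fewer than two complete raters the method
is reported as failed.

## The synthetic-data generator

The study whose design this package mirrors deposited no raw scores, so the
generator is the test bed for every downstream stage. It draws from exactly
the crossed model above, parameterised on the scale users think in:
`components_from_targets()` inverts the coefficient definitions, assigning
$\rho_\text{inter} T$ to subjects, $(1-\rho_\text{intra}) T$ to error, and
splitting the remaining slice between rater and interaction by
`rater_share` (default 0.5, i.e. agnostic). Values are clamped to
$[0, 100]$ — a clamp rather than a logistic warp, because it preserves the
linear model when rare, and the clamped fraction is recorded in the table's
metadata (flagged above 1%). `round_to_five = TRUE` additionally rounds to
multiples of 5, mimicking eyeballed percentages that cluster on 0/5 endings.
Each variance component draws from its own sub-stream derived from the
master seed, so enlarging `n` does not perturb the rater effects.

Defaults mimic the motivating study: $n=50$ subjects, $k=4$ analysed raters,
$m=3$ repetitions, mean labelling index 18%, total variance 80
(SD ≈ 9 percentage points, consistent with a G2 cohort clustered around the
clinical cut-offs), and `study_presets()` carries the seven published
(inter, intra) pairs for methods A–G. The paper gives no distributional
detail beyond cut-off relevance, so `mu` and `total_var` are presets, not
estimates. What the generator does *not* emulate: spatial tumour
heterogeneity, hotspot geometry, rater-specific bias drift over rounds, and
the non-normal, possibly multimodal shape of real labelling indices. Passing
tests therefore demonstrate correctness of the estimators under their
assumed model, not robustness to real-world violations of it.

Power and coverage simulations default to `mu = 50`, `total_var = 100`
instead: the coefficients are location/scale invariant in the untruncated
model, and a central mean keeps clamping below 0.1%, so those simulations
measure the statistics rather than a truncation artefact.

## Power and sample size

For the intra-observer test the one-way collapse yields a closed form:
with $N = nk$ cells, $\theta(\rho) = 1 + m\rho/(1-\rho)$,
$$\text{power} = P\!\left(F_{N-1,\,N(m-1)} >
  \frac{\theta(\rho_0)}{\theta(\rho_1)} F_{1-\alpha;\,N-1,\,N(m-1)}\right).$$
It returns exactly $\alpha$ at $\rho_1 = \rho_0$ and 1 at $\rho_1 = 1$, and
is validated against a Monte-Carlo simulation of the one-way model it
addresses. At the planning design of the motivating study ($n=50$, $k=5$,
$m=3$, $\alpha=0.05$, $\rho_0=0.6$, $\rho_1=0.75$ — an effect size of 0.15
on the reliability scale) this power is effectively 1, consistent with the
design being described as more than sufficient for 80% power.
`minimum_n()` inverts the formula (the analytic power is monotone in $n$);
at $k=5$, $m=3$ eleven subjects already suffice for 80%.

For the inter-observer test no closed form is attempted;
`inter_power_mc()` simulates `R` studies at the alternative (defaults
$\rho_1 = 0.75$, assumed $\rho_\text{intra} = 0.9$, `rater_share` 0.5,
chosen to sit inside the published intra range while remaining agnostic
about the rater/interaction split) and applies the bootstrap test to each
(`B = 500` inside the power loop keeps `R = 2000` runs to about a minute on
one CPU).

*Known limitation.* At that allocation the Monte-Carlo inter power is about
73%, not 80%. This is not a property of the bootstrap test: the sampling SD
of $\hat\rho_\text{inter}$ at $n=50$, $k=5$ is ≈ 0.056 under the
alternative, dominated by the $k-1 = 4$ degrees of freedom of the rater
component, and an oracle test using the exact null 95th percentile as its
critical value reaches only ≈ 73% as well. An 80% figure for the *inter*
hypothesis at this design is attainable only under variance allocations
with (near-)zero rater variance; the intra hypothesis comfortably exceeds
80% regardless. Both numbers are recomputed, not asserted, by
`scripts/acceptance.R`.

## Numerical choices and problem sizes

All computation is in double precision; reports round only at
serialisation. Negative variance components truncate at zero. Degenerate
inputs fail loudly with classed conditions (`ki67agree_*_error`) rather
than returning NA. Quantiles use R's default type 7. The test suite sizes
its simulations to what the properties need: 200-seed batches for recovery
bias, 500 studies for coverage, `R = 400`–`2000` for power checks, with all
seeds fixed.
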