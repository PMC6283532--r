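---
title: "Deviation graphs for diagnosing the double burden of malnutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviation graphs for diagnosing the double burden of malnutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devgraph)
```

## The problem

Many countries carry a *double burden of malnutrition*: undernutrition
(stunting, wasting, micronutrient deficiency) coexisting with overnutrition
(overweight, obesity, diet-related noncommunicable disease). The indicators
that describe it — UNICEF child-nutrition rates, WHO NCD risk factors and
mortality, WASH service coverage, World Bank socioeconomic measures — live
on incompatible scales, so a country's profile across the life course
cannot be read directly from the raw numbers.

devgraph puts every indicator on a common **deviation value** (T-score)
scale: across all countries reporting an indicator, scores have mean 50 and
standard deviation 10. A country at 50 sits at the international reference;
60 is one standard deviation better than average, 40 one standard deviation
worse. Plotting one country's scores, grouped by life stage, yields a
*deviation graph* whose spikes and troughs are that country's specific
strengths and weaknesses relative to economically comparable peers.

## The scoring model

For each indicator $j$ with observed values $x_{1j},\dots,x_{nj}$ over the
countries reporting it:

1. **Normalization.** Cross-country indicator distributions are usually
   skewed and sometimes multimodal, and a log transform is not always
   enough. Each indicator is passed through a Box–Cox power transformation
   $$y = \begin{cases}((x+s)^\lambda - 1)/\lambda, & \lambda \ne 0\\
   \log(x+s), & \lambda = 0\end{cases}$$
   with $\lambda$ chosen to maximize the profile log-likelihood
   $\ell(\lambda) = -\tfrac n2 \log\hat\sigma^2_\lambda +
   (\lambda-1)\sum_i \log(x_i+s)$ over a grid on $[-3,3]$ (step 0.05),
   refined between the best grid point's neighbours by `stats::optimize`
   (golden-section search with parabolic interpolation). The shift $s$ is 0
   for strictly positive data, otherwise $-\min(x) + 0.01\,\mathrm{range}(x)$
   — mortality and prevalence variables can legitimately be 0 and Box–Cox
   needs positivity. $\lambda$ is estimated per indicator over **all**
   countries with data, never within an income group: scores are global,
   grouping is display.

2. **Standardization.** The deviation value is the classical T-score
   $T = 50 + 10\,(y - \bar y)/s_y$ with the sample (n−1) standard
   deviation. This guarantees mean 50 and SD 10 exactly, for any input
   distribution — the package's central invariant, tested across all
   generator families.

3. **Ceiling indicators.** Near-universal rates (primary school
   participation, adult literacy, vitamin A supplementation) pile up
   against 100% and carry almost no usable spread; a power transform
   cannot unpile them. These are scored by rank instead: with midranks for
   ties, $p_i = (r_i - 0.5)/n$ and $T_i = 50 + 10\,\Phi^{-1}(p_i)$. The
   median country gets 50, the 25th percentile $\approx 43.3$. The plotting
   position $(r-0.5)/n$ was chosen over $r/(n+1)$ and the empirical CDF
   because it is symmetric and keeps $p$ strictly inside $(0,1)$; the
   choice is recorded in every export. The registry's `ceiling` flag
   decides the method; a heuristic (≥ 25% of values within 1% of the
   100-point ceiling) warns about percent-scaled indicators that look
   compressed but are not flagged — it never switches methods silently.

4. **Orientation.** For indicators where lower raw values are desirable
   (stunting, smoking, NCD mortality), scores are reflected about the
   reference, $T \mapsto 100 - T$, so that *higher always means more
   desirable* in every display. Reflection is an involution and preserves
   the mean-50/SD-10 calibration. Profiles keep both readings: a
   raised-blood-pressure score displayed as a weakness at 27 is still
   recoverable as "blood pressure very high at 73". Neutral indicators
   (total population — purely descriptive) are never reflected and are
   excluded from strength/weakness flagging, but stay in the profile for
   context.

## Reading a profile

Scores are banded for narration: below 35 `very_low`, 35–45 `low`, 45–55
`middle` (inclusive on both ends), above 55 to 72 `high`, 72 and up
`very_high`. The middle band brackets half a standard deviation around the
reference; the outer cuts sit where practitioners switch from "high" to
"very high" language. They are conventions, overridable per run.
`flag_extremes()` mechanizes the verbal reading: oriented scores at least
one SD (k = 10 points) from the reference are strengths or weaknesses,
most extreme first.

Because the score is a *relative position among reporting countries*, a
country missing an indicator never affects others' scores on other
indicators, but removing a country that does report shifts the reference
for everyone else. Comparisons are only meaningful against the same
reporting set; exports therefore record per-indicator n.

## Distribution modality

Even after transformation, score distributions fall into four shapes —
normal, distorted (unimodal, skewed), bimodal, trimodal — and the shape is
itself diagnostic: a bimodal indicator splits countries into two regimes.
`classify_modality()` labels each indicator. The skewness gate runs first
(|moment skewness| > 0.8 → `distorted`); otherwise modes are counted.

The default mode counter fits Gaussian mixtures with 1–4 components (EM,
equal- and unequal-variance models) and keeps the most complex fit whose
BIC is within 6 of the best, then counts the fitted density's modes with a
prominence gate (≥ 5% of the peak density). The BIC slack matters: at
~200 observations BIC alone is conservative and folds moderately separated
three-component mixtures into two. A plain fixed-bandwidth KDE counter is
available as `method = "kde"` for transparency, but no single bandwidth
both resolves three modes at 3-SD separation and ignores sampling ripples
at this sample size — we verified this across bandwidth multipliers
0.3–1.2, Silverman and Sheather–Jones rules, and prominence thresholds
0.02–0.2, which is why the mixture counter is the default. Defaults were
calibrated once against the synthetic generator's four families (recovery
rates 0.99 / 0.98 / 0.96 / 0.93 over 100 replicates each) and then frozen.
Labels are invariant under affine rescaling. Below 20 observations the
shape is not estimable and the label degrades to `normal` with a
low-confidence flag. These labels are a reproducible proxy for a
taxonomy that is usually assigned by eye; they are not a significance
test (no dip-test machinery).

## The synthetic generator

No raw multi-agency country table ships with the package, so
`generate_table()` makes one with the structure the method assumes: 194
countries in income classes of 55/57/48/34 (high / upper-middle /
lower-middle / low), indicators drawn i.i.d. per country from five
families — gaussian, skewed (gamma, shape 2, affinely mapped), bimodal and
trimodal Gaussian mixtures with adjacent means 3 component-SDs apart, and
ceiling (`100·Beta(45, 1)`, putting over a third of countries within one
point of 100) — with completely-at-random missingness per indicator.
Separation at 3 SDs makes the mixtures clearly but not trivially
multimodal; Beta(45,1) reproduces the near-universal-literacy regime that
forces percentile scoring.

What the generator deliberately does **not** emulate: between-indicator
correlation (real GNI and stunting are strongly dependent), informative
missingness (real reporting gaps correlate with income), and country
identity. Passing tests therefore demonstrate the *per-indicator* scoring
machinery — calibration, orientation, banding, modality — not the joint
realism of any particular country's profile.

## Numerical conventions and edge cases

- Sample SD uses the n−1 denominator throughout (conventional for
  T-scores); the conservation tests pin this choice.
- An indicator needs ≥ 3 reported values for a defined SD; sparser columns
  are dropped with a warning (sparse reporting of vitamin A
  supplementation and diarrhea deaths is expected in practice, and should
  not sink a run). A constant indicator is a hard per-indicator error,
  collected into the run report without aborting other indicators.
- `boxcox_apply` uses the exact `lambda == 0` branch for the log; the
  power branch converges to it entrywise as λ → 0 (tested at λ = 1e−6).
- Ties in percentile scoring share a midrank score; distinct values map to
  strictly increasing scores.
- Banding is total and exclusive over the finite scale; missing values
  carry a missing band.

## Problem sizes

The test suite and examples run the full pipeline at the study scale
(194 countries, ~10–53 indicators), 20-seed conservation sweeps over all
five families, and 100-replicate-per-family modality recovery; the whole
suite completes in well under a minute on one core.

## Limitations

Scores are relative: they move when the reporting set changes, and say
nothing about absolute attainment (a country can be "high" on an indicator
on which every country does poorly). The modality labels and banding
cutpoints are package conventions, exposed as configuration. Real country
tables must be assembled by the user from agency sources; the packaged
53-indicator registry is a template for that assembly, not a dataset.
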