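---
title: "Ribosome resource allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribosome resource allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboalloc)
```

## The growth law and what its parameters mean

Making protein is the dominant activity of a growing yeast cell, and
ribosomes make all of it — including themselves.  Under balanced growth
(total protein doubling once per division) the specific growth rate
$\mu = \ln 2 / T_d$ is set by how much of the proteome is actively
translating ribosomes, $\mu = \gamma\, r_a$, where $\gamma$ is the rate at
which one active ribosome synthesises its own mass equivalent.  Writing the
*measured* ribosomal proteome fraction as $r = r_a + r_0$, with $r_0$ the
residual fraction that is not translating, gives the linear law this
package is organised around:

$$ r = \gamma^{-1}\mu + r_0 = s\,x + r_0, $$

where $x = \mu/\ln 2$ is the growth rate in generations per hour — the
plotting unit used throughout — and $s$ is the slope in that unit.
`scaling_fit()` estimates $(s, r_0)$ by ordinary least squares and reports
the slope in both time readings: $60s$ minutes (exact if single-cell
growth were linear in time) and $60s/\ln 2$ minutes per unit $\mu$
(exponential growth).  The two differ by exactly $\ln 2$; `slope_vs_gamma()`
compares either against the first-principles translation time
`gamma_inverse()` $= 12485\,\mathrm{aa} / (10.5\,\mathrm{aa/s} \cdot 60)
\approx 19.8$ min and reports the exact percentage gap rather than a
rounded one, because the reconciliation depends on which growth reading one
adopts.

Three consequences of the law are exposed as predictions from a fitted
object:

* the **inactive share** $\rho(x) = r_0/(s x + r_0)$ (`predict(fit, x,
  type = "inactive")`), equal to 1 at zero growth and about 0.25 at
  0.67 gen/hr for the wild-type parameters $s = 0.35$, $r_0 = 0.08$;
* the **active:inactive ratio** $r_a/r_0 = s x / r_0$, which depends only
  on the condition if a burden rescales $(s x, r_0)$ proportionally;
* `residual_scenarios()`: if $\gamma$ is growth-rate independent, $r_0(x)$
  is flat and $\rho$ rises as growth slows; if instead
  $\gamma = a^{-1}\mu$, then $r_0(x) = (s x + r_0) - a$ rises with growth
  rate.  The package computes both; it does not adjudicate between them.

Fitting uses condition medians by default (`ribosomal_scaling(aggregate =
"median")`) because replicate-level weighting schemes are not identifiable
from typical three-replicate designs; a replicate-level fit is available
via `aggregate = "none"`.  Negative fitted intercepts are reported with a
warning, never clamped — a clamped intercept would silently hide a
violation of the model.

## From peptide tables to sector fractions

`quantify_top3()` implements top-3 label-free quantification: a protein's
abundance is the sum of its three most intense *unique* peptides.  Proteins
with fewer than three unique peptides contribute the sum of what they have
(dropping them would censor low-abundance proteins); proteins with none are
dropped and reported.  `to_fractions()` normalises to total signal, after
which `group_fraction()` sums sector (gene-group) fractions.  Sector maps
may overlap slightly; each group is summed independently (duplicated mass
allowed) and `group_fractions()` adds a residual "other" entry, floored at
zero, for the unassigned remainder.

`proteome_correlation()` correlates compositions pairwise over the
proteins detected in both profiles.  Because MS fractions span decades and
linear-scale Pearson is dominated by a handful of glycolytic proteins, the
default correlates $\log_{10}$ fractions floored at $10^{-7}$; the raw
scale is kept behind a flag since the convention used for published
condition-correlation heatmaps is rarely stated.  In
`log2_mean_normalized()` a protein must be detected in at least half the
conditions; remaining zeros are imputed at half the per-condition detection
floor.  Both thresholds are arguments.

External calibration (`calibrate_to_reference()`) rescales a profile by a
single factor — the median reference/profile ratio over shared proteins
(at least 50 by default) — deliberately not per-protein replacement, so
within-profile ratios are untouched.

## Polysome profiles and the rRNA correction

A sucrose-gradient absorbance trace mixes rRNA and mRNA signal.  One
ribosome carries about $L_{rRNA} = 5500$ nt of rRNA while the average mRNA
is $L_{mRNA} = 1250$ nt, so the rRNA share of an $n$-ribosome particle is
$f_n = n L_{rRNA}/(n L_{rRNA} + L_{mRNA})$ — 81.5 % for monosomes, 95.7 %
for pentasomes (`rrna_fraction()`).  Multiplying raw peak areas by $f_n$
converts them to ribosome-equivalents.  Free 40S/60S subunits are treated
as pure rRNA ($f = 1$) since they carry no mRNA; this case is isolated in
one place so the convention is easy to change.  The inactive fraction is

$$ \rho = \frac{e_{40S} + e_{60S} + e_{mono}}{\sum_k e_k}, $$

on corrected equivalents by default; the uncorrected variant is one
argument away because published descriptions of the correction leave the
arithmetic implicit.  The polysome:monosome ratio, by contrast, is defined
on *raw* areas — polysome integral over (40S + 60S + monosome) integral —
matching the stated experimental definition exactly.

Numerical choices in `integrate_peaks()`: peak boundaries are the local
minima of a moving-average smoothed copy (window 5 samples) between
adjacent expected peaks, with window edges as fallback; integration is
trapezoidal on the *raw* trace (densely sampled traces gain nothing from
higher-order schemes at realistic noise); boundaries are snapped to grid
indices so splitting a window into sub-windows conserves area exactly.
Signal beyond the last resolved polysome peak (default $n = 8$) is
integrated as a tail and corrected as $n = 9$; since $f_9 > 0.97$, the
worst-case assignment error there is under 3 % of that tail's mass.
`preprocess_trace()` subtracts an interpolated blank gradient, registers
traces in x on the monosome peak (the most consistent feature across
conditions) and optionally y-scales to a reference's total area; negative
post-subtraction values are floored at zero with the floored mass
reported.

## Growth kinetics

All rates are log2 slopes per minute times 60 (gen/hr).  `lag_and_rate()`
fits a continuous hinge — flat, then log-linear — by least squares with the
breakpoint searched over the observed sample times only; at 15–20 min
plate-reader sampling a sub-sample breakpoint would be precision the data
do not contain, so single-curve lag estimates are grid-quantised and
multi-seed means should be used when the lag matters.  `recovery_time()`
is the first (interpolated) time the culture reaches 1.5× its initial
density, which on a noiseless lag-then-exponential curve equals
$L + 60\log_2(1.5)/g$ — the identity the tests exploit.
`shift_response()` estimates rates in 25-min windows flanking an upshift;
single-cell volume traces should be pooled with
`average_growth_curves()` first (the experimental convention averages 50
cells).  `lead_time()` needs an explicit change-point rule where the
original analyses judged onset visually: a series has changed when it
drops below 90 % of its initial plateau (mean of the first three samples)
for two consecutive samples.  All of $\delta$, $k$ and the plateau width
are arguments.

## Burden analysis

Relative fitness is the OLS slope of $\log_2$ wild-type frequency against
generations (`fitness_from_competition()`), exactly as the assay protocol
defines it, even though log-odds would be the population-genetics
standard; the natural-log reading is returned alongside, never silently
substituted.  `per_copy_cost()` regresses fitness on copy number.
`mcherry_calibration()` converts the TDH3-anchored reference (2.2 % of
the proteome) through the measured 14.5 % one-copy deficit to absolute
burden fractions, linear per copy unless measured relative levels are
given.  `burden_scaling()` fits the growth law per strain and summarises
the expected structure — a burden-invariant slope and a copy-linear
intercept — via the largest pairwise slope difference scaled by the pooled
SE of a pairwise contrast ($\sqrt{2\,\overline{se^2}}$), a z-like
statistic whose expectation is about 1.5 for four strains under perfect
homogeneity.  `predict_recovery_delay()` models the recovery delay as
inversely proportional to the residual pool (fold = $r_0^{ref}/r_0^{burden}$);
a $-\log r_0$ alternative is behind a flag because for small pool changes
the two are close and the data do not separate them.

## What the synthetic generators emulate — and what they do not

Every pipeline input has a generator whose output carries a
`synthetic_truth` record, so each analysis can be tested as a round trip
against known ground truth.  The defaults describe the study conditions
the analyses were built for:

* `simulate_proteome()`: 15 conditions spanning 0.15–0.67 gen/hr with the
  ribosomal sector exactly on $r = 0.35x + 0.08$; other sectors follow
  linear tilt rules (mitochondrial and stress sectors up at slow growth,
  glycolysis flat) and are renormalised so sectors sum to one; three
  replicates with multiplicative lognormal per-protein noise (CV 5 %, a
  typical label-free replicate spread).  Within-sector protein weights are
  lognormal with $\sigma_{\log} = 1$ — a free choice, since per-protein
  distributions within sectors are not constrained by the sector-level
  analyses.
* `simulate_polysome_trace()`: Gaussian peaks at fixed canonical positions
  (40S = 1.0, 60S = 1.4, monosome = 1.9, then +0.5 per ribosome) whose
  areas *invert* the rRNA correction so the true ribosome-equivalent
  inactive fraction equals the requested $\rho$; polysome weights decay
  geometrically (ratio 0.7 over $n = 2..8$, matching the visual shape of
  fast-growth profiles); additive Gaussian noise at 1 % of the tallest
  peak.
* `simulate_growth_curve()`: flat lag, exponential growth, optional rate
  step at an upshift, logistic flattening at saturation; multiplicative
  Gaussian noise (OD readers err proportionally).
* `simulate_competition()`: log2-linear frequency drift from a 50 %
  starting frequency, noise on the log2 scale, frequencies clipped to the
  open unit interval.

Noise structure is the standard one for each measurement type
(multiplicative lognormal for positive right-skewed MS intensities,
additive for absorbance, multiplicative for OD), chosen once.  Seeds are
explicit arguments everywhere; no generator touches global RNG state.

What the generators deliberately do **not** emulate: peptide-level
chromatography and spectral interference, gradient baseline drift and
peak-shape asymmetry, halfmers, condition-correlated replicate structure,
or cell-to-cell variability beyond independent trace noise.  Passing
round-trip tests therefore shows the estimators are correct and unbiased
under clean generative assumptions — not that they are robust to every
artefact of real instruments.

## Problem sizes and tolerances

Round-trip checks use 20 seeds per setting: the condition-series proteome
(15 conditions × 3 replicates × 240 proteins) recovers the slope within
±0.02 and the intercept within ±1 percentage point; the gradient pipeline
recovers $\rho$ within ±0.02 over targets 0.1–0.5; lag recovery uses
15-min sampling over 5 h (mean within ±10 min of a 40-min lag) and the
upshift uses 50 averaged 3-min-sampled volume traces (rates within 10 %).
These sizes match the scale of the corresponding experiments while keeping
the whole suite's runtime in seconds.  Integration accuracy is held to
0.1 % against closed-form Gaussian areas on noiseless traces, and all OLS
paths are checked against the normal equations at $10^{-10}$.

## Known limitations

The piecewise lag model assumes a clean flat-then-exponential shape; real
stationary-exit curves with slowly accelerating growth will bias the
breakpoint late.  The change-point rule in `lead_time()` is sensitive to
the plateau estimate when a series starts mid-decline.  Monosomes are
counted as wholly inactive in $\rho$ — the field debates how much
initiation-engaged monosome signal is translating, and this package
computes the stated convention rather than resolving the debate.  The
burden recovery-delay model is a one-parameter proportionality; it is not
a mechanistic model of translation during starvation exit.
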