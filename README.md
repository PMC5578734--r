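# riboalloc

Condition-dependent proteome resource allocation in budding yeast, built
around the linear growth law between ribosome content and growth rate.

## The problem and the model

Ribosomes synthesise all protein, including themselves, so under balanced
growth the specific growth rate µ = ln(2)/T_d is set by the actively
translating ribosomal proteome fraction r_a through µ = γ·r_a, where γ is
the rate at which one active ribosome makes its own mass equivalent.  The
*measured* ribosomal fraction r also contains a residual, non-translating
part r₀, giving the law this package fits and interprets:

    r = γ⁻¹µ + r₀ = s·x + r₀,        x = µ/ln 2  (generations per hour)

From a fitted (s, r₀) the package predicts the inactive ribosome share
ρ(x) = r₀/(s·x + r₀) and the active:inactive ratio s·x/r₀, compares the
measured slope with the first-principles translation time
γ⁻¹ = 12,485 aa / (10.5 aa/s · 60) ≈ 20 min, and tests the prediction
against sucrose-gradient polysome profiles via the rRNA correction
f_n = n·L_rRNA/(n·L_rRNA + L_mRNA).  Around this core sit modules for
top-3 label-free proteome quantification and sector fractions, gradient
peak integration, growth-curve kinetics (lag, recovery, upshift response,
lead times), protein-burden costs from competition assays, and synthetic
generators that produce every input type with known ground truth.

Intended users: systems biologists analysing condition-series proteomes,
polysome profiles, or burden/competition experiments, and anyone wanting a
tested desk-scale reimplementation of the growth-law analysis chain.

## Worked example

```r
library(riboalloc)

## synthetic 15-condition proteome on the wild-type line (s=0.35, r0=0.08)
sim <- simulate_proteome(seed = 1)
fit <- ribosomal_scaling(sim$profiles, sim$group_map)
summary(fit)
#> Ribosome-content growth law (OLS)
#>   r = 0.3466 * x + 0.08189   (x in gen/hr, n = 15, R^2 = 0.9988)
#>   slope = 20.8 min (linear reading);  dr/dmu = 30.01 min
#>   intercept r0 = 0.08189 +/- 0.00148
#>   slope     s  = 0.3466 +/- 0.003362 per (gen/hr)
#>   inactive ribosome share at x = 0.67 gen/hr: 0.2607
```

The fitted slope read in minutes (≈21 min) is the time an active ribosome
would need to duplicate itself if growth were linear in time; per unit µ
it is ≈30 min, about 34% above the first-principles 19.8 min
(`slope_vs_gamma(fit, gamma_inverse())`).  The intercept says ≈8% of the
proteome encodes ribosomal proteins even at zero growth, so at fast growth
(0.67 gen/hr) about a quarter of ribosomal protein is not translating.

```r
## polysome profile with true inactive fraction 0.18, quantified end to end
tr <- simulate_polysome_trace(rho = 0.18, seed = 1)
bl <- simulate_blank_trace(tr, seed = 2)
quantify_trace(tr, blank = bl)
#> Gradient peak quantification
#>                   40S    60S   mono  poly2  poly3  poly4  poly5  poly6 ...
#> area           0.0372 0.0553 0.1113 0.2979 0.2017 0.1389 0.0958 0.0675
#> ribosome_equiv 0.0372 0.0553 0.0907 0.2675 0.1875 0.1314 0.0916 0.0650
#>   inactive fraction rho = 0.1815 (raw 0.1868);  P:M = 4.353
```

Blank subtraction, boundary detection, trapezoidal integration and the
rRNA correction recover ρ = 0.18 within noise; the raw (uncorrected)
variant is reported alongside.

```r
## stationary-exit kinetics: 40-min lag, 0.55 gen/hr, 15-min OD sampling
gc <- simulate_growth_curve(od0 = 0.1, lag = 40, rate = 0.55,
                            noise_cv = 0.02, seed = 1)
unlist(lag_and_rate(gc)[c("lag", "rate")])
#>        lag       rate
#> 45.0000000  0.5590561

## burden: the 8-copy strain's smaller residual pool predicts slower recovery
predict_recovery_delay(0.081, 0.055)
#> $fold                 $percent_prolongation
#> [1] 1.472727          [1] 47.27273
```

Single-curve lag estimates are quantised to the sampling grid (here 45 vs
a true 40 min); multi-seed means converge to the truth.

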