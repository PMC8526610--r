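# railbat

Quantifying how passing trains suppress bat echolocation activity.

Railway verges are attractive foraging and commuting habitat for
pipistrelle bats, yet every train pass is a brief, intense disturbance.
`railbat` implements an event-anchored interval analysis of trackside
acoustic monitoring data: bat-pass counts in fixed-duration windows
**before**, **after** and **between** train passes (within each train-free
*inter-train gap*) are compared with negative binomial count models, and an
estimated effect duration is converted into the fraction of night-time a
site loses to disturbance.

The package is aimed at ecologists analysing paired bat-detector /
train-log recordings, and ships a synthetic generator (train schedules,
suppressed bat-pass point processes, calibration audio with known ground
truth) so the entire pipeline is testable without field data.

## The model

Interval counts are NB2 negative binomial with log link,

    y_ij ~ NB(mu_ij, theta),   Var = mu + mu^2 / theta
    log mu_ij = b0 + b_cat(j) + x_ij' g + u_site(i),  u ~ N(0, s_u^2)

with interval category (before / between / after) the exposure of interest,
screened confounders (nightly pass total, time since recording start,
weather, gap duration, train density) as covariates, and a location random
intercept fitted by Laplace approximation. Candidate covariates pass a
univariate screen at p ≤ 0.1; all subsets of the screened fixed effects are
ranked by AICc; coefficients are averaged over the ΔAICc ≤ 6 set with
Akaike weights (full, zero-substituted averaging). Category contrasts are
reported as incidence rate ratios, `IRR = exp(estimate)`.

Supporting modules provide: bat-pass segmentation (calls separated by
> 1 s), train length (cars × 21 m) and speed ((length / duration) × 3.6)
estimates, inter-train gap construction with overlap exclusions, calibrated
sound-pressure-level curves (94 dB reference tone; 6.25 readings/s at
5 Hz minimum pitch), distance standardisation (SPL2 = SPL1 −
20·log10(r2/r1)), Welch mean spectra with a high/low squeal-frequency
classifier, and the exposure arithmetic
`min(1, trains_per_hour × duration / 3600)`.

## Worked example

Simulate a 6-site study (two nights per site, activity halved for 120 s
after each train), build the 30 s interval table, and run the full
screening → AICc → averaging chain:

```r
library(railbat)

st <- simulate_study(n_sites = 6, nights_per_site = 2, seed = 42)
ds <- assemble_dataset(st$calls, st$trains, st$nights, d = 30)
res <- disturbance_analysis(
  ds, candidates = c("nightly_total", "time_since_start_h", "wind"))
res
#> Interval-category contrasts:
#> # A tibble: 3 × 10
#>   contrast         estimate    se conf_low conf_high     z       p   irr irr_low
#>   <chr>               <dbl> <dbl>    <dbl>     <dbl> <dbl>   <dbl> <dbl>   <dbl>
#> 1 between vs befo…   -0.250 0.104   -0.454  -0.0457   2.40 1.64e-2 0.779   0.635
#> 2 after vs before    -0.480 0.111   -0.698  -0.263    4.33 1.51e-5 0.619   0.498
#> 3 after vs between   -0.230 0.116   -0.458  -0.00260  1.98 4.74e-2 0.794   0.632
```

Activity in the 30 s after a train is ~38% below the 30 s before the next
one (IRR 0.62, 95% CI 0.50–0.77). The contrast is attenuated relative to
the generating factor (0.5) because in short gaps even the "before" and
"between" windows sit inside the 120 s post-train window — see the methods
vignette. `autoplot(res$contrasts)` draws the IRR forest plot.

Convert an effect duration into lost time per site:

```r
site_exposure_report(st$sites, effect_duration_s = 120)
#> # A tibble: 7 × 6
#>   site_id trains_per_hour effect_duration_s suppressed_fraction ...
#> 1 S01                1.7                120              0.0567
#> 2 S02                5.22               120              0.174
#> 3 S03                8.74               120              0.291
```

At 6 trains/hour a 120 s effect suppresses activity for one-fifth of the
night (`suppressed_fraction(6, 120)` = 0.2); a train every three minutes
costs two-thirds.

Acoustics round trip on synthetic audio:

```r
aud <- simulate_calibration_audio(
  passes = tibble::tibble(start_s = 20, end_s = 26),
  peak_spl_db = 107.3, seed = 5)
cal <- calibrate_spl(compute_spl_curve(aud), ref_segment = c(1, 9),
                     ref_level_db = 94)
max_spl(cal, 20, 26)          # 107.4 — recovers the 107.3 dB truth
correct_distance(107.3, 10.6) # 127.8 dB at 1 m
```

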