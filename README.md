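# gaitcx

Linear and nonlinear stride-time variability from a pocket-worn
smartphone accelerometer, for researchers studying gait dynamics in
free-living settings (ageing, fall risk, telehealth monitoring).

Healthy walking is variable in a structured way: the inter-stride-interval
(ISI) series of an adult shows persistent long-range correlation, and that
structure — not just the size of the fluctuations — changes with age and
pathology. `gaitcx` turns a raw, irregularly sampled vertical-acceleration
recording into per-participant gait measures:

| stage | what it does |
|---|---|
| preprocessing | linear interpolation to a uniform 100 Hz grid; gravity-bias removal; orientation correction; causal 4th-order Butterworth low-pass at 16 Hz (raw and filtered streams kept in parallel) |
| heel-contact detection | 0.1 Hz drift high-pass → cumulative trapezoidal integration to velocity → first-derivative-of-Gaussian wavelet at scale 12 → thresholded candidate minima (40% of the median of the 10 deepest, >0.8 s apart) → minimum→maximum→minimum chaining → 3-frame relocation in the raw stream |
| bout segmentation | split at >1.8 s gaps; keep bouts of >24 strides; trim 2 strides at each end; retain 20+ strides |
| measures | xISI, SD, COV (bouts ≥20 strides); FSI/DFA, ApEn, SaEn (bouts >255 strides); MSE scales 1–4, CI, SPD, EnHL (first 800 strides of the longest bout) |

The core statistics, in the field's standard notation:

* **FSI** (fractal scaling index): DFA slope α of log₁₀F(n) vs log₁₀n,
  boxes n = 10…40; α ≈ 0.5 for uncorrelated stride times, α ≈ 1 for
  strongly persistent ones.
* **ApEn / SaEn**: template regularity with m = 2, r = 0.15·SD
  (Chebyshev); SaEn excludes self-matches and is exactly 0 for a periodic
  series.
* **MSE / CI**: SaEn of coarse-grained series at scales τ = 1…4 (radius
  fixed from the scale-1 SD) and the trapezoidal area under that curve.
* **SPD**: reshape the series at stride-order separations s = 1…100
  (deal-into-s-piles), compute α(s), and report the first s with α(s)
  below the permutation-surrogate critical limit mean(α_rand) + 2·SD(α_rand).
* **EnHL**: normalized SaEn(s) = (SaEn_reshape − SaEn_orig)/(SaEn_rand −
  SaEn_orig); the half-life is the first s at which half the series'
  predictability is lost (normalized value reaches 0.5).

Because study recordings are not distributable, the package ships a
first-class synthetic module: exact circulant-embedding fractional
Gaussian noise for stride times and a parametric gait waveform whose heel
contacts are known exactly, so every pipeline stage is testable.

## Worked example

Simulate a persistent walker (Hurst 0.9, mean stride 1.12 s, SD 0.04 s)
with two walking bouts, run the pipeline, and score detection against the
known ground truth:

```r
library(gaitcx)

isi1 <- simulate_isi("fgn", n = 300, mean_s = 1.12, sd_s = 0.04,
                     hurst = 0.9, seed = 1)
isi2 <- simulate_isi("fgn", n = 60, mean_s = 1.12, sd_s = 0.04,
                     hurst = 0.9, seed = 2)
rec <- simulate_recording(list(isi1, isi2), gap_s = 12, seed = 3)
rec
#> <synthetic_recording> 2 bout(s), 362 true contacts, 416.9 s

report <- run_pipeline(list(walker = rec))
report$frequency
#>   participant walking_bouts total_strides longest_bout shortest_bout
#> 1      walker             2           352          296            56

round(report$measures$xisi, 3)   #> 1.102
round(report$measures$cov, 2)    #> 2.94
round(report$measures$fsi, 2)    #> 0.81
round(report$measures$saen, 2)   #> 2.01

ev <- detect_heel_contacts(preprocess_recording(rec$accel))
ev$raw
#> <heel_contacts:raw> 362 events, median ISI 1.110 s
max(abs(sort(ev$raw$times) - rec$true_rhc_times)) * 1000
#> [1] 7.236579
```

All 362 true contacts are recovered with a worst-case error of 7 ms. The
mean stride time (1.102 s) and COV (2.94%) match the realized series (the
sample mean of persistent fGn wanders more than an i.i.d. series would);
the FSI of 0.81 reflects the single 296-stride bout — short-series DFA
estimates scatter around the generating H = 0.9. MSE/CI/SPD/EnHL are `NA`
here with the recorded reason that no bout reaches 800 strides;
`report$details$walker$eligibility` lists it.

A thin CLI wraps the same functions:

```sh
inst/cli/gaitcx simulate --model fgn --n 804 --hurst 0.9 --out rec.csv
inst/cli/gaitcx run --out results rec.csv
```

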