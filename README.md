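# vctkit

Simulation and analysis of **video cone tests (VCTs)** — WHO cone
bioassays of insecticide-treated bed nets (ITNs) augmented with video
recording — for entomologists and net-evaluation labs who want
behavioural endpoints (movement, excito-repellency, knockdown dynamics)
alongside the classical mortality/knockdown readouts.

The package provides the complete measurement chain in one place:

* an **agent-based simulator** of a 5-mosquito, 3-minute cone assay with
  the four scan-sampling states — contacting the net (N), flying (F),
  resting on the cone (C), knocked down (K) — including
  contact-driven irritancy (excito-repellency) and delayed
  contact-driven knockdown, plus a grayscale video renderer that gives
  the vision stage exact ground truth;
* a **movement detector**: per-pixel adaptive mixture-of-Gaussians
  background subtraction (Stauffer–Grimson-style; K = 3, λ = 2.5 SD,
  T = 0.9, α = 0.02) with 8-connected blob extraction, counting moving
  mosquitoes at 0.1-s intervals — 1800 analyzed frames per assay;
* **activity summaries**: total movements per assay, upper/lower cone
  region split, half-open 5-s bins, cross-replicate means with 95% CIs;
* **scan-sampling summaries**: N/F/C/K counts at 5-s intervals (37 time
  points per assay) with replicate means and CIs;
* the **statistics workflow** used on such data, operating directly on
  published group summaries (n, mean, SD): Welch's *t* with
  Welch–Satterthwaite df, Cohen's *d* (pooled SD) with CI, *t*-based
  mean CIs and their inversion to recover group sizes, mean-centred
  Levene, Type-III two-way ANOVA with partial η², Shapiro–Wilk residual
  checks, estimated marginal means and Tukey-adjusted contrasts, WHO
  bioassay endpoints with Abbott control correction;
* **chemical QC**: the HPLC content equation
  `I = (x/a) · (0.001/m) · C · f` (g/kg) with multi-round extraction
  totals and RSD, conversion to mg/m², and Raman preprocessing
  (Savitzky–Golay, asymmetric-least-squares baseline, vector
  normalisation) with a 1000 cm⁻¹ crystallinity marker call.

## Worked example

```r
library(vctkit)

geom   <- cone_geometry()                                   # 128 x 96 px cone scene
truth  <- simulate_cohort(net_presets("irritant_toxic", rng_seed = 1), geom)
frames <- render_video(truth, geom, noise_sd = 4, seed = 2) # 1801 grayscale frames
series <- analyze_recording(frames, fps = 10)               # 1800 analyzed frames
aggregate_bins(series, geom)$total_activity
#> [1] 3120

scans <- scan_sample(truth)           # 37 scan points, states N/F/C/K
scans[scans$time_point_s %in% c(90, 180), ]
#>    time_point_s n_N n_F n_C n_K
#> 19           90   0   3   0   2
#> 37          180   0   1   0   4
```

Total activity of 3120 movement events is in the range typical of an
irritant net; the scan rows show knockdown accumulating late in the
assay (2 of 5 down at 90 s, 4 of 5 at 180 s), the signature of
contact-driven delayed toxicity.

The statistics work straight from published summaries:

```r
a <- group_summary(3628.3,   n = 40, sd = 1014.209, label = "PFAS (+)")
b <- group_summary(3211.655, n = 55, sd = 830.311,  label = "PFAS (-)")
welch_t(a, b)
#> Welch two-sample t test (from summaries)
#>   t: 2.13034
#>   df: 73.6488
#>   p: 0.0364836
cohens_d(a, b)
#> Cohen's d (pooled SD)
#>   d: 0.45687
#>   conf_int: 0.0389994 to 0.87474
```

A command-line wrapper with `simulate / render / detect / activity /
scan / stats / chem / demo` subcommands lives at `inst/cli/vct.R`;
`demo --seed 1 --out dir` runs the whole chain on generated fixtures and
writes a byte-stable JSON report.

See `vignettes/cone-assay-platform.Rmd` for the models, parameter
conventions, validation strategy and known limitations.

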