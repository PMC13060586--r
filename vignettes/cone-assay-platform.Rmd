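---
title: "Models and methods behind vctkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vctkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vctkit)
```

# What this package models

The WHO cone assay confines five female mosquitoes under a plastic cone
pressed against a swatch of insecticide-treated net (ITN) for 3 minutes;
knockdown is read at 60 minutes and mortality after 24 hours.  A video
cone test (VCT) adds a camera.  Two complementary readouts are then
possible: an automated one — per-frame counting of *moving* mosquitoes by
background subtraction, analyzed at 0.1-s intervals and aggregated into
5-s bins split between the upper and lower halves of the cone — and a
manual one, scan sampling of each mosquito's behavioural state every 5 s
into four categories: contacting the net (N), flying (F), resting on the
cone (C), knocked down (K).  `vctkit` implements the full measurement and
analysis chain, plus an agent-based simulator that stands in for real
recordings (none are publicly deposited) and provides exact ground truth
for validating the vision stage.

The package also carries the two satellite workflows that surround such
assays in a net-evaluation study: the summary-statistic comparison
workflow used on total-activity data (Welch *t*, Cohen's *d*, Levene,
two-way ANOVA with estimated marginal means), and chemical QC
computations (HPLC content quantification and Raman spectral
preprocessing with a crystallinity marker call).

# The behavioural simulator

`simulate_cohort()` runs a continuous-time Markov-style model on a fixed
0.1-s grid.  Each agent is in one of the four states N, F, C, K.  Per-step
transition probabilities discretise per-second hazards as
$1 - e^{-\lambda\,\Delta t}$, which is exact in the $\Delta t \to 0$ limit
and keeps one analysis frame equal to one simulation step.  Design
choices, in order of consequence:

* **Initial state.** All agents start flying at uniform positions inside
  the cone: mosquitoes are introduced through the cone's apex hole and
  are airborne when the assay starts.
* **Excito-repellency.** Contact with an irritant surface drives activity
  up.  The model multiplies the N→F and C→F hazards by
  $1 + g \cdot c(t)$ where $c(t)$ is the agent's cumulative net-contact
  time (seconds spent in state N) and $g$ is `irritancy_gain`.  This
  produces the characteristic rise of activity over the first half of an
  assay on a treated net without any explicit time dependence.
* **Knockdown as delayed toxicity.** The knockdown hazard at any instant
  is `toxicity_hazard` × cumulative contact time, so knockdowns
  accumulate late in the assay — a rise-then-decline activity shape
  emerges when irritancy and toxicity are combined, with no extra
  states.  K is absorbing; a knocked-down agent drops to the cone base
  and stays there.  Setting `toxicity_hazard = 0` provably forbids
  knockdown.
* **Movement.** Flying agents follow a correlated random walk (heading
  noise SD 0.6 rad per step) at `flight_speed` pixels/s, clipped to the
  projected cone silhouette — an isosceles trapezoid, apex up, with the
  net edge along the base.  Agents landing on the net sit on the base
  edge; resting agents sit on the cone wall at their current height.
* **Presets.** `net_presets()` bundles four qualitative parameter sets
  (control, irritant, weak irritant, irritant + toxic).  The rates were
  chosen once so the resulting mean-activity and state-occupancy curves
  have the shapes observed in cone-test studies — stable low activity on
  control nets, a strong rise (then decline, when toxic) on irritant
  nets, an attenuated rise with prolonged net contact on weakly
  bioavailable surfaces.  No published transition rates exist for real
  strains; these values are illustrative dynamics, **not** estimates of
  any strain's parameters, and none of the package's validation depends
  on their particular values.

# The vision stage

`analyze_recording()` reproduces an automated movement detector:
per-pixel adaptive mixture-of-Gaussians (MOG) background subtraction,
8-connected blob extraction with an area filter, then per-frame counts
and centroids at 0.1-s intervals.  Parameter defaults are the standard
Stauffer–Grimson-style settings: K = 3 components, match threshold 2.5
SD, background weight threshold T = 0.9, learning rate α = 0.02,
variance floor 4 gray² (the floor prevents degenerate components on
noise-free synthetic video).  The exact update equations are documented
in `src/mog.cpp`; an independently written, deliberately naive R
implementation of the same equations lives in the test suite and must
agree **bit-for-bit** in float64, which pins the compiled code to the
declared contract rather than to "whatever the library does".

Consequences of the model worth knowing:

* A mosquito that stops moving is absorbed into the background within a
  few frames and stops being counted.  "Total activity" therefore counts
  movement, not presence.
* A mosquito that leaves a long-occupied resting spot leaves a short-lived
  "ghost" detection there, and a freshly landed mosquito keeps being
  detected for a few frames.  Both are inherent to adaptive background
  models; they are measured, not hidden: `score_detections()` counts a
  detection as correct for precision if it falls on any agent, and as a
  recall hit only if that agent actually moved since the previous frame.
* Two agents closer than about one blob radius merge into one detection
  (occlusion undercount).  At the default 128×96 geometry this costs a
  few percent recall; at the deliberately crowded 40×30 study geometry it
  is the dominant error and the per-assay totals are compressed — which
  is fine for arm-versus-arm contrasts and is why the discrimination
  study calibrates its effect size *through* the pipeline rather than on
  truth counts.
* The first second of each recording is burn-in: processed for model
  adaptation, reported as count 0 and flagged.  Background models need
  initialisation; excluding a fixed, flagged prefix keeps totals
  comparable across assays.

# Activity and scan-sampling summaries

Image coordinates have `y` increasing downward, so the cone apex is the
*smallest* `y`; this convention is declared once in `cone_geometry()` and
used everywhere.  A detection is "top" iff strictly above the midline;
midline ties go to "bottom", the net-proximal region, which is the
conservative choice for contact-related interpretation.  Bins are
half-open `[t, t+5)` so no detection can double-count; 36 bins cover a
180-s assay, and binned counts sum exactly to total activity.

Scan sampling reads the simulator truth at 5-s instants, t = 0 through
t = 180 inclusive — 37 points, forced by the arithmetic.  Replicate
summaries (both for activity bins and state counts) use per-point
arithmetic means with *t*-based 95% confidence intervals; with means the
per-point state averages still sum to the cohort size.

# The statistics workflow

All two-group machinery operates on `group_summary` objects (n, mean,
sample SD), so published summary tables can be fed straight in.
`welch_t()` uses the Welch–Satterthwaite statistic; `cohens_d()` uses the
pooled-SD form with CI variance $(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$
and a *t* quantile on $n_1+n_2-2$ df — this specific convention is the
one that reproduces the published interval widths the package targets,
and it matches the widely used `effsize`-style implementation.
`ci_mean()` is the plain one-sample *t* interval, and
`infer_n_from_ci()` inverts it over integer n: given a printed (mean,
SD, CI bound) triple it recovers the group size, erroring unless the
solution is unique at the printed precision.  This inversion is how
unpublished group sizes are pinned down from published summaries before
any reproduction is attempted.

`levene_test()` is classical mean-centred Levene (ANOVA on absolute
deviations, via `car`), appropriate under unequal group sizes.
`two_way_anova()` fits the crossed model by least squares with
sum-to-zero contrasts and Type-III sums of squares; on balanced data this
coincides with the classical decomposition (tested), and on unbalanced
data it makes the estimated marginal means unweighted over the other
factor — the `emmeans` convention, with Tukey-adjusted pairwise
contrasts.  Partial $\eta^2$ is $SS_e/(SS_e+SS_r)$ with a one-sided 95%
CI from noncentral-F inversion, upper bound 1, as effect sizes are
conventionally reported alongside ANOVA tables.

Bioassay endpoints follow WHO conventions: per-swatch percentages pool
5 replicates × 5 mosquitoes = 25 exposed; Abbott control correction
$100(T-C)/(100-C)$ is applied only when control mortality lies in
(5%, 20%], left unapplied at ≤ 5%, and the assay is flagged invalid
above 20%.

# Chemical QC

The HPLC content equation $I = (x/a) \times (0.001/m) \times C \times f$
is evaluated exactly as written.  Its unit reading, declared here because
the equation's source does not define units for $x$, $a$ or $C$: $x/a$
is the concentration (µg/ml) of the 1-ml acetonitrile resuspension, and
the 0.001 factor converts µg to mg against the sample mass in grams,
giving g/kg.  This is the only reading that makes the printed equation
dimensionally coherent.  The internal-standard factor $C$ is accepted as
an input.  Conversion to areal density uses mg/m² =
$I \cdot m / (A \cdot 10^{-4})$ for a swatch of mass $m$ g and area $A$
cm².  Four-round totals raise a QC flag when the first extraction round
yields less than 97% of the total, the efficiency expected of a working
extraction protocol.

Raman preprocessing is Savitzky–Golay smoothing (window 5, order 1 — a
first-order filter passes linear signal untouched, which is the tested
invariant), then Eilers-style asymmetric least squares baseline
subtraction (λ = 1e5, p = 0.01, 10 iterations; common settings for this
algorithm), then L2 normalisation (idempotent by construction).  A known
property of ALS worth stating: with asymmetry p ≪ 1 the estimate tracks
the *lower envelope* of the noise, so it sits below the true baseline by
roughly the noise amplitude; the recovery test therefore bounds the
relative RMS error against the baseline magnitude (< 5%), not against
machine precision.  The crystallinity call measures the
signal-to-local-noise prominence of the 1000 cm⁻¹ marker band within a
±5 cm⁻¹ window; the 942/479 cm⁻¹ bands are scored and reported but do
not drive the call, so a spectrum with only those secondary particulate
bands is classified amorphous-like.  The call is a QC heuristic with
configurable thresholds, not a claim about polymorph physics.

# Validation strategy and problem sizes

Every stochastic validation in the package runs at a size chosen to keep
the whole suite comfortably reproducible on a laptop while leaving the
statistics decisive:

* **Vision validity**: 10 seeded 180-s videos at the default 128×96
  geometry; pooled recall and precision against simulator truth must
  reach 0.9 (they come in around 0.95 and 0.99).
* **MOG oracle**: bit-exact agreement on a 20×20, 40-frame noisy crop.
* **Discrimination study**: two irritancy settings, calibrated once by
  simulation to a standardised effect of about 2.5 on pipeline-measured
  total activity (the contrast acts through the net take-off rate and
  irritancy gain; the gain alone saturates, so the take-off rate carries
  most of it), 10 assays per arm at the 40×30 study geometry, 100
  repetitions of the full
  simulate → render → detect → activity → Welch chain; the difference
  must be flagged at p < 0.01 in at least 95% of repetitions.
* **Null calibration**: Levene and the ANOVA net effect at 1000
  null replicates each must reject at ≈ 5%.
* Mortality/knockdown percentages, ANOVA F values and HPLC contents of
  any particular real net are *experimental outcomes*; no raw data
  exist to recompute them, so they are covered by the property suite
  (monotone knockdown accumulation, state-count conservation,
  polynomial preservation, unit-norm idempotence, content-equation
  linearity) rather than by numeric reproduction.

What passing these tests does **not** show: the simulator's renderer is
far simpler than a smartphone recording (static background, clean disks,
Gaussian noise, no shadows, reflections, rolling shutter or compression),
so detector scores here bound its behaviour on ideal input, not on field
video.  The behavioural model has no spatial preference within a state,
no host stimulus (deliberately — the assays it mirrors provided none)
and no 3-D structure.

# A worked example

```{r example, eval = FALSE}
library(vctkit)
geom <- cone_geometry()
truth <- simulate_cohort(net_presets("irritant_toxic", rng_seed = 1), geom)
frames <- render_video(truth, geom, noise_sd = 4, seed = 2)
series <- analyze_recording(frames, fps = 10)
profile <- aggregate_bins(series, geom)
profile$total_activity

scans <- scan_sample(truth)
head(scans)

# the published-summary workflow
a <- group_summary(3628.3, n = 40, sd = 1014.209, label = "PFAS (+)")
b <- group_summary(3211.655, n = 55, sd = 830.311, label = "PFAS (-)")
welch_t(a, b)     # t = 2.130, df = 73.649, p = 0.036
cohens_d(a, b)    # d = 0.457 (0.039, 0.875)
```

# Known limitations

* The MOG parameterisation of the original detector software is not
  published; the defaults here are declared, standard values, and the
  oracle pins this package's implementation, not the original's.
* Whether real analyses exclude initialisation frames is unknown; the
  1-s flagged burn-in is a declared deviation.
* The study-geometry pipeline undercounts heavily under occlusion;
  absolute totals from different geometries are not comparable.
* `read_scan_csv()` expects a tidy export; proprietary ethology-software
  formats must be converted to it first.
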