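---
title: "Customized dual-band sound therapy and trial analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Customized dual-band sound therapy and trial analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dfcrs)
```

## The therapy model

Chronic subjective tinnitus is commonly anchored to a narrow frequency
region: patients can match their percept to a pitch in a psychophysical
matching task. Digital frequency customized relieving sound (DFCRS) takes
that matched pitch $f_p$ and enhances the two 1/3-octave bands immediately
flanking it in soft music, on the rationale that stimulating the auditory
regions adjacent to the (often deafferented) tinnitus frequency promotes
adaptive reorganization rather than further driving the tinnitus region
itself.

The prescription is fully determined by four band edges placed symmetrically
around the pitch in log-frequency:

$$
\text{lower band} = (f_p\,2^{-g-1/3},\; f_p\,2^{-g}), \qquad
\text{upper band} = (f_p\,2^{\,g},\; f_p\,2^{\,g+1/3}),
$$

where $g \ge 0$ (octaves) is an optional guard gap, zero by default so the
bands abut at the pitch. Each band spans exactly 1/3 octave
($f_{hi}/f_{lo} = 2^{1/3}$). `compute_band_endpoints()` implements this
closed form; placement is unique up to the guard once one requires two
1/3-octave bands directly below and above the pitch. The guard parameter
exposes the one genuinely open design choice — whether a notch should
separate the boosted bands from the pitch itself — without committing to it.

## The enhancement engine

`apply_dfcrs()` raises the energy inside both bands by a constant relative
gain (default +10 dB) while leaving the rest of the spectrum untouched. A
constant *relative* gain is the only implementation consistent with a fixed
decibel prescription: the boost then tracks the music's instantaneous
in-band content, which is what "dynamically increasing the intensity" of a
band in music means in practice.

Implementation choices, all configurable through `dfcrs_config()`:

* **STFT overlap-add.** Square-root-Hann analysis and synthesis windows of
  2048 samples (about 46 ms at 44.1 kHz) with 75% overlap. This pair
  satisfies the constant-overlap-add condition exactly, so a unit mask
  reconstructs the input to machine precision and the processing is linear
  (below the limiter).
* **Band mask.** The per-frame spectrum is multiplied by a gain mask that is
  $10^{G/20}$ inside the bands and 1 outside, with raised-cosine transitions
  spanning 1/24 octave centred on each band edge. The taper confines the
  filter's impulse response well within the frame, avoiding audible ringing
  and time-aliasing from circular convolution; because it is centred on the
  edge, the mask is already at full gain 1/48 octave inside the band and
  back to unity 1/48 octave outside, so spectral measurements more than 1/6
  octave away see less than 0.5 dB of change. Where the two bands share an
  edge (guard 0) the mask takes the maximum of the two band shapes, so there
  is no dip at the pitch.
* **Peak limiter.** Boosting can push loud material over full scale. A soft
  limiter engages 1 dB below full scale and tanh-compresses only the
  overshoot; quiet material passes through bit-exact, and the test suite
  asserts the limiter does not reduce the measured band gain on the
  verification fixtures.
* **No silent resampling.** If the upper band edge reaches the Nyquist
  frequency the engine raises an error naming the offending edge; an 8 kHz
  pitch needs more than a 16 kHz sample rate because
  $8000 \cdot 2^{1/3} \approx 10079$ Hz.

Verification is spectral: `measure_band_gain()` integrates the periodogram
over a band in both the input and the output and reports the power ratio in
dB. On a 5 s sine at the geometric centre of either band the measured gain
is 10.00 dB to within a few thousandths of a dB; the property suite checks
20 in-band and 20 out-of-band probe tones and 1000 random pitches for the
exact 1/3-octave band-ratio invariant.

## Audiometry and eligibility

The four-frequency pure-tone average (PTA) is the arithmetic mean of the
air-conduction thresholds at 0.5, 1, 2 and 4 kHz. Enrollment requires age
≥ 18 years, worse-ear PTA ≤ 55 dB HL (the boundary itself is eligible —
"no more than"), and none of the exclusion diagnoses (pulsatile or
objective tinnitus, otosclerosis, Meniere disease, acute sudden hearing
loss, severe systemic disease). The worse ear is defined as the ear with
the larger PTA; a tie gives the same value either way. Verdicts carry every
failed rule, not just the first.

## Instrument scoring

Six patient-reported instruments are scored as validated sums:
THI (25 items in {0, 2, 4}, total 0–100), HADS (14 items in 0–3, split into
7-item anxiety and depression subscales, each 0–21), AIS (8 items in 0–3,
total 0–24), FTQ (17 binary items, total 0–17), TCS (13 items in 0–4, total
0–52), and a 0–10 VAS passthrough. Missing items are an error by default;
an opt-in prorating mode scales the observed sum to the full item count when
at least half the items are present, and flags the score. The HADS
anxiety-item positions are configuration: the shipped default is the
conventional alternating assignment (odd items anxiety), which is a scoring
convention, not a property of the data. THI subscale assignments are not
shipped at all — output is total-only unless a site supplies its own
mapping.

## The synthetic cohort

No patient-level data accompany the trial design this package targets, so
the generator produces cohorts with the exact statistical structure the
analysis assumes, making every stage of the pipeline testable end to end.

* **Design.** 107 treated (DFCRS) and 77 control (UM) subjects, visits at
  days 0/30/60/90.
* **THI trajectory.** $THI_{it} = \beta_0 + \beta_t\,day_{it} +
  \beta_g\,[arm_i = \text{DFCRS}] + b_i + \varepsilon_{it}$ with
  $b_i \sim N(0, \sigma_b^2)$, $\varepsilon_{it} \sim N(0, \sigma_e^2)$.
  Defaults $\beta_0 = 56.13$, $\beta_t = -0.119$/day, $\beta_g = -16.65$.
  Time is coded in days because $-0.119 \times 90 \approx -10.7$ THI points
  over the trial, the right order of magnitude for the observed decline,
  whereas a per-month coding would imply a negligible change.
* **Variance components.** $\sigma_b = 10$, $\sigma_e = 8$ THI points.
  These are chosen once so that fewer than about 2% of generated scores hit
  the scale bounds: THI lives on [0, 100], and a linear Gaussian generator
  is only self-consistent — and its coefficients only recoverable without
  truncation bias — while the trajectories rarely touch the bounds. Scores
  are clipped to the scale range and rounded to the even integers real THI
  totals take; `round_scores = FALSE` exposes the exact linear-Gaussian
  limit used by the noise-free recovery tests.
* **A purely additive arm effect cannot also match equal-looking baselines.**
  With a time-constant group effect the treated arm starts
  $|\beta_g| \approx 16.6$ points below the control arm at day 0. Real arms
  differ far less at baseline; capturing both a realistic baseline and a
  time-constant group effect would need a group-by-time interaction, which
  the analysis model (and therefore the generator) deliberately omits. The
  generator therefore reproduces the analysis model's world, not the
  baseline table of any particular trial.
* **Secondary scales** are noisy monotone maps of the subject's expected
  THI (a shared latent severity), clipped to each instrument's range. This
  gives the correlated multi-scale decline the instruments show in practice
  without inventing an unsupported joint model.
* **Outcome.** For treated subjects a 3-category outcome (worsened /
  relief / disappeared, reference worsened) is drawn from a multinomial
  logit whose log-odds are linear in daily listening hours (odds ratios
  13.07 and 64.78 per hour for relief and disappeared) and baseline severity
  grade. The two category intercepts are not free constants: they are
  calibrated by direct minimization (Nelder-Mead on the expected-proportion
  error) so the marginal outcome proportions match 8/93/6 of 107 under the
  realized covariate draw. Daily listening hours are gamma-distributed with
  mean 2.2 h/day around the recommended minimum of 2 h/day; treatment time
  is modelled continuously in hours per day.
* **Reproducibility.** `generate_cohort()` refuses to run without an
  explicit seed, and the seed is recorded in the CSV metadata.

What passing tests on this cohort do *not* show: robustness to missing
visits, informative dropout, floor effects in severely affected patients,
self-selection between arms (the design is nonrandomized), or measurement
properties of the translated instruments. The generator emulates the
statistical skeleton of such a trial, not its clinical texture.

## The analysis stack

* **Baseline comparisons** (`baseline_tests()`): chi-square for categorical
  covariates; for continuous covariates a Shapiro-Wilk gate at α = 0.05 per
  group routes to one-way ANOVA (all groups normal) or Kruskal-Wallis. The
  gate is explicit and its minimum p value is reported with each row,
  because "use ANOVA for normal variables" is a rule, not a test, until the
  normality check is named.
* **THI mixed model** (`fit_thi_lmm()`): random intercept per subject, fixed
  effects for day, arm, gender, age, location and course; REML via `lme4`,
  Satterthwaite degrees of freedom via `lmerTest` (falling back to residual
  df with a flag if the approximation fails). UM is the reference arm, so
  treatment benefit appears as a negative arm estimate, matching
  lower-is-better THI. Singular fits are flagged, not hidden.
* **Outcome model** (`fit_outcome_multinomial()`): multinomial logistic
  regression (`nnet::multinom`) with bidirectional stepwise selection from
  the intercept-only model, scored by AICc by default (AIC and BIC are
  switches; AICc is the defensible default at n ≈ 107 with up to ~10
  parameters). The stepwise driver is a small scorer over full `multinom`
  fits — selection only chooses the covariate set, and refitting the
  selected set without selection reproduces the coefficients exactly, which
  the tests assert. Odds ratios are exponentiated coefficients with Wald
  95% CIs on the log scale; the wide, asymmetric CIs that small outcome
  categories produce are expected. A separation diagnostic flags implausible
  coefficient magnitudes instead of failing silently.
* **Timepoint contrasts** (`timepoint_contrasts()`): two-tailed paired t
  tests over all six pairs of the four visits, per scale, with listwise
  handling of missing visits reported per pair. The all-identical-scores
  edge case reports t = 0, p = 1 rather than erroring.
* **Outcome proportions** (`outcome_proportions()`): percentages of the
  category counts rounded to one decimal, with support for pooled
  categories.

### Numerical choices and degenerate inputs

Stepwise ties are broken toward the current model (a move must improve the
criterion by more than 1e-8). Constant covariates produce a degenerate-test
row rather than an error. An outcome with fewer than three observed levels
is an explicit error, since the model's reference-category structure is
meaningless without it. Paired contrasts with zero-variance differences
distinguish "no change" (t = 0, p = 1) from genuinely degenerate input (NA
with the pair counts reported).

### Problem sizes used in the test suite

Oracle-equivalence fixtures use 5–10 subjects so that brute-force references
(closed-form paired t, Yates chi-square, grid-plus-polish likelihood
maximization) are exact and instant. Parameter recovery of the LMM group
effect and time slope uses 200 replicate cohorts at the full design size
(n = 184, four visits), fitting the day + arm model per replicate; the full
covariate model is exercised in the single-fit tests. The DSP property suite
uses 1000 random pitches for the closed-form band invariant and 40 probe
tones of 1 s each through the full engine.

## Known limitations

* The four-endpoint placement is the unique symmetric reading of the
  therapy's published description; if a deployed system inserts a
  hearing-level-dependent correction or a notch at the pitch, that belongs
  in `guard_octaves` or a custom `band_spec`, and the package makes no claim
  about which variant was used clinically.
* The engine is offline; it processes files, not streams.
* The generator's covariate distributions are plausible clinic marginals,
  not estimates from any dataset; analyses of real cohorts should use the
  CSV schema directly.
* Wald CIs understate uncertainty under quasi-separation; with ~8 subjects
  in the reference category, very wide CIs are the honest answer, and
  profile-likelihood intervals would be the next refinement.
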