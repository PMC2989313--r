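---
title: "Evaluating EMG amplitude estimators by mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating EMG amplitude estimators by mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emginfo)
```

## The method

A surface EMG is the summed activity of many asynchronously firing motor
units and is well described, for amplitude purposes, as a zero-mean
stochastic signal whose power tracks the level of muscular contraction.
When the contraction level is driven by a measurable stimulus — here the
arm's angular position during abduction/adduction in the scapular plane —
any windowed amplitude estimator turns the signal into a sequence of
(stimulus, response) pairs, and the quality of the estimator can be scored
by how much Shannon information those responses carry about the stimulus.

`emginfo` implements that evaluation end to end:

1. **Segmentation.** The signal is cut into non-overlapping windows of a
   chosen length (overlap is supported but unused by default). Window
   sample count is `round(length_ms * fs / 1000)`, so 200 ms at 2 kHz is
   exactly 400 samples.
2. **Amplitude estimation.** One of RMS, AMV, DAMV or VAR per window
   (`rms()`, `amv()`, `damv()`, `var_feature()`). VAR uses the population
   (divisor-`N`) form implied by its expectation definition; this was left
   ambiguous in common usage and is fixed here as a deliberate choice.
3. **Discretization.** For static sessions the stimulus is already a class
   label (one per held position). For dynamic sessions the per-window mean
   angle is binned into equal-width bins of `stim_bin_deg` degrees
   (default 5°) spanning the observed angle range. Responses are binned
   into equal-width bins over the observed response range; the bin count
   follows the square-root-of-the-data histogram rule
   (`response_bin_count()`), rounding half away from zero with a floor of
   two bins, with a fixed-count override available.
4. **Information.** The co-occurrence counts, normalized by the total
   window count, are the joint distribution `P(s, r)`; marginals are its
   row and column sums, the conditional is `P(s|r) = P(s,r)/P(r)`, and the
   score is the plug-in mutual information in bits,
   `I = sum_r P(r) sum_s P(s|r) log2[P(s|r)/P(s)]`, with `0 log 0 = 0` and
   zero-probability responses skipped.

Study-level wrappers sweep the window length (`window_sweep()`), normalize
each subject's curve by its own maximum and aggregate
(`normalize_and_aggregate()`), select the optimal segmentation
(`optimal_window()`), and compare techniques, movement directions and
channels (`compare_techniques()`, `direction_analysis()`,
`ied_analysis()`).

## The synthetic generator

No public recordings exist for this protocol, so the package ships a
generator whose output has exactly the statistical structure the method
consumes: band-limited (default 10–500 Hz at 2 kHz) zero-mean Gaussian
noise, amplitude-modulated so that the RMS envelope is a function of arm
angle. The defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `sample_rate` | 2000 Hz | acquisition rate |
| `band` | 10–500 Hz | analog pass band |
| `envelope_fn` | linear, 0.2 → 2.0 over 0–90° | RMS amplitude vs angle (arbitrary units) |
| `noise_floor` | 0.05 | additive baseline RMS (quiescent muscle + instrumentation) |
| `hysteresis_gain` | 1 | envelope multiplier on the adduction branch (< 1 = abduction louder) |
| `channel_gains` | 1 | per-channel envelope multipliers (inter-electrode-distance proxy) |
| static protocol | 0–90° by 10°, 3 s holds | held-position sequence |
| dynamic protocol | 4.5°/s ramp, 4 s hold at 90°, return ramp | one 44 s movement cycle |

The linear default envelope mirrors the observed linear behaviour of
deltoid RMS medians with arm position; its absolute scale is arbitrary
since mutual information is invariant to monotone rescaling of responses
up to binning. No quantitative envelope for deltoid EMG versus angle is
established, so this is a modeling choice, and any vectorized
`envelope_fn` can be substituted (exponential or logistic shapes emulate
the VAR/AMV-like response behaviours). A dynamic session can repeat the
movement cycle (`n_cycles`); study-scale analyses use 5 cycles, the usual
number of repeated trials pooled per subject.

Two deliberate simplifications, and what they imply for the tests:

* **Filtered Gaussian noise, not motor-unit action potential trains.** The
  evaluation only consumes amplitude structure, and Gaussian noise makes
  the generator analytically checkable (windowed RMS concentrates on the
  envelope by the law of large numbers). Passing tests therefore
  demonstrate correctness of the *evaluation pipeline*, not robustness to
  MUAP waveshape, firing-rate statistics, crosstalk or fatigue-induced
  spectral shifts, none of which are modelled.
* **Exact amplitude conditioning.** Generated noise is rescaled to unit
  sample RMS before envelope scaling, so a static hold's overall RMS
  equals its target amplitude exactly (the draw is conditioned on its
  empirical power). Windowed values within a hold still fluctuate
  naturally; only the whole-segment power is pinned. This gives the
  pipeline a sharp deterministic limit — with zero noise floor and windows
  equal to whole holds, every position maps to a single distinct response
  and the measured information is exactly `log2(number of positions)` —
  which the test suite uses as an end-to-end oracle.
* **Inter-electrode distance as pure gain.** Channels differ only by an
  envelope multiplier against a shared noise floor (an SNR difference);
  there is no volume-conductor model.

Static transitions can include labelled `gap` stretches (baseline noise,
`NA` label) emulating repositioning intervals; segmentation discards any
window touching them, as it discards windows straddling two labels —
dropping rather than splitting keeps per-class window counts well defined.

## Numerical choices and degenerate inputs

* Logarithms are base 2 throughout; results are in bits.
* Response bin edges span the observed (not theoretical) min–max with
  equal widths; values are assigned by `floor` indexing with the maximum
  clamped into the top bin, so the last bin is right-closed. The observed
  range is used because the theoretical response range of an amplitude
  estimator is unbounded.
* Plug-in estimates are used raw: no smoothing, no bias correction by
  default. Plug-in mutual information is biased upward at small window
  counts (roughly `(S-1)(R-1) / (2 n ln 2)` bits), which inflates sweep
  curves at very long windows where few windows remain; a Miller–Madow
  first-order correction hook (`bias_correction = "miller_madow"`) is
  exposed but off by default so that reported values are the standard raw
  estimates.
* If every response is identical, the response axis degenerates to one bin
  with a warning and the information is 0.
* Sweep lengths yielding fewer than 4 windows or fewer than 2 occupied
  stimulus bins are reported as `NA`, never silently dropped.
* The dynamic top-of-range dwell is tagged `hold`; `direction_analysis()`
  includes hold windows in both single-direction subsets (they contribute
  only the top angle bin) as well as in the pooled set, and says so in its
  output attributes, since whether pooled analyses should include the
  dwell is a protocol ambiguity rather than a property of the method.

## Optimal segmentation and the plateau

Information-versus-window-length curves rise steeply at short windows
(longer windows average out amplitude-estimation noise, raising the
effective SNR), flatten into a broad near-maximal plateau, and eventually
decline as windows grow so long that they average away the stimulus
variation itself. Because reported optima are ranges as often as single
values, `optimal_window()` returns both: the smallest window length whose
mean normalized information reaches `(1 - tolerance)` of the curve maximum
(default tolerance 0.05), and the full contiguous interval satisfying that
criterion. The plateau is a bounded interval — the curve is *not* required
to stay near its maximum out to arbitrarily long windows, and typically
does not.

## Problem sizes

The test suite exercises the estimator against an independent brute-force
double-sum oracle on 1000 random joint matrices (2×2 to 6×6), checks
non-negativity, the `min(H(S), H(R))` bound, transpose symmetry and
relabeling invariance on the same ensemble, verifies the deterministic
`log2(10)`-bit limit, a 50 000-pair permutation-null independence check, a
100-session noise-monotonicity ensemble (5 noise floors × 20 seeds), a
10-seed dynamic sweep on a 20–2000 ms grid, and a 20-seed hysteresis
detection ensemble. The acceptance study uses five synthetic subjects with
the full 10 ms-step sweep grids. These sizes were chosen to keep the whole
suite comfortably under a minute of compute per heavy block while leaving
the statistical checks well powered.

## Known limitations

* Plug-in information values are comparable *within* a fixed
  discretization; comparing across different stimulus bin widths conflates
  resolution with information (finer stimulus bins raise the ceiling
  `log2 N_s` while lowering per-bin counts).
* The generator's Gaussian envelope model cannot probe technique
  differences that hinge on waveform shape — DAMV, for instance, differs
  from AMV on real signals mainly through spectral content, which here is
  identical across angles.
* Human-subject numbers from deltoid recordings are not reproducible here;
  analyses on synthetic cohorts reproduce the qualitative structure
  (technique ordering, plateau location, direction asymmetry), not the
  published magnitudes.
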