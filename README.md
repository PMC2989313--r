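# emginfo

Information-theoretic evaluation of EMG amplitude-estimation techniques.

## The problem

Surface electromyogram (EMG) amplitude can be estimated by many windowed
time-domain techniques — root mean square (RMS), absolute mean value (AMV),
difference absolute mean value (DAMV), variance (VAR) — and myoelectric
control, prosthetics and rehabilitation applications all need to pick one,
plus a window length. `emginfo` scores a technique by the amount of Shannon
information its per-window values carry about the motor stimulus (the arm's
angular position), so techniques and segmentations can be compared on a
common scale of bits.

For a window of `N` samples `x_1..x_N` the four estimators are

    RMS  = sqrt( (1/N) * sum x_k^2 )
    AMV  = (1/N) * sum |x_k|
    DAMV = (1/(N-1)) * sum |x_{k+1} - x_k|
    VAR  = E{x^2} - E{x}^2            (population form, divisor N)

Per-window (stimulus, response) pairs are discretized — position labels for
static (held-posture) sessions, equal-width angle bins (default 5°/bin) of
the window-mean angle for dynamic (continuous-movement) sessions; response
values into equal-width bins whose count is the square root of the number
of windows — and counted into a co-occurrence matrix whose normalization is
the joint distribution `P(s, r)`. The score is the plug-in mutual
information

    I = sum_r P(r) sum_s P(s|r) log2[ P(s|r) / P(s) ]   [bits]

Sweeping the window length and normalizing each subject's curve by its own
maximum locates the optimal segmentation (the plateau of near-maximal
information). The same machinery quantifies movement-direction hysteresis
(abduction vs adduction) and the effect of inter-electrode distance,
emulated as per-channel gain differences.

A seeded synthetic-EMG generator (band-limited Gaussian noise whose RMS
envelope follows the arm angle) reproduces the static and dynamic
protocols, so the whole pipeline is testable without human recordings.

## Worked example

```r
library(emginfo)

params  <- synth_params(seed = 42)                      # 2 kHz, 10-500 Hz band
session <- generate_static_session(params, static_protocol())
session
#> <emg_session> static, 1 channel(s), 30.00 s at 2000 Hz
#>   positions: 0, 10, 20, 30, 40, 50, 60, 70, 80, 90 deg
#>   directions: abduction

features <- extract_features(session, 200, "RMS")       # 200 ms windows
series_information(features)
#> <mi_result> I = 2.8420 bits (10 x 12 bins, n = 150)

compare_techniques(session, window_ms = 200)
#> <emg_comparison> information (bits), mean +/- SD across sessions:
#>   RMS   2.842 +/- 0.000  (n = 1)
#>   AMV   2.894 +/- 0.000  (n = 1)
#>   DAMV  2.775 +/- 0.000  (n = 1)
#>   VAR   2.478 +/- 0.000  (n = 1)

sw  <- window_sweep(session, "RMS", seq(20, 1000, by = 10))
optimal_window(normalize_and_aggregate(sw))
#> $optimum_ms
#> [1] 180
#> $plateau_ms
#> [1] 180 180
#> $threshold
#> [1] 0.95
```

The 150 windows (15 per held position) are discretized into 12 response
bins (`round(sqrt(150))`); 2.84 bits of the `log2(10) = 3.32`-bit stimulus
entropy are recovered at this noise level. On this single session the
information-versus-window-length curve first enters the 5%-of-maximum
plateau at 180 ms; VAR extracts the least information, as its values spread
increasingly with contraction level.

A thin command-line interface over the same functions is installed at
`inst/cli/emginfo.R` (subcommands `simulate`, `features`, `evaluate`,
`sweep`, `direction`, `ied`, `pipeline`).

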