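---
title: "Methods: ECG rhythm scoring and gait kinematics in ecgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG rhythm scoring and gait kinematics in ecgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgait)
```

## The problem

Exercise studies in mouse disease models (here, the reserpine-induced
fibromyalgia model) ask whether an intervention changes cardiac rhythm and
locomotion. The raw materials are short single-lead ECG recordings taken
before and after a gait test, and overhead video tracks of the animal during
the test. `ecgait` turns these into three cardiac readouts per recording —
average heart rate (HR), the SD of HR, and a rhythm irregularity score — and
three locomotion readouts per trajectory — distance, maximum speed, average
speed — and then runs the study's comparison grid with small-sample
nonparametric tests.

Because such recordings are rarely deposited, the package also contains a
first-class synthetic generator for both modalities, with ground truth, so
every stage of the pipeline is testable end to end.

## Cardiac readouts

### Cycle periods and the irregularity score

R peaks at times $t_1 < t_2 < \dots$ define cycle periods
$P_n = t_{n+1} - t_n$ (the RR intervals). The irregularity score of cycle
$n$ is its absolute percent period change relative to the preceding cycle:

$$S_n = 100 \cdot \frac{|P_n - P_{n-1}|}{P_{n-1}} \; [\%],$$

so a window of 50 cycles yields 49 scores, and the per-recording score
(`is_mean`) is their arithmetic mean — the only summary consistent with
reporting one number per animal. The score is dimensionless and invariant to
rescaling all periods, which `ecgait` verifies as a property test. A
perfectly regular rhythm scores 0; a single dropped beat in an otherwise
regular rhythm contributes roughly $100\% + 50\%$ across its two affected
cycles, so even rare events move the mean visibly.

### Heart rate and its SD

`heart_rate_summary()` offers two HR definitions, because "beats per
minute" is ambiguous at the cycle level:

* `per_cycle` (default): instantaneous rate $60 / P_n$ per cycle; `hr_mean`
  and `hr_sd` are the mean and sample SD (denominator $n-1$) over the
  window. This is the definition under which an SD of HR is coherent
  cycle-wise, and it is the default because per-cycle HR traces are what
  before/after line plots display.
* `count_extrapolate`: the literal beat count per elapsed time,
  $60 \, n_{\text{periods}} / \sum_n P_n$. On a constant rhythm the two
  definitions agree exactly; on a 20-s recording with 224 peaks they differ
  by well under 1%. `hr_sd` is computed per-cycle in both modes.

Neither mode is asserted to be the historical analysis software's; both are
recorded in the output.

### The analysis window

A 20-s mouse recording holds 200–250 cycles but the scoring convention uses
50 consecutive cycles. Which 50 is an analyst's choice that the package
refuses to make silently: `select_analysis_window()` exposes `first`
(default — deterministic and reproducible), `last`, and `min_artifact`,
which scans every contiguous window and minimises the count of periods
outside $[0.25\times, 4\times]$ the series median (earliest window wins
ties). `min_artifact` exists because a human analyst plausibly picks a clean
stretch; it is not the default because it couples the window to the data.

## R-peak detection

The detector is deliberately simple and fully parameterised
(`detector_config()`):

1. **Band-pass** 5–150 Hz (order-2 Butterworth, zero-phase via
   forward–backward filtering; the high edge is capped at $0.45 f_s$).
   The low edge removes baseline wander; the high edge removes most
   wide-band noise while preserving the narrow mouse QRS.
2. **Polarity**: the study's limb-lead configuration renders the R wave as
   a *negative* deflection, so `negative` is the default; `auto` picks the
   sign of the larger robust extreme for rigs with inverted leads, and a
   symmetry test guarantees `auto` reproduces the upright result on an
   inverted trace.
3. **Threshold**: local extrema exceeding `threshold_k` (default 4) times
   the median absolute deviation of the filtered trace. MAD is used rather
   than SD so the threshold does not inflate with the QRS spikes
   themselves.
4. **Refractory period** 25 ms (a 2400 beats/min ceiling, far above mouse
   physiology): conflicting candidates within it resolve to the
   larger-magnitude peak.
5. **Refinement**: each peak time is moved to the extremum of the raw
   signal within ±2 ms of the filtered extremum, computed on a 3-sample
   running mean of the raw trace (white single-sample noise spikes would
   otherwise capture the extremum), followed by quadratic (parabolic)
   interpolation through the three samples around the extremum.
   Sub-sample interpolation matters: at a 1–2 kHz sampling grid, pure
   sample quantisation alone would add ±0.25–0.5 ms of period noise, which
   on a 91 ms cycle is an artificial irregularity score of up to ~1% —
   an order of magnitude above what a zero-jitter signal should score.
   With interpolation, a noise-free constant rhythm scores below 0.01%.
   Plateau ties resolve to the earliest sample.

On synthetic 20-s recordings with beat jitter up to 5 ms SD and additive
white noise down to 10 dB SNR (R amplitude over noise SD), the detector's
sensitivity and precision against generator truth exceed 0.99 at a ±2 ms
matching tolerance; this is checked over 20 seeded replicates in the test
suite.

## Gait kinematics

`gait_summary()` smooths the centroid track with a centred moving average
(default 5 frames = 50 ms at 100 frames/s; the window shrinks at the
edges), then computes distance as the summed Euclidean step lengths,
instantaneous speed as step length over the inter-frame interval,
`max_speed` as its maximum, and `avg_speed = distance / duration`. Light
smoothing is the package's own choice: raw per-frame maximum speed is
dominated by tracking jitter, and the window is recorded in every output
row so no result detaches from its setting. All three readouts are
invariant under rotations and translations of the arena coordinates, and
`avg_speed × duration = distance` holds to floating tolerance — both are
property-tested.

## Group statistics

The study design compares paired (pre vs post, within animal) and unpaired
(wild-type vs model) groups of 6–10 animals at $\alpha = 0.05$. At these
sizes large-sample approximations are the main reproducibility hazard, so:

* `paired_compare()` (Wilcoxon signed-rank) drops zero differences
  (Wilcoxon's convention, count reported) and enumerates all $2^n$ sign
  assignments of the midranks of $|d|$ for $n \le 15$. Enumeration over
  midranks handles tied magnitudes exactly — the textbook small-sample
  case of *n* uniformly shifted pairs (all differences equal) yields
  $p = 2/2^n$, e.g. $2/64 = 0.03125$ at $n = 6$, which tie-refusing exact
  implementations cannot produce. Above $n = 15$: normal approximation
  with tie correction and continuity correction.
* `unpaired_compare()` (Mann-Whitney U) enumerates all
  $\binom{n_1+n_2}{n_1}$ labelings when $n_1 + n_2 \le 16$ and the pooled
  sample is tie-free; otherwise the tie-corrected normal approximation.
  Swapping groups maps $U \mapsto n_1 n_2 - U$ and leaves $p$ unchanged.
* Every result records which method produced it, and the test suite checks
  the exact paths against independently coded brute-force enumeration and
  against `stats::wilcox.test` on tie-free inputs.
* An all-zero-differences comparison is returned as a flagged degenerate
  result with $p = 1$, not an error: it is a legitimate experimental
  outcome.
* `sd_is_correlation()` uses Spearman's rank correlation for the SD-of-HR
  versus irregularity-score association, because a monotone, not
  necessarily linear, relation is the scientific claim; the coefficient
  choice is recorded in the output rather than implied.

Under the null, the exact $n = 10$ signed-rank test rejects at rate 0.0488
(the largest achievable level below 0.05); simulation in the acceptance
suite confirms the empirical rate lands in $[0.03, 0.07]$ over 2,000
replicates.

## The synthetic generator

### What it emulates

* **Rhythm** (`rr_model()` / `simulate_rr()`): periods are
  $P = b + \delta t + \varepsilon$, $\varepsilon \sim N(0, \sigma_j)$,
  floored at $0.2b$. Arrhythmia is modelled by the two simplest mechanisms
  that raise the irregularity score: *skipped* beats (probability
  $p_s$ per cycle; the beat is deleted and neighbouring periods merge) and
  *premature* beats (probability $p_p$; the period splits into
  $fP$ followed by the compensatory remainder $(1-f)P$, so mean rate is
  unchanged). No specific clinical arrhythmia is claimed — the source
  recordings' morphology did not support classifying one.
* **Trace** (`ecg_template()` / `render_ecg()`): each beat is a sum of
  three Gaussian bumps — a dominant negative R deflection (SD 1.5 ms,
  matching a ~10 ms mouse QRS) flanked by small positive P- and T-like
  bumps whose integrals nearly cancel the R lobe's; plus sinusoidal
  baseline wander and white noise. The rendered grid is padded by the
  template support before the first beat so a beat at $t = 0$ carries its
  full waveform. The default simulation sampling rate is 2000 Hz: the
  digitizer rate is explicit metadata in the file format (never assumed),
  and 2 kHz resolves the narrow mouse QRS comfortably while keeping a
  20-s trace at 40k samples.
* **Gait** (`gait_profile()` / `simulate_trajectory()`): a two-state
  (moving/paused) correlated random walk in a 30 cm arena, with per-frame
  heading diffusion and speed relaxation, reflecting at walls. The
  built-in profiles are calibrated once to the magnitudes reported for
  freely walking wild-type (average speed ≈ 8–9 cm/s) and hypoactive
  model animals (≈ 1 cm/s), with an intermediate water-facilitated
  profile.
* **Cohorts** (`cohort_spec()` / `generate_cohort()`): the full
  two-group × pre/post × three-test grid, written as CSV + JSON files
  with a manifest and a ground-truth table. The default rhythm effects
  place the baseline irregularity score near 2.5% (jitter 2 ms at a 91 ms
  period, from the closed form
  $\mathbb{E}[S] \approx 112.8\,\sigma_j / b$), a mild disturbance after
  the 1-min water test, and the headline condition after the 5-min water
  test: period 101 ms (≈ −10% HR) with $p_s = 0.03$, $p_p = 0.02$,
  jitter 3 ms, which lands the cohort score near 12%. These defaults are
  scenario realism for testing effect recovery, not reproductions of any
  particular cohort's numbers.

### What it does not emulate

Electrode motion artifacts, electromyographic contamination, temperature
dependence of heart rate, autonomic-tone dynamics, reserpine
pharmacokinetics, arena-edge thigmotaxis, and tracking dropouts. Passing
tests therefore demonstrate algorithmic correctness and statistical power
under clean-to-moderately-noisy conditions, not robustness to every
artifact a physiological recording can contain.

## Numerical and interface choices

* Randomness: every simulator takes an explicit seed; the caller's RNG
  state is saved and restored, and cohort generation derives one seed per
  file from the master seed, so cohorts regenerate byte-identically.
* File dialect: comma-separated, mandatory header, '.' decimal, UTF-8;
  numeric columns written via `%.17g` so write→read round trips are
  bit-exact. Metadata (sampling rate, frame rate, identities) lives in a
  JSON sidecar per data file, and the sampling rate is *required* — the
  loader checks time-column spacing against it to 1 part in $10^4$ and
  names the first offending row on mismatch.
* Short recordings (< 20 s) warn rather than fail by default, since the
  20-s figure is a typical, not mandatory, acquisition length; a strict
  mode is available.
* Group aggregates use the sample SD; a single-animal group reports SD 0
  with an explicit warning rather than `NA`, so downstream tables stay
  numeric.
* Detection failures inside `run_pipeline()` exclude the recording with a
  logged reason (file, subject, message) surfaced in the run log — never
  silently.
* Problem sizes in the test and acceptance suites — 20-s ECGs at 2 kHz,
  20 detector replicates, 100 effect cohorts of $n = 10$, 2,000 null
  replicates — were chosen as the smallest sizes at which the binomial
  noise of the measured rates is well inside the asserted margins.

## Known limitations

* The detector assumes a single dominant deflection per beat; it does not
  delineate QRS onset/offset, P waves, or QT intervals, and multi-lead
  fusion is out of scope.
* `min_artifact` window selection optimises a simple outlier count; it is
  not a general artifact classifier.
* The exact Mann-Whitney path requires a tie-free pooled sample; tied
  unpaired data always route to the tie-corrected approximation, which at
  $n_1 = n_2 = 3$ is conservative.
* Gait readouts depend on the smoothing window for noisy tracks (max
  speed especially); the window is therefore part of every output row,
  and cross-study comparisons should hold it fixed.
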