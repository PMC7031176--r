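---
title: "Models and methods behind mousehrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mousehrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousehrv)
```

## The measurement problem

Murine heart rate spans a factor of two across routine laboratory
conditions: roughly 600 bpm under the mild cold stress of a 20 °C holding
room and roughly 300 bpm at thermoneutrality (30 °C). A double autonomic
blockade (muscarinic + β-adrenergic) removes neural input and exposes the
intrinsic sinoatrial rhythm; the difference Δ = basal − intrinsic of any
HRV metric indexes net autonomic influence. Analysing such data poses two
specific problems this package is organised around:

1. **Spectral bands must track rate.** Respiratory-coupled and
   baroreflex-scale oscillations scale with beat rate, so fixed VLF/LF/HF
   cut-offs would classify the same physiological rhythm differently at
   the two temperatures. `band_scheme()` therefore indexes the cut-offs by
   ambient temperature (20 °C: 0–0.5/0.5–1.5/1.5–5.0 Hz; 30 °C:
   0–0.2/0.2–0.75/0.75–3.0 Hz), and the pipeline selects the scheme from
   the manifest temperature.
2. **No raw animal data are distributable.** All calibration and testing
   run on synthetic series whose generating parameters are the published
   group means, so every pipeline claim is a parameter-recovery claim.

## Time domain

Mean HR is defined as 60000 / mean NN, not the mean of per-beat
instantaneous rates; the two differ by a Jensen term of order CV² (≈0.3 %
here), and the 60000/meanNN convention is the one consistent with
cross-checking the published HR and CV tables. All variances are sample
(n − 1) variances. SDNN is computed over the analysis window as a single
segment; windowing is exposed in `run_config(window = )` but off by
default. Poincaré axes follow the standard identities
SD1² = var(ΔNN)/2 and SD1² + SD2² = 2 var(NN) (SD2 clamped at zero), so
SD1/SD2 are algebraically tied to the time-domain variances rather than
estimated from an ellipse fit.

## Frequency domain

The NN sequence is an irregular point-process sample; `resample_evenly()`
cubic-spline interpolates (closing beat time, NN) to a uniform 20-Hz
signal (Nyquist 10 Hz, above the highest HF edge of 5 Hz). Welch
estimation uses 60-s Hann segments, 50 % overlap, per-segment linear
detrending, density scaling (ms²/Hz). Welch was chosen over Lomb–Scargle
because the records are long (≥ 90 s required, 1.5 h typical) and cleaning
gaps are bridged by the spline, so averaged-periodogram variance reduction
dominates; this is an estimator decision, not a claim inherited from any
particular dataset.

Band powers integrate the PSD by the trapezoid rule with interpolated band
edges. The DC bin is excluded; `total` is *defined* as VLF + LF + HF
(power above the HF edge is ignored), which makes the conservation
property exact rather than approximate. Because absolute Welch magnitudes
depend on the estimator settings, cross-study comparisons should use band
*fractions*; the calibration targets of the synthetic generator do the
same.

## Non-linear domain

* **β slope**: OLS of log₁₀ PSD on log₁₀ f. The fit band defaults to
  [lowest non-zero bin, LF upper cut-off of the active scheme]; it is a
  configuration choice (`beta_slope(fit_low, fit_high)`) because no
  canonical fit band exists. At least 10 bins are required.
* **Multiscale entropy**: SampEn(m = 2, r = 0.15·SD) on coarse-grained
  series, scales 1–10, with r fixed from the *original* series SD (the
  standard convention; `r_per_scale = TRUE` gives the variant). The
  scalar MSE is the mean of the profile — a reduction chosen here and
  documented, since a single-number MSE is otherwise underdefined. Scales
  whose coarse series falls under 100 points are dropped with a warning.
* **DFA**: order-1 detrending in non-overlapping boxes, 16 log-spaced box
  sizes in [4, N/8], α = OLS slope of log F(n). Benchmarks: α = 0.50 ± 0.01
  on white noise, 1.48 on Brownian motion, 0.91 on fGn(H = 0.9)
  (20-seed means, n = 8192; computed in the test suite).
* **Hurst**: corrected rescaled range. For each of 14 log-spaced window
  sizes in [16, N/2] the series is split into non-overlapping blocks and
  the block R/S values are averaged geometrically (log-domain, matching
  the log-scale regression). Both the observed log R/S curve and the
  Anis–Lloyd/Peters expected curve of an uncorrelated series are fitted
  with regressors [1, log w, 1/√w], and the estimate is
  0.5 + slope(observed) − slope(expected). The 1/√w term matters: the
  Anis–Lloyd expectation is derived under independence, and for
  persistent series the finite-size transient it misses biases the plain
  two-regressor fit low by up to ~0.06 at n = 4096 — outside the
  package's bias budget (|Ĥ − H| ≤ 0.05 on fGn, H ∈ {0.5, 0.7, 0.8}).
  Absorbing the transient brings the bias below 0.01 at the cost of a
  larger per-realisation variance (sd ≈ 0.10 at n = 4096), a trade
  chosen deliberately: the reported quantity is a group mean.

Sample entropy is implemented in C++ (the only compiled code); the test
suite checks it against a brute-force R oracle that enumerates all
template pairs, to 10⁻¹².

## R-peak detection and cleaning

The detector is a derivative-energy device tuned for 1-kHz murine ECG: a
4-ms moving-average pre-smooth (so differencing does not merely amplify
wide-band noise), a 2-ms central difference, squaring, an 8-ms energy
smooth, and an adaptive threshold of rolling median + 5·MAD over 1-s
blocks. A 30-ms refractory period (well under the ~67-ms period at the
fastest murine rates) is enforced greedily from the strongest candidate
down, and peak times are refined on a Gaussian-smoothed (σ = 3 ms) copy of
the raw signal — a QRS-scale matched filter that makes localisation
curvature-limited rather than noise-limited. On synthetic ECG at 10 dB SNR
the round trip recovers ≥ 99 % of beats within ±2 ms.

Cleaning excludes intervals outside [50, 350] ms — spanning the plausible
murine NN range around the observed group means (≈ 96–195 ms) — or more
than 30 % from the 9-beat running median. Removed intervals are dropped,
never interpolated, for time-domain metrics; the spectral path bridges
gaps by spline. Exclusion above 5 % flags a warning, above 20 % a hard
error; both alarms require at least 20 raw intervals so that toy inputs
are not spuriously fatal. These thresholds are explicit artifact-handling
decisions: published murine HRV work rarely states its beat-screening
rule, so none is claimed here as reproduction.

## The synthetic generator

`ipfm_beats()` implements integral pulse frequency modulation: beats are
emitted where the running integral of the instantaneous rate
1000/NN(t) crosses successive integers. IPFM cleanly separates the
modulation spectrum from point-process sampling and is the standard
idealisation of sinoatrial integrate-and-fire pacing. The modulation
(`generate_modulation()`) is a sum of

* an HF sinusoid (respiratory-like), placed in the lower part of the HF
  band (2.0 Hz at 20 °C, 1.0 Hz at 30 °C) where beat-interval sampling
  attenuates it least (the attenuation is ≈ sinc(f·NN); at the chosen
  frequencies it costs ≲ 6 % of HF amplitude),
* an LF sinusoid (1.0 / 0.45 Hz) with a slow Wiener phase drift
  (0.3 rad·s^−1/2) that broadens the LF peak as in real data,
* broadband 1/f^β Gaussian noise band-limited to [1/30 Hz, VLF top]. The
  lower edge exists because fluctuations at or below the Welch resolution
  are removed by per-segment detrending: generating them would spend SDNN
  on power the analyser cannot see. β-recovery checks accordingly fit over
  [1/30, VLF top], the support of the generated power law.

Component variances are scaled so total modulation SD equals the target
SDNN and band shares equal the target fractions.

Presets (`hrv_presets()`) set, per design cell, mean NN = 60000 / (cell
mean HR), the cell SDNN, band fractions = cell VLF/LF/HF powers normalised
to their sum (fractions, not absolute powers, because absolute PSD
magnitudes are estimator-dependent), the cell |β| as spectral exponent,
and a between-animal SD = SE·√N of the cell heart rate. Default record
length is 1800 s, a desk-scale stand-in for 1.5-h telemetry records.

`generate_cohort()` creates `n_per_cell` animals per age group, each
recorded in all four of its cells (2 temperatures × basal/intrinsic); one
standardised animal effect z is drawn per animal and reused across its
records (animal HR in a cell = cell mean + z · cell between-animal SD).
Reusing z across temperatures is an assumption — the within-animal
cross-temperature correlation is not identifiable from published group
tables — and is stated here rather than buried. The generator returns a
truth table of all generating parameters per record.

**What a green test establishes, and what it does not.** The generator
reproduces group means of HR/SDNN, spectral band shares, and a power-law
spectral tail under a stationary Gaussian modulation model. It does not
emulate non-stationarity (activity bouts, light/dark transitions),
drug-response transients after blockade, ectopy or arrhythmia, QRS
morphology beyond a Gaussian bump, or core-temperature physiology.
Pipeline correctness on real telemetry therefore rests on the per-module
property tests (conservation laws, oracle equivalence, estimator
benchmarks on processes with known exponents), not on the cohort
emulation alone.

## Statistics layer

`lmm_contrasts()` fits the cell-means form of metric ~ age × temperature ×
state with a random intercept per animal (REML via lme4). The contrast
family is the set of within-design pairwise comparisons actually
computable (state within age×temperature, temperature within age×state,
age within temperature×state; ≤ 12), and the Bonferroni multiplier is the
number computed — the family must be declared somewhere, and this is the
declaration. Degrees of freedom for mixed-model contrasts are taken
conservatively as (number of animals − 2), since Satterthwaite machinery
is deliberately out of dependency scope; when the random-effect variance
is singular (e.g. one record per animal) the model falls back to a
fixed-effects fit with a warning, where contrast p-values reduce exactly
to pooled-variance t-tests. A response with zero variance short-circuits
to zero estimates with p = 1. This layer is a contract for the study
design, not a reproduction of any particular table's p-values, which
would require animal-level raw data.

## Numerical and interface decisions

* Units everywhere: beat times s, intervals ms, powers ms², rates bpm.
* Sample (n − 1) variance throughout; fixed for exactness of closed-form
  tests even where n ≈ 30 000 makes it irrelevant.
* CSV interchange only; no proprietary telemetry formats. `time_s,nn_ms`
  files carry one row per interval (closing beat time + interval), so
  cleaned, non-contiguous series round-trip exactly.
* All generators are pure functions of (parameters, seed); cohort
  generation is byte-reproducible.
* Errors are classed conditions (`insufficient_data_error`,
  `configuration_error`, `degenerate_input_error`, ...) so the pipeline can
  mark a domain incomplete and continue instead of failing a whole run.

## Known limitations

* The R/S Hurst estimator is nearly unbiased after the finite-size
  correction but has per-realisation sd ≈ 0.10 at n = 4096; single-record
  Hurst values are noisy, and DFA α is the steadier exponent. Both are
  reported.
* Welch + spline resampling assumes gaps from cleaning are sparse; records
  losing more than 20 % of beats are rejected rather than analysed.
* The LF/HF split at high murine rates leaves little spectral headroom at
  30 °C (HF top 3 Hz vs ~5 beats/s); aliasing of genuinely faster rhythms
  is not modelled.
* `mse` at scale 10 on a 1.5-h record at 300 bpm uses ~2700 points — above
  the 100-point floor but entropy estimates at the largest scales remain
  the noisiest numbers the package reports.
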