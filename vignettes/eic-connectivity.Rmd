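---
title: "Envelope-of-imaginary-coherence connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope-of-imaginary-coherence connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiconn)
```

## The problem

M/EEG sensors observe instantaneous mixtures of underlying cortical sources
(volume conduction, VC). For a two-source, two-sensor local leadfield
`u = a1 x + b1 y + eps`, `v = a2 x + b2 y + eps`, the *real* part of the
sensor cross-spectrum is contaminated by auto-spectral terms, so coherence
and phase-locking report strong "connectivity" between sensors even when the
sources are independent. The *imaginary* part, in contrast, is exactly
`(a1 b2 - a2 b1) * Im S_xy(f)` — a scaled copy of the sources' imaginary
cross-spectrum — which is why imaginary-coherence-family measures (iCOH,
lagged coherence, PLI, wPLI) are VC-robust.

The price of discarding the real part is blindness to true interactions
whose phase difference is near 0 or pi (modulo 2*pi): there the imaginary
part vanishes even though coupling is real. The estimator this package is
built around, the **envelope of the imaginary coherence (EIC)**, addresses
that: treat the iCOH curve as a *function of frequency*, take its discrete
analytic signal (Hilbert quadrature), and report the magnitude. Because the
Hilbert transform of a (co)sine is its quadrature counterpart, the envelope
approximately restores the magnitude information that the discarded real
part carried, while inheriting VC robustness from the imaginary part. Across
frequency the imaginary part waxes and wanes through its zero crossings; the
envelope bridges them.

## Estimators

All measures are computed from per-epoch Fourier coefficients
`U_n(f), V_n(f)` (raw DFT of centred epochs, rectangular window, no padding,
one-sided grid `0..fs/2` at `fs/Nt` resolution) via the per-trial cross
products `P_n = U_n V_n*` and the trial-averaged complex coherence
`C_uv = mean(P_n) / sqrt(mean|U_n|^2 mean|V_n|^2)`:

| id | definition |
|------|------------|
| COH | `abs(C_uv)` |
| PLV | `abs(mean_n exp(i(arg U_n - arg V_n)))` |
| ICOH1 | `Im(C_uv)` |
| ICOH2 | `mean_n Im(P_n) / mean_n abs(H(Im P_n))` |
| PLI | `abs(mean_n sgn(Im P_n))`, `sgn(0)=0` |
| WPLI | `abs(mean_n Im P_n) / mean_n abs(Im P_n)` |
| LCOH | `Im(C_uv)^2 / (1 - Re(C_uv)^2)` |
| EIC1 | `abs(H(ICOH1))` |
| EIC2 | `abs(H(ICOH2))` |

`H` is the discrete analytic-signal operator applied along frequency.
`ICOH2` replaces the auto-spectral normaliser of `ICOH1` — which VC
contaminates through a cosine-weighted cross term — by the trial-averaged
Hilbert envelope of the per-trial imaginary cross-spectrum curves, an
imaginary-part-only normaliser. `EIC2` (the preferred estimator) is the
envelope of that curve.

Two genuinely open readings were implemented:

* **Expectation placement in the ICOH2 denominator.** The denominator's
  expectation can sit outside the envelope (`per_trial`, the default:
  envelope per trial, magnitudes averaged — matching the printed placement
  of the expectation operator) or the envelope can be applied to the
  already-averaged curve (`post_average`). Both are exposed via
  `icoh2_denominator=`; they differ numerically, and sensitivity checks are
  one flag away.
* **Edge handling of the analytic signal.** The Hilbert transform on a
  finite frequency grid overshoots near the grid ends (the envelope's
  "heavier tails"). The default applies no padding — reproducing the plain
  construction — and EIC values are reported *unclipped*; a reflective
  padding option (`pad = "reflect"`) exists for users who prefer softer
  edges. Envelope overshoot is why EIC may exceed 1 (a few percent on
  narrow-band fixtures; up to ~15% on broadband AR simulations, where the
  quadrature of the rapidly oscillating iCOH curve adds to its peaks); we
  document rather than clip.

Degenerate-denominator conventions, all logged via warnings: coherence at
zero-power bins is 0; `WPLI` 0/0 is 0; `LCOH` with `1 - Re(C)^2 <= 1e-12` is
0; an all-zero `ICOH2` denominator yields an all-zero curve.

## Significance: trial-shuffling surrogates

`surrogate_threshold()` destroys the trial correspondence between the two
channels (channel v's epochs are permuted uniformly; the identity
permutation is not excluded — at 100 trials its probability is negligible)
and recomputes the measure; the per-frequency maximum over `n_surrogates`
(default 1000) is the upper threshold, the minimum the lower one for signed
measures. The percentile is exposed for users wanting e.g. 0.95 instead of
the max statistic. Permutations are seeded and the ambient RNG state is
restored, so thresholds are fully reproducible. Under exchangeability the
per-bin false-positive rate of the max statistic is about `1/(n+1)`; the
test suite checks the pooled empirical rate over 200 repetitions against
`2/(n+1)`. Phase-randomisation surrogates and cluster corrections across
frequency are out of scope.

## Ground-truth simulators

**Delayed MVAR** (`simulate_mvar`). Every ROI follows
`x(t) = 1.5 x(t-1) - 0.75 x(t-2) + sum C * src(t - delta) + N(0, 1)` at
`fs = 250` Hz: a stable AR(2) (root modulus `sqrt(0.75)`) whose resonance
sits at ~20 Hz. Epochs are independent; the recursion starts from a zero
history and discards a 2 s burn-in so buffer artefacts vanish. Stability of
the full delayed multivariate system is verified via the companion-matrix
spectral radius before simulating; unstable systems are refused with the
radius named. Note the resonance is broad: on 1-Hz bins the 18–22 Hz
ordinates all lie within 10% of the maximum, so the argmax of a 100-trial
averaged periodogram scatters over 19–21 Hz (occasionally 18/22).

**Delayed stochastic Jansen–Rit** (`simulate_nmm_sdde`). Six states per ROI;
inter-ROI coupling `C * y1(t - tau)` enters the excitatory-interneuron
velocity equation, which also receives the Wiener increment
(`A*a*sigma_w*sqrt(dt)`). Standard parameters (`A=3.25` mV, `a=100` 1/s,
`B=22` mV, `b=50` 1/s, `e0=2.5` 1/s, `v0=6` mV, `rho=0.56` 1/mV,
`C1..C4 = 135, 108, 33.75, 33.75`) with mean drive `I = 220` put the column
in its alpha regime (~10.87 Hz). Integration is Euler–Maruyama in compiled
code at `dt = 0.05` ms by default; the convergence contract (halving `dt`
moves the trial-averaged spectral peak by < 0.5 Hz) is tested, and
`dt = 0.01` ms is one argument away. Two numerical choices deserve note:

* the inhibitory velocity leak uses the standard `-b^2 x3`; a
  `strict_printed = TRUE` flag switches to the alternative published form
  `-a^2 x3` for comparison;
* `sigma_w` is not a published constant. It was calibrated once on a grid
  (`scripts/calibrate_sigma_w.R`): the peak leaves 10.87 ± 0.5 Hz beyond
  sigma_w ≈ 3, and the default is 2.5 — the largest value with a margin.

The raw 20 kHz potential `x2 - x3` is decimated to 250 Hz by multistage FIR
decimation to 1 kHz followed by an 8th-order Butterworth low-pass at 100 Hz
applied forward-backward and stride-4 downsampling. A single 8th-order IIR
at the raw rate (normalized cutoff 0.005) is numerically unstable, which is
why the FIR pre-stages exist.

**Band-limited noise pairs** (`simulate_bandlimited_pair`). `x` is white
noise through a zero-phase ideal band-pass (frequency-domain mask,
`center ± bandwidth/2`), `y = x(t - delay)` by generate-and-slice (no
circular wrap), mixed by the local leadfield coefficients and blended with
fresh white noise by the Frobenius-normalised convex combination with weight
`beta` (0.9/0.5/0.1 ≈ +20/0/−20 dB). At `center = 15.625` Hz and
`fs = 250`, lags 0, 2, 4, 8, 16, 32 give 0, pi/4, pi/2, pi, 2pi, 4pi phase
differences. One grid subtlety matters for pi-phase experiments: 1-s
(250-sample) epochs have no 15.625 Hz bin, and at the nearest bin (16 Hz) a
lag of 8 samples is *not* a pi-phase interaction, so the imaginary part does
not vanish there. The package's pi-phase experiment therefore uses
256-sample epochs (`fs/Nt = 0.9766` Hz), which place the centre frequency
exactly on-grid.

## Sensor space: synthetic layout, mixing, nearest-sensor ROIs

The anatomical-template/BEM leadfield chain is external data and is replaced
by a documented synthetic stand-in: 102 sensors quasi-uniform (Fibonacci
lattice) on an upper hemispheric cap of unit radius, gains
`1/(d^2 + 0.02)` with unit-norm columns, no dipole orientation modelling.
The nearest-sensor ROI heuristic only needs gains that decay monotonically
with distance, which this construction guarantees (and the tests check
gain/distance order agreement exhaustively). Background activity uses 500
interior sources by default — scaled down from a full cortical mesh; because
each gain column is unit-norm and the alpha-blend is Frobenius-normalised,
results are insensitive to this count at fixed `alpha`. Defaults chosen
where the two-sensor model leaves constants free: sensor noise sd = 10% of
the noiseless mixed-signal sd; `beta = 0.9`.

`kns_rois()` defines each ROI in sensor space as its K nearest sensors
(default K = 6; ties broken by sensor index). An edge of the thresholded FC
map is a true positive iff its endpoints belong to the sets of two
*different* ROIs — transitivity accepted — and a false positive otherwise.

## ROC evaluation and the Monte-Carlo harness

`full_fc_map()` collapses each pair's curve to one scalar: by default the
maximum magnitude over the simulated rhythm ± 2 Hz (20±2 Hz MVAR,
10.87±2 Hz neural-mass), with `mean` and single-`bin` alternatives — the
aggregation is a package choice, recorded in the map's metadata.
`percentile_graphs()` keeps edges at or above the `(100m/M)`-th weight
percentile for `m = 0..M` (default `M = 100`); ties are kept, `m = 0` is the
complete graph, and `m = M` is empty by convention. `roc_auc()` integrates
TPR–FPR by trapezoid with (0,0) and (1,1) appended; AUC is invariant to
strictly monotone reweighting (tested). `mc_harness()` runs R realizations
per scenario (fresh MVAR sources, background and sensor noise each time;
SDDE sources simulated once per scenario and reused, since integration
dominates cost), averages AUC over a KNS range (default 6–10), and the
companions `compare_measures_paired()` (Wilcoxon signed-rank, Bonferroni
with recorded N), `compare_auc_unpaired()` (Mann–Whitney) and
`score_winloss()` (win 3 / draw 1 "league" and win 1 / draw 0.5 "chess"
points) implement the comparison protocol.

## What the generators emulate — and what they do not

The simulators reproduce the statistical structure the estimators are
sensitive to: narrow/broad-band rhythms, controlled transmission delays and
coupling strengths, instantaneous mixing, background activity and
measurement noise at set SNRs. They do not emulate realistic head geometry,
dipole orientations, non-stationary coupling, 1/f background spectra, or
artefacts (eye, muscle, line noise). Passing tests therefore demonstrate the
estimators' contracts under the stated generative models — VC robustness,
pi-phase recovery, calibrated surrogates, above-chance sensor-space network
recovery — not performance on real recordings.

## Problem sizes used by the test suite

The suite favours the smallest sizes that exercise each claim: 100 trials ×
1 s for bivariate experiments (10 seeded repetitions where a success rate is
asserted, 1000 surrogates as in the default), 20 trials × 4 s for the
neural-mass spectral peak (0.25 Hz resolution), 20 Monte-Carlo realizations
× 102 sensors × KNS 6 for the scaled sensor-space ROC (against a
label-permuted null, Mann–Whitney p < 0.01), and 200 repetitions × 200
surrogates for the null calibration of the max statistic. Full-scale
replication of the 100-realization tournament tables is out of scope.

## Known limitations

* EIC is reported unclipped and may exceed 1: the Hilbert quadrature of a
  bounded sequence is not itself bounded by 1, so the envelope overshoots
  near sharp spectral features and grid edges (a few percent on narrow-band
  fixtures, up to ~15% observed on broadband AR simulations). Comparisons
  across measures should use ranks or thresholds, as the ROC analysis does.
* The surrogate max statistic can overestimate thresholds for highly stable
  narrow-band synchronisation (near-constant phase differences inflate the
  surrogate extremes), making EIC conservative in that regime.
* Sensor-space analysis cannot assign directionality, and transitivity means
  indirect associations count as true positives by construction.
* The synthetic leadfield is distance-coherent but not physical; absolute
  AUC levels depend on its geometry even though measure *rankings* are
  stable across KNS 6–10.
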