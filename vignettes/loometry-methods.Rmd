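---
title: "Models and methods behind loometry"
author: "loometry maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loometry)
```

`loometry` re-implements, as reusable and tested components, the
computational analyses of visual looming-threat extinction and updating
experiments in mice: stimulus-schedule modeling, rule-based behavioral
scoring from pose tracks, two-channel fiber-photometry zdFF processing,
stimulus-locked neural and behavioral statistics, and engram
(c-Fos/EYFP) reactivation quantification. This vignette explains the
models, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open.

## Stimulus model

A looming train is a sequence of expanding-disc presentations: the disc
appears at 2° of visual angle, expands linearly to 20° over 250 ms,
holds for 250 ms, and disappears instantaneously (no off-ramp is
modeled; none is specified for the assay). Repetitions are separated by
a 500 ms inter-repetition interval measured **offset-to-onset**, giving
a fundamental period of exactly 1 s. The offset-to-onset reading is the
only one consistent with the 1 Hz stimulus-locked spectral peak the
assay produces (an onset-to-onset reading would give 1/0.5 = 2 Hz with
overlapping events); it is therefore adopted throughout.

```{r loom}
loom <- LoomSpec()
stimulusFundamentalFreq(loom)
onsets(buildLoomTrain(loom, t0 = 0))
```

The dimming control stimulus is a constant-size 20° disc whose contrast
ramps linearly from 0 to 0.75 over 250 ms and holds. Contrast is stored
as a fraction in [0, 1]; percent appears only at I/O boundaries. The
fear-updating session appends a 0.75 mA, 2 s foot-shock that
co-terminates with the train: shock offset equals the train offset
exactly. Multi-wave extinction sessions compose trains with a 60 s
offset-to-onset rest (the inter-wave gap convention is ambiguous in
assay descriptions; offset-to-onset is documented here and
configurable).

The session clock is seconds from recording start. The live assay
triggers the train manually when the animal is in the shelter-opposite
half of the arena; the model replaces that trigger with an explicit
`t0` parameter, and TTL rising edges imported from the acquisition
system map train onsets onto the photometry clock.

## Behavioral scoring

Scoring consumes calibrated pose tables (14 keypoints by default, three
of them tail points) at a user-supplied frame rate — pose tables do not
record fps, so it is a required input.

**Freezing** is the cessation of all movement except breathing,
operationalized per frame as: no more than one keypoint moved 2 mm or
more (Euclidean, inclusive threshold) since the previous frame,
sustained for at least 0.5 s. The displacement window is the
consecutive-frame difference — the simplest reading of a "2 mm
movement" rule; it is exposed as a parameter. Frame 1 copies frame 2's
flags (no backward difference exists). A run of `k` immobile frames
lasts `k/fps` seconds, and the duration comparison is inclusive, so 15
immobile frames at 30 fps are exactly 0.5 s and count as a bout.

**Sheltering** is containment: every non-tail keypoint within the
shelter's y-limits and at least half of the non-tail keypoints within
its x-limits. Tail keypoints are ignored entirely, so arbitrary tail
motion cannot change the call. No minimum duration applies.

**Flight** is shown in this literature but rarely operationally
defined; the package scores it as speed ≥ 150 mm/s sustained for
≥ 0.2 s. These defaults are package choices, flagged as such, and
should be tuned per assay.

Freezing and sheltering are computed independently and may co-occur (an
animal can freeze inside the shelter); figures in this literature plot
the channels separately, so no exclusion is applied.

**Speed** is the finite difference of the non-tail-keypoint centroid
times fps, timestamped at inter-frame midpoints, unsmoothed by default
(an optional centred boxcar is available). The centroid is used because
no single reference keypoint is canonical; the choice only matters at
the ~1 body-length scale. Speed scales exactly linearly with any
pixel-calibration error.

Coordinates are millimetres, origin at the arena's front-left corner, y
increasing toward the rear (shelter) wall. The default arena is the
460 mm × 300 mm floor with a 75 mm × 150 mm shelter centred on the rear
wall. Keypoints below a likelihood threshold (default 0.6) are linearly
interpolated on import — standard pose-table hygiene.

## Photometry: the zdFF chain

Recordings carry a calcium-dependent channel (465 nm excitation) and a
calcium-independent isosbestic channel (405 nm) that sees the same
motion and bleaching artifacts but not the calcium signal. The
correction chain is:

1. **Smoothing** — centred moving mean, default window `0.04 * fs`
   rounded odd (5 samples at 100 Hz); edges shrink symmetrically.
2. **Baseline removal** — airPLS per channel: iteratively solve the
   weighted Whittaker system `(W + λ DᵀD) z = W x` with second
   differences `D`, zeroing weights where the residual is non-negative
   (candidate peaks) and up-weighting points below the baseline as
   `exp(iter·|d|/Σ|d₋|)`; stop when the summed negative residual falls
   below `ratioTol · Σ|x|`. Defaults: λ = 1e8, 50 iterations,
   ratioTol = 0.001. λ = 1e8 at 100 Hz gives a baseline cutoff near
   0.05 Hz — stiff enough to ride under second-scale transients, supple
   enough to track photobleaching.
3. **Standardization** — `(x − mean)/sd` per channel.
4. **Reference fit** — the standardized isosbestic channel is fit to
   the standardized signal channel as `y = a·x + b` by iteratively
   reweighted least squares with Huber weights (c = 1.345, MAD scale)
   and the slope clamped to `a ≥ 0`: artifacts can only enter the
   signal channel with non-negative gain. With `c = ∞` the fit reduces
   to ordinary least squares; a non-negative-lasso alternative sits
   behind a switch.
5. **Subtraction** — `zdff = std465 − (a·std405 + b)`.

The output is invariant to pure gain changes of the raw channels;
additive offsets perturb only the airPLS stopping criterion (which
normalizes by `Σ|x|`), so offset invariance holds to about 1e−3 rather
than machine precision.

One subtlety worth spelling out: after per-channel standardization the
fitted slope `a` no longer estimates the physical channel coupling —
standardization divides that coupling out, pushing `a` toward 1
regardless of the true gain. Parameter-recovery tests therefore apply
the reference fit to the airPLS-corrected, *unstandardized* channels,
where the slope estimand is the generative coupling; the `ZdffResult`
slot `a` remains the standardized-channel fit, as the processing chain
defines it.

### Stimulus-locked summaries

Peri-event matrices use nearest-sample alignment (the t = 0 column is
the sample closest to each onset); events too close to the recording
edges are dropped with a warning. Pre/post AUC is the trapezoidal
integral over `[onset − w, onset]` and `[onset, onset + w]` on the
native grid with the onset sample shared, so the two halves add exactly
to the full-window integral; the conventional half-windows are 15 s
(photometry) and 15 or 30 s (behavior).

Magnitude spectra detrend the segment before the FFT: the mean is
removed and, by default, a slow trend estimated by a 5 s moving mean is
subtracted. The slow-trend removal exists because the airPLS stage has
a finite cutoff (~0.05 Hz at the defaults) and leaves sub-0.1 Hz
residue in the corrected trace — channel-specific baseline wiggle that
survives the reference subtraction and is not stimulus-related; without
detrending it can occupy the lowest spectral bins. The 5 s window puts
the high-pass edge near 0.2 Hz and attenuates a 1 Hz component by less
than 1%. A Hann taper is optional; the default is no taper. The
dominant peak is the largest non-DC bin, and for a loom-locked
recording it sits at the 1 Hz train fundamental to within one frequency
bin.

Behavior-triggered averages align the trace to bout onsets and report
the across-bout mean ± SEM (a single usable bout yields a zero SEM by
convention).

## Neural–behavioral statistics

Logistic regression of per-sample freezing on zdFF is fit by
Newton–Raphson with step-halving, which makes the log-likelihood
non-decreasing across iterations; perfect separation (a zdFF threshold
splitting the classes exactly) is detected up front, flagged, and
warned about, because the slope is then unidentified. The 95% band is
the delta-method band on the linear predictor mapped through the
inverse link, so it stays inside (0, 1). Linear regression of speed on
zdFF uses ordinary least squares with the classical mean-prediction
band, which widens away from the predictor mean.

General machinery: unpaired comparisons use the equal-variance Student
t test and paired comparisons the paired test; a Shapiro–Wilk gate
(α = 0.05) routes non-normal samples to the rank-based equivalents
(Mann–Whitney U / Wilcoxon signed-rank) — the gate is standard, the
non-parametric branch is a documented package choice. Repeated-measures
one-way ANOVA is fit via the within-subject error decomposition
(`aov` with an `Error(subject)` stratum); with two conditions its F
equals the squared paired-t statistic, and post-hoc pairwise paired t
tests run only when the omnibus test is significant. No sphericity
correction is applied by default. Benjamini–Hochberg adjustment
(`bhFDR`) produces q values per family; the family convention is all
regions within one contrast, matching how such panels are reported.
(Note that the BH step-up adjustment is monotone but **not** idempotent
— re-adjusting adjusted values inflates them — so q values are computed
once per family.)

## Engram reactivation

Total cells per region are extrapolated as sampled DAPI density
(cells/µm²) times the counted region area; the product is kept
real-valued until report time to avoid small-area rounding bias. The
c-Fos rate divides the c-Fos count by that total (a per-area density is
available as an alternative output, since panel conventions vary).
Reactivation is `n_double / n_eyfp` — the proportion of initially
tagged EYFP⁺ cells that re-express c-Fos. No chance-normalization is
applied in the standard outputs because group comparisons are made
directly; a fold-over-chance variant exists and is labelled as a
derived, non-standard measure. Two-group contrasts use unpaired t tests
per region, three-group contrasts one-way ANOVA, with BH-FDR across the
region family; regions with singleton groups are skipped with a
warning. Region-by-behavior Pearson correlations require at least three
paired mice per cell.

## Synthetic data: what it emulates, and what it does not

The generators provide ground-truth-bearing stand-ins for the animal
data, which is not publicly deposited; every pipeline stage gets a
parameter-recovery test without any download.

**Pose tracks** place a rigid 14-keypoint body template on a scripted
centroid trajectory: `locomote` is a persistent random walk at 3
mm/frame (~90 mm/s at 30 fps), `freeze` holds the centroid, `shelter`
dithers the body inside the shelter tube at 2.5 mm/frame (so sheltering
does not masquerade as freezing), and `flight` dashes toward the
shelter entrance at 10 mm/frame (~300 mm/s). Independent Gaussian
tracking jitter (default σ = 0.3 mm, a typical pose-estimation
residual) is added per keypoint and frame. Freezing and flight ground
truth follow the script; sheltering ground truth applies the geometric
containment rule to the noiseless template, because a freeze scripted
inside the shelter *is* sheltering under the definitions. Defaults:
30 fps (frame rates are assay-specific and not standardized).

**Photometry** recordings share a double-exponential bleaching baseline
and a low-frequency motion artifact (Ornstein–Uhlenbeck process
low-passed at 0.5 Hz, stationary SD 0.04) across channels; the signal
channel adds calcium transients (double-exponential kernel, 50 ms rise,
800 ms decay — the kinetics class of fast genetically encoded calcium
indicators) scaled by the channel coupling `ch465 = a·(bleach +
artifact) + b + transients + noise`, with defaults a = 0.8, b = 0.1,
per-channel noise SD 0.005, 100 Hz, 60 s.

**Cell counts** draw DAPI density and counted area around realistic
confocal values (0.001–0.002 cells/µm², 4–8 × 10⁵ µm²), tag a Poisson
number of EYFP⁺ cells, and draw double-positives as
Binomial(n_eyfp, reactivation) with the remaining c-Fos⁺ cells binomial
among the untagged population — so the count invariants hold by
construction.

All generators are pure functions of (specification, seed): the global
RNG state is saved and restored, and identical inputs give identical
outputs.

What the generators do **not** emulate — and hence what passing tests
do not show about real data: postural articulation and body-shape
change (the template is rigid, so keypoint-specific movement patterns
like grooming are absent), tracking dropouts and identity swaps,
hemodynamic or wavelength-specific artifacts that violate the shared-
artifact assumption, bursty or state-dependent calcium dynamics, and
anatomical correlation structure between regions in the count tables.
Recovery results certify the pipeline's correctness under its own
model assumptions, not the assumptions themselves.

## Numerical choices and degenerate inputs

- airPLS solves its banded system with sparse Cholesky factorization;
  at λ = 1e8 the solution is accurate to ~1e−8 relative, which bounds
  several test tolerances. Non-convergence returns the last iterate
  with a warning and a `converged = FALSE` attribute.
- A constant series is its own airPLS baseline (zero residual,
  immediate convergence); standardizing a constant series is an error.
- The Huber IRLS stops on a 1e−10 relative coefficient change or when
  the residual MAD hits zero (exact fit); a finite-c fit that fails to
  converge in 100 iterations errors rather than returning silently.
- Time-to-sample conversion is nearest-sample throughout
  (`round(t * fs)`), making peri-event alignment exact on-grid.
- Freezing durations compare inclusively with a 1e−9 guard against
  floating-point shortfall in `minDur * fps`.
- `bhFDR` validates p ∈ [0, 1]; `pearsonCor` and `linearFit` reject
  constant inputs rather than returning NaN.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale, chosen to make every
stochastic check statistically decisive: 60 s photometry recordings at
100 Hz (6,000 samples), 20-seed ethogram-recovery sweeps over ~20 s
10-bout scripts, 10⁴-point robust-regression recoveries, 5,000-replicate
null calibrations of the paired t test, the complete enumeration of all
4,421,275 sorted 4-element p-value multisets on the 0.01 grid for the
BH check, and 500-replicate detection studies for the region-contrast
design (Δ = 0.25, n = 8 mice per group, ~150 tagged cells).

## Known limitations

- The flight definition is a package convention, not an assay standard.
- Ethogram boundary frames shift by ±1 frame around state transitions
  (the first frame of an immobility period carries the entering
  displacement), which bounds achievable interval IoU slightly below 1.
- The reference fit assumes a single shared artifact process; colored,
  channel-specific artifacts bias the slope like classical
  errors-in-variables attenuation.
- rm-ANOVA offers no sphericity correction yet; with more than two
  conditions and heterogeneous covariance its p values are liberal.
- The pipeline runner is single-session; cohort-level aggregation is
  left to the user's scripts.
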