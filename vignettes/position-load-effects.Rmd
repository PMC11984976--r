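---
title: "Limb-position and load effects on EMG/FMG gesture classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limb-position and load effects on EMG/FMG gesture classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfmg)
```

## The problem

Pattern-recognition control of hand prostheses and gesture interfaces is
usually trained in one comfortable posture with nothing in the hand. In
daily use the arm moves through space and the hand carries loads, and both
factors change the signals that the classifier sees: surface
electromyography (EMG) picks up stabiliser co-contraction and electrode
shift, and force myography (FMG) — force-sensitive resistors pressed
against the forearm — responds to gravity-dependent muscle bulk shifts and
grip-force scaling. This package implements, as a reusable and fully
seeded pipeline, an experimental analysis of those effects: four hand
grasps (key, pulp pinch, power, tripod) held for 3 s and released for 3 s,
three repetitions each, across five added loads (0–1000 g on a 53 g
manipulandum) and eight reaching positions — 160 conditions and 480 trials
per participant — recorded by an 8-channel EMG plus 8-channel FMG armband
at 2000 Hz.

No recordings of this protocol are publicly deposited, so the package is
organised around a synthetic-session generator that emulates the study
design and the signal phenomenology. Every downstream stage — segmentation,
feature extraction, classification, evaluation, statistics — is exercised
and tested against that generator.

## The synthetic signal model

`generate_schedule()` reproduces the protocol's randomized block structure:
grasps form the outermost blocks, loads nest inside grasps, positions
inside loads, all three block orders permuted by the seed, and the three
repetitions of a condition always consecutive (the manipulandum stays on
its shelf while a grasp is repeated).

`simulate_session()` renders a schedule into continuous 16-channel data.
EMG is amplitude-modulated Gaussian noise: channel $c$ of a contraction of
condition $(g, \ell, p)$ has plateau amplitude

$$a_c = A_{g c}\,(1 + s_c \ell)\,\bigl(1 + \kappa_\mathrm{pos}\,
\delta_\mathrm{pos}(p, c) + \kappa_\mathrm{load}\,
\delta_\mathrm{load}(\ell, c)\bigr),$$

with a linear onset/offset ramp and a rest-phase noise floor. $A$ holds
per-gesture channel patterns (smooth phase-shifted cosine profiles over
the circular channel array, defaults $0.7 \pm 0.25$), $s_c$ is a monotone
load gain ($5\times10^{-4}$ per gram, i.e. +50 % at 1000 g), and
$\delta_\mathrm{pos}, \delta_\mathrm{load} \in [-1, 1]$ are fixed,
deterministic perturbation tables that vanish at the neutral levels
(position 2, 0 g) and grow with distance from them. The tables are sine
profiles over the channel index whose phase advances in steps of $\pi/3$
(plus a $\pi/6$ offset) across positions/loads; the step was chosen so the
perturbation directions couple to the cosine gesture patterns rather than
staying orthogonal to every between-class direction, which would leave
classifiers artificially immune to position change. FMG channels follow a
first-order lag toward a per-condition target pressure (rise constant
0.15 s, decay 0.25 s — unequal constants give FSR-like hysteresis), with
optional linear drift, additive noise, and clipping at zero.

Two stochastic ingredients matter for realism:

* **Trial-to-trial jitter** (`trial_jitter_sd`, default 0.05): every
  trial's channel gains are multiplied by lognormal factors, drawn
  independently for the EMG and FMG sides. Without it, window features
  cluster so tightly around their condition means that every
  classification cell is a deterministic 0 %-or-100 % cliff; with it,
  accuracies degrade gradually, the way real cross-condition transfer
  does.
* **Window noise**: the Hudgins features of a 400-sample window of
  amplitude-modulated noise have a coefficient of variation of a few
  percent, which sets the within-condition scatter.

The defaults ($\kappa_\mathrm{pos} = 0.55$, $\kappa_\mathrm{load} = 0.18$,
patterns above) were fixed once, as the package's definition of the
simulated study conditions, to reproduce the qualitative phenomena the
analysis is about — neutral-posture training transfers poorly to moved or
loaded arms, compound changes are worst, and condition variability erodes
gesture separability — while keeping all 160 conditions learnable well
above chance. They are not fitted to any empirical accuracy value, and the
generator makes no claim of physiological EMG realism (no motor-unit
structure, no electrode-skin dynamics); conclusions from the synthetic
cohorts are about the pipeline's behaviour, not about human data.

## Segmentation

Timestamps are ground truth (the protocol was script-cued), half-open
`[onset, offset)` in seconds, with sample index `floor(t * rate)`.
`extract_contraction()` keeps the central 70 % of each 3 s hold (35 %
either side of the midpoint, i.e. 2.1 s, 6.3 s per condition after pooling
three repetitions), avoiding the transition states near grasp onset and
release. `slide_windows()` cuts 200 ms windows with a 50 ms increment —
400 and 100 samples at 2000 Hz, 39 windows per repetition.

One deliberate deviation from the source protocol: windows are cut within
each repetition separately rather than after concatenating the three
repetitions of a condition. Cross-repetition windows would have no
unambiguous repetition label and would leak information across
leave-one-repetition-out folds. The cost is 117 windows per condition
instead of 123; the benefit is a clean CV contract.

## Features

Per window and channel, EMG uses the five-feature Hudgins-style set —
mean absolute value, waveform length, zero crossings, slope sign changes,
root mean square — in channel-major order (40 values); FMG uses mean
absolute value only (8 values); the "stacked" fusion concatenates the two
blocks (48 values), and its first 40 entries are bit-identical to the
EMG-only vector. ZC and SSC accept an amplitude deadband; the default is
0 (the textbook definitions). A fixed, configurable threshold is exposed
instead of deriving one from each training fold's rest noise, because a
fold-dependent threshold would make feature values depend on the CV split
and break the featurize-once architecture. With the white-noise carrier,
ZC/SSC are amplitude-invariant and carry no class information; they are
retained because the feature contract, not the simulator, defines the
pipeline.

## Classification

`fit_lda()` is a standard pooled-covariance Gaussian classifier: class
means, within-class scatter over $n - K$, empirical priors, and a small
shrinkage $\Sigma \leftarrow (1-\lambda)\Sigma +
\lambda\,\mathrm{tr}(\Sigma)/D\,I$ with default $\lambda = 10^{-3}$. The
shrinkage exists for numerical conditioning only: 160-class folds train on
two repetitions per condition, and the EMG amplitude features
(MAV/WL/RMS) are strongly collinear. Ties in the discriminant break
deterministically to the earliest label in canonical order (gesture-major,
load ascending, position 1–8). Classification is per window; no majority
voting. Tests verify the implementation against the explicit discriminant
formula and against `MASS::lda` on clean fixtures, and that predictions
are invariant to invertible per-feature affine maps.

`loro_cv()` uses repetitions as global fold keys: fold $r$ trains on all
windows with repetition $\neq r$ and tests repetition $r$; window-level
predictions from the three folds accumulate into one confusion matrix.
Accuracy is everywhere the mean of the row-normalized diagonal
(macro-averaged recall).

## The three evaluation designs

* **Test 1, combined** (`test1_combined()`): the class label is the full
  (gesture, load, position) triple — a 160 × 160 confusion matrix; the
  best and worst diagonal conditions are reported.
* **Test 1, neutral vs varying** (`test1_neutral_vs_varying()`): 4-gesture
  CV at the unloaded neutral posture (position 2, elbow at 90°, 0 g)
  versus 4-gesture CV pooling all 40 load × position combinations.
* **Test 2, transfer** (`test2_transfer()`): at constant load, train at
  one position and test at each other (8 × 7 cells per load); mirrored
  with constant position and varying load (5 × 4 cells per position). The
  train and test cells are disjoint conditions, so all three repetitions
  are used on both sides without leakage.
* **Test 3, extremes** (`test3_extremes()`): train at the neutral cell and
  test at neutral (via leave-one-repetition-out, so the baseline is not
  train-on-test), loaded (position 2, 1000 g), outstretched (position 5,
  0 g) and outstretched+loaded. The three non-neutral evaluations use all
  three neutral repetitions for training, since their test data are
  disjoint anyway — holding one out would only waste training data.

On the default synthetic cohorts the directions mirror the expected
phenomenology: neutral ≥ varying for every modality; transfer accuracy
decreases monotonically in each effect magnitude; and the compound extreme
is at most as accurate as either single perturbation for EMG and the
stacked modality. Synthetic FMG saturates near chance in all three
non-neutral extreme cells, where the ordering between them is sampling
noise; the test suite therefore asserts the compound-worst property for
EMG and the fusion. A dedicated fixture in which EMG only separates
{key, pulp pinch} from {power, tripod} and FMG only separates
{key, power} from {pulp pinch, tripod} verifies that stacking strictly
beats both single modalities when their information is complementary.

## Statistics

The comparison layer mirrors the repeated-measures analysis:
`fit_modality_lme()` fits `accuracy ~ modality + (1 | participant)` by
REML (delegated to `lme4::lmer`), and `pairwise_emm_contrasts()` forms all
pairwise estimated-marginal-mean differences with standard errors from the
fixed-effect GLS covariance, two-sided p-values from the normal reference
distribution, and Benjamini–Hochberg adjustment within the model
(`bh_fdr()`, a validated wrapper over `p.adjust`). The normal (z)
reference rather than a Satterthwaite degrees-of-freedom correction is a
documented simplification; with ~27 subjects the difference is negligible.
Under the balanced design the EMMs equal raw level means, which the tests
assert, along with agreement of the REML variance ratio with a brute-force
profile-likelihood grid and calibration of the contrasts' type-I error
(≤ 6 % per contrast at α = 0.05 in a 100-replicate null simulation).
Because accuracy distributions for the transfer designs are often skewed,
summaries always include median/IQR (type-7 quantiles) beside mean ± SE,
and a rank-transformed fit is available via `transform = "rank"`; the
package does not adjudicate which the original analysis used.

## Numerical and design choices

* Sample-count rounding is round-half-up; window and step lengths must be
  whole samples at the recording rate (400/100 at 2000 Hz).
* The whole pipeline is a pure function of (config, seeds): schedules,
  signals and the statistics layer each take explicit seeds, substream
  seeds are derived arithmetically, and `run_pipeline()` stamps every CSV
  with a hash of its configuration. Rerunning a config is byte-identical.
* Session containers are flat little-endian doubles plus a JSON sidecar
  and an events CSV — chosen for bit-exact round-trips, easy validation
  (channel counts, enum ranges, rates) and cross-language readability.
* Problem sizes in the test-suite and acceptance cohorts: property suites
  simulate at 1000 Hz (window counts per repetition are rate-invariant:
  39 everywhere) with 5-participant cohorts for direction-of-effect
  checks and 3-participant cohorts for end-to-end summaries; structural
  checks use 2000 Hz. These sizes are the package's own choice of
  desk-scale defaults; all of them are configurable upward.

## Limitations

The generator reproduces the protocol's combinatorics, the envelope/lag
phenomenology and the direction of position/load effects, but not real
EMG/FMG waveforms: no motor-unit interference structure, no electrode
lift or sweat drift beyond a linear term, no inter-participant anatomy
differences (participants differ only by noise realization). Passing the
synthetic suites therefore demonstrates that the pipeline measures what
it claims to measure — not that a particular accuracy level would be
attained on human recordings.
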