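---
title: "Microscale motor mapping with msom: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscale motor mapping with msom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msom)
```

# Scope

`msom` implements an end-to-end analysis chain for micromotor mapping with
dense surface microelectrode arrays: 1024 contacts at 400 um pitch over
roughly 1.2 x 1.2 cm of sensorimotor cortex, recorded while a participant
performs cued hand-gesture transitions or self-paced isolated-joint
movements. The chain runs from raw multichannel voltage to (i) per-channel
movement effect sizes with family-wise-error-controlled significance on the
electrode grid, (ii) spatial summaries of the activated territory, (iii)
representational similarity analyses across movements, (iv) time-resolved
multivariate decoding, and (v) cross-participant spatial-gradient pooling.
Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic-data generator that plants known ground truth so
that every downstream stage is testable without any external data.

# The measurement model

## From voltage to broadband high gamma

Broadband high-gamma activity (80-200 Hz) is used as a proxy for local
population firing. The preprocessing chain is:

1. **Impedance exclusion.** Channels with impedance strictly above 2 MOhm
   are excluded; excluded channels are zero-imputed after referencing so
   they pass inertly through the spectral stage and carry 0 dB downstream.
2. **Common-average referencing (CAR).** The mean voltage over included
   channels is subtracted from every channel at every sample, removing
   common-mode noise.
3. **Multitaper spectral estimation.** Sliding 100 ms windows at 90 %
   overlap with discrete prolate spheroidal (DPSS) tapers at a frequency
   resolution (smoothing bandwidth) of F = 40 Hz. The time-bandwidth
   product is NW = window x F/2 = 2 and the taper count T = 2NW - 1 = 3.
   Tapers are computed from the standard symmetric tridiagonal
   eigenproblem; the single-taper limit reduces to a plain tapered
   periodogram, which the tests verify. Window timestamps follow the causal
   convention (a bin at time t is the window *ending* at t), so decoding
   features never see future samples.
4. **1/f normalization.** Power at each channel and frequency is divided by
   that frequency's mean over the recording, flattening the characteristic
   1/f decay. The movement/baseline power *ratio* is insensitive to this
   per-channel, per-frequency scaling; it matters for band averaging, where
   it acts as an inverse-spectrum weighting.
5. **Band averaging and dB.** Power is averaged over the 80-200 Hz band
   (band edges inclusive on the 10 Hz bin grid of the 100 ms window) and
   converted to decibels against the channel's mean baseline power pooled
   across all trials: dB = 10 log10(trial power / pooled baseline power).

Two baseline anchors are supported because the source conventions differ
between a cue-anchored and an onset-anchored definition: the default for
the gesture task is the 500 ms before each trial's *audio cue* (a period in
which the hand is demonstrably at rest), with the 500 ms before movement
onset available via `baseline = "onset"`. For self-paced sessions, which
have no cues, rest is instead drawn from kinematically quiet 500 ms
segments (below, *Kinematics*).

## Effect size: signed R^2

For each channel, per-trial band power under movement and rest is compared
with the signed coefficient of determination

$$ r^2_\pm \;=\; \operatorname{sign}(\bar m-\bar r)\,
   (\bar m-\bar r)^2\,
   \frac{N_m N_r}{\sigma^2_{m\cup r}\,N_{m\cup r}^2}, $$

where $\bar m,\bar r$ are condition means, $N_m,N_r$ the trial counts and
$\sigma^2_{m\cup r}$ the pooled variance over the union of both conditions.
With the population (divide-by-N) variance convention the statistic is
bounded in $[-1, 1]$ and attains exactly 1 for perfectly separated balanced
samples; a sample-variance alternative is available by argument. The
penalty term $N_mN_r/N^2$ discounts unbalanced designs. The tests verify
the closed form against term-by-term evaluation and against signed
eta-squared for balanced conditions.

## Inference: TFCE with max-statistic permutation

Per-channel statistics are enhanced with threshold-free cluster enhancement
on the electrode grid,

$$ \mathrm{TFCE}(c) \;=\; \sum_{h = dh,\,2dh,\dots}^{\max} h^H\,
   e(c,h)^E\, dh, $$

with $H = 2$, $E = 1$, $dh = 0.1$, where $e(c,h)$ is the size of the
8-connected component of supra-threshold ($\ge h$) cells containing $c$.
This rewards both signal height and spatially contiguous extent without a
fixed cluster-forming threshold. Family-wise error is controlled by
permutation: movement/rest labels are shuffled over the pooled trials, the
statistic map and directional TFCE are recomputed, and the maximum score
over all electrodes is recorded per direction. P-values use the
add-one rule $p = (k+1)/(n_{\mathrm{perm}}+1)$ against the directional
maxima, with significance at $\alpha = 0.025$ per direction (two-tailed
family-wise 0.05). The compiled TFCE kernel is checked exactly (1e-12)
against a brute-force connected-component oracle on random maps.

Two design choices deserve note. First, the statistic entering TFCE is the
signed R^2 map (a pooled-variance t map is available via `stat = "t"`);
within a channel the two are strictly monotone transformations of one
another under label permutation, so they induce the same permutation
ranking — the tests verify the identical channel ordering. Second, for
time-resolved (channel x time) maps, one shuffle set is shared across all
time bins and the null maxima are taken over channels *and* bins, so the
family-wise error rate is controlled over the entire map.

## Spatial summaries

The extent of activation (EoA) is the sum of signed R^2 over channels that
are both significant and positively modulated. Binary activation masks
assign each electrode a disc of radius 0.2 mm (half the pitch), about
0.126 mm^2; pairwise spatial overlap uses the Dice coefficient
$2|A\cap B|/(|A|+|B|)$, and "exclusive territory" is quantified as the
symmetric difference times the disc area (the only symmetric reading of a
non-overlap area). Mediolateral profiles partition grid columns into
contiguous bands whose EoAs sum exactly to the global EoA.

## Representational similarity

Per-movement dB maps are embedded on the grid and flattened row-major
(1023 dimensions for the default array: 1019 grid contacts plus the four
references mapped to the corner cells; the fifth reference is unmapped and
dropped). Dissimilarity is Euclidean distance; embeddings use *metric* MDS
by SMACOF majorization (classical-scaling initialization plus seeded random
restarts), since the quality measure is Kruskal's normalized stress on raw
distances, $\sqrt{\sum(d_{orig}-d_{proj})^2/\sum d_{orig}^2}$. Hierarchies
use Ward linkage; Ward on the feature vectors and `ward.D2` on their
Euclidean distance matrix coincide, which is how "clustering on the
dissimilarity matrix" is honored while keeping Ward's centroid-based
criterion well defined. Trees export as Newick.

## Decoding

Multivariate decoding uses causal 100 ms windows (10 bins of 10 ms) ending
at each decoding timepoint, every 50 ms from -1 to +1 s around movement
onset (41 timepoints), flattened channel-major. Classes are balanced by
undersampling when the max/min class-count ratio exceeds 1.2. The
classifier is L1-regularized logistic regression (glmnet) with the inverse
regularization strength C = 0.1 mapped to lambda = 1/(C n); multi-class
problems use one-vs-rest with argmax of decision values (ties to the
earlier class). Evaluation is 5-fold stratified cross-validation with one
fold assignment shared across training times; features are standardized
with training-fold statistics only, which is mandatory for L1 stability
and avoids leakage. Both accuracy and macro one-vs-rest AUC are reported
over the full train x test temporal-generalization matrix; chance is 1/k.
Encoding-decoding coupling interpolates the EoA series to the decoding time
axis with a natural cubic spline, zeroing points outside the encoding
range, and reports a Pearson correlation.

## Kinematics

Sensor speed is the Euclidean norm of central-difference velocities.
Movement bounds are found per cue by locating the first post-cue local
maximum above a noise floor (5x the median absolute speed of the trace)
and tracing backward/forward to the last/first crossing of a threshold
fraction of the peak speed. The threshold fraction defaults to 0.1 because
the empirically determined per-participant value used with real recordings
is not recoverable; it is configurable, and a deterministic rule replaces
manual verification. Trials are excluded (flagged, never dropped — they
remain usable for decoding) under two pooled 4-SD rules: baseline-window
hand speed (before -250 ms or after +750 ms around onset) above the pooled
mean + 4 SD, and the magnitude of the hand-wrist speed difference inside
(-250, +750) ms above its pooled mean + 4 SD; with zero pooled SD the
strict inequality excludes nothing. Rest segments for self-paced sessions
are 500 ms windows in which the max-over-sensors speed stays below its 1st
percentile over the recording, at least 1 s from any movement and 0.5 s
from each other, selected greedily left to right.

# The synthetic-data generator

The generator is the package's study design: its defaults define the
conditions under which the validation suite runs.

* **Noise.** Per-channel 1/f ("pink") Gaussian noise with spectral
  exponent 1 and 20 uV RMS, plus a common-mode pink component at half that
  amplitude (removed by CAR). Synthesis is in the frequency domain
  (single-precision, matching acquisition data width), with one complex
  spectrum per channel pair — the real and imaginary parts of the inverse
  FFT are two independent channels. The spectral slope of the output
  matches the requested exponent within 0.1 on a binned log-log
  periodogram fit (tested at exponents 1 and 1.5).
* **Footprints.** A movement's cortical territory is an isotropic Gaussian
  weight $w(d) = \exp(-d^2/2s^2)$ in grid-cell units. During each matching
  trial a band-limited (80-200 Hz) noise carrier is amplitude-modulated by
  $w$ times a temporal envelope: rising over 20 ms starting `lead_s`
  (default 0.25 s) before movement onset, sustained to offset, decaying
  over 100 ms. The carrier gain is calibrated against the *measurement
  operator* — the DPSS taper transfer functions, the 10 Hz band grid, and
  the movement-window share of the 1/f reference — so that the measured
  dB at the footprint center equals `amplitude_db` within sampling error
  (verified to +-0.5 dB over 40 trials). The ground-truth mask of a
  footprint is its half-maximum contour: cells whose planted dB is at
  least half the center amplitude.
* **Schedules.** Gesture schedules alternate away/back transitions from
  the closed-hand baseline with balanced random away-gestures and the
  task's 1-1.5 s uniform audio-to-visual cue delay. Reaction time,
  movement duration and inter-trial gap are generator parameters
  (desk-scale defaults 0.15 s, 0.35 s, 0.6 s); the real task's feedback
  period is not modelled beyond the gap. Joint schedules are self-paced
  blocks per effector with quiet gaps.
* **Kinematics.** Minimum-jerk displacement profiles (peak speed exactly
  at the movement midpoint) on the moving sensors, with optional slow
  (0.25 s moving-average) sensor noise. Displacements persist after offset,
  as posture changes do.
* **Nested hierarchies.** `make_nested_footprints` shares a center and
  grows the spatial scale geometrically (defaults: base 0.6 cells, growth
  1.6 on the 16 x 16 validation grid). These values were fixed by two
  design requirements stated up front: the *detected* extent of the
  largest footprint must stay inside the array (a mask clipped by the
  boundary cannot test containment), and the ideal noiseless dB maps must
  place the three distal effectors in their own Ward clade, which holds
  for growth well above ~1.5 and fails below it because the
  forearm-elbow distance then drops under the distal-group merge cost.

What the generator does *not* emulate: spatially correlated local noise
(only common-mode correlation is modelled), trial-to-trial amplitude
variability of the bursts, line noise and movement artifacts, electrode
drift, and any biophysical forward model. Passing tests therefore show the
*procedures* behave as specified on data satisfying their assumptions, not
that real micro-ECoG recordings will match.

# Validation design and problem sizes

The validation suite (and the acceptance script) uses desk-scale problem
sizes chosen once: a 16 x 16 grid at 500 Hz sampling (Nyquist-safe for the
200 Hz band edge) for the inference suites, an 8 x 8 grid for the decoding
suite, 200 permutations per test at alpha = 0.025 per direction, and
non-overlapping analysis windows inside movement/baseline epochs (the 90 %
overlap default applies to sliding spectrograms; inside a fixed epoch,
overlapping windows change the variance of the mean only marginally).

* **Error control.** 1000 independent global-null sessions (40 trials
  each): the lower 95 % binomial bound of the per-direction family-wise
  false-positive rate must not exceed 0.025.
* **Recovery.** A planted 3 dB, 3-cell footprint over 40 trials is
  compared to its half-max mask by Dice coefficient over 50 seeded runs,
  and EoA is checked for monotone growth over a planted scale sweep
  {1, 2, 4, 8} cells. A caveat discovered by this suite and worth stating
  plainly: at these trial counts the max-TFCE procedure reliably detects
  planted modulation well below the 1.5 dB half-max contour, so the
  recovered mask is a systematic superset of the half-max mask and the
  Dice comparison against the half-max truth saturates well under 0.7. The
  recovered *ordering* and growth of extents is unaffected, which is what
  the overlap and nesting analyses rely on.
* **Nesting.** Nested footprints (digits through shoulder) must reproduce
  strict mask containment and the distal-clade dendrogram in >= 95 % of
  runs; the boundary noise of tiny distal masks makes strict containment
  the harder of the two.
* **Decoding.** Disjoint planted class patterns must decode at >= 0.9
  diagonal accuracy in the movement epoch; shuffled labels must sit within
  3 SE of chance; corrupting future time bins must leave earlier features
  bit-identical (causality).
* **Timing.** With a high-SNR footprint leading movement onset by 0.25 s,
  the first significant bin of the EoA timecourse (20 ms bins, map-wide
  FWER) must fall within 2 bins of -0.25 s.
* **Gradients.** Ten-participant cohorts with a planted 0.1 dB/mm lateral
  gradient (noise SD 1 dB, 200 channels): the pooled Fisher-z CI must
  exclude zero and BH-FDR across the three axes must flag only the planted
  axis, each in >= 90 % of runs.

# Numerical choices and degenerate inputs

* TFCE thresholds start at `dh` with `>= h` inclusion; the brute-force
  oracle fixes the discretization semantics exactly.
* The pooled variance in signed R^2 uses the population convention so the
  balanced separated case attains 1; zero pooled variance returns 0.
* Permutations draw one seeded shuffle per iteration, evaluated on both
  directions; per-channel p-values are floored at 1/(n_perm + 1).
* Dice of two empty masks is defined as 0 (with a message).
* MDS converges on stress change < 1e-9 with at most 500 iterations and 8
  restarts; realizable configurations reach stress < 1e-6.
* `hclust`'s deterministic input-order tie rule is documented behavior for
  equidistant merges; duplicated items merge at height 0.
* Excluded (high-impedance) channels are zero-imputed, carry 0 dB, NA
  p-values, and never enter statistics.
* Fisher pooling rejects |r| = 1; zero across-participant variance flags
  the t-test as degenerate instead of dividing by zero.
* Files round-trip exactly: floats are written with 17 significant digits.

# Known limitations

* The generator's noise is spatially independent across channels (plus a
  common-mode term); spatially correlated noise would raise the TFCE null
  maxima and make inference more conservative than the validation suite
  suggests.
* The paper-scale array (33 x 31, 1024 contacts) is fully supported by the
  geometry and analysis code, but the validation suites run at 16 x 16 to
  keep runtimes desk-scale; statistical thresholds scale with channel
  count, so absolute sensitivities differ on the full array.
* The kinematic onset detector replaces the manual verification step used
  with real recordings by deterministic rules plus an override table; the
  empirical velocity threshold is a calibration choice, not a reproduced
  value.
* Reported per-participant quantities from patient recordings (stress
  values, decoding accuracies, onset latencies) are not reproducible
  without the original data and are out of scope for the validation suite.
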