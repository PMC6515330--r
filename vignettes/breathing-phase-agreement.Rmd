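---
title: "Detecting breathing phases and measuring agreement in lung-sound recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting breathing phases and measuring agreement in lung-sound recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungphase)
```

## The problem

A lung-sound recording from chest auscultation is a 10–15 s mono waveform,
typically sampled at 44.1 kHz. Clinicians and algorithms alike segment it
into *breathing phases*: inspiration and expiration events, each a time span
with an onset and an end. `lungphase` models a phase event as a half-open
interval `[start, end)` with a class label and, for detector output, a
confidence in `[0, 1]`. The half-open convention makes abutting phases
measure-disjoint, which matters because the post-processing step below
deliberately makes neighbouring boxes touch.

Two questions drive the package design. First, how do we turn audio into the
representation a detector consumes and clean up what a detector emits?
Second — the statistically interesting one — how do we quantify agreement
between two sets of interval annotations, whether annotator-vs-annotator or
annotator-vs-algorithm, when the "ratings" are functions of continuous time
rather than a fixed list of items?

## Spectrogram preprocessing

`compute_spectrogram()` computes a magnitude STFT with 4096-sample segments
overlapping by 3200 samples (hop 896 samples ≈ 20.3 ms at 44.1 kHz), Hann
taper, no padding — the first frame starts at the first sample, so a signal
of `N` samples yields exactly `floor((N − 4096)/896) + 1` frames. Normal
lung sounds carry little energy above 2 kHz, so rows whose bin centre
frequency is ≥ 2000 Hz are dropped; with a 4096-point transform at 44.1 kHz
the bin spacing is 10.77 Hz and 186 rows remain. A 10 s recording maps to a
186 × 488 image, a 15 s one to 186 × 734.

Numerical choices the transform itself does not fix:

* **Window**: Hann, the standard audio-spectrogram default.
* **Crop rule**: "below 2000 Hz" is read strictly (`bin centre < 2000`).
* **Magnitude scale**: dB relative to the per-file maximum, clipped at
  −80 dB (`log_floor_db`). A bounded log scale is required for a stable
  8-bit image export; the per-file reference makes the representation
  invariant to recording gain.
* **PNG export**: min–max scaled to 8-bit grey, replicated into three
  identical channels (the convention for feeding image-pretrained
  detectors), low frequencies at the bottom. A spectrogram with zero
  dynamic range maps to 0 everywhere.
* **Pixel ↔ time**: columns are 1-based (R convention); column `c` is
  centred at `((c−1)·hop + 2048)/44100` s. `time_to_column()` rounds to the
  nearest column and clamps, so detector pixel boxes convert losslessly to
  time spans and back.

## Detector contract and the baseline

Any detector — in particular a learned object detector over spectrogram
images — integrates with the pipeline by returning an annotation tibble
whose rows all carry confidences. Training such a model is out of scope
here; instead `detect_phases()` provides a deliberately simple baseline so
the whole chain is exercisable: band-pass 100–1500 Hz, a 150 ms smoothed
energy envelope, hysteresis thresholding (enter at 15% of the file's peak
envelope, extend down to 8%, minimum 0.25 s), and alternation labelling in
which the louder parity of the candidate sequence is called inspiration —
reflecting that chest-wall expiration is quieter and can be nearly silent.
Its confidence is the candidate's mean envelope normalised by the file's
maximum envelope.

That confidence is an *energy ratio*, not a calibrated probability: a real
but quiet expiration scores around its relative loudness (≈ 0.33 at the
synthetic default gain), well below the 0.5 pruning threshold appropriate
for a calibrated detector. The pipeline examples and end-to-end tests
therefore run the baseline with a 0.25 confidence threshold — the baseline's
documented operating point — while `postprocess_config()` keeps the 0.5
default that a probability-scored detector should be pruned at.

## Post-processing scored detections

Three assumptions, applied per recording and source in a fixed order:

1. **Prune** (`prune_low_confidence`): proposals with confidence *strictly
   below* the threshold are noise. "Below" is read literally: a box at
   exactly 0.50 survives.
2. **Suppress duplicates** (`remove_duplicates`): same-class boxes
   overlapping by more than 0.5 are multiple detections of one phase; only
   the highest-confidence one is kept. Overlap is measured by Jaccard — the
   same index the box-agreement statistic already uses — with
   intersection-over-shorter-box available as a config switch
   (`overlap_measure = "min_fraction"`), since a fraction-of-the-smaller
   reading is also defensible. Suppression is greedy in descending
   confidence (ties: earlier start), each kept box silencing later boxes
   above the threshold against it — the interval analogue of non-maximum
   suppression. Cross-class overlap is legitimate adjacency, never
   duplication.
3. **Shrink** (`shrink_overlaps`): small residual overlaps between
   successive phases (typically under 10% after suppression) are boundary
   errors; both boxes give up half the overlap so they abut. The sweep runs
   left to right over boxes sorted by start (ties: earlier end), which makes
   the result deterministic; because residual overlaps are small, the order
   has no practical effect. A shrink that would invert a box (half the
   overlap exceeding a box's length) indicates duplicate-level overlap that
   should not have reached this stage and is an error naming the pair.

The chain is idempotent, never overlaps in its output, and its stage counts
reconcile (`input = pruned + suppressed + output`); these are tested
properties, over detector-like random geometry (jittered true boxes plus
near-duplicates plus low-confidence spurious proposals).

## Box-level agreement

Two boxes agree when they are of the same class and their Jaccard index
(intersection length over union length) exceeds 0.5. Matching is one-to-one
within each recording and class, greedy in descending Jaccard with
deterministic tie-breaks. For non-overlapping sides — annotators and
post-processed detectors — a box can have at most one partner above 0.5 (a
box sharing more than half its union with two disjoint boxes is
geometrically impossible), so greedy matching provably coincides with
exhaustive optimal matching; the suite verifies this against a brute-force
matcher on 1000 random instances.

Percentage agreement needs a denominator, and with two interchangeable
sources an asymmetric one would be arbitrary. The default is the *mean box
count* of the two sources (`100 · matched / ((n_a + n_b)/2)`), which reduces
to the intuitive fraction when the counts are equal; reference-count and
max-count denominators are exposed as options. Counts are pooled over the
corpus by default; per-file averaging is available (`by_file = TRUE`). Two
sources with no boxes at all agree at 100% by convention.

## Continuous-time agreement

Let `A` be the region (union of spans) annotated by the first source and
`B` by the second, within a recording of length `T`. The package measures,
by exact interval sweep with no time discretisation:

* `TP = |A ∩ B|`, `FP = |A − B|`, `TN = |¬A ∩ ¬B|`, `FN = |¬A − ¬B| = |B − A|`,

which always sum to `T`. Note the orientation: `A` is the human reference,
so time only the *human* marked counts as a false positive. This is the
reverse of the usual screening convention; it is implemented as stated
because the package's sensitivity (`TP/(TP+FN)`) and specificity
(`TN/(TN+FP)`) definitions are tied to it, and a documented
`orientation = "conventional"` switch swaps the two sources' roles
(equivalently, swaps FP and FN) rather than leaving the discrepancy silent.
Ratios with a zero denominator are undefined (`NA`) and excluded from
corpus averages, never errors.

`corpus_summary()` reports unweighted per-file means for the inspiration,
expiration and both-phase scopes. The both-phase scope is computed on the
union region of the two classes (so an inspiration met by an expiration
still counts as breathing-time agreement); since averaging the two
per-class values is an equally plausible reading, that is reported alongside
as scope `"class_mean"`.

### Pseudo-kappa

Cohen's kappa corrects observed agreement for chance, but its usual
contingency-table form does not apply to time-continuous ratings. The
continuous analogue used here is

\[ \kappa = \frac{p_o - p_e}{1 - p_e} \]

with `p_o` the pooled, duration-weighted agreement `Σ(TP+TN)/ΣT` over the
corpus (per-file averaging being a reasonable alternative, the pooled form
follows from reading agreement as a fraction of total time). Chance
agreement `p_e` is estimated by destroying the correlation between
annotation and sound structure: each first-source annotation is re-paired
with a second-source annotation from a *different* recording — a uniform
random derangement of the pairing, so no file is compared with itself —
the pooled agreement recomputed, and the average taken over `n_shuffles`
repetitions (default 100; the number is a precision/cost trade-off, not a
substantive choice). When re-paired recordings differ in length both
regions are truncated to the shorter duration.

Two calibration facts anchor the statistic, and both are tested: identical
corpora give `p_o = 1` and hence exactly `κ = 1` whatever `p_e` is; and two
corpora generated independently from the same breathing profile (hence
matched marginal phase fractions) give `κ ≈ 0`. Because breathing occupies
most of a recording, `p_e` is large (often > 0.85) and kappa is a far
stricter measure than raw agreement — that is its point.

Confidence intervals are non-parametric bootstrap percentile intervals:
recordings are resampled with replacement `n_bootstrap` times (default
1000), the full statistic — including its own chance-agreement estimate —
recomputed on each resample, and the 2.5/97.5 percentiles reported. The
implementation precomputes the `n × n` cross-pairing agreement table once,
so shuffles and bootstrap replicates are table lookups and the defaults are
cheap even for hundreds of files. A degenerate corpus with `p_e = 1` leaves
kappa undefined (flagged, not raised).

Interpretation labels follow the conventional scale — slight, fair,
moderate, substantial (0.61–0.80), almost perfect (0.81–1.0) — with bins
half-open on the left so the printed boundaries 0.20/0.40/0.60/0.80 fall in
the lower category; 0 and below is "no agreement".

## What the synthetic generator does and does not emulate

`generate_schedule()` + `synthesize_audio()` produce recordings that mimic
the structural features the pipeline depends on: alternating
inspiration/expiration separated by pauses (default 15 breaths/min, I:E
ratio 1:1.5, 15% of the cycle silent, Gaussian cycle jitter of 0.1 s),
band-limited (100–1200 Hz, under the 2 kHz crop) noise-like sound,
inspiration louder than expiration (default amplitude ratio 0.4, with a
`silent_expiration_profile()` at 0.05 to stress-test detectors), a −40 dB
pause floor, and 15 s at 44.1 kHz. The defaults describe an adult breathing
deeper than normal with an open mouth — the recording protocol such
validation corpora use. `annotator_noise()` models imperfect annotators via
boundary jitter, missed phases, and spurious short phases inserted in
silent gaps.

The generator does *not* emulate adventitious sounds (crackles, wheezes),
heart-sound contamination, airflow physiology, sensor/handling noise, or
the within-subject correlation of real corpora. Passing tests on synthetic
corpora therefore validate the *statistical machinery and the pipeline
plumbing* — that the measures are computed exactly, calibrate correctly, and
degrade monotonically with annotation noise — not that the baseline detector
would perform comparably on clinical recordings.

All generation is deterministic given a seed; every file and simulated
annotator derives an independent substream from the corpus seed, so
corpora are reproducible across platforms.

## Problem sizes in the test suite

The suite checks the interval sweep against a 1 ms dense-grid oracle on 500
random annotation pairs; greedy matching against exhaustive matching on
1000 instances with up to 6 boxes per side; post-processing properties on
200 detector-like box sets; kappa calibration on 50-file corpora with 200
shuffles; and monotone degradation of sensitivity and kappa over boundary
jitter σ ∈ {0, 0.1, 0.3, 0.6} s with 20-file corpora and 20 replicates per
σ. The end-to-end check runs the baseline detector on a 10-file seeded
synthetic corpus and requires exact inspiration-count recovery and ≥ 80%
both-phase box agreement. These sizes give stable Monte-Carlo behaviour
while keeping a full run in the minutes range on one CPU.

## Known limitations

* Kappa is defined for exactly two sources; no multi-annotator
  generalisation is attempted.
* The baseline detector's alternation labelling assumes reasonably regular
  cycles; pathological breathing patterns (apnoea, double inspirations)
  will confuse it — by design, it is a contract exerciser, not a clinical
  detector.
* Box matching above a 0.5 Jaccard threshold is only provably equivalent to
  optimal matching for non-overlapping sides; raw (un-post-processed)
  detector output should not be fed to `percent_agreement()` directly.
* TextGrid support covers interval tiers in both Praat text dialects with
  single-line labels; point tiers are ignored.
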