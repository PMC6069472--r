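---
title: "Dynamic facial representation for infant pain assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic facial representation for infant pain assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painface)
```

## The problem

Infants in neonatal intensive care undergo repeated painful procedures
(heel lancing, line placement) and cannot report pain; bedside scales such
as the Neonatal Infant Pain Scale (NIPS) rely on trained observers scoring
behavioural indicators at short intervals. Facial expression is the most
specific behavioural pain indicator, and the actions catalogued by the
Neonatal Facial Coding System — brow bulge, eye squeeze, vertical mouth
stretch, nasolabial furrow — are geometric and textural events that a
video pipeline can measure. `painface` implements such a pipeline: from
per-frame facial landmarks and grayscale frames to a subject-independent
pain / no-pain decision.

## The representation

Four feature streams are computed per video (one epoch of one subject):

1. **DG_DisFace** (528 values). Eleven deformation distances per frame —
   eyebrow–eye, upper–lower eyelid, eyebrow–mouth, eye–mouth on each side,
   nose–mouth, mouth width and height — each the Euclidean distance between
   the centroids of two configured landmark groups. Each of the 11 temporal
   signals is summarised by the 48-value descriptor scheme below:
   11 × 48 = 528.
2. **DG_DisPose** (384 values). Eight head-pose distances per frame, from
   the left/right face boundary to the brow, eye, nose and mouth centroids
   on that side. Lateral head shaking — a common pain behaviour — shortens
   one side and lengthens the other; no 3-D pose angles are estimated.
   8 × 48 = 384.
3. **DA_Gradient** (1488 values). Thirty-one 32 × 32 patches (regions
   around points, RAPs) ride on landmarks in the wrinkle-prone regions;
   the per-frame feature is the patch mean of the 3 × 3 Sobel gradient
   magnitude. 31 signals × 48 = 1488.
4. **DA_LBP-TOP** (5487 values). For each RAP volume (the patch following
   its landmark across frames), Local Binary Patterns are coded on the XY,
   XT and YT plane families with 8 neighbours at radius 1 and accumulated
   into 59-bin uniform-2 histograms: 3 × 59 = 177 per patch,
   31 × 177 = 5487 per video.

### Temporal descriptors

Every frame-level signal `x` is smoothed to `s` by a first-order
Butterworth low-pass filter with a 1 Hz cutoff, and differentiated twice
(central differences scaled by the sampling rate) to a speed signal `v`
and an acceleration signal `a`. From each of `s`, `v`, `a`, sixteen
parameters are extracted — state (max, min, mean, median), variability
(range, SD, IQR, inter-decile range, median absolute deviation), peak
(time of first maximum, s), duration (time above the mean and above the
mean–minimum midpoint, s), segments (number of maximal runs above those
thresholds), and area (AREA, the rectangle-rule integral of the signal
above its minimum, and AREA/(max − min)) — 16 × 3 = 48 values per signal.

Conventions the source description leaves open are fixed (and tested) as:
zero-phase forward–backward filtering, so peak-time descriptors inherit no
phase lag (the effective magnitude response is the squared first-order
response); strict `>` in the threshold tests; first occurrence for the
argmax; linear-interpolation quantiles; the raw (unscaled) MAD; durations
in seconds and segments as counts; AREA/(max − min) defined as 0 for a
flat signal. The zero-phase pass is applied with steady-state (DC) initial
conditions and odd edge extension so that a constant signal is reproduced
exactly; filter coefficients come from `signal::butter()`. Smoothing
requires a sampling rate above twice the cutoff (the generator default is
30 Hz).

### Appearance conventions

LBP bits are set when a neighbour is ≥ the centre (tie → 1); the
neighbour ring is traversed counter-clockwise from the positive first-axis
direction; codes with at most two circular transitions map to their own
histogram bin (58 of them, in ascending code order) and all others to a
shared 59th bin. Plane histograms are L1-normalised by default (the
pre-normalisation mass equals the number of coded pixels; a flag disables
it). Patches are extracted around the rounded landmark position with edge
replication at image borders. The coding compares gray levels only, so the
descriptor is invariant under gray-level shifts; the gradient stream is
not, but is invariant under additive constants by construction of the
derivative kernels.

The 31 RAP landmark indices (10 brow, 8 eye corner/lid, 4 nose, 9 mouth)
are configuration, not algorithm: any 31 indices keep the printed
dimensions. Right-side patches are listed as mirror counterparts of the
left-side ones so hemiface vectors align elementwise across sides.

## Embedding and classification

Each stream is reduced by Supervised Locality Preserving Projections:
samples are standardized, pre-projected by PCA retaining 98% of variance
(keeping the generalized problem nonsingular), and connected by a
within-class k-nearest-neighbour graph (k = 5) with heat-kernel weights
`exp(-d²/t)`, `t` set to the mean squared pairwise distance. The
projection solves `X L Xᵀ a = λ X D Xᵀ a` and keeps the `d_out`
smallest-eigenvalue directions (default 30, capped at the achievable
rank). These four values are free parameters of the method — the printed
feature dimensions do not constrain them — and are exposed as
configuration keys.

Per stream, a support vector machine with a radial-basis kernel (width
`1/d_out`, unit cost; both overridable) is trained on the embedded
vectors. The signed decision value gives the label (positive = pain) and
its magnitude the confidence. Streams are fused by majority voting: the
label with more than half the votes wins; a tie (even voter counts only)
goes to the single most confident voter. For ROC analysis a fused score
sums ±confidence over voters — an artifact convention, monotone in the
vote margin, since the voting rule itself outputs only a label.

Evaluation is leave-one-subject-out: one fold per subject, the held-out
subject never in training, accuracy pooled over instances (rather than
averaged over folds — the alternative would weight small subjects up), and
AUC computed from the fused scores as the Mann–Whitney statistic with
half-credit ties, which equals the trapezoidal area. Folds whose training
labels collapse to one class are skipped with a warning and reported.

## Ground truth

NIPS scores five binary indicators plus cry (0–2), totalling 0–7; totals
≥ 3 are labelled pain, and severity groups are none (0–2), moderate (3–4),
severe (> 4). Procedure videos segment into seven half-open epochs: up to
five minutes of baseline (T0), the procedure (T1, duration from the
annotation), and five one-minute recovery windows (T2–T6), truncated and
flagged at the video end. Seconds map to frames by
`floor(start·fs) … floor(end·fs) − 1`. One NIPS record per epoch is
assumed.

## The synthetic cohort generator

No public infant pain video corpus exists, so the package ships a
generator that emulates the study conditions: by default 12 subjects × 4
epochs (two pain, two baseline per subject), 60 frames at 30 Hz on a
256 × 256 canvas, gender balanced, gestational ages normal (mean 36.4,
SD 2.7 weeks, truncated to 30.4–40.6) and races in proportions
0.5/0.37/0.13 — matching a small NICU cohort's composition. Pain epochs
superimpose, on a fixed mirror-symmetric neutral template, a raised-cosine
envelope of: brow lowering (6 px), eye squeeze (4 px), vertical mouth
opening (10 px), 2 Hz lateral boundary oscillation (6 px), and oriented
sinusoidal gratings (contrast 40 gray levels) in the glabellar,
nasal-root and nasolabial regions; all magnitudes are configurable, and
1 px Gaussian landmark jitter is always present. Noise is drawn before
the deformation is applied, so a pain epoch and a neutral epoch generated
from the same seed form a matched pair. NIPS totals are drawn from 3–7
for pain epochs and 0–2 for baselines, consistent with the dynamics.

Rendered frames are schematic: a shaded facial ellipse, smooth per-subject
skin texture, and dark blobs riding on the landmarks. The generator does
**not** emulate photorealistic appearance, occlusion, illumination change,
camera motion, landmark-tracking failure, or inter-subject facial
morphology. Passing tests therefore demonstrate that the pipeline
recovers controlled geometric/textural pain signatures end-to-end — not
that it attains any particular accuracy on clinical recordings.

A consequence worth stating: with all effect magnitudes at zero the
generated classes are exchangeable, and the pooled leave-one-subject-out
AUC sits at chance only under a null that respects the balanced
per-subject label layout. Unconstrained per-instance label shuffling
biases pooled cross-validated AUC well below 0.5 (the familiar
fold-imbalance pessimism), which is a property of pooled CV scores, not of
this implementation; the test suite uses the balanced null.

## Problem sizes used by the test suite

The suite exercises: oracle equivalence of LBP-TOP against a naive
per-pixel recoder on volumes up to 8 × 8 × 8; the 16-descriptor extractor
against a per-definition oracle on 100 random signals; SLPP eigenpairs
against a dense generalized eigensolver on 10 × 5 toys (tolerance 1e-8);
majority voting against exhaustive enumeration; a full four-stream cohort
run (12 subjects × 4 epochs, 60-frame videos) for end-to-end recovery;
20 zero-effect cohorts for the null; and 4 × 10 cohorts for effect-size
monotonicity, the last three on the geometry streams. These sizes were
chosen as the smallest at which each property is meaningfully tested.

## Known limitations

* Landmarks are an input: no face detection or landmark fitting is
  provided, and landmark noise propagates into every stream.
* The 68-point ordering is a convention carried entirely by the mapping
  configuration; data using another ordering need a new mapping, not new
  code.
* Whether mouth width/height follow the inner or outer lip contour is a
  configuration choice (default inner).
* The SVM confidence is the raw decision magnitude, not a calibrated
  probability; fused scores are comparable within one evaluation only.
* Descriptor blocks are fixed; no feature selection or weighting is
  performed beyond the SLPP embedding.
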