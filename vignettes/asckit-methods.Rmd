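---
title: "Methods: dual-pathway evaluation of the aortic-stenosis continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-pathway evaluation of the aortic-stenosis continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Aortic stenosis (AS) is staged on a five-level ladder — normal, aortic-valve
(AV) sclerosis, mild, moderate, severe — from three Doppler-derived
parameters: the peak transvalvular jet velocity Vmax (m/s), the mean
pressure gradient mPG (mmHg), and the continuity-equation valve area AVA
(cm²), with calcification splitting the sub-2 m/s band into normal versus
sclerosis. The full work-up needs continuous-wave (CW) Doppler across the
valve, pulsed-wave (PW) Doppler in the left ventricular outflow tract
(LVOT), and an LVOT diameter from the parasternal long-axis (PLAX) view —
acquisitions that demand equipment and expertise.

`asckit` implements, at desk scale, a dual-pathway automated evaluation:

1. a **continuum pathway** that scores plain PLAX/PSAX grey-scale videos
   with a small (2+1)D convolutional network trained on ordered severity
   labels plus auxiliary regression of Vmax/mPG/AVA, producing a 0–100
   index (DLi-ASc) with stage cutoffs derived from score distributions; and
2. a **conventional pathway** that segments spectral-Doppler envelopes and
   PLAX anatomy, quantifies Vmax/mPG/VTI and the LVOT diameter, applies the
   continuity equation, and stages the result by the guideline table, with
   discordance and low-flow–low-gradient (LFLG) detection and a
   predictive-entropy gate that halts unreliable automatic measurement.

Because clinical studies cannot ship with the package, a seeded phantom
generator produces echo-like videos, label maps, spectrograms and cohort
tables with closed-form ground truth; every stage of both pathways is
trained and validated on those phantoms.

## Staging engine semantics

The guideline table prints bands as Vmax 2–2.9 / 3–3.9 / ≥ 4 m/s, mPG
< 20 / 20–39 / ≥ 40 mmHg, AVA > 1.5 / 1–1.5 / ≤ 1 cm². Three engine
decisions were genuinely open:

* **Gap closure.** The printed gaps (2.95 m/s, 39.5 mmHg) are closed as
  half-open intervals `[2,3)`, `[3,4)`, `[20,40)`; severe bounds are
  inclusive exactly as printed (≥ 4, ≥ 40, ≤ 1).
* **Compatible-stage sets.** mPG and AVA have no band of their own below
  mild (they are not measured in normal valves), so each parameter maps to
  a *set* of compatible stages: e.g. mPG < 20 is compatible with
  {normal, sclerosis, mild}. The concordant stage is the most severe member
  of a non-empty intersection across available parameters; Vmax < 2 m/s
  resolves normal versus sclerosis by the calcification flag (missing flag:
  normal band plus an `insufficient_data` flag, never a silent guess).
  This reproduces the clinical reading that a normal study with mPG
  8 mmHg is *normal*, not "mild".
* **No forced stage under discordance.** When the intersection is empty the
  engine reports the most severe single-parameter band only as a ceiling,
  with `concordant = FALSE` and the classical flags (`mild_to_moderate`,
  `moderate_to_severe`, `lflg_severe_pattern`); consumers must check
  `concordant`. This mirrors the exclusion of discordant labels from
  training data rather than adjudicating them.

## Phantom generator

The generator is the package's study condition, fixed once:

* **Ejection profile.** `v(t) = Vmax sin(pi t / T_ej)` per cycle. The
  half-sine yields closed forms used as oracles everywhere:
  `VTI = (2/pi) Vmax T_ej x 100` cm and `mPG = 2 Vmax²` mmHg (the time
  average of the instantaneous simplified-Bernoulli gradient `4 v²`). The
  `2 Vmax²` identity is a generator convention, not physiology.
* **Concordance by construction.** Vmax is uniform within its stage band,
  but the band is trimmed where the half-sine identity would put mPG in a
  different band (below 3.17 m/s the mean gradient drops under 20 mmHg;
  below 4.47 m/s under 40 mmHg): moderate samples on [3.19, 3.88] and
  severe on [4.49, 5.5] m/s. The LVOT VTI is then *solved* so the
  continuity-equation AVA lands inside the stage's AVA band. A small
  interior margin (~1–5%) from every band edge absorbs the measurement
  quantisation of the desk-scale pipeline (velocity axis 0.02 m/s per row;
  LVOT diameter one pixel ≈ 2.5%), so noiseless phantoms always stage
  concordantly. Remaining physiology: heart rate U[60, 90] bpm, ejection
  time U[0.27, 0.33] s, LVOT diameter U[1.8, 2.4] cm.
* **Videos.** Stylised PLAX (chambers, septum, posterior wall, aorta,
  mitral valve, two AV leaflets) and PSAX at valve level (root ring, three
  leaflets) over one cardiac cycle, field of view 6.4 cm (0.05 cm/px at the
  128-px reference resolution, rescaled to keep the field constant).
  Severity is encoded observably: the systolic leaflet-opening excursion
  decreases continuously with a severity index (stage ordinal plus the
  within-band position of Vmax, keeping per-ordinal ranges disjoint so the
  ordinal ordering is strict), and calcified leaflets render brighter and
  thicker. Speckle is multiplicative-plus-additive Gaussian noise scaled by
  `noise_level`; the cohort default is 0.2, a level at which anatomy is
  clearly visible but per-pixel contrast is noticeably degraded.
* **Spectrograms.** 0.02 m/s per row, 256 columns/s, jet filled below the
  baseline; the AV signal uses CW calibration and the LVOT signal PW, with
  the LVOT peak velocity implied by the solved LVOT VTI.

What the phantoms do *not* emulate: realistic speckle statistics and
attenuation, probe geometry, arrhythmia, valve pathology other than AS, and
view-classification errors (views arrive tagged). Passing tests therefore
demonstrate that the algorithms are correct and trainable on data whose
generative truth is known — not clinical performance.

## Continuum pathway

Stages map to ordered targets y ∈ {0, 0.25, 0.5, 0.75, 1}. The scorer is
trained by minimising a negative Bernoulli log-likelihood with soft targets,
`-(y log p + (1-y) log(1-p))` with p clamped to `[1e-7, 1-1e-7]` — for
fractional y this is soft-target cross-entropy, minimised at `p = y` — plus
`lambda` times the summed squared error of three auxiliary heads predicting
Vmax, mPG and AVA on the z-scored scale (z-normalisation by training-set
mean/sd; missing auxiliary labels are masked out of their terms). `lambda`
defaults to 1. DLi-ASc is 100 × the continuum-head probability.

The desk-scale backbone has four factorised (2+1)D blocks — 3×3 stride-2
spatial convolution then a 3-tap temporal convolution, ReLU after each,
channels 8/16/24/32 — global average pooling, a sigmoid continuum head and
three linear auxiliary heads (~1.7×10⁴ parameters, 16 frames at 64×64
input). The training loop is Adam (lr 5×10⁻³, batch 8, up to 60 epochs,
early stopping on validation combined loss with patience 15), fully seeded:
identical inputs give identical trajectories. These optimiser settings were
fixed by capacity probing on small phantom sets; the cohort conditions (300
videos = 150 patients × PLAX+PSAX, noise 0.2) are the study conditions and
were fixed first.

Per-video scores aggregate per patient by averaging within each view type
and then averaging the available view-type means. Stage cutoffs are the
midpoints between mean scores of consecutive severity categories
(patient-level); the clinically derived reference values 24.6 / 45.4 /
53.7 / 69.7 ship as defaults, with classification inclusive at the
boundary. Saliency uses Grad-CAM; with a global-average-pooled linear head
the channel weights coincide with the head gradient, so the map is
`relu(sum_c w_c A_c)` on the last convolutional stage, max-normalised and
upsampled. Feature embeddings take the pooled penultimate vector into 2-D
with a seeded neighbour embedding (fuzzy 15-NN graph with locally adaptive
bandwidths, Euclidean metric, minimum embedding distance 0.1, spectral
initialisation, attraction/repulsion gradient descent); it is implemented
in-package because no R implementation of this family is available in the
tool-chain.

## Conventional pathway

Envelope segmentation has two interchangeable providers: a deterministic
isodata-threshold + connected-component oracle (components comparable to
the largest are kept — one per ejection cycle), and a small
fully-convolutional encoder–decoder (stride-2 conv, conv, 2× nearest
upsample, classifier conv; intensity plus normalised x/y coordinate input
channels) trained on phantom pairs. The velocity trace takes, per time
column, the furthest mask pixel from the baseline on the configured flow
side times the velocity calibration (binarisation at 0.5, no hysteresis).
Ejection windows are maximal runs above 15% of the global peak lasting
≥ 0.1 s, then expanded outwards to the surrounding zero crossings so the
sub-threshold tails of the profile are integrated; without the expansion
the trapezoidal VTI is biased ~1% low. Per window, Vmax is the maximum,
mPG the time-averaged `4 v²`, VTI the trapezoidal integral × 100; windows
aggregate by mean (Vmax also reported as the global maximum), configurable
to max.

PLAX segmentation uses the same encoder–decoder with nine anatomy classes
(or the truth label maps as an oracle provider). The LVOT diameter is
measured at the annulus: pixels of the LV class 4-adjacent to the aorta
class form the annulus line; the inner-edge to inner-edge extent
perpendicular to the outflow axis — taken as the LV-to-aorta centroid
direction, which is stable where the principal axis of a nearly isotropic
aorta region is not — converts by the pixel spacing, taking the median over
the three most-open frames (widest AV leaflet gap; ties to the earliest
frame). An `offset_cm` parameter slides the measurement plane into the
LVOT for protocols that measure below the annulus; the default measures at
the annulus. Automated calcification is a fixed brightness threshold
(0.68) on AV-labelled pixels, halfway between the rendered uncalcified
(0.55) and calcified (0.83) leaflet intensities.

## Uncertainty gating

Per-pixel predictive entropy (mean of `-sum p log p`, nats) decomposes over
Monte-Carlo dropout passes (default 8, dropout 0.25 on the hidden channels)
into aleatoric (mean per-pass entropy) and epistemic (entropy of the mean
map minus aleatoric — the mutual information, non-negative by Jensen)
parts. The measurement gate halts when predictive entropy reaches the
threshold (tie halts, conservatively); halted measurements propagate as
unavailable, never as numbers. The default threshold can be calibrated as
the 95th percentile of entropies on noise-free validation phantoms. The
gate applies to the conventional pathway only; the continuum score is
always produced. Gating is per study, the simplest policy consistent with
halting a measurement chain.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-7, 1-1e-7]` before the log; label-map
  probability stacks must sum to 1 within 1e-5.
* Empty envelope masks yield a flagged all-zero trace, which yields no
  ejection windows, which yields unavailable measurements — degenerate
  inputs degrade to "unavailable" rather than numbers throughout.
* All measurements are unavailable → stage `indeterminate` with an
  `insufficient_data` flag.
* Ties: mid-systolic frame selection and cutoff classification are
  inclusive/lowest-index as documented.
* Seeds: every stochastic step (cohort sampling, speckle, initialisation,
  shuffling, dropout, embedding) flows from an explicit integer seed, and
  RNG state is restored after use.

## Problem sizes used in the shipped tests

The recovery experiment trains on 300 videos (150 phantoms × 2 views,
16 frames, 64×64, noise 0.2) with a stratified held-out set of 60 videos;
segmenters train on 10–12 phantoms for a few hundred Adam steps; the
staging truth-table suite draws 10,000 random measurement tuples; the
end-to-end concordance suite runs 15 noiseless phantoms at the 128-px
measurement resolution. These sizes were chosen so the whole suite trains
every learnable component from scratch in minutes on a single CPU while
leaving the conclusions (severity recovery, oracle equivalence, perfect
noiseless staging) comfortably away from their thresholds.

## Known limitations

* The phantom appearance model is deliberately schematic; no claim is made
  that the trained desk-scale weights transfer to clinical images.
* The spectral envelope post-processing (column-maximum extraction,
  window expansion) is a reconstruction of a standard pipeline, not a
  validated clinical algorithm.
* mPG and Vmax derive from the same rendered jet, so the generator cannot
  produce genuinely discordant physiology (e.g. true LFLG severe AS);
  discordance handling is exercised through the staging engine's own unit
  suite instead.
* DICOM import is not provided; bundles use PNG/RDS arrays with JSON
  sidecars.
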