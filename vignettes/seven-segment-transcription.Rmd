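---
title: "Transcribing blood-pressure monitor displays from phone photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcribing blood-pressure monitor displays from phone photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automated oscillometric blood-pressure cuffs show systolic pressure (SBP),
diastolic pressure (DBP) and heart rate (HR) on a seven-segment LCD, and in
many screening programmes — antenatal hypertension screening in particular —
the reading is transcribed by hand into a record or an app. Manual
transcription is error-prone, and commodity OCR engines fail on
seven-segment digits because each glyph is a set of *disconnected* strokes
rather than a connected character. `bpocr` implements a dedicated pipeline:
a photograph of the monitor (nominally 640×480 px) goes through image
enhancement, contour-based LCD frame localization, frame normalization, and
a multi-digit convolutional recognizer, yielding a `(sbp, dbp, hr)` triple
in which any value that cannot be read is `NaN` rather than a guess.

Because the field image corpus this emulates is not publicly deposited, the
package ships a first-class synthetic generator that renders the same scene
structure with exact ground truth, and the whole pipeline is validated on
those synthetic scenes.

## Enhancement

Four deterministic stages (`enhance()`):

1. **Grayscale** — luminance combination `0.299 R + 0.587 G + 0.114 B`.
2. **Bilateral filter** — edge-preserving smoothing; each pixel is a
   normalized neighborhood average weighted by
   `exp(-d²/2σ_s²)·exp(-Δi²/2σ_r²)`. Defaults: diameter 9 px,
   `σ_r = σ_s = 75`. These are conventional values; the source pipeline
   does not publish its own.
3. **Gamma correction** — `O = (I/255)^γ·255` per pixel. Default `γ = 1.2`,
   fixed per run. The transform fixes 0 and 255 and is monotone, so
   binarization downstream is what actually matters; `γ` is exposed for
   unusually bright or dark corpora.
4. **Adaptive mean thresholding** — a pixel becomes foreground iff it is
   more than `C` below the arithmetic mean of its `block_size × block_size`
   neighborhood (inverse polarity: dark LCD strokes on a light display
   become foreground). Defaults `block_size = 31`, `C = 5`, chosen for the
   observed LCD scale (frames of roughly 140–300 px in a 640×480 image):
   the window must be larger than a stroke width (~10 px) and smaller than
   a frame, and `C` must exceed the background noise amplitude.

Numerical conventions, applied everywhere: intensities are integers in
`[0, 255]`; rounding is half-away-from-zero then clamping; windowed
operations replicate edge pixels. Binary images use `{0, 255}` with
foreground 255.

## Localization

The enhanced image is closed once with a 3×3 structuring element (the
thresholded frame borders have small gaps by construction), its 8-connected
components are extracted, and each component's tight bounding box is scored
by two attributes: the width/height **aspect ratio** and the **box-area
fraction** of the image. The BP frame is the largest box with aspect ratio
in `[0.7, 1.4]` and area fraction in `[2%, 60%]` — a roughly square frame
that is neither clutter nor the whole device. The HR frame is the largest
remaining box with aspect ratio in `[1.2, 3.0]` and area in `[0.3%, 15%]`
lying below the BP digit region; its horizontal extent is then snapped into
the BP frame's column span (`correct_hr_box()`), which encodes the physical
device: the HR window sits directly under the BP window and can never be
wider. The published pipeline tuned its thresholds on ~500 held-back field
images without reporting them; the intervals above span the observed frame
geometry (137×146 to 264×303 px) with margin and are config-exposed.

Two deliberate details:

* The size attribute is the bounding-**box** area `w·h`, not the component
  pixel count — a frame border is a thin hollow ring whose enclosed area,
  not stroke mass, is what discriminates it from clutter.
* Ties between equal-area candidates break by smallest `(y, x)` for
  determinism.

If no BP candidate passes the filter the image is recorded as unprocessed
and its reading is `NaN` — localization failure is a tracked outcome, not
an error.

## Normalization

The BP frame is cropped (half-open box convention), scaled bilinearly to a
180×160 canvas, trimmed by 4% of each dimension on every edge (removing the
residual frame border included in the box), split at half its height into
the systolic (top) and diastolic (bottom) values, and each half is scaled
to the recognizer input of **180 columns × 80 rows**. The HR frame follows
the same path on a single-height canvas so one recognizer serves all three
values. Every geometric resample is followed by re-binarization at the
intensity midpoint to keep the `{0, 255}` invariant. Two open choices were
fixed as follows: the 180×80 input is interpreted as width × height (three
digits are about twice as wide as tall), and trimming happens after
scaling so the trim counts are fractions of a known size.

## The recognizer

A reading is a sequence of three slots over `{0,…,9, BLANK}`, right-aligned
with leading blanks (`82 → (BLANK, 8, 2)`), because BP values are
magnitude-ordered: the hundreds digit is the costliest to get wrong, and a
fixed slot order lets each head specialize. `P(S|X)` factorizes over slots;
the model is a three-block convolutional network — 5×5 kernels with 32, 64
and 128 filters, each block followed by batch normalization, ReLU and 2×2
max-pooling — on the 180×80 binary frame, flattened (22×10×128 = 28 160
features) into three independent 11-way softmax heads. Training maximizes
`log P(S|X)` (summed per-head cross-entropy) with Adam (lr 1e-3, batch 32,
global-gradient-norm clipping at 5 for stable warm-up), a seeded 3:1
train/validation split, and the returned parameters are the checkpoint with
minimum validation loss. The forward/backward passes are implemented in
C++ (im2col + BLAS sgemm, single precision); all randomness flows through
R's RNG so `set.seed()` reproduces a fit exactly on the same BLAS.

At inference each head reports its argmax class and probability. The
sequence confidence is the product of the three slot confidences
(consistent with the factorized likelihood); a prediction is accepted iff
that product reaches a threshold `τ`, otherwise it decodes to `NaN`. The
default `τ = 0` reports everything — the gate exists to let deployments
trade coverage for accuracy, and the package only asserts the qualitative
property (coverage non-increasing in `τ`, accuracy over accepted items not
hurt by raising it).

`decode_sequence()` is the inverse of `encode_value()` on well-formed
sequences; an all-blank sequence or a blank after a digit decodes to `NaN`.

## The synthetic generator

`render_scene()` draws what the field photographs show: a flat light-gray
device body filling most of the canvas, a roughly square LCD frame holding
SBP over DBP, a wider-than-tall HR frame directly below, dark
seven-segment glyphs (disconnected strokes with corner gaps) right-aligned
in each window, a darker cluttered background, small in-plane rotation
(±5°, the parallax stand-in), and additive Gaussian pixel noise (sd 4).
Frame sizes and positions jitter between scenes inside the observed
137×146–264×303 px range. Readings are sampled uniformly: DBP on
`[34, 120]` mm Hg, SBP on `[dbp+10, 203]`, HR on `[40, 180]` bpm — the
annotated field range; uniformity is a stand-in for the unpublished cohort
distribution, not a claim about it.

`degrade()` applies one of six quality classes, with the default mixture
taken from the field-corpus proportions (740 blur : 314 dark : 3885
reflections : 375 far : 630 cropped : 1261 good, of 7205):

| label | transform | parameters (uniform draws) |
|---|---|---|
| `OK` | identity | — |
| `B` | Gaussian blur | σ ∈ [1.2, 2.8] px |
| `D` | global darkening | factor ∈ [0.25, 0.5] |
| `R` | additive elliptical glare | 1–3 patches, radius 25–70 px, peak 120–220 |
| `FAR` | downscale device into a sub-region | scale ∈ [0.35, 0.6] |
| `CROPPED` | shift so part of the LCD border leaves the frame | cut at border + 0–4 px |

Ground-truth boxes are transformed alongside and every drawn parameter is
recorded. What the generator does **not** emulate: perspective distortion
beyond in-plane rotation, specular glare structure, color LCDs, motion-blur
direction, or real household backgrounds. Passing tests on synthetic
scenes therefore demonstrate that the pipeline's logic is correct under
controlled degradations of the right kinds and magnitudes — not that field
performance would match the synthetic numbers.

## Experiments and evaluation

`run_experiment()` mirrors the two published training regimes on one
corpus: images are split 3:1 into train and test within each of the good
(`OK`) and poor (all other labels) strata; `"good_only"` trains on
good-quality frames alone, `"good_and_poor"` on all frames with a
stratified 3:1 train/validation split preserving the good/poor
proportions; both are evaluated on identical held-out sets. Training
frames are extracted by the package's *own* localization — images that
fail it drop out of training and count as unreadable at test time, so the
reported metrics include localization failures, and the per-group
extraction rates are reported separately (both denominators are visible).

Metrics (`evaluation_report()`): exact-value **classification accuracy**
(a reading is right only if every digit is right; `NaN` counts as wrong),
**MAE** in mm Hg over pairs where both values exist (exclusions counted
and reported), and **coverage** (share of readings with a non-`NaN`
prediction). Reports are stratified by each quality label, the binary
good/poor roll-up, and the pooled total; HR rows are flagged best-effort
since the recognizer is shared with BP and no reference numbers exist for
HR.

## Problem sizes and defaults

The packaged experiments use a 2 400-image corpus (≈ 5 000 training frames
for the good+poor regime once localization failures and the 3:1 test split
are taken out), 3 training epochs for the good+poor regime and 6 for the
much smaller good-only regime — enough for the validation loss to flatten
on this task, as the recorded history shows. A full two-regime run takes
roughly a quarter of an hour on one CPU core.

## Known limitations

* The rendering family is one device layout; other monitors need layout
  parameters (and retraining).
* `FAR` scenes defeat the area filter by design (the shrunken LCD competes
  with the device outline), which matches the field behavior of distant
  shots but means FAR recovery is poor.
* HR transcription reuses the BP recognizer and is unvalidated against any
  reference.
* Single-precision training is bit-reproducible only on the same BLAS
  build.
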