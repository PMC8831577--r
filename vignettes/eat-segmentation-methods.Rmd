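---
title: "Methods: automated EAT segmentation and quantification in calcium-score CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated EAT segmentation and quantification in calcium-score CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatseg)
```

## The measurement problem

Epicardial adipose tissue (EAT) is the fat enclosed by the pericardial
sac. Its volume and attenuation carry cardiovascular risk information,
and CT calcium score scans — low-dose, non-contrast, thick-slice
(≈2.5 mm) cardiac CT — are acquired at population scale, so an automated
EAT measurement on them is valuable. The catch is that these scans are
hard to read: no contrast agent, thick slices, and a pericardium that is
a thin, faint membrane. The standard manual protocol segments the region
*inside* the sac slice by slice and then thresholds the standard fat
window $[-190, -30]$ HU within it; `eatseg` automates exactly that
pipeline and evaluates the result with the field's standard agreement
statistics.

The package is organised as a chain of small, separately testable
stages:

1. **Volume I/O** — DICOM series in (HU after rescale, slices ordered
   inferior→superior), NIfTI binary masks in/out, manual heart extent.
2. **Preprocessing** — HU attention window to 8-bit; bisected look-ahead
   slab sequencing; physical-kernel median filtering.
3. **Segmentation** — a pluggable per-slice segmenter contract with a
   small trainable reference network and an oracle test double.
4. **Quantification** — fat-window thresholding inside the predicted
   sac; volumes in cm³ and mean HU.
5. **Evaluation** — Dice/IOU, per-slice analysis with quartile grouping,
   Bland–Altman, origin-constrained regression, percent error, paired t.
6. **Phantoms** — synthetic scans with analytic ground truth that make
   the whole chain verifiable without clinical data.

## HU attention window

Networks (and 8-bit image pipelines generally) quantise their input.
A full CT range of ~4000 HU crushed into 256 levels leaves the
pericardium — a few tens of HU of contrast — one or two grey levels
wide. The attention window applies the radiology display convention
first: a linear map of the window/level **350/40 HU** (i.e. HU −135 to
+215) onto 0..255, clamped outside, with round-half-up:

$$v_8 = \operatorname{round}\!\left(255 \cdot
\operatorname{clamp}\!\left(\frac{\mathrm{HU} - lo}{hi - lo}, 0, 1\right)\right).$$

Everything the sac borders on (blood ≈ +40, soft tissue ≈ +30, fat
≈ −100) lands inside the window, so the membrane's contrast survives
quantisation. The mapping is monotone; −135 → 0, +40 → 128, +215 → 255.

## Bisected look-ahead slab sequencing

The sac's cross-sectional area is unimodal along the body axis: it grows
from the heart bottom to the mid-heart and shrinks toward the top. The
slab plan (`bisect_plan()`) exploits this: the heart slices are split
into two halves; the lower half is presented bottom-to-middle with
look-ahead step $s = +1$, the upper half top-to-middle with $s = -1$.
Each target slice $k$ is stacked with its two upcoming slices
$(k+s, k+2s)$ into a 3-channel slab, so the network always sees the sac
*growing* — the same local geometry in training and inference, and real
anatomical context (rather than replicated padding) at the difficult
top/bottom slices. Design choices worth stating:

* **Odd slice counts.** "Two equal halves" is exact only for even $n$;
  the lower half takes $\lfloor n/2 \rfloor$ slices, the upper the
  remainder. The extra slice sits next to the middle where either
  direction is near-symmetric.
* **Midline crossing.** Look-ahead indices may cross the middle (slice
  $k+2s$ of the last lower-half target lies in the upper half). Those
  slices physically exist; discarding them would waste context.
  Replication clamping applies only at the extent borders, which the
  bisected plan reaches only for tiny extents (the sequential ablation
  plan reaches them at every top slice — that is the point of bisecting).
* **1-based indices.** Slice 1 is the most inferior slice; the heart
  extent is a 1-based inclusive `[bottom, top]` pair and remains a quick
  manual input, as in clinical practice.

## Median filtering with a physical kernel

Noise reduction mirrors the manual protocol: a median filter with a
**3 mm** box kernel. The kernel is specified physically and converted
per axis to the largest odd voxel count whose span does not exceed the
kernel: $n_{ax} = 2\lfloor k / (2 s_{ax})\rfloor + 1$. At the default
spacing (0.7, 0.7, 2.5 mm) this yields a 5×5×1 kernel — effectively
in-plane, which the function reports in its log message. Edges use
replicate padding. By default filtering is applied before fat
thresholding only; the network sees unfiltered windowed data. (Both
orderings are defensible; this one matches the manual protocol, where
the filter serves the threshold, and it is what `quantify_eat()` does.)
Mean EAT HU is computed on the filtered volume for consistency with the
mask derived from it.

## Training protocol and augmentation

The per-slice segmenter is trained with Adam (constant learning rate
1e-3), soft Dice loss
$1 - (2\sum p t + \varepsilon)/(\sum p + \sum t + \varepsilon)$
with $\varepsilon = 10^{-6}$, mini-batches of 20 slabs, at most 30
epochs, validation (slice-mean Dice of binarised predictions) at the end
of each epoch, and early stopping when the epoch-to-epoch change in
validation Dice falls below $10^{-5}$. Dice loss is used because the
sac interior is a small, size-varying fraction of each slice; it makes
the loss indifferent to class prevalence.

Augmentation has two tiers with exact accounting. First, every training
slab is duplicated once with a Gaussian blur whose σ is drawn uniformly
below 2 pixels (the mask is copied untouched) — this doubles the set
once, up front. Second, each epoch every item gets a fresh random
rotation (−5..+5°) and isotropic scale (0.9..1.1), applied identically
to all three channels (bilinear) and the mask (nearest neighbour, so it
stays binary) about the image centre, with out-of-frame pixels filled
with 0 (the 8-bit value of below-window HU). With $n$ labelled slices
and $e$ epochs the network therefore sees $2n$ distinct items and
$2n\cdot e$ total presentations — e.g. 1446 slices → 2892 after
duplication → 86,760 presentations over 30 epochs. Blur σ is drawn
per copy; rotation/scale per item per epoch.

## The segmenter contract and the reference network

Heavy pretrained segmentation backbones are deliberately *not* part of
this package: the pipeline treats the per-slice segmenter as a contract
(`predict_slice()`: slab in, binary mask of the target slice out).
Two implementations ship:

* `oracle_segmenter()` — a test double returning stored ground truth,
  which lets slab assembly, reassembly and quantification be verified
  independently of model quality.
* `unet_segmenter()` — a small two-level U-Net (3→8→pool→16→pool→32,
  then upsample+skip→16, upsample+skip→8, 1×1 sigmoid head; ≈15k
  parameters) implemented in RcppArmadillo with batched im2col+GEMM in
  single precision, trainable in CPU-minutes. The sigmoid head bias is
  initialised to −2 so the initial prediction matches the
  background-dominated prior — a standard stabilisation for Dice-loss
  training, without which early optimisation is slow. Probabilities are
  binarised at 0.5. All randomness (weight init, batch order,
  augmentation draws) is drawn on the R side under the training seed, so
  training logs are bit-reproducible.

Full-volume inference (`segment_volume()`) windows the volume, builds
the plan, predicts every in-extent slice exactly once and places each
mask back at its anatomical index; slices outside the extent are zero,
and the result is independent of the order plan entries are processed.

## Quantification

A voxel is EAT iff it lies inside the sac-interior mask and its
(filtered) HU lies in the **closed** interval $[-190, -30]$ — ties at
the bounds count as fat. Volumes are voxel count × voxel volume / 1000
(cm³), reported per scan and per axial slice (the per-slice vector sums
to the total). Mean HU over the EAT mask is the attenuation summary.

## Evaluation statistics

Dice $= 2|A\cap B|/(|A|+|B|)$ and IOU $= |A\cap B|/|A\cup B|$ are
computed per axial slice and over the whole volume; the identity
IOU $=$ Dice$/(2-$Dice$)$ is property-tested. When both masks are empty
the score is defined as 1 (empty slices agree perfectly); per-slice
values are reported so such slices can be excluded from summaries.
Slices can be grouped into four contiguous bottom-to-top quartile
regions (remainder slices go to the earliest groups) to localise where
errors concentrate. Volume agreement uses Bland–Altman differences
(automated − manual; bias, sd with the $n-1$ denominator, limits of
agreement bias ± 1.96 sd), a through-origin fit $y = mx$ with
$m = \sum x_i y_i / \sum x_i^2$ alongside the ordinary Pearson $r$ (p
from the t transform with $n-2$ df), signed percent error
$100(auto-manual)/manual$, and a two-sided paired t-test.

## The phantom model

Clinical cohorts for this task are private, so the package carries its
own study population: synthetic axial stacks with an elliptical
soft-tissue body (+30 HU), lateral lung fields (−800 HU), and a heart
whose sac-interior radius follows the unimodal profile
$r(z) = r_{max}\sqrt{1 - ((z - z_{mid})/h)^2}$. Inside the sac, EAT sits
as an annulus against a thin (+20 HU, 1.4 mm) pericardial wall with a
paracardial fat ring (−90 HU) outside it — fat on *both* sides of the
wall, so mask gating is actually exercised — and blood/soft tissue
(+40 HU) fills the rest. EAT voxels draw uniformly from
$[-180, -40]$ HU: strictly inside the fat window with a 10 HU guard band
so that at zero noise classification is exact by construction. All HU
are rounded to integers (scanners store integers; this also makes DICOM
round trips bit-exact), optional Gaussian noise is added, and cohorts
draw $r_{max}$, EAT fraction and noise sd per phantom from configured
ranges (defaults 10–16 mm, 0.15–0.35, 5–15 HU — realistic for low-dose
CT) reproducibly from a single seed.

Two constructional details matter for exactness:

* **Median stability.** The quantification path filters before
  thresholding, and a median filter can flip boundary voxels of a thin
  fat annulus. Noise-free phantoms are therefore made a fixed point of
  the 3 mm median filter: in-sac voxels whose filtered HU lands on the
  wrong side of the fat window are iteratively relabelled (with matching
  HU draws) until filtered and unfiltered classification agree with the
  truth mask. This converges in a few passes and is what makes "0%
  recovery error at zero noise" an exact statement rather than an
  approximate one.
* **Minimum annulus thickness.** The EAT annulus is at least 3 in-plane
  voxels thick regardless of the requested area fraction, the width at
  which a straight-boundary band survives a 5×5 median.

What the phantoms do **not** model: chambers, vessels, calcium lesions,
motion artifacts, anatomical shape variability, or the texture of real
fat. Passing tests on phantoms therefore demonstrate that the pipeline's
*mechanics* (sequencing, windowing, thresholding, accounting, statistics)
are correct and that the training harness can learn a sac-like geometry —
not that the reference network matches clinical-grade segmentation on
real scans, which is what the pluggable-backend slot is for.

## Problem sizes and numerical choices

The test-suite training harness uses a 28-phantom cohort at 64×64
in-plane resolution (spacing 0.7×0.7×2.5 mm, 24 heart slices + 4 padding
slices each side): 16 training / 4 validation / 8 held-out test volumes,
batch 20, learning rate 1e-3, 15 epochs (within the ≤30-epoch protocol) —
sizes chosen so a full two-arm (bisect vs sequential) comparison runs in
a few CPU-minutes. On this setting the with-bisect arm reaches held-out
volume Dice well above 0.85 and at or above the sequential arm, and its
validation Dice climbs visibly faster in the first epochs — the same
qualitative picture the slab sequencing is designed to produce.

Other fixed numerical choices: soft-Dice ε = 1e-6; binarisation
threshold 0.5; Adam β = (0.9, 0.999), ε = 1e-8; early-stop comparison
is `|valDice(e) − valDice(e−1)| < 1e-5`; both-empty Dice/IOU = 1;
Bland–Altman sd uses n−1; quartile remainder slices go to the earliest
(most inferior) groups; fat-window bounds are inclusive; mask warps use
nearest-neighbour interpolation; DICOM stored values are int16 with
slope 1 / intercept −1024.

## Known limitations

* The DICOM codec is minimal by design: little-endian, uncompressed,
  single-frame CT with the geometry/rescale tags this pipeline needs.
  It is cross-checked against an independent reader in the test suite
  but is not a general DICOM implementation.
* The reference network is a demonstration backend. Clinical-grade
  accuracy requires plugging a pretrained segmentation model into the
  `predict_slice()` contract.
* The heart extent is manual, as in the underlying protocol; no
  heart-slice classifier is included.
* Validation Dice is slice-mean (not volume) Dice; the choice is logged
  with the training log.
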