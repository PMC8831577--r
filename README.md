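# eatseg

Automated segmentation and quantification of **epicardial adipose tissue
(EAT)** in non-contrast CT calcium score scans, for imaging researchers
who need EAT volume and attenuation at cohort scale without manual
slice-by-slice contouring.

EAT — the fat enclosed by the pericardial sac — is an emerging
cardiovascular risk marker, and calcium-score CT archives are large, but
the scans are hard to analyse: thick slices (~2.5 mm), no contrast, and
a pericardium that is a faint, thin membrane. `eatseg` implements the
measurement pipeline end to end:

* **HU attention window** — linear window/level **350/40 HU** mapping to
  8-bit, so the pericardium's few tens of HU of contrast survive
  quantisation: `v8 = round(255 · clamp((HU − lo)/(hi − lo), 0, 1))`.
* **Bisected look-ahead slab sequencing** — heart slices split into two
  halves, the lower sequenced bottom-to-middle (step +1), the upper
  top-to-middle (step −1); each target slice *k* is stacked with its two
  upcoming slices (*k+s*, *k+2s*) into a 3-channel slab, so the network
  always sees the sac's cross-section growing.
* **Pluggable per-slice segmentation** — a `predict_slice()` contract
  with a small CPU-trainable U-Net reference backend (Adam, soft Dice
  loss, batch 20, lr 1e-3, ≤30 epochs, early stop at 1e-5 validation
  Dice change) plus an oracle test double; blur-duplication and
  per-epoch rotation/scale augmentation with exact presentation
  accounting (1446 slices → 2892 → 86,760 over 30 epochs).
* **Fat-window quantification** — EAT = voxels inside the sac with
  (median-filtered, 3 mm kernel) HU in **[−190, −30]**; volumes in cm³,
  per-slice volumes, mean HU.
* **Agreement evaluation** — slice/volume Dice `2|A∩B|/(|A|+|B|)` and
  IOU `|A∩B|/|A∪B|`, quartile slice grouping, Bland–Altman (bias,
  LOA = bias ± 1.96·sd), through-origin fit y = mx with Pearson R,
  percent error, paired t.
* **Synthetic phantoms** — cardiac CT stand-ins with analytic ground
  truth (unimodal sac profile, fat annulus inside a thin wall,
  paracardial fat outside it, integer HU, optional noise), so every
  stage is testable without clinical data.

I/O: DICOM series in (minimal built-in codec, cross-checked against an
independent reader), NIfTI masks in/out, CSV/JSON reports.

## Worked example

```r
library(eatseg)

# a synthetic scan with known truth, written as a DICOM series
ph <- generate_phantom(phantom_spec(noise_sd = 10), seed = 7)
write_ct_series(ph$volume, "scan_dicom")

volume <- load_ct_series("scan_dicom")
extent <- ph$extent                       # manual heart extent (bottom, top)

# perfect segmenter stand-in; swap in a trained unet_segmenter() here
truth  <- eatseg:::crop_mask_to_extent(ph$sac, extent)
sac    <- segment_volume(volume, extent, oracle_segmenter(truth))

res <- quantify_eat(volume, sac)          # 3 mm median, fat window [-190,-30]
res
#> <eat_result> EAT volume 8.44 cm^3, mean HU -70.7, 32 slices
percent_error(res$total_volume, ph$truth$eat_cm3)
#> [1] -0.1160093
```

The printed result is the EAT volume inside the predicted sac (here
8.44 cm³ against an analytic truth of 8.4476 cm³ — a −0.12% error at
noise sd 10 HU; at zero noise the recovery is exact), the mean fat
attenuation of the recovered voxels, and the number of axial slices
carrying per-slice volumes.

Training the reference segmenter on a phantom cohort:

```r
dirs <- cmd_phantom(10, "cohort", seed = 1)        # DICOM + truth masks
fit  <- cmd_train(dirs[1:8], dirs[9:10], "run1")   # checkpoint + log
out  <- cmd_segment("cohort/phantom_001/dicom", "5,28",
                    "run1/checkpoint.rds", "seg1")
```

A thin shell front end with the same commands (`phantom`, `train`,
`segment`, `evaluate`) is installed at
`system.file("cli", "eatseg", package = "eatseg")`.

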