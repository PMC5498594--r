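# cortigap

Detection, sizing and cross-modality matching of **cortical interruptions**
(erosions and large pores) in 3D CT volumes of peri-articular bone.

Peri-articular cortical interruptions are a hallmark of inflammatory joint
disease. In-vivo high-resolution peripheral quantitative CT (HR-pQCT, ~82 µm
isotropic voxels) can show them, but detecting them reproducibly requires an
algorithm rather than a reader, and validating that algorithm requires a
higher-resolution gold standard (ex-vivo micro-CT, ~18 µm). `cortigap`
implements the full semi-automated chain for both modalities, plus a
synthetic phantom generator so that every stage can be validated without
scanner data.

## The algorithm

For a bone volume with isotropic voxel size `v`:

1. **Periosteal contour** — the outer margin of the cortex is found by
   auto-contouring (Gaussian pre-smooth, Otsu threshold, 3D morphological
   closing over a physical radius, enclosed-void fill), or supplied by an
   operator.
2. **Bone segmentation** — Laplace–Hamming filtering + thresholding for the
   low-resolution modality; Gaussian filtering (σ = 0.8, support 1 voxel)
   with a constant threshold of 247‰ of the maximum possible value for the
   high-resolution modality (optionally calibrated so both modalities match
   in bone volume fraction, BV/TV).
3. **Cortical mask** — a constant-thickness rind peeled off the periosteal
   mask by iterated face-connected erosion: 4 voxels (0.328 mm) at 82 µm,
   18 voxels (0.324 mm) at 18 µm.
4. **Interruption detection** (five steps): (I) the void phase is the
   cortical mask minus bone; (II) bone is dilated by `k` face-connected
   steps, closing every channel of opening diameter ≤ `2k` voxels;
   (III) surviving void components that connect the periosteal to the
   endosteal boundary — true openings through the cortex — are selected;
   (IV) they are geodesically reconstructed within the original void;
   (V) the reconstructed regions are labelled and measured (voxel count,
   volume, periosteal cross-section area).

The number of dilation steps sets an **exclusive minimum diameter**
`d_min = 2·k·v`: 1/2/3 steps at 82 µm enforce > 0.164 / 0.328 / 0.492 mm;
3/5/9/14 steps at 18 µm enforce > 0.108 / 0.180 / 0.324 / 0.504 mm.

For validation, the high-resolution volume is rigidly registered to the
low-resolution grid (per bone), its interruption labels are resampled by
majority vote, and interruptions are **matched** when they share at least
20 voxels (0.011 mm³ at 82 µm). Lesion-level reliability is summarised as

    PPV         = matched test-side interruptions / all test detections × 100%
    sensitivity = matched reference interruptions / all reference lesions × 100%

and joint-level agreement as ICC(2,1) (two-way random, absolute agreement,
95% CI) with paired Wilcoxon signed-rank tests (exact null distribution up
to 25 informative pairs).

## Worked example

A paired phantom — a cortical tube with six through-holes of known diameters
(0.30–0.70 mm), imaged at 82 µm and 18 µm with partial volume and 5% noise —
run end to end:

```r
library(cortigap)
spec <- phantom_spec(
  holes = data.frame(angle_deg = rep(c(0, 120, 240), 2),
                     z_mm = rep(c(0.7, 1.4), each = 3),
                     diameter_mm = c(0.30, 0.45, 0.65, 0.70, 0.32, 0.48),
                     through = TRUE),
  noise_sd = 0.05, seed = 7)
res <- run_pipeline(pipeline_config(spec, register = "identity", seed = 7))
res
#> <cg_run_result>
#>  k min_diameter_mm n_lowres n_reference ppv_0.10mm sensitivity_0.10mm
#>  1           0.164        6           6        100          100.00000
#>  2           0.328        4           6        100           66.66667
#>  3           0.492        2           6        100           33.33333
```

Reading the table: at the loosest cut-off (k = 1, interruptions > 0.164 mm)
the low-resolution side finds all 6 holes and every one is confirmed by the
18 µm reference (PPV 100%, sensitivity 100%). Raising the cut-off discards
the smaller true interruptions: detections stay perfectly confirmed (PPV
does not fall) while sensitivity against the fixed > 0.10 mm reference set
drops to 66.7% and then 33.3% — the characteristic precision/recall
trade-off of diameter-filtered detection.

Individual stages are ordinary functions:

```r
ph  <- generate_phantom(spec)
ct  <- auto_contour(ph$lowres)
seg <- segment_lowres(ph$lowres, ct)
cm  <- build_cortical_mask(ct, thickness_mm = 0.328)
det <- detect_interruptions(seg, cm, diameter_spec(1, 0.082))
det
#> <cg_interruptions> 6 interruption(s) > 0.164 mm (k = 1, 0.082 mm voxels)
#>   total surface 1.4591 mm2, total volume 0.38155 mm3
```

A thin Rscript front end (`inst/cli/cortigap.R`) exposes
`convert`, `segment`, `mask`, `detect`, `phantom`, `match` and `run`
subcommands over the same functions.

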