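---
title: "Detecting cortical interruptions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical interruptions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortigap` detects channels of non-bone — cortical interruptions — that pass
through the cortical shell of a peri-articular bone, sizes them, and matches
them between a low-resolution in-vivo acquisition (HR-pQCT class, 0.082 mm
isotropic voxels) and a high-resolution ex-vivo gold standard (micro-CT
class, 0.018 mm). This vignette explains the underlying model, every
parameter that matters, the numerical conventions, and the design decisions
that were genuinely open — with the reasoning behind each.

## The detection model

The central quantity is the *opening diameter* of a void channel. A channel
survives `k` dilation steps of the bone phase exactly when its narrowest
cross-section is wider than `2k` voxels: dilation advances one structuring
element per step from each wall, so a gap of exactly `2k` voxels closes and a
gap of `2k + 1` voxels does not. The enforced minimum diameter is therefore
an **exclusive** bound, `d_min = 2 k v` for voxel size `v`. Detection
proceeds in five steps (void extraction, k-step bone dilation, two-boundary
component selection, geodesic reconstruction, labelling); components are
counted **after** reconstruction, so seed fragments that reconstruct into
one region count once.

Two connectivity conventions coexist deliberately:

* the **structuring element** of the dilation steps is the face-connected
  (6-neighbourhood) cross, because the cut-off table is parameterised in
  voxel counts and the L1 ball makes `2k` exact along grid axes (a
  26-neighbourhood "ball" mode is available via `element = "ball"`);
* **components and adjacency** use the 26-neighbourhood throughout, so
  diagonal contact counts as connected — the permissive convention for void.

"Connected to both boundaries" is operationalised as: the component, before
reconstruction, contains at least one voxel 26-adjacent to the outside
region and at least one 26-adjacent to the trabecular interior. A blind pit
reaching only one surface is never an interruption.

### The constant-thickness cortical mask

The cortical region is the periosteal mask minus its erosion by
`round(thickness_mm / v)` face-connected steps — 4 voxels (0.328 mm) at
0.082 mm and 18 voxels (0.324 mm) at 0.018 mm by default, matching the
average cortical thickness of metacarpophalangeal joints. A constant
thickness is robust but known to bias sizes: where the real cortex is
thinner, marrow voxels inside the mask can join an interruption (size
overestimated); where it is thicker, the channel is truncated (size
underestimated). Two choices here were open and are fixed as follows:

* the mask is **anchored on the periosteal contour**, not on segmented bone,
  so that a locally absent cortex (the pathology of interest!) does not
  deform the mask;
* the first and last slice of the stack are treated as **continuations of
  the scanned region**: the mask erosion pads the stack ends by replicating
  the end slices. Without this, erosion fabricates full-disc "cortical" end
  slices whose marrow content floods the void phase.

### Interruption surface

No standard definition exists for the "surface" of an interruption; this
package defines it as the component's cross-section in the periosteal
boundary layer: `(component voxels in the periosteal layer) × v²` — the
area of the cortical opening as seen from outside the bone, which is the
clinically read quantity. Totals per joint are sums over components. Any
comparison of surface values between implementations depends on this
definition, so it is stated prominently here.

## Segmentation

**Low resolution.** The in-vivo protocol character is edge enhancement plus
noise suppression: a frequency-domain Laplace–Hamming filter
(`(1 + sharpen · |f|²/max|f|²)` times a Hamming window reaching zero at
`cutoff` × Nyquist) followed by a threshold at `threshold_permille` of the
maximum filtered intensity. The vendor's exact constants are not public;
this package's defaults — `cutoff = 1.0` (a mild full-band taper),
`sharpen = 1`, `threshold_permille = 450` — were fixed once by maximising
the Dice overlap between the segmentation of a noisy partial-volume phantom
and its ground-truth bone map (Dice 0.986 at these settings). Strong
low-pass settings (e.g. cutoff 0.4 × Nyquist) reach Dice only ~0.86 and
visibly close the 3–8-voxel channels the method exists to detect, which is
why they are not the default despite being the more literal reading of
"low-pass filtering".

**High resolution.** Gaussian filtering with σ = 0.8 voxels and a hard
truncation radius of 1 voxel ("support = 1" is read as kernel truncation,
the scanner-vendor convention), thresholded at 247‰ of the maximum possible
voxel value. The maximum possible value is an acquisition property and must
be supplied (`max_value`); the phantom fixes it at 1000 so permille
thresholds are literal. Alternatively `calibrate_threshold_to_bvtv()`
chooses the threshold so the high-resolution BV/TV matches the
low-resolution one — the histogram-quantile route used when the two
modalities must be made comparable.

**Ties.** Everywhere, a voxel exactly at the threshold is bone
(`value >= threshold`). This is fixed and documented rather than
configurable.

**Auto-contour.** The default periosteal contour is: Gaussian pre-smooth
(σ = 1 voxel) → threshold at the Otsu level (the 50%-edge-height criterion
on a bimodal image, which places the boundary at the periosteal surface) →
3D morphological closing over a physical radius (`closing_mm = 0.4`) →
largest 26-connected component → enclosed-void fill. Three details matter:

* thresholding at a *fraction* of the Otsu level (e.g. 50%) inflates the
  contour by ~2 voxels; the constant-thickness rind then contains a
  connected void sheath just inside the periosteal surface which
  geodesically merges all interruptions into one component. The full Otsu
  level keeps the contour tight;
* the closing radius is a **physical length** so that cortical openings up
  to ~0.8 mm are sealed at any resolution (a fixed 3-voxel radius can seal
  nothing larger than 0.49 mm at 82 µm, less than the largest cut-off class
  in routine use); closing is 3D because a wide hole cutting a thin
  cortical ring is frequently open within individual 2D slices even when
  the 3D surface around it is sealable;
* hole filling is a 3D flood seeded from the four lateral faces only: the
  z faces are stack ends, so a marrow cavity open at the stack ends still
  counts as inside.

An operator-corrected contour can always replace the automatic one
(`accept_manual_contour()`), which validates geometry, fills enclosed
voids with a warning, and rejects masks that exclude segmented bone.

## Cross-resolution matching

Cut-offs are paired across resolutions by **nearest step count**:
`choose_steps_for_diameter()` returns `round(target / 2v)` with a floor of
one step, which reproduces the canonical pairings (e.g. a > 0.33 mm class
is 2 steps at 82 µm and 9 steps at 18 µm; the fixed > 0.10 mm reference is
3 steps at 18 µm). The alternative "smallest k whose enforced diameter is
at least the target" was rejected because it contradicts those canonical
pairings (it would map 0.33 mm at 82 µm to 3 steps, i.e. > 0.492 mm).

Registration is rigid, per bone (different joint angles between
acquisitions make one joint-wide rigid map invalid), multi-resolution
(3 levels of 2× box-averaging), optimised by Nelder–Mead over three
rotation angles (degrees) and three translations (mm) with restarts until
convergence. The similarity metric rescales each volume between its Otsu
class means and clips to [0, 1] — a *soft* bone-probability map. Two
rejected alternatives: raw-intensity MSE is not comparable across
modalities with different intensity scales, and a hard binarisation (with
or without smoothing) flattens the metric because it discards the
partial-volume gradient at the bone surface that actually drives the
optimisation. The procedure is fully deterministic; no stochastic sampling
is used.

Labels are resampled to the target grid by nearest neighbour, or, when the
target voxels are coarser than the source by more than 1.5×, by majority
vote over the target voxel's source footprint with ties going to the lowest
label. Two interruptions match when they share at least `overlap_min = 20`
voxels on the common grid (0.011 mm³ at 82 µm — the smallest interruption
volume detectable at the loosest cut-off there). The bound is strict: 19
voxels do not match.

The lesion-level metrics use **side-consistent numerators**: PPV counts
matched components on the test side over all test detections, and
sensitivity counts matched components on the reference side over all
reference lesions. With one-to-many matches these numerators differ, and
each is the one that keeps its ratio a proportion of its own denominator.

## Reliability statistics

ICC(2,1) — single measure, two-way random effects, absolute agreement — is
computed from the two-way ANOVA mean squares, with the 95% CI from the
standard F-distribution bounds using a Satterthwaite-approximated
denominator df. Degenerate tables (zero between-joint variance) return NaN
with a warning rather than a misleading number. Qualitative labels
("almost perfect" ≥ 0.81 and so on) follow the Landis–Koch scale and are
annotations only.

The paired Wilcoxon signed-rank test drops zero differences, uses midranks
for ties, and computes the exact two-sided null distribution by dynamic
programming over doubled ranks (equivalent to enumerating all 2^n sign
assignments) for up to 25 informative pairs — the default at the study
sizes this package targets — switching to a tie-corrected,
continuity-corrected normal approximation above. Whether the original
analyses used exact or asymptotic p at n ≈ 19 is not documented anywhere;
both are provided and exact is the default.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes an analytic object — by default a cortical tube
(outer radius 1.0 mm, wall 0.33 mm, length 2 mm, a long-bone diaphysis in
miniature) — pierced by right-circular cylindrical holes normal to the
surface, so each hole's diameter and mouth area are unambiguous ground
truth. Rasterisation happens at a supersampled grid (3× at 82 µm, 2× at
18 µm by default) followed by box averaging, which produces genuine partial
volume; Gaussian noise (seeded) is added afterwards. Intensities are
two-level (0 background, 1000 bone) before degradation, making permille
thresholds literal. The tube spans the full z extent of the volume — a
cropped scan stack, with no artificial end caps. The paired outputs can be
rigidly offset; the applied transform is stored with the ground truth in
the orientation `resample_labels()` expects.

Study conditions fixed in the test suite (chosen once, for the reasons
given): noise SD 5% of bone intensity for "noisy" experiments; hole
diameters {0.10, 0.25, 0.45, 0.65} mm for the noise-free recall/precision
grid, placed well clear of the 2k-voxel cut-offs so rasterisation cannot
move a hole across a bound; and {0.30, 0.32 | 0.45, 0.48 | 0.65, 0.70} mm
for the noisy trend experiment — two holes in each detectability band,
each at least about one voxel above its cut-off, because partial volume
physically narrows a channel by roughly one voxel and a hole marginally
above a cut-off is simply invisible at 82 µm. That last point is the
trade-off the method exists to quantify, not an artefact.

The thin-cortex demonstration (`thin_cortex_phantom()`) embeds a locally
thinned patch (default 0.06 mm over 0.5 mm) in a normal wall: at 82 µm the
patch falls below the bone threshold and becomes a false interruption; at
18 µm it segments intact. On a perfectly grid-aligned cylindrical wall the
surviving outer voxel layer keeps the wall closed down to ~0.07 mm, which
is why the default is below that; real cortices are oblique to the grid
and drop out at larger thicknesses.

What the phantom does **not** emulate: trabecular texture (the interior is
empty, so endosteal adjacency is cleaner than in real bone), beam
hardening, scanner-specific noise spectra, motion artefacts, and
density calibration. Passing phantom tests therefore demonstrates the
correctness of the morphology, matching and statistics — not in-vivo
performance, which depends on exactly the omitted effects.

## Numerical conventions and degenerate inputs

* Internal axis order is (z, y, x) = (slice, row, column); all file formats
  are converted on load. Coordinates are voxel-centre based, 0-indexed.
  Anisotropic spacing is rejected at load time (the algorithm is
  parameterised in voxel counts).
* Erosion uses zero-padded borders (the grid border erodes) except where
  the operation semantically extends the object past the grid: the closing
  inside `auto_contour()` pads with background by the closing radius, and
  the cortical-mask erosion replicates the z end slices.
* Float grids round-trip through NIfTI/MetaImage/raw at 1e-6; TIFF stores
  32-bit floats rescaled to [0, 1] with the affine recorded in the JSON
  sidecar, so its round trip is faithful to ~1e-7 of the intensity range.
  NIfTI voxel sizes are 32-bit floats on disk and are recovered to 7
  significant digits on load.
* Label maps must be contiguous 1..K; writers renumber with a warning (or
  error, per `gap_policy`).
* `calibrate_threshold_to_bvtv()` fails (rather than silently returning a
  boundary) when no achievable BV/TV is within `tol = 0.05` of the target
  from below — e.g. on flat or binary-valued images.
* An empty cortical region is an error; a `k` so large that dilation fills
  the mask returns an empty interruption set (a valid result).

## Problem sizes

The test suite and validation experiments run on: tubes of 1–2 mm at both
voxel sizes (up to ~160³ voxels at 18 µm), 100 random grids of up to 20³
voxels for the brute-force oracle equivalence, and registration on ~32³
(82 µm) volumes with 3-level pyramids. These sizes keep the full suite
around two minutes on one CPU while exercising every code path at both
resolutions.

## Known limitations

* The constant-thickness mask biases interruption size, as discussed above;
  locally adaptive thickness is out of scope.
* The Laplace–Hamming constants are this package's calibrated defaults, not
  a claim about any vendor's protocol; they are configurable.
* Registration assumes overlapping fields of view and a single bone per
  call; deformable registration and joint-angle normalisation are out of
  scope.
* Scanner-native formats (AIM/ISQ) and DICOM series are not parsed; convert
  externally to NIfTI/MetaImage/TIFF.
* Density calibration (mgHA/cm³) and volumetric BMD are out of scope.
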