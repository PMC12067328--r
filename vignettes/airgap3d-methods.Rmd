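---
title: "Methods: air-artifact suppression and pore morphometrics in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: air-artifact suppression and pore morphometrics in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phase-contrast micro-CT of formalin-fixed, paraffin-embedded (FFPE)
lung tissue resolves soft-tissue structure without staining, but air
bubbles trapped in the block defeat single-distance phase retrieval:
the retrieval is tuned to the tissue–paraffin interface, so air–tissue
and air–paraffin interfaces keep strong edge enhancement.  In the
reconstructed 8-bit volume these artifacts appear as near-black voids
wrapped in near-white rims — after windowing, a histogram spike at
intensity 0 and another at 255 — while artifact-free tissue occupies a
mid-gray band.  The artifacts merge neighboring airspaces, break
watershed-based morphometrics and dominate volume renderings.

`airgap3d` implements a complete artifact-suppression workflow: it
synthesizes training pairs by *transplanting* real artifacts into
artifact-free regions, trains a 3D pix2pix conditional GAN to translate
artifact-bearing cubes into artifact-free ones, selects a generator
checkpoint by relative error (RE), PSNR and SSIM, applies the generator
tile-wise to whole scans, and quantifies pore structure before and
after suppression.

## Training-pair construction

True pairs (the same tissue with and without bubbles) cannot be
acquired, and artifacts synthesized from scratch do not look right.
The pair factory therefore:

1. extracts cubes from scans on a stride lattice (`extract_cubes`);
2. classifies each cube by its extreme-intensity fraction
   (`classify_artifact_cube`): the score is the fraction of voxels at
   `I <= low_thr` or `I >= high_thr` after discarding connected
   components smaller than `min_component_vox`.  The component filter
   replaces the human judgment of a manual sort — isolated salt/pepper
   voxels are not artifacts;
3. builds a binary air mask per artifact cube (`make_air_mask`):
   two-sided threshold, opening, small-component removal, then
   dilation to catch the transition zone beyond the saturated rim.
   Structuring elements are Euclidean balls, so the mask is isotropic;
4. copies the masked voxels of an artifact (donor) cube into a clean
   (recipient) cube (`transplant_artifacts`), yielding a source with
   artifacts and a bit-identical-elsewhere target without.

Defaults `low_thr = 10`, `high_thr = 245` tolerate noise around the
0/255 artifact signature; no canonical values exist, so all knobs sit
in `mask_params()`.  Whether void and rim should be masked in one
two-sided pass or two merged passes is ambiguous; we use one two-sided
pass.  Recipients are sampled with replacement under a seed — donor
and recipient anatomy cannot be matched, a known limitation inherited
by any transplant-based factory (the network learns to inpaint
*plausible* tissue, not the true tissue).

## The 3D pix2pix model

The generator is a 3D U-Net: encoder blocks are convolution (4-cube
kernel, stride 2, same padding), batch normalization (absent in the
first block and the bottleneck) and leaky ReLU (slope 0.2); the
bottleneck uses a plain ReLU.  The edge halves per block, so depth is
`log2(cube_edge)` and the bottleneck is a 1-cube: at the published
scale of 256-cubes the encoder is C64–C128–C256–C512–C512–C512–C512–C512,
the decoder its mirror T512–T512–T512–T512–T256–T128–T64.  Decoder
blocks are transposed convolution, batch norm, 50% dropout on the
first three blocks, concatenation with the same-resolution encoder
output, ReLU; a final transposed convolution with a tanh head emits
one channel.  Intensities are mapped to `[-1, 1]` to match the tanh
range (the input scaling is otherwise a free choice).

The discriminator is a 3D PatchGAN over the channel-concatenated
(source, candidate) pair: C64–C128–C256–C512 with strides 2,2,2,1 and
a stride-1 sigmoid scoring convolution.  By the standard recurrence
`RF <- RF + (k-1)*jump; jump <- jump*s` this stack sees a 70-voxel
patch per score (`receptive_field()`, cross-checked empirically by a
gradient-footprint probe).  For a 256-cube input the score map is a
32-cube; we implement the printed layer stack and report the computed
sizes.

Losses: the discriminator minimizes
`0.5 [BCE(D(a,b), 1) + BCE(D(a, G(a)), 0)]` — the halving follows the
original pix2pix convention of slowing the discriminator — and the
generator minimizes `BCE(D(a, G(a)), 1) + lambda * |G(a) - b|_1` with
`lambda = 100`.  Training alternates one discriminator and one
generator update per pair at batch size 1, with Adam at learning rate
0.0002, `beta1 = 0`, `beta2 = 0.999`.  `beta1 = 0` is kept as
published for this workflow even though the original pix2pix uses 0.5;
both are plain `train_config()` fields.  Weights start from
N(0, 0.02²), the pix2pix convention.  Batch normalization is applied
exactly as written even at batch size 1 (where it normalizes over the
spatial voxels of the single volume); an instance-norm variant is
deliberately not substituted.

Because there is no deep-learning framework underneath, the network
stack is implemented in the package itself: convolutions are im2col
gathers through precomputed sparse matrices followed by BLAS matrix
products, transposed convolutions are their exact adjoints, and every
gradient is hand-derived and verified against central finite
differences in the test suite.

### Inference

`generate()` runs the network deterministically: dropout off, batch
norm on running statistics.  The original pix2pix keeps dropout on at
test time as a noise source; here checkpoint selection compares fixed
generated/ground-truth pairs, which presumes deterministic outputs, so
inference-mode dropout is off (`training = TRUE` paths remain
available internally).

## Checkpoint selection

A generator checkpoint is written at epoch 0 (untrained baseline) and
every `checkpoint_interval_epochs` (default 10).  For each checkpoint,
held-out pairs are scored by:

* **RE** — `sum |I_gen - I_real| / sum I_real`, absolute differences
  summed before a single per-pair normalization (the alternative,
  voxel-wise normalization, is noise-amplifying at dark voxels);
* **PSNR** — `10 log10(255² / MSE)` in dB, `Inf` for identical pairs;
* **SSIM** — the single-window (whole-volume) form with the standard
  stabilizers `c1 = (0.01·255)²`, `c2 = (0.03·255)²`; the formula is
  written per volume pair with one mean/variance/covariance term each,
  so the global form is the faithful reading.  A sliding-window mean
  is available as an option.

How the three metrics are *combined* is open; `evaluate_checkpoints()`
uses the best average rank (RE ascending, PSNR and SSIM descending),
ties toward the later epoch, with an RE-only rule selectable.

## Whole-volume suppression

`suppress_air_artifacts()` tiles the scan into non-overlapping cubes
of the generator's edge, classifies each tile with the same
`mask_params` rule used during training-data construction, regenerates
only the flagged tiles and reassembles at the original coordinates.
Unflagged tiles are copied bit-exactly, making the operation
idempotent on clean data.  Tiling remainders are handled by `"crop"`
(faithful to the published non-overlapping scheme; margins recorded
untouched) or `"pad_reflect"` (mirror-pad to the next multiple, trim
after).  Tiles are deliberately not blended or overlapped; seam
artifacts are accepted as in the published workflow.

## Pore morphometrics

`segment_pores()` implements: threshold (`I <= pore_threshold`, the
darker paraffin/air phase), binary closing and hole filling, an exact
Euclidean distance transform, marker extraction (plateau-merged local
maxima of the distance map, thinned to `min_distance_vox` separation,
stronger peaks first), and a marker-based watershed by priority
flooding — deterministic, with labels partitioning the pore mask
exactly.  Lung airspaces are strongly connected, which is precisely
why the watershed split is needed before per-pore statistics.

Per pore, `pore_properties()` reports voxel and physical volume,
*extent* (volume / bounding-box volume) and *solidity* (volume /
voxelized convex-hull volume).  The hull is computed on voxel centers
by an incremental 3D hull and re-voxelized, so solidity stays a
voxel-count ratio; a filled cuboid scores exactly 1, concave shapes
below 1.  Pores thinner than one voxel in some direction have a
degenerate hull; their solidity is computed on the dilated-by-one
region and flagged.  The distance transform, component labeling and
watershed are compiled kernels (true 26/6-neighborhood 3D — the
slice-wise 2D behavior of generic image tools is not sufficient here).

`porosity()` is the pore-phase fraction after morphology.  The
fixed-value masking baseline (`mask_artifacts_fixed_value`) replaces
artifact voxels with one intensity, by default the histogram mode of
the unmasked voxels (a paraffin estimate).
`compare_structural_metrics()` puts original / masked / generated
variants side by side per ROI, with the generated variant as the
reference; the characteristic failure of ignoring artifacts —
bridging voids merging alveolar regions and inflating mean pore
volume — is reproduced as an ordering property in the tests.

## The phantom generator

`generate_lung_phantom()` emulates only what the downstream stages
need: a seeded Gaussian random field smoothed at
`pore_correlation_length_vox` (default 4 voxels) and thresholded at
the quantile matching `target_porosity` (default 0.4) yields a
two-phase medium of connected airway-like channels; the pore phase
gets `paraffin_mean = 90`, tissue `tissue_mean = 160`, plus Gaussian
noise (sd 6) and a slight blur (sigma 0.8), clipped to `[5, 250]` so
clean phantoms never touch the artifact extremes.
`inject_air_artifacts()` adds spheres (optionally radially perturbed;
exactly spherical at `shape_irregularity = 0`, keeping voxel counts
analytically checkable) with the void at 0 and a Euclidean-distance
rim band at 255.  Phantom and artifact seeds are independent so one
tissue can carry different artifact realizations.

What the phantom does *not* model: Fresnel/transport-of-intensity edge
physics, beam hardening, detector noise correlation, real alveolar
anatomy, or the anatomical mismatch of transplanted artifacts.
Passing tests therefore demonstrate that the machinery — pairing,
optimization, selection, tiling, morphometrics — behaves correctly and
that the network can learn this artifact phenotype; they do not certify
inpainting quality on real synchrotron scans.

## Numerical choices and conventions

* Arrays are `(z, y, x)` with `z` the slice axis; origins are 0-based
  voxel offsets into the parent volume.
* 8-bit conversion rounds half away from zero, then clips; a constant
  volume min–max-maps to 0 rather than erroring (flat phantom
  sub-blocks are legal).  How floating-point phase-retrieved data are
  windowed to 8 bits is left to `to_uint8(..., "fixed_window")`.
* Same padding everywhere in the networks (required for the
  256 → 1-cube bookkeeping), TensorFlow split (floor on the leading
  side).
* Watershed ties are broken by insertion order (FIFO), making labels
  deterministic; components are numbered in scan order.
* BCE probabilities are clamped to `[1e-7, 1 - 1e-7]`; training uses
  the fused sigmoid+BCE gradient `(p - y)/N` for stability.
* Every stochastic stage derives its seed from one global seed plus a
  stage label (`derive_seed`), so runs reproduce end to end.

## Problem sizes in the test suite

Tests exercise the full workflow at desk scale, a deliberate package
choice: 16-cube training pairs (depth-4 U-Net with filters
16-32-64-64, discriminator 16-32-64-64), 16 training and 4 held-out
pairs, 30 epochs — enough for the held-out RE of the trained generator
to drop below the RE of the artifact-bearing sources, with the same
optimizer settings as the full-scale setup.  Morphometric fixtures use
64-cubes where sphere voxel counts are brute-force checkable.  The
published 256-cube, 900-pair, GPU-scale configuration is expressible
with the same objects (`generator_spec(256)`), but its headline
inpainting quality on real scans is outside what CPU-scale phantoms
can certify.

## Known limitations

* Training at the published 256-cube scale is impractical in plain R;
  the implementation is intended for method study, phantom-scale
  experiments and as a complete, testable reference of the workflow.
* The transplant factory inherits the anatomical-mismatch limitation
  discussed above.
* The artifact phenotype is calibrated only to the 0/255 histogram
  signature (void near 0, rim near 255, rim thickness 1–3 voxels);
  real rim-intensity statistics are not quantified in the source
  material.
* No overlapping-tile blending: tile seams can be visible in
  regenerated regions, as in the published workflow.
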