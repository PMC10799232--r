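---
title: "Methods: preprocessing cycle-based multiplexed acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing cycle-based multiplexed acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cycleproc)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cycleproc`, and what the synthetic-data tests do and do
not establish.

## The acquisition model

One experiment images a grid of `n_cols × n_rows` tile positions in *snake
order* (row-major, first row left-to-right, direction alternating per row),
re-visiting every position once per cycle with `n_z` Z planes and a handful
of channels. Channel 1 carries the nuclear stain in **every** cycle — it is
the registration and stitching anchor. The first and last cycles are
acquired without reporters in the non-nuclear channels ("blank anchor
cycles") and exist solely to estimate what the tissue looks like with no
signal: autofluorescence under the instrument's illumination profile.

All user-facing indices (cycle, position, Z, channel, grid row/col) are
1-based, matching the tile file names
(`<name>-position{P}_Z{ZZ}_CH{C}.tif`); 0-based array coordinates appear
only inside the low-level image code. The `13x9` grid of the reference
acquisition is read as 13 *columns* × 9 *rows*: with 13 columns, snake
indices 56/57 (row 5) sit directly above 75/74 (row 6) in columns 4–5,
forming a contiguous 2×2 block — the only reading consistent with the
published example tiles. Snake order affects only tile *placement*; tiles
are never mirrored.

## Stage-by-stage choices

### PSF and deconvolution

The widefield PSF is approximated by an anisotropic Gaussian with
`σ_xy = 0.21·λ/NA` and `σ_z = 0.66·λ·n/NA²` (converted to voxels). This is
the standard scalar approximation; it is deliberately simple, testable
(normalisation, centrosymmetry, wavelength/NA ordering), and sits behind the
`psf_model` seam so a Born–Wolf or vectorial kernel can replace it without
touching `richardson_lucy()`. Deconvolution is the textbook multiplicative
Richardson–Lucy update, 10 iterations by default, with reflective boundary
handling; it is an *optional* stage — any external deconvolution can be
substituted by pre-staging its output in the work directory.

### Extended depth of field

Per pixel, the slice maximising a local focus measure — the variance of the
discrete Laplacian in a 9×9 window — is selected; a 5×5 median filter on the
winning-slice index map suppresses isolated slice switches, and the winning
pixel is copied ("hard" selection; a focus-weighted "soft" blend is
available). The external tool the reference workflow delegates to is
configured by opaque quality/topology flags that are not publicly defined,
so this operator is a re-specification with its own contract, not a clone:
equivalence with that plugin is not claimed.

### Shading correction

For each channel, at each blank anchor cycle, the profile is computed
literally as

> `profile = M / (G_σ ∗ M)`,  `σ = 64 px`,

where `M` is the pixelwise median across all positions, followed by
mean-normalisation to 1. The description this implements is ambiguous
between that fixed-pattern ratio and the conventional smooth flat-field
`(G_σ ∗ M)/mean`; both are provided (`mode = "ratio"` / `"smooth"`), the
literal reading is the default. The two differ most on large tiles, where a
64 px blur tracks the vignette itself; on the ~100 px tiles used in the test
suite the blur is near-global and the ratio mode recovers the vignette
directly. Per-cycle profiles are the linear interpolation of the two anchors
(exact at the endpoints, affine in the cycle index), and tiles are divided
by the interpolated, strictly-positive (ε-floored at 1e−6, logged) profile.

### Autofluorescence subtraction

Blank anchor tiles — *after* shading correction, per position and channel —
are blurred with `σ = 10 px` and taken as the autofluorescence field at
that anchor; the field at any cycle is again the linear anchor
interpolation, and is subtracted. Blurring before or after interpolation
commutes (both are linear), so the order is a non-choice. Backgrounds are
kept per position, not pooled: each tile sees its own tissue. Results may go
negative; they stay signed floats until stage 5.

### Registration and crop

Translation-only inter-cycle registration by phase correlation of the
nuclear channel against the reference cycle, per position: the peak of the
inverse-transformed normalised cross-power spectrum gives the integer
displacement, an optional 1-d parabola fit through the peak refines it to
subpixel. The reported `quality` is the normalised cross-correlation after
undoing the integer shift. The translation class is the constraint the
reference workflow imposes; phase correlation satisfies it with a testable
optimality contract. Each cycle's translation is applied unchanged to all
channels of that cycle. All tiles are then cropped by *symmetric* margins of
`ceil(max |dx|)` columns and `ceil(max |dy|)` rows per side — symmetric so
the tile centre (hence the stitching pitch) is unchanged; the margins are
taken globally over all positions so every position keeps one shape. Whether
the original workflow crops symmetrically or by signed per-side maxima is
unstated; symmetric is this package's documented choice.

### Negative-value cleanup

Negatives are clipped to 0; then the minimum over the strictly positive
values is subtracted from every positive value. "Minimal intensity value" is
read as the minimum over *positive* pixels — the only reading under which
the second operation does anything after the clip — and zeros stay zero.

### Stitching

Seam offsets between 4-neighbour tiles are measured by phase correlation of
the nominal overlap strips; seams with NCC below 0.3 (or with less than 4 px
of overlap) fall back to the nominal offset implied by the overlap fraction
and are flagged. Global positions follow a maximum-quality spanning tree
(Prim) over the tile graph — the MIST-style translation model without the
stage-model regression. One important geometric fact: the drift crop shrinks
tiles around their centres but does **not** change the stage pitch, so the
nominal seam spacing is computed from the *acquired* tile size, not the
cropped one. The layout is computed once, on the reference cycle's nuclear
channel, and reused for every (cycle, channel), guaranteeing all mosaics
share dimensions. Overlaps are blended with linear distance-to-edge
feathering (average-preserving: two identical strips blend to themselves); a
"reference-tile-wins" mode exists for strict intensity provenance. Mosaics
are cast to uint16 only at write time, after stage 5 guarantees
nonnegativity.

### Segmentation and measurement

The trained star-convex network the reference workflow uses is *not*
bundled: core correctness rides on a deterministic classical segmenter —
1st–99th percentile normalisation, Gaussian smoothing (σ 1.5 px), Otsu
threshold, exact Euclidean distance transform, h-maxima seeds (h = 0.5 px),
seeded watershed, minimum area 20 px². The `method = "plugin"` seam accepts
any `function(image) -> label matrix`, so a learned model drops in without
touching the pipeline. The h and σ defaults were chosen so two equal disks
overlapping by 20 % of their radius split reliably while isolated noisy
nuclei do not fragment (the min-area filter absorbs residual
oversegmentation); they are tuned for nuclei of roughly 4–8 px radius at the
test scale.

Measurements per label: unweighted pixel centroid, area, perimeter (length
of the traced Moore boundary polygon, diagonal steps weighted √2),
circularity `4π·area/perimeter²` (clipped at 1 + 1e−6 — the discrete
perimeter estimator can slightly undershoot on small disks), orientation
from second central moments, and the mean intensity over the label's pixels
in every non-blank (cycle, channel) mosaic. Blank channels are excluded from
the measurement table, whose fixed column order is `cell_id, x, y, size`,
then `cyc{NN}_ch{C}_{reporter}` columns.

### Exports

FCS 3.1 is written natively: 58-byte HEADER with ASCII offsets, delimited
TEXT segment with `$PAR/$TOT/$DATATYPE=F/$BYTEORD=1,2,3,4` and fixed-width
`$BEGINDATA/$ENDDATA` (so the TEXT length is independent of their values),
and a little-endian float32 list-mode DATA segment. The ImageJ ROI archive
is a STORE-method ZIP of binary `"Iout"` polygon entries written from the
traced boundaries. Readers for both formats are implemented independently
of the writers and serve as the round-trip oracles in the tests. All
writers are deterministic (no timestamps), and the output tree ships a
manifest with MD5 checksums, which is how the resumability test asserts
"two runs, same inputs → identical outputs".

## The simulator: what a green test establishes

`generate_phantom()` builds the ground truth the pipeline is measured
against: soft-edged disk nuclei (radius 4–7 px) with per-nucleus log-uniform
reporter levels (500–4000 counts) in every non-blank slot, nuclear stain at
3000 counts; smooth low-order-polynomial autofluorescence (~300 counts,
±20 %) defined at the two anchors and — by construction — linear in the
cycle index in between; a per-channel polynomial vignette (~30 % corner
falloff) in the *camera* frame, slightly different at the two anchors;
per-cycle integer stage drift up to 8 px (subpixel optional), zero at the
reference cycle; Gaussian defocus growing linearly with distance from the
focal plane; Poisson shot noise (gain 1) plus Gaussian read noise (σ = 2).
Defaults reflect the reference acquisition (2048 px tiles at 0.325 µm, NA
0.8, 11 Z planes at 1.5 µm, 13×9 grid, 10 % overlap); tests pass explicitly
small descriptors (~100 px tiles, 2×2 grids) to stay within CPU budgets.

Because the simulator's autofluorescence is *exactly* linear across cycles
and its vignette *exactly* interpolates between the anchors, a green
correction-chain test establishes that the pipeline inverts its own forward
model to within noise — not that real tissue autofluorescence is linear in
cycle index, nor that real shading drift is. Likewise the phantom has no
spectral bleed-through, no photobleaching, no tissue deformation, and its
nuclei are circular; segmentation scores here do not transfer to crowded
real tissue. Those are model limits, stated as such.

The simulator also fixes an interface question the physics decides: the
vignette is a *tile-frame* (camera) field applied identically to every
position, because a per-tile estimated profile can only ever correct a
camera-frame pattern.

## Numerical conventions

* Images are `matrix[row = y, col = x]`; stacks `array[y, x, z]`.
* All Gaussian blurs: reflective boundaries, kernels truncated at 4σ.
* All corrected intermediates are float32 on disk (in the work directory);
  uint16 appears only in raw input and final mosaics.
* Phase correlation returns the displacement of the *moving* image's
  content; alignment applies its negative. Constant images are rejected.
* Interpolation weight of the last anchor is `(c − 1)/(n_cycles − 1)`;
  a single-cycle experiment degenerates to the first anchor (logged).
* Per-tile render noise is seeded from `(seed, cycle, position, z,
  channel)`, so any tile is reproducible in isolation and acquisitions are
  byte-identical under a fixed seed.

## Known limitations

* The Gaussian PSF ignores refractive-index mismatch and aberrations; no
  GPU path.
* The stitching solver omits MIST's hill-climbing refinement and
  stage-model regression; with fewer than ~4 px of genuine overlap it
  simply trusts the nominal grid.
* Subpixel registration is estimated but applied rounded to integers; the
  quadratic peak fit is accurate to ~0.25 px on textured content.
* The vendor's project format is unpublished; the output tree is a
  documented approximation, with the mapping recorded in `manifest.json`.
* `remove_negative_values` discards a constant per image by design (it
  rebases positives); downstream statistics are shift-invariant per image
  only.
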