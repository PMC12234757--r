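---
title: "Surface-guided 3D reconstruction of sparse multimodal serial sections: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-guided 3D reconstruction of sparse multimodal serial sections: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Post-mortem serial sectioning produces stacks of 2D images — receptor
autoradiographs, cell-body or myelin stains — that interleave many
*acquisitions* (one ligand or stain per physical slice) along the cutting
axis. Three obstacles stand between those images and a usable 3D map:

1. **Geometric disorder.** Each fresh-tissue section is independently
   rotated, shifted and non-linearly deformed by cutting and mounting, and
   whole tissue slabs deform before freezing.
2. **Intensity heterogeneity.** Different acquisitions have unrelated
   intensity distributions, so neighbouring sections cannot be aligned (or
   stacked) by any intensity-based similarity directly.
3. **Sparsity.** Each acquisition samples only a fraction of the cutting
   axis (roughly a quarter to a third of planes carry *any* section, and a
   given acquisition far fewer), and sections are lost or excluded, so
   most voxels of the final per-acquisition volume have no measurement.

`recortex` addresses all three with a single idea: reduce every section to
its cortical gray-matter (GM) morphology, align morphology to morphology,
and then let the cortical surface geometry carry intensities across the
gaps.

## The pipeline

### Stage 0 — contrast-agnostic GM segmentation

Every section is reduced to a binary GM mask. The package ships a
classical segmenter — Otsu's 256-bin threshold with automatic tissue-side
selection, a hierarchical second threshold when the first split only
separated background from tissue (leaving white matter inside), a
largest-component cleanup and small-hole filling — plus the machinery to
train a learned replacement: `synthesizeTrainingPair()` /
`generateTrainingSet()` produce synthetic sections from a labelled volume
with randomised per-class Gaussian intensities, 0–11 cortical layers with
Dirichlet-proportional thicknesses, random affines (scaling U(0.9, 1.1),
rotations U(0°, 15°)), an optional skull ring in half the examples and
smoothing/noise/scale/crop augmentation. Any function honouring the
`Segmenter` interface (image in, binary mask on the same grid out) can be
plugged into the pipeline; when the primary segmenter returns an empty
mask the Otsu fallback is used and logged.

The side-selection heuristic deserves a note: the tissue side of the
threshold is chosen as the side that does not own the image border and
whose largest connected component looks most like a ribbon (large, low
solidity). The hierarchical second threshold is accepted only when it
exposes a ring (filling the holes of the refined component grows its area
by at least 30%); solid GM caps near the poles of the brain therefore keep
the single-threshold mask.

### Stage 1 — contrast-ranked rigid chaining

Acquisitions are ranked by the median Michelson contrast
\((I_{max}-I_{min})/(I_{max}+I_{min})\) of their tissue pixels. Within each
slab, the central section of the highest-contrast acquisition is fixed;
moving outward, each same-acquisition section is rigidly registered to its
nearest already-fixed neighbour toward the centre and then becomes fixed.
Each lower-contrast acquisition is then aligned section-by-section against
the nearest fixed section of the higher-ranked groups, so low-contrast
sections never anchor high-contrast ones. Rigid registration minimises the
mean squared difference of Gaussian-smoothed masks, initialised by the
centre-of-mass offset and a coarse rotation sweep and refined by
Nelder–Mead at two resolutions. All the alignment in the package is
mask-based and therefore mono-modal by construction, which is why a simple
quadratic metric suffices.

The chain has a *gauge*: every recovered pose is relative to the central
section's (unknown) true pose. Chaining accuracy is therefore always
assessed modulo that gauge; absolute placement is the next stage's job.

### Stage 2 — multi-resolution 3D/2D alignment to a reference

At each resolution of a strictly decreasing schedule (default
4, 3, 2, 1, 0.5, 0.25 mm; the phantom studies use 4, 2, 1 mm):

1. the per-section masks are resampled through their best available
   transforms (stage-1 rigids first time round, refined chains after) onto
   a common grid, stacked at their plane positions, and the unacquired
   planes are filled by inverse-distance linear interpolation between the
   two nearest acquired planes — a continuous *fuzzy* GM volume;
2. the reference GM (cropped to the slab's manually identified bounds when
   there are several slabs) is registered to that volume with a
   nine-parameter affine (centre-of-mass and in-plane-rotation-sweep
   initialised) followed by diffusion-regularised demons;
3. every section is refined in 2D against the reference plane at its world
   position (nearest plane, ties toward posterior): a small rigid
   pre-alignment, then 2D demons, composed into a single displacement
   field appended to the section's chain.

Every registration stage is guarded: the result is kept only while the GM
Dice does not decrease, so a diverging stage degrades to the identity (and
is flagged) rather than corrupting the reconstruction. The fuzzy volumes
are deliberately not binarised before 3D registration — the interpolated
gap planes are genuinely fractional evidence — and Dice is computed at a
0.5 threshold for reporting only.

### Stage 3 — surface-based interpolation of missing intensities

Twenty (human-scale; ten for smaller brains) shared-topology surfaces are
generated by evenly subdividing the segment between the WM–GM and pial
border meshes, then upsampled by regular barycentric subdivision
(`P = A + αAB + βAC`, α, β, α+β ∈ [0, 1]) at a single global order chosen
so the longest edge is at most the output resolution — one vertex per
voxel inside acquired sections, and a crack-free subdivision that all
depth surfaces and spheres share index-for-index. The surfaces are carried
into each slab's reconstruction space through the inverse of the 3D
registration (solved per vertex by fixed-point iteration), and every
vertex within half a section thickness of an acquired plane of the target
acquisition samples that section's nearest-neighbour pixel through the
full inverse transform chain. A sampled value is accepted only if the
pixel lies inside the section's GM mask: with coarse phantom pixels the
border surfaces would otherwise sample white matter or background, which
real micron-scale pixels largely avoid.

Missing vertices are filled by piecewise-linear interpolation on the unit
sphere: the known vertices are triangulated by their 3D convex hull (for
points on a sphere the hull *is* the spherical Delaunay triangulation, an
in-package incremental hull with conflict lists), and each missing
direction takes the barycentric interpolant of the triangle its ray
crosses. The weights are convex, so interpolated values never leave the
range of the observed ones — the property that motivates linear
interpolation in the first place. Phantom meshes are star-shaped by
construction, so sphere inflation is exact radial projection; real
cortical meshes are not star-shaped and externally inflated spheres must
be supplied (they are validated and passed through).

Finally each completed depth field is projected into the volume: every
cortical voxel averages the vertex values inside it, and the few cortical
voxels containing no vertex are filled by iterative neighbour averaging
restricted to the cortex mask (a Laplacian fill, which reduces exactly to
linear interpolation across 1D gaps).

## The phantom: what it emulates and what it does not

All quantitative claims in the test-suite are made on a synthetic phantom
with known ground truth, generated by `makePhantom()` /
`synthesizeTruthFields()` / `sliceSections()`:

* a star-shaped folded cortical ribbon: pial radius
  `R(u) = R0 + A·f(u)` about a fixed centre with constant cortical
  thickness below it, stretched along the cutting axis. The folds run in
  the in-plane angle with a fixed angular phase and smoothly modulated
  amplitude, so coronal cross-sections share one fold orientation and the
  rigid chaining has a well-defined ground truth;
* the elongation (default 1.9) and thin sections (0.25 mm planes, 1 mm
  in-plane) reproduce the *ratios* that matter in real serial datasets:
  neighbouring acquired sections differ only slightly in anatomy, and the
  per-acquisition sampling distance is a few times the reconstruction
  resolution;
* per-acquisition analytic density fields (sums of random cosine waves
  with wavelengths ≥ 16 mm, scaled to 50–200 density units) that can be
  evaluated at voxels and vertices alike — a known forward model;
* an 8-bit intensity model per acquisition
  (`value = offset + gain·density`, WM at a low constant level, dark
  background, Gaussian noise of sd 4 gray levels, optional polarity flip)
  emulating heterogeneous acquisitions;
* sparse sampling: acquisition labels cycle over the planes, planes are
  kept with the coverage probability (default 0.3), kept sections are lost
  with a dropout probability, fragment planes with less than a quarter of
  the peak GM area are discarded (as fragment sections at slab ends are in
  practice), slabs are separated by discarded planes, and each kept
  section is perturbed by a random in-plane rigid motion (≤5°, ≤3 px by
  default) plus a shared per-slab offset (≤2°, ≤2 px) and a smooth random
  warp (0.75 px).

What the phantom does **not** emulate: histological texture, laminar
intensity profiles, tears and folds, out-of-plane (3D) slab shear, and
segmentation failure modes of real stains. Passing phantom tests therefore
demonstrates the correctness and stability of the geometry and
interpolation machinery under realistic sparsity and perturbation — not
segmentation performance on real histology, which is exactly the part the
pluggable learned segmenter exists for.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| resolution schedule | 4, 3, 2, 1, 0.5, 0.25 (phantom: 4, 2, 1) | mm | coarse-to-fine; last entry is the output resolution |
| depth surfaces | 18 intermediate + 2 borders (phantom runs: 10 total) | – | ≥ 1 surface per voxel across the cortical thickness |
| mesh upsampling | max edge ≤ output resolution | mm | ≥ 1 vertex per voxel within acquired sections |
| capture window | ± thickness/2 | mm | the physical extent of a section |
| Otsu histogram | 256 bins | – | 8-bit sources |
| QC rule | area < 75% of 4-neighbour median | – | automated version of the missing-cortex exclusion |
| demons iterations | 30 (3D), 40 (2D) | – | convergence on 64³/64² grids; guarded by Dice |
| rigid metric blur | 1 px | – | differentiable mask edges |

## Numerical choices and degenerate inputs

* Grids use the pixel-centre convention; world units are mm; the cutting
  axis is array axis 2. Resampled grids preserve the world bounding box,
  which makes an exact factor-2 linear downsample equal the block mean.
* Out-of-domain samples are background 0, and tissue masks are strictly
  positive, so background never counts as tissue.
* `dice(∅, ∅) = 1`: empty windows agree perfectly; windowed aggregation
  skips prediction-empty windows anyway.
* Otsu ties take the lowest threshold bin; a constant image is a
  degenerate-input error.
* Registration divergence returns the identity (2D rigid), the affine-only
  result (3D), or a flagged identity field (2D refinement) — never an
  abort — because damaged sections are a fact of serial datasets.
* Displacement fields are stored in pull-back form on their own grid and
  are numerically invertible by fixed-point iteration; the inversion
  residual is itself a tested invariant (median ≤ 0.5 voxel).
* The patch-validation distance window scales with the dataset: the
  default (0.05–1.2 mm) matches sub-millimetre real sampling distances;
  phantom studies use 0.05–6 mm because the phantom's vertex spacing and
  per-acquisition sampling distance are several times coarser.
* Problem sizes in the shipped studies were chosen for desk-scale
  reproducibility: a 64³ reference at 1 mm, ~60 sections over two slabs,
  schedule 4–2–1 mm, 1000 validation patches.

## Known limitations

* Linear interpolation across the sphere smooths over sharp
  receptor-architectonic boundaries by design; it trades bias for
  guaranteed boundedness.
* The demons backend is diffusion-regularised and guarded, not
  diffeomorphic; extreme deformations would need a stronger backend, which
  can be swapped in behind the same narrow interface.
* Only the cortical ribbon is reconstructed; subcortical structures are
  outside the masks and therefore outside the model.
* Radial sphere inflation is exact only for star-shaped surfaces; real
  cortical meshes need externally computed spheres.
* The hierarchical Otsu fallback assumes dark, preprocessed backgrounds;
  acquisitions with exotic polarity should configure the tissue side
  explicitly or use a trained segmenter.
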