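---
title: "Soma detection in neuronal cultures: models, parameters and design choices"
author: "somatect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soma detection in neuronal cultures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind it: the
model each stage assumes, the parameters that matter and why their
defaults are what they are, the numerical choices, and the limits of what
the phantom-based validation shows.

## The imaging model

The input is a fluorescence image of a cultured neuronal network in which
somas and dendrites share one channel (MAP2-style staining). We model a
neuron as a *cartoon neuron*: a union of bright, roughly isotropic
blob-like regions (somas, nominal diameter about 40 px at
0.28 µm/px) and thin elongated tube-like processes (neurites, a few
pixels wide), over a dark background, corrupted by Poisson photon-counting
noise. Confocal stacks of cultures are thin — 15–40 optical slices at
1 µm z-steps — and their contrast decays multiplicatively with depth.
Every stage below is designed around these three facts: one shared
channel, blob-vs-tube geometry, and a nearly 2D acquisition.

## Denoising: shearlet shrinkage

`build_system_2d()` constructs a tight frame of frequency windows: a
Meyer-type radial partition into `n_scales` band-pass annuli plus a
low-pass, each annulus cut into `shears_per_scale` overlapping
raised-cosine angular wedges. The squared windows sum to one at every
frequency (enforced numerically), so `transform_inverse(transform_forward(f))`
reproduces `f` to machine precision, and each coefficient equals the inner
product of the image with a shifted directional analyzing function — a
property the test suite checks against direct spatial summation.

`shrink_denoise()` soft-thresholds the directional bands at
`k · sigma_hat · g_b`, where `sigma_hat` is a median-absolute-deviation
estimate of the noise level from the finest-scale coefficients
(normalized by each band's white-noise gain `g_b = sqrt(mean(W_b^2))`),
and `k = 3` by default. The low-pass band is never shrunk. Consequences
worth knowing: thresholding is a contraction (the output norm never
exceeds the input norm), a zero image maps to zero, and a noiseless
piecewise-constant image passes nearly unchanged because its finest-band
median absolute deviation is close to zero. The shrinkage rule and the
number of scales (default 3) are exposed in the configuration; the method
is robust to both.

Poisson noise is not white — its variance tracks intensity — so the MAD
estimate is an effective compromise, not an exact model. A variance
stabilizing transform would be the next refinement.

## Segmentation: SVM on multiscale Laplacian features

`compute_feature_bank()` computes scale-normalized isotropic
Laplacian-of-Gaussian responses at scales {1, 2, 4, 8} px plus the raw
intensity. Isotropy matters: the filters commute exactly with 90°
rotations on square grids (tested), so the classifier cannot latch onto a
preferred orientation. `train_segmenter()` fits a linear-kernel SVM with
class-balanced weights on a balanced random sample of labeled pixels
(2000 per class per image by default) with stored per-channel z-score
normalization, so intensity rescaling between acquisitions is absorbed.
Training runs once per imaging condition; prediction uses the primal
weight vector directly, which makes whole-image classification a single
matrix product. Components below 20 px² are removed as speckle — small
enough to never delete a 6 px-wide neurite of any meaningful length.

The kernel and cost are configurable; the linear default is deliberate:
with LoG features the classes are nearly linearly separable, and a linear
model is fast, convex and reproducible.

## Soma extraction: Directional Ratio + level set

The Directional Ratio at location p is the ratio of the minimum to the
maximum magnitude of the directional filter responses over orientation.
It is computed **on the binary segmentation mask**, not on intensities,
so it measures shape only. The package realizes the directional filters
at a prescribed support length as oriented averaging kernels (length 20
or 40 px, width 3 px, 12 orientations). This choice is forced by the
binary input: a zero-mean band-pass filter responds with 0 in any
constant region, so min/max over orientation would be 0/0 exactly at soma
centers — where the statistic must be near 1. With averaging kernels the
behavior is the classical one: every orientation of a 20 px kernel fits
inside a 40 px soma the same way (ratio ≈ 1), while across a 6 px neurite
the kernel is mostly empty (ratio ≈ width/length ≈ 0.3).

Thresholding at `dr_threshold = 0.9` (with `seed_min_area = 50` px²)
yields regions strictly inside each soma. These initialize a multi-front
evolution with speed `v = max(0, M − |∇D|)` (gradient by central
differences, D taken as 0 outside the mask, M the maximum gradient
magnitude over the mask): fronts move fast where D is flat (soma
interiors) and stall where D changes rapidly (soma boundaries and the
segmentation edge).

Numerics: the monotone evolution `∂φ/∂t = v|∇φ|` with `v ≥ 0` is solved
by a first-order upwind fast-marching scheme — each pixel's arrival time
satisfies the discrete eikonal equation `|∇T| = 1/v`, pixels are accepted
in increasing time order, and each inherits the label of the upwind
neighbor that determines it (simultaneous claims go to the lower label,
making the evolution fully deterministic; fronts freeze where they meet).
The time-stepped stopping rule is then applied on the arrival-time
histogram: with the CFL-bounded step `dt = 0.5/max(v)`, evolution stops at
the first simulated iteration where the labeled area grows by less than
1e-3 (relative) over 10 iterations, or at 500 iterations. For constant
speed this reduces to a geodesic-distance Voronoi partition of the mask,
which the tests verify against an independent Dijkstra oracle.

In practice the fronts still creep some distance into neurites before the
stopping rule fires (the speed field slows them there but does not
vanish). Each label is therefore cleaned by a morphological opening with
a disc of radius `open_radius = 5` px — larger than half a neurite width,
much smaller than a soma — keeping the component that contains the seed.
This is the one place the pipeline uses the blob-vs-tube prior directly
rather than through the Directional Ratio.

## Clustered somas: the 3-σ rule and the coarse scale

Somas in a homogeneous culture are assumed to have Normally distributed
areas; `fit_area_model()` estimates (µ, σ) and runs a one-sample
Kolmogorov–Smirnov check, warning (not aborting) on rejection — the rule
is a heuristic and remains useful under mild non-normality. A region is
compatible with N somas if `|area − N·µ| ≤ 3σ`; the smallest compatible N
is kept, no compatible N sends the region to the nearest multiple, and an
over-sized region (`area > µ + 3σ`) is never assigned fewer than two.

Resolving the circularity between fitting and flagging: the configured
nominal model (µ = π·20² ≈ 1257 px², σ = 150 px²) makes the first
flagging pass; if at least three detections look single under it, (µ, σ)
are refit on those and the flags recomputed, with σ floored at 0.08 µ so
a coincidentally homogeneous sample cannot shrink the band into spurious
flags. The nominal values are simply the area of the nominal 40 px-diameter
soma and the spread induced by a ±10% radius variation.

Flagged regions are re-analyzed with 40 px filters (about one soma
diameter), where the high-ratio set concentrates into per-soma cores. One
subtlety: 0.9 is exactly the chord-to-filter-length ratio of a nominal
soma at this scale, so somas slightly under 40 px can have an *empty*
coarse superlevel set at the printed threshold. When fewer seed
components than the expected N appear, the threshold is relaxed in 0.02
steps (floor 0.78) until they do; the N largest components are kept, and
any split part smaller than µ/2 — typically a seed raised in leaked or
neck pixels — is merged into the neighboring part that reaches it first.
If no more than one seed can be found, the region is returned unsplit
with a warning, which also makes a falsely flagged single soma harmless.

A related boundary effect: within a few pixels of the mask boundary, a
40 px kernel sees similar partial coverage in every orientation, so the
ratio is spuriously high there at any scale. The scale-nesting property
(coarse superlevel sets contained in fine ones, splitting into more
components) therefore holds — and is tested — on the mask interior.

## The 3D pipeline

`preprocess_stack()` denoises each slice, equalizes per-slice contrast
(each slice rescaled so its 0.995 intensity quantile matches the
brightest slice's, gain capped at 4 — compensating the multiplicative
depth attenuation without amplifying signal-free slices without bound),
and smooths with a 3×3×3 Gaussian of σ = 0.6 voxels. The 2D detection
runs on the projection of the *raw* stack — equalization would amplify
background noise in the projection — while the equalized stack feeds the
surface and volume extraction.

Deblocking assigns each detected soma its 2D support dilated by 2 px;
colliding dilations go to the nearest original support, so substack
footprints are disjoint and not necessarily rectangular.

The surface measure is deliberately pseudo-3D: with 15–40 z-samples,
genuinely 3D directional atoms are not meaningful. In-plane directional
band-pass windows (12 orientations, one-sided in frequency so that the
coefficient magnitude is an envelope peaking *on* an intensity step
rather than straddling it) are combined with an axial low-pass, plus an
in-plane low-pass times a one-sided axial band for surfaces facing the
optical axis; in-plane extension is periodic and axial extension
symmetric. Surface strength is the geometric mean of the directional
energy at two consecutive dyadic scales — large only where coefficients
decay slowly across scale, the signature of a surface point — thinned by
non-maximum suppression along the local normal (from the smoothed
gradient) out to 3 voxels, which also removes the filters' secondary
ringing ridges (about 0.16 of the main ridge, 3–4 voxels off). Voxels
above `surface_threshold = 0.1` of the maximum strength are kept. The
axial band weight 0.5 was calibrated once so that the polar caps and
equatorial walls of a reference sphere phantom score comparably;
calibrating on ideal planes instead gives 0.64 and under-detects the
walls of oblate somas.

The bottom half of each substack (below slice ⌈n_z/2⌉) is recovered by
localized thresholding: each slice's threshold is the scalar mean
intensity over the masked region of the three successive slices centered
on it (clamped at the ends; strict `>`, so a uniform slice triple yields
an empty support), followed by hole filling and one erosion with a 3×3
cross. This works *because* the deblocking mask tightly encases the soma:
the mean mixes soma and background levels and lands between them.
`assemble_soma_volume()` closes and fills the detected surface slice by
slice in the top half, unions it with the bottom supports, and keeps the
largest 26-connected component; volumes are reported in voxels and µm³
(voxel size 0.28 × 0.28 × 1 µm by default, configurable).

## Validation metrics

`segmentation_scores()` implements TPR = TP/(TP+FN), the soma-normalized
false-positive rate FPR = FP/(TP+FN) — false detections expressed as a
fraction of true soma size, because on sparse neuronal images the
conventional FP/(TN+FP) is indistinguishable from zero — and the Dice
coefficient 2TP/(2TP+FN+FP). `pratt_fom()` sums `1/(1 + α d_i²)` over
detected boundary points (d_i the Euclidean distance to the nearest true
boundary point, α = 1/9) and normalizes by `max(N_I, N_B)`; the sum over
detected points is the standard convention and coincides with a sum over
true points whenever the counts match. Distances are computed in the
native dimension, so the same function scores 2D edges and 3D surfaces.

## The phantom module: what it does and does not emulate

Phantoms render ellipse/ellipsoid somas (radius ~ U(18, 22) px around the
nominal 40 px diameter) and constant-width stadium-tube neurites
(width 6 px in 2D, 5 px in 3D), background 0.05, soma intensity 1.0,
neurite intensity ≈ 0.55, then apply per-slice attenuation (0.93 per
1 µm slice in the 3D generator) and Poisson noise at
`photon_scale = 60` — a level at which denoising visibly matters (a
clear PSNR gain on a disk phantom) without overwhelming the signal.
Ground truth is computed from the noiseless geometry and never altered by
noise. All of these were fixed as the package's standard imaging
condition before the benchmark suites were frozen.

Not emulated: the microscope's point-spread function and spherical
aberration, intensity inhomogeneity *within* a soma, curved or branching
dendritic arbors (neurites are straight tubes), somas overlapping the
image border, and z-overlapping cells. Passing the phantom benchmarks
therefore demonstrates the pipeline's geometric and statistical logic —
seeds strictly inside somas, correct splitting of contiguous pairs, exact
counts, high overlap with truth — under controlled noise, but it does not
certify performance on real cultures, where segmentation quality and the
homogeneous-area assumption are the vulnerable points.

## Benchmark problem sizes

The test suite works at the sizes that exercise every code path while
staying comfortably reproducible on one CPU: 256² images for the 2D
pipeline (20-phantom count-recovery and Dice/TPR suite, 3–8 somas each,
up to two contiguous pairs), 160 × 160 × 20 stacks for the 3D volume
suite, 128³ for the ellipsoid surface benchmark, and 48²–128² grids for
the transform oracles. The acceptance script reproduces the ellipsoid
surface figure of merit at 128³.

## Known limitations

- The level-set stopping rule interacts with the opening cleanup: a soma
  genuinely shaped like a thick tube (width below ~10 px) would be
  eroded away. Such shapes violate the blob model the method is built on.
- The 3-σ machinery assumes one culture-wide soma size scale. Mixed
  populations (e.g. small interneurons among pyramidal cells) will
  mis-split or under-split: somas well below the fitted µ are simply not
  recognized as members of a cluster.
- The coarse-scale threshold relaxation assumes the flagged region really
  contains multiple somas of roughly nominal size; grossly over-sized
  single objects (debris, stitching artifacts) may be split.
- Surface detection assumes the top half of the soma is well contrasted;
  if attenuation is severe enough to defeat the gain-capped equalization,
  the volume falls back to little more than the bottom-half thresholding.
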