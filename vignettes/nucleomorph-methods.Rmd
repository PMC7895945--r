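---
title: "Methods: from nucleus images to GMV correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from nucleus images to GMV correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleomorph)
```

This vignette documents the models, numerical choices and limitations of
`nucleomorph`.  It states no empirical result that the test suite does not
itself compute.

## The pipeline in one paragraph

Cortical volumes are imaged longitudinally in two modalities: structural
MRI, analysed by deformation-based morphometry so that every voxel carries
a Jacobian determinant (local volume-change factor, the basis of gray
matter volume, GMV), and in vivo two-photon stacks of fluorescently
labeled cell nuclei.  From the nucleus positions four families of cellular
metrics are computed — physical tissue volume from the convex hull of
re-identified fiducial nuclei, nucleus counts, 3D nearest-neighbor (NN)
distances, and nucleus volumes with size-category fractions — each for the
whole stack and within 175-µm depth layers.  Per imaging position and
interval, the percent change of each metric is paired with the percent GMV
change inside the registered MRI mask, and random-intercept mixed models
quantify how much GMV variance the cellular metrics explain.

## Synthetic world

The generator is the package's ground truth; its defaults are the
conditions the pipeline is meant to emulate, chosen once:

* **Density.** Nucleus centroids follow an inhomogeneous Poisson process
  along depth with a hard-core minimum separation enforced by dart
  throwing to a Poisson-drawn target count.  The default profile is
  6.28e-5 nuclei/µm³ below 100 µm with a 0.35 sparse factor above
  (molecular layer), giving a depth-averaged 5.7e-5/µm³ — about 19,500
  nuclei in a 700-µm cube, matching the reported per-stack counts.  The
  hard-core distance defaults to 8 µm, roughly a small-nucleus diameter;
  with a ~12.9 µm mean NN distance at this density the hard core is a weak
  constraint, which is what in vivo nucleus fields look like.
* **Sizes.** A two-component lognormal mixture: glia median 600 µm³,
  neurons median 1450 µm³, neuron fraction 0.55, sdlog 0.2.  Note an
  internal tension: those medians already average to 1067 µm³, so no sdlog
  makes the mixture mean exactly the ~1054 µm³ anchor; with sdlog 0.2 the
  mean is ≈ 1089 µm³ (3 % high).  We keep the stated medians and document
  the gap rather than silently re-deriving them.
* **Longitudinal presets.** `study_preset("week12")` applies a −5 % volume
  change (isotropic affine about the box center, so hulls of corresponding
  points scale by exactly 0.95), 7 % cell loss and 1 µm fiducial
  re-localization noise; `"week1"` uses −1.26 % and 9 % loss.  Fiducials
  are exempt from cell loss: a fiducial is by definition a nucleus
  re-identified at every timepoint, so "lost fiducial" is a contradiction;
  loss acts on the remaining population.
* **Rendering.** Nuclei are anisotropic Gaussian blobs with per-axis sd =
  radius/2, peak decaying as exp(−z/L) with L = 200 µm (a typical
  two-photon attenuation length), plus constant offset, additive Gaussian
  noise (not Poisson–Gaussian; sufficient for pipeline testing), vessel
  cylinders carrying offset-only signal, and zeroed blankout planes.
* **MRI phantoms.** A smooth baseline volume is resampled through the
  inverse of a known deformation (affine or random-phase sinusoid field);
  the displacement u(x) is stored on the grid so that det(I + ∇u) is the
  exact local volume ratio.

What a green test establishes: that each algorithmic stage recovers known
ground truth under this model.  What it does not establish: performance on
real autofluorescent texture, sub-nuclear structure, depth-dependent laser
power ramps, or classifier-grade foreground probabilities — the
probability stand-in is deliberately simple, and real deployments are
expected to import externally computed probability maps.

## Segmentation chain

Seeds are per-plane 2D local maxima with value ≥ `foreground_threshold`
and a noise tolerance `h` (a maximum merges into a higher one reachable
through pixels above its value − h, FIJI-style), dilated in-plane and
linked across z by 26-connectivity.  The watershed is a priority flood on
the probability landscape restricted to the suprathreshold mask, with a
documented deterministic tie-break (raster index).  Objects below
`min_voxels` (default 1500, the standard false-positive filter at study
sampling) are removed; objects above `max_voxels` (default 18,000) are re-segmented once
inside their bounding box.

A design choice worth flagging: during re-segmentation *both* the
foreground threshold and the seed tolerance are scaled by
`reseg_threshold_factor` (default 0.8).  Lowering only the foreground
threshold can never split a merged pair whose second maximum was
suppressed by the seed tolerance, which is precisely the situation that
produces oversized objects; a lower watershed threshold is therefore read
as the watershed tool's seed/dynamic threshold as well.  The recursion depth is 1, and if re-segmentation yields no
part above the minimum size the original object is kept and flagged.

Centroids are unweighted voxel-set means.  On rendered Gaussian blobs the
exp(−2) isosurface of a blob equals the nominal nucleus boundary (since
sd = radius/2), which is how the acceptance test derives its segmentation
threshold analytically instead of tuning it.  Phantoms for recovery tests
keep nuclei ≥ 14 µm from the stack faces: border-clipped blobs have
centroid bias that says nothing about the segmentation itself.

## Hull volumetry

No computational-geometry package is assumed; the package carries its own
3D Delaunay triangulation: Bowyer–Watson incremental insertion with an
infinite vertex (hull faces as virtual cells, visibility as their
in-sphere predicate), the lifted 4×4 in-sphere determinant evaluated in
compiled code, per-axis normalization, and a deterministic symbolic-style
jitter applied only to predicate inputs.  Every triangulation is validated
(manifold face counts, every boundary face a supporting plane of the point
set, tetrahedra volumes summing to the divergence-theorem hull volume
within 1e-9 relative); validation failure escalates the jitter and
retries.  All reported volumes use the original, unjittered coordinates.

Layer volumes assign whole tetrahedra to depth bins by centroid z — no
clipping at bin boundaries — so individual layer volumes are approximate
while their sum is exactly the total.  Completeness filtering keeps only
fiducial ids present at every declared timepoint; fewer than 4 common ids
is an error, fewer than 30 a warning (the recommended minimum for reliable
hulls).  The baseline is the first declared timepoint unless overridden.
Duplicate coordinates within one timepoint are rejected as degenerate
rather than merged.

## MRI space

The cross-modal registration is a 2D affine fit (exact for 3 vessel
landmarks, least squares beyond) mapping the 700-µm stack footprint into
MRI in-plane coordinates; a voxel belongs to the mask iff its center falls
inside the transformed quadrilateral (center rule: deterministic and
brute-force checkable), and exactly three consecutive z planes from the
surface plane are occupied, confining GMV readout to superficial cortex.
Stack tilts are reduced to the surface-plane index; full oblique-box
rasterization is out of scope.  GMV change is 100 × the mean Jacobian
determinant over mask voxels (the determinant is the exact local volume
ratio on synthetic fields), with slicewise profiles per mask plane.
Jacobians use central differences in the interior and one-sided stencils
at borders, which are exact on linear (affine) fields.  The RARE
point-spread arithmetic evaluates
FWHM = 1.23 − 0.05 (Tk/T2) + 0.08 (Tk/T2)², with Tk = RARE factor × echo
spacing.

## Quality control

SNR is the signal-ROI mean over the background-ROI standard deviation
(n−1); comparability between timepoints requires every one of at least 3
paired reference areas to stay within 10 %.  The z-density-profile score
evaluates Gaussian kernel densities of the nucleus depths on a common
512-point grid over [0, 700] µm, scales each by its nucleus count to
cells-per-µm, and integrates the absolute difference (trapezoid rule); the
unit is cells, which makes the flag threshold of 500
dimensionally sensible against ~19,500 cells per stack.  One common
Silverman bandwidth is computed from the pooled depths of both tables so
that nuclei present in both cancel exactly — with per-table bandwidths the
shared mass does not cancel and the score loses its cells interpretation.
Blankout planes are those whose mean falls below 5 % of the median plane
mean.  Homogeneity screening remains a manually set flag; no automatic
detector is claimed.

## Longitudinal statistics

Models are `response ~ fixed terms + (1 | animal)` fitted by REML (lme4),
reflecting positions nested in animals; a single animal falls back to
ordinary regression with a warning.  Fixed-effect p-values are Wald t with
residual degrees of freedom n − rank(X); rather than committing to a
particular df convention, the acceptance suite verifies the resulting
95 % CI coverage (93–97 %) and type-I error (3–7 %) by simulation rather
than by appeal to any particular df convention.  R² is the marginal
(fixed-effects) flavor, var(Xβ) over the sum of fixed, random-intercept
and residual variances, configurable to conditional.  VIFs are
1/(1 − R²_j) from regressing each predictor on the rest.  Pairwise
timepoint contrasts use cell-mean coding with Holm correction by default
and a studentized-range (Tukey) option for the repeated-measures
descriptive analysis, which is also provided as a classical blocked ANOVA
with Tukey HSD.  One-sample tests of percent changes against the
theoretical 100 % choose between the t-test and the Wilcoxon signed-rank
test by a Shapiro–Wilk pre-check (exact Wilcoxon below n = 25 without
ties, continuity-corrected normal approximation otherwise).

## Numerical and degenerate-input conventions

* Depth bins are half-open [a, b), last bin closed; a value exactly on an
  edge belongs to the upper bin.  Size categories likewise, with volumes
  above 3000 µm³ counted separately as overflow.  The three lower size
  category edges (750/1500/2250) are equal-width choices consistent with
  the largest category spanning 2250–3000 µm³.
* Constant stacks map to all-zero probability; empty seed sets produce an
  empty labeling with a warning; an empty nucleus table is allowed for
  counting (zeros) but an error for volume and NN statistics.
* Arrays are (z, y, x) with z = 0 at the tissue surface; TIFF pages are z
  planes; NIfTI files are written x-fastest with displacement components
  stored (z, y, x) in µm.
* Same seed, same output, bit-identical — the generators consume the seed
  through R's RNG only, and the geometry code keeps predicate jitter
  deterministic and RNG-free.

## Known limitations

The probability stand-in is not a classifier; deep-tissue contrast loss
is modeled only as exponential peak decay; vessel shadows are ideal
cylinders; the MRI phantom resamples a smooth synthetic volume, not a
brain; no fiducial re-identification is automated (matched ids are input
data); and real-data group coefficients are not reproducible here because they
require the original imaging data — the package's claims are recovery of
known synthetic ground truth at stated tolerances.
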