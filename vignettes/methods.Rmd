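---
title: "Segmenting rodent abdominal fat depots: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting rodent abdominal fat depots: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abdofat)
```

## The problem and the intensity model

On fast spin echo abdominal images of rodents, subcutaneous (SAT) and
visceral (VAT) adipose tissue are both hyper-intense, the abdominal
muscle wall between them is iso-intense, organs are hypo- to iso-intense,
and the air background is dark. Intensity alone therefore separates *fat
from non-fat* but not *SAT from VAT*: the only reliable separator is the
muscle wall, a thin closed ring. The pipeline makes this anatomical
assumption explicit and is organized around it:

1. find the body (pre-processing + adaptive mask),
2. find the wall (automatic initialization + hybrid curve evolution),
3. classify fat on each side of the wall (fuzzy C-means + merging),
4. strip skin and wall remnants from SAT,
5. convert voxel counts to volumes and masses.

Everything is two-dimensional and applied slice by slice; the slice stack
only enters through the final volume integration and the optional pooled
clustering mode.

## Curve evolution to the muscle wall

The contour is represented implicitly as the zero level of a signed
distance field $\phi$ (negative inside). Its outward normal speed is

$$F = g(x)\,[\,\beta + R(x)\,] - \mu\, g(x)\, \kappa(x),$$

with $g = 1/(1+|\nabla (G_\sigma * I)|^2)$ the geodesic edge-stopping
map, $\beta$ a constant balloon pressure, $\kappa$ the level-set
curvature, and the local-region force

$$R(x) = \frac{(I(x)-v_x)^2 - (I(x)-u_x)^2}{(u_x-v_x)^2+\varepsilon},$$

where $u_x$ and $v_x$ are the mean intensities of the interior and
exterior portions of a radius-$r$ ball around $x$ (computed for the whole
grid at once by masked convolution; an empty side falls back to the
pixel's own intensity). $R$ is positive — pushes outward — when the pixel
resembles the exterior more than the interior, and its normalization
makes it an $O(1)$ quantity; we additionally clamp it to
$\pm$`region_clamp` because in noisy homogeneous regions both the
numerator and the denominator are noise-scale and their ratio is
otherwise unbounded. The balloon drives expansion through the interior;
the region force pins the front where local means genuinely separate,
which on this anatomy is the muscle wall.

Two behaviours of this force law are worth knowing. First, bright VAT
blobs also present a local-means boundary, so the front can wrap around a
blob and leave it as an exterior island; the pipeline therefore defines
the VAT side as the *hole-filled* interior of the converged contour,
which swallows such islands. Second, the equilibrium face of the wall
depends on what backs it: where bright VAT lines the wall the front stops
at the inner (VAT/wall) face, where dark organs back it the front walks
through the iso-intense wall and stops at the outer (wall/SAT) face. Both
are inside the wall ring, so the SAT/VAT side split is correct either
way; the consequence for stripping is discussed below.

Termination follows an area-change rule: the enclosed area is recorded
every `check_interval` iterations and evolution stops when it changes by
fewer than `area_tol` pixels (default 10, the working example value)
between checks, or at `max_iters`. A vanishing contour and contact with
the image border are hard errors rather than silent outcomes, because
both indicate initialization or contrast failures the user must see.

### Numerical scheme

The advective part of $F$ uses the Osher–Sethian upwind gradient, the
curvature part central differences; the time step (0.25 by default) keeps
$|F|\,\Delta t$ below one pixel per iteration given the clamp. Curvature
is the standard divergence form with an $\varepsilon$-regularized
denominator; on an exact signed-distance circle of radius $r$ it
reproduces $1/r$ to a few percent at $r \ge 20$ px.

$\phi$ is periodically reinitialized (every 20 iterations) by the
redistancing PDE $\phi_t = \mathrm{sign}(\phi_0)(1-|\nabla\phi|)$ with a
Godunov Hamiltonian and *subcell interface anchoring*: cells straddling
the zero crossing relax toward the fixed estimate
$\phi_0/|\nabla\phi_0|$ instead of being advected. Without the anchoring,
redistancing carries a small curvature-proportional inward drift that
accumulates over hundreds of iterations; with it, redistancing leaves the
interface in place to sub-pixel accuracy, which the test suite checks via
the curve-shortening rate ($dA/dt = -2\pi$) of a pure curvature flow.
Signed distance fields constructed from binary masks use the Euclidean
distance transform (half-pixel centered) followed by the same
redistancing pass to smooth orientation-dependent ripple.

## Initialization

The initial contour is the traced body edge (Moore boundary tracing,
8-connected) scaled about its own centroid by `shrink_scale` and
translated to the slice center. The default 0.80 is the midpoint of the
empirically useful 0.75–0.85 range; values outside it are accepted with a
warning, since unusually thick subcutaneous rings can require stronger
shrinkage. Scaling about the contour centroid (rather than the image
center) makes the construction translation-equivariant, and a
`mask_centroid` placement mode exists for animals positioned off-center,
where slice-center placement could break containment. Rasterization of
the scaled polygon includes the polygon's own boundary pixels: the traced
chain runs through pixel centers, so an interior-only fill would bias the
enclosed area low by about half the perimeter (Pick's theorem); with the
boundary included the enclosed-area ratio of a scale-$s$ shrink is $s^2$
to well within a percent on convex shapes.

## Pre-processing defaults

| stage | parameter | default | rationale |
|---|---|---|---|
| normalization | clip percentiles | 0.5% / 99.5% | hot-pixel robustness without flattening tissue contrast |
| background | threshold | 0.05 of normalized range | suppress air speckle only |
| diffusion | iterations, $\kappa$, $\Delta t$ | 15, 0.1, 0.2 | smooth within-tissue noise, preserve edges ($\Delta t \le 0.25$ is the 2-D stability bound; the flux-form stencil conserves the mean exactly and never raises total variation) |
| enhancement | unsharp gain, $\sigma$ | 0.6, 1 px | restore edge strength after diffusion |
| body mask | — | Otsu on nonzero pixels + hole fill + largest component | deterministic and parameter-free; hole filling keeps hypo-intense organs in the body |

## Clustering, merging and stripping

Each side of the converged contour is clustered by fuzzy C-means on
intensities with the empirical class counts 3 (SAT side) and 5 (VAT
side), fuzzifier $m = 2$, tolerance $10^{-5}$ on centroid movement.
Initialization is deterministic — centroids start at evenly spaced
quantiles — so results are reproducible without a seed; a seed only adds
an optional jitter. Defuzzification takes the maximum membership, ties
breaking toward the brighter class (fat is the bright phase). Clustering
is per-slice by default; a pooled mode clusters all slices' voxels
jointly and applies the shared centroids per slice, for stacks with
coherent intensity scales.

Merging starts from the brightest class as the fat anchor and admits
classes whose mean lies within `intensity_gap` (default 0.15) of the
anchor *and* whose region touches the anchor's region. The adjacency
requirement excludes bright but detached structures; the gap excludes the
iso-intense wall and the organs.

Stripping removes from the SAT fat mask a `skin_depth` band (2 px) inside
the body boundary and a `wall_depth` band (2 px) around the converged
contour. Because the contour may legitimately sit at either face of the
wall (see above), a purely geometric wall band can overlap true
subcutaneous fat; the pipeline therefore restricts the band to voxels of
wall-like intensity, using as the ceiling the midpoint between the
dimmest merged (fat) class and the brightest excluded class of the
SAT-side clustering. This guard is exactly the pipeline's own contrast
assumption — the wall is iso-intense — applied once more at the stripping
stage; calling `strip_skin_wall()` without intensities reproduces the
purely geometric behaviour.

## The phantom: what it emulates and what it does not

`make_phantom()` builds, per slice, an elliptical body (semi-axes 76 × 64
px in a 192 px field by default, tapering 2 px per slice), a 2 px skin
line, a 6 px SAT ring, a 3 px muscle wall — ring depths measured as true
Euclidean depth from the body edge, so thicknesses are uniform along the
boundary — and an organ-filled interior with 6 circular VAT blobs (radius
6–10 px) placed to clear the wall. Intensity means follow the qualitative
contrast ordering of the imaging model (background 0.05, organ 0.35, wall
0.45, skin 0.8, VAT 0.85, SAT 0.9); a multiplicative low-frequency bias
field (amplitude 0.1) and Rician noise ($\sigma$ = 0.03) are applied on
top, and the noise-free assignments are the ground-truth labels. The
geometry was chosen once so that the 0.8-shrunk body contour starts
strictly inside the wall, as the initialization contract requires; 0.2 mm
pixels and 1.6 mm slices mirror typical small-animal scan geometry at a
reduced matrix size that keeps test runtimes in seconds per slice. The
skin is drawn fat-bright deliberately, so that skin stripping is
exercised rather than vacuous. A `skin_fold` mode erases the wall over an
angular sector, reproducing the known failure mode in which skin folding
or abdominal compression leaves SAT and VAT with no intensity separation;
it exists for documented-failure tests, not for accuracy claims.

Paired pre/post series rescale the SAT ring thickness (solved against the
actual rasterized voxel counts) and the VAT blob radii (by
$\sqrt{1+\delta}$) around shared anatomy, so programmed fractional depot
changes are realized in ground truth to within rasterization error.

What the phantom does *not* emulate: partial-volume mixing at tissue
boundaries (edges are crisp), chemical-shift and motion artifacts,
anatomical irregularity of real organs and fat lobules, and
through-plane continuity of real depots. Near-perfect recovery on
phantoms therefore demonstrates the pipeline's internal consistency under
its stated intensity model — not clinical-grade accuracy on real scans,
where partial volume and anatomy will lower overlap scores.

## Fuzzy-clustering recovery under inhomogeneity

With a multiplicative bias field of amplitude 0.1, a tissue's voxel
intensities span a range wider than the noise scale, and fuzzy C-means
may split one tissue across two classes. Per-class centroid matching is
then the wrong statistic: the meaningful statement is per *intensity
compartment* — the size-weighted mean of the fat-candidate (bright)
centroids should recover the realized mean of the fat compartment, and
likewise for the dim compartment. The acceptance suite asserts this
compartment-level recovery within the noise scale; the strict per-tissue
statement (nearest centroid within $\sigma$ of the configured mean) is
asserted on bias-free phantoms, where it is well-posed.

## Degenerate inputs and edge behaviour

Constant slices normalize to zero and are fixed points of diffusion and
enhancement; all-zero slices raise "no body detected"; fewer distinct
intensities than classes is a clustering error; an empty pre-scan depot
makes percent change undefined (signalled, not NaN); empty-vs-empty
masks score Dice 1 by convention; `max_iters = 0` returns the initial
field untouched with `stop_reason = "max_iters"`. Slice-level pipeline
failures are collected per slice with the slice index and reported,
rather than aborting the remaining slices; the CLI exits nonzero if any
slice failed.

## Problem sizes used in the checks

The automated checks run the full pipeline on ten 3-slice 192 px default
phantoms, one paired series (+18% SAT / −15% VAT), diffusion invariants
on one hundred random 64 × 64 images, and initialization geometry on
twenty random convex masks — a few minutes in total on one CPU. These
sizes are the package's validation conditions, chosen to make each check
statistically meaningful at interactive runtimes.

## Known limitations

- The wall is found per slice; no 3-D regularization links contours
  across slices.
- Where skin folding or compression removes the intensity separation
  between SAT and VAT, the contour has no boundary to converge on; the
  `skin_fold` phantom mode reproduces this, and such slices need manual
  exclusion, as the hard-error policy makes explicit.
- No bias-field correction is applied; strong inhomogeneity (well beyond
  the default 0.1 amplitude) will eventually break the merge rule's
  single intensity gap.
- DICOM series are not read directly; convert to NIfTI or the CSV +
  JSON-sidecar array format first.
- The exact local-region energy is one committed interpretation of a
  hybrid geodesic/region scheme; all of its constants are configuration,
  not hard-coded truth, and the defaults are validated only under the
  phantom's conditions.
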