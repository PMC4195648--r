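# abdofat

Fully automatic segmentation and quantification of subcutaneous (SAT) and
visceral (VAT) adipose tissue in transverse abdominal MR slices of
rodents.

Quantifying how the two abdominal fat depots respond to an intervention
(diet, exercise, drug) is a standard endpoint in preclinical obesity
research. On fast spin echo images both depots are hyper-intense, so
intensity alone cannot separate them; what does separate them is the
iso-intense abdominal muscle wall running between the subcutaneous ring
and the visceral compartment. `abdofat` finds that wall automatically and
turns a slice stack into per-depot volumes (ml) and masses (g), with no
manual contouring.

## Method

For each slice:

1. **Pre-processing** — robust min–max intensity normalization
   (0.5th/99.5th percentile clipping), background suppression,
   Perona–Malik anisotropic diffusion
   (`u_t = div( g(|∇u|) ∇u )`, with exponential or rational conductance
   `g`), unsharp edge enhancement, and a body mask from Otsu thresholding
   of the nonzero pixels plus hole filling and largest-component
   selection.
2. **Automatic initialization** — the traced edge of the body mask is
   shrunk about its centroid by a factor `s ∈ [0.75, 0.85]` (default
   0.80) and placed at the slice center, guaranteeing a starting contour
   inside the abdominal cavity, away from the strong background edge. It
   is embedded as a signed distance field `φ` (negative inside).
3. **Hybrid geodesic/local-region curve evolution** — the contour expands
   with outward normal speed

   `F = g(x) · [ β + R(x) ] − μ · g(x) · κ(x)`

   where `g = 1 / (1 + |∇(G_σ ∗ I)|²)` is the geodesic edge-stopping map,
   `β` a balloon pressure, `κ` the level-set curvature, and
   `R(x) = ((I − v_x)² − (I − u_x)²) / ((u_x − v_x)² + ε)` the local-region
   force built from the interior/exterior mean intensities `u_x`, `v_x`
   in a ball around each contour point. The front expands through the
   visceral compartment and pins where the local means separate — at the
   muscle wall. Evolution stops when the enclosed area changes by fewer
   than `area_tol` pixels (default 10) between successive checks.
4. **Fuzzy C-means + region merging** — voxels outside the converged
   contour (SAT side) are clustered into 3 classes, voxels inside (VAT
   side) into 5; classes within an intensity gap of the brightest class
   that touch its region are merged into the fat mask.
5. **Skin/wall stripping** — a skin-depth band inside the body boundary
   and a wall band around the converged contour (restricted to voxels of
   wall-like intensity) are removed from SAT.
6. **Quantification** — `volume = voxels × pixel_area × slice_thickness`,
   `mass = 0.9 g/ml × volume`, with per-slice breakdown, paired pre/post
   percent change, and Dice scoring against reference labels.

Because no animal scans ship with the package, a synthetic phantom
generator (`make_phantom()`) reproduces the geometry the algorithm
assumes — elliptical body, skin line, SAT ring, muscle wall, organ
interior with VAT blobs, multiplicative bias field, Rician noise — with
voxel-exact ground-truth labels, so the whole pipeline is testable and
its accuracy measurable.

## Worked example

```r
library(abdofat)

ph  <- make_phantom(phantom_spec(seed = 1))   # 3-slice synthetic scan
seg <- segment_volume(ph$volume)              # full pipeline
print(seg)
#> Abdominal fat segmentation
#> Adipose depot quantification
#>   SAT: 0.4564 ml, 0.4108 g
#>   VAT: 0.2095 ml, 0.1885 g
#>   density 0.9 g/ml, 3 slice(s)
#>   3 slice(s) segmented

print(seg$traces[[2]])
#> Curve evolution: 30 iteration(s), stop: area_converged
#>   areas at checks: 9870, 10390, 10968, 11243, 11272, 11272

dice(seg$labels, ph$labels)[c("SAT", "VAT")]
#> SAT VAT
#>   1   1
```

The report says the phantom carries 0.46 ml (0.41 g) of subcutaneous and
0.21 ml (0.19 g) of visceral fat; the trace shows the contour expanding
(enclosed area 9870 → 11272 px) until the area change between checks
drops below 10 px and evolution stops; and both recovered depots agree
voxel-for-voxel with the ground truth on this phantom.

Label volumes are written as NIfTI-1 with the coding 0 background, 1 SAT,
2 VAT, 3 skin/wall, 4 organ (row-major in-plane indexing, slice axis
last). Volumes can be read from NIfTI or from a plain CSV + JSON-sidecar
array format (`read_volume()`, `write_volume_sidecar()`).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "abdofat", package = "abdofat"))')
Rscript $CLI phantom --out-dir ph --seed 7
Rscript $CLI segment --input ph/phantom.json --out-dir seg
Rscript $CLI compare --pre seg_pre/labels.nii --post seg_post/labels.nii --out change.csv
```

`segment` writes `labels.nii`, `quant.csv`, `evolution_trace.csv` and a
`run_manifest.json` recording every parameter used; runs are bit-for-bit
reproducible for a fixed config and seed. Defaults can be overridden by a
JSON config file (`--config`), with unknown keys rejected.

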