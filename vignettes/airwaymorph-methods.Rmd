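---
title: "Automated small-airway, collagen and emphysema morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated small-airway, collagen and emphysema morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Histological assessment of airway remodeling is classically done by
semi-quantitative scoring: an investigator grades epithelial damage or
inflammation on an ordinal scale. That is observer-dependent and loses the
continuous structure of the change. `airwaymorph` replaces it with a fully
automatic numerical analysis of whole-section scans, producing per-object
measurements in micrometres that can be aggregated per animal and compared
across exposure groups.

Three readouts are implemented, mirroring the tissue compartments of a
murine lung section:

* the **small bronchioles** (no cartilage, no smooth-muscle sheath) on H&E,
* the **peribronchial collagen** on a picrosirius-red (PSR) serial section,
* the **parenchymal airspaces** for emphysema, after removing bronchi and
  vessels.

# Calibration and image model

All geometry is computed in pixel space and converted once through the
scalar calibration `um_per_px`. The default, 0.452 µm/px, is the pixel size
of a ×20 whole-slide scan; it is overridable per image (`loadImage()`,
`--um-per-px`). Pixels are 8-bit RGB; deeper inputs are linearly rescaled on
load so the full input range maps to 0–255. Pixel centers sit at
(index − 0.5), so a segment spanning k pixels measures exactly
k·`um_per_px` µm — the calibration round-trip is exact by construction and
is asserted in the tests.

## Tissue segmentation

Slide glass is bright in all three channels while any stain pulls at least
one channel down. A pixel is background when min(R, G, B) > 220 of 255;
the mask is cleaned by a morphological closing (disc, radius 2 px) and
connected components smaller than 50 µm² are dropped as specks. These three
constants are exposed as arguments of `segmentTissue()`. Large sections can
be processed tile-wise with a 64 px overlap; because thresholding and
closing are local, the tiled result equals the whole-image result (speck
removal runs globally after merging), which the tests assert exactly.

PSR-positive collagen is separated by colour: a pixel is chromogen when its
hue lies in a window around red (default −20° to +25°) with HSV saturation
above 0.25, and it lies inside the tissue mask. Full stain deconvolution
was deliberately not used: the hue window is simpler, sufficient for
phantom-validated operation, and swappable behind `separatePsr()`.

# Bronchiole detection

A small bronchiole appears as a lumen — an enclosed background region —
surrounded by a contiguous epithelial ring. Detection proceeds:

1. **Lumen finding.** Enclosed background components of the raw tissue mask
   are closed-ring lumen candidates. To also catch rings interrupted by a
   sectioning artifact, the mask is additionally closed morphologically
   (radius 40 µm); enclosed holes that exist only in the closed mask are
   open-ring candidates, flagged `closed_ring = FALSE`. Arc gaps up to
   roughly 30° on a 200 µm bronchiole are bridged. Lumina with Feret
   below 50 µm are not considered (alveolar scale).
2. **Internal limit.** The lumen boundary is traced sub-pixel by marching
   squares on a Gaussian-smoothed copy of the mask (σ = 1.5 px, iso-level
   0.5). Smoothing suppresses the pixel-staircase inflation of perimeters;
   without it the circularity of a true circle would systematically read
   ≈ 0.90 instead of 1.00.
3. **External limit.** 360 rays are cast from the lumen centroid at 1°
   spacing. Per ray, the wall is the contiguous tissue run beyond the
   internal crossing, capped at a maximum wall thickness (60 µm) so growth
   cannot bleed into parenchyma; the run endpoints form the external
   (basal-membrane) contour. Whether the original instrument measured along
   contour normals instead is unknowable from its description; centroid
   rays are simple, deterministic, and exact on the annular phantoms.
4. **Ring gates.** Three configurable gates separate genuine ringed lumina
   (bronchioles, vessels) from parenchymal holes:
   * *solid wall*: ≥ 80 % of rays must meet a wall ≥ 8 µm thick — alveoli
     are bounded by thin shared septa and fail;
   * *bounded wall*: ≤ 10 % of rays may reach the 60 µm cap without finding
     an outer limit — a hole in a solid tissue block has no wall to bound;
   * *wall regularity*: the coefficient of variation of per-ray wall
     thickness must not exceed 0.35 — true walls are nearly uniform around
     the lumen, merged airspaces are not. An eccentric annulus with a 5 µm
     lumen offset on a 20 µm wall has CV ≈ 0.18 and passes comfortably.
5. **Selection.** Small bronchioles are those with external Feret diameter
   in the inclusive window [100, 500] µm and a closed ring. The bound
   inclusivity is a package decision (the size rule is stated as a range
   without specifying openness); open rings can be admitted with
   `keep_open_rings = TRUE`, but circularity and thickness are ill-defined
   on them, so they are excluded by default. No explicit smooth-muscle
   detector exists; the size window plus the ring gates are the operative
   filter.

A measurement caveat at the window bounds: a disc rasterized at exactly
500 µm genuinely extends about one pixel past the analytic circle, so its
measured Feret is ≈ 500.5 µm and it falls outside the window. Retention at
the exact bounds is therefore a property of the filter contract (tested on
constructed candidates with exact Feret values), while raster sweeps test
sizes resolvable at pixel precision.

# The morphometric panel

Per selected bronchiole (`measureBronchioles()`):

* areas by the shoelace formula on the sub-pixel contours; the epithelium
  area is the exact difference bronchiole − lumen (it may legitimately be
  smaller than the lumen area in thin-walled airways);
* epithelium thickness as mean ± SD of the per-ray wall widths (360 rays;
  rays failing to cross both contours are dropped; fewer than 100 valid
  measures flags the record unreliable rather than erroring);
* circularity 4π·Area/Perimeter² of both limits. Rasterization can push a
  traced circle marginally above 1; values are stored raw and clipped to 1
  only in the written CSV report;
* Feret diameter as the maximum pairwise distance over the convex hull of
  the external contour.

On phantom annuli the panel recovers areas within 0.1 %, thickness within
0.2 %, and disc circularity within 0.01 of 1.

# Peribronchial collagen

The analysis band is the annulus between the external contour and its
outward offset by `band_width_um`, rasterized via a distance transform,
clipped to tissue and excluding every bronchiole interior (including
neighbours). **Band width is the dominant free parameter of this
measurement**: the spatial extent of "peribronchial" is not standardized,
so the default of 25 µm is a package choice — roughly one epithelial wall
width — and results should be reported together with it. The collagen
content is 100·PSR/(epithelium + PSR) percent, which is bounded in
[0, 100], zero exactly when no chromogen falls in the band, and strictly
increasing in the PSR area.

Serial sections are supported two ways: bronchioles detected directly on
the PSR slide (same-image mode; the external limit then stops where the
chromogen begins, so the collagen band is not swallowed into the wall), or
contours from the H&E slide mapped by a user-supplied 2×3 affine transform.
Automatic registration is out of scope.

# Emphysema

Bronchi and vessels must not be counted as airspaces. Every detected
ringed-lumen structure is removed from the analysis region (external
contour dilated by 10 µm): structures inside the bronchiole window with a
closed ring and wall-to-lumen area ratio ≤ 2 are logged as bronchioles, the
rest (too large, too small, open, or thick-walled — the vessel signature on
H&E, where no specific vessel stain is available) as vessels/large airways.
Airspaces are then the enclosed background regions of the remaining
parenchyma, each at least 20 µm² (artifact floor; no biological minimum is
imposed), excluding regions touching the image border or abutting a removal
(truncation bias). Alveoli and ducts are pooled — the readout does not
attempt to separate them.

The summary reports airspace density as airspace area ÷ parenchymal
*tissue* area. The alternative convention airspace ÷ (airspace + tissue) is
computed alongside (`density_fraction`) so the ratio convention is always
explicit in the output. Feret diameters of airspaces are measured on traced
sub-pixel contours (pixel-corner fallback for specks).

The qualitative emphysema signature — density and diameter up, count down —
is exercised by `dilationSeries()`: the same foam scene with airspace radii
scaled by increasing factors, merging handled in the ground truth by
connected components.

# The phantom generator

`phantomSpec()` declares a scene: annular bronchioles (optionally with an
arc gap or an eccentric lumen), thick-walled vessels, collagen bands with
partial arc coverage, and a foam of non-overlapping circular airspaces
placed by seeded rejection sampling with a minimum septal separation.
Palettes are chosen to exercise the segmentation thresholds (H&E:
epithelium pink-purple, septa pink, background white; PSR: collagen
saturated red, other tissue pale yellow). Additive Gaussian pixel noise and
the seed are part of the spec; noise is off by default so exactness tests
stay exact, and the same seed and spec are byte-reproducible without
disturbing the caller's RNG stream.

What the phantom does *not* emulate — and hence what passing tests do not
show about real slides: staining variability and stain overlap, blur and
chromatic aberration, tissue folds and debris, non-circular airway
cross-sections, smooth-muscle or cartilage texture, and true alveolar
septal networks (the foam is holes-in-tissue, not a septal skeleton).
Phantom recovery demonstrates the geometry engine is unbiased; threshold
robustness on real material must be established per staining protocol.

Problem sizes used in the shipped tests were chosen to keep the suite
fast while exercising every code path: single-annulus scenes at the ×20
scale, a 50-bronchiole grid and a 250-airspace foam at 1 µm/px, and an
80-airspace dilation series.

# Group statistics

The statistical unit is the **animal**: objects within an animal are
averaged before testing (`aggregateByAnimal()`), avoiding pseudoreplication
when sections contribute many bronchioles. Per-object testing remains
available as an explicit override. Groups are compared by one-way ANOVA
with Bonferroni-adjusted pooled-SD pairwise t tests — the adjusted p is
exactly min(1, m·p_raw) over m comparisons — or by Kruskal–Wallis with
Bonferroni-adjusted pairwise Wilcoxon tests; the choice is caller-specified
per metric, since which metrics warrant a non-parametric treatment depends
on the data at hand. Results carry mean ± SEM per group and stars at
p < 0.05/0.01/0.001/0.0001. Degenerate input (all groups constant and
equal) reports non-significance with a warning instead of failing.

# Numerical choices and degenerate inputs

* Marching squares at iso-level 0.5 on σ = 1.5 px Gaussian-smoothed masks;
  the tracing pad exceeds the blur support so the FFT filter's wrap-around
  never reaches an object.
* Ray–polygon intersection takes the crossing nearest the origin per
  contour (relevant for non-star-shaped lumina; a documented limitation of
  the centroid-ray method), with an inclusive treatment of hits exactly at
  polygon vertices.
* Self-intersecting contours are rejected with a geometry error where the
  user supplies polygons; traced contours are simple by construction.
* Zero-perimeter contours, negative areas, empty masks, fully-background
  images, and empty candidate lists all follow the contract: warnings and
  empty results where the input is merely uninformative, errors where it is
  inconsistent.

# Known limitations

* Vessel discrimination uses geometry only (size, wall ratio, ring gates);
  on real H&E it will misclassify some vessels as airways and vice versa —
  the removal log exposes every decision for audit.
* The external-limit ray method assumes approximately star-shaped airways;
  deeply folded epithelium would need normal-based growth.
* Same-image PSR detection requires the lumen-epithelium contrast to
  survive the PSR counterstain; heavily collagen-encircled airways are
  better handled with the affine serial-section mode.
* The wall-regularity gate (CV ≤ 0.35) may reject airways with genuinely
  erratic wall thickness; raise `max_wall_cv` when studying severe
  remodeling.
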