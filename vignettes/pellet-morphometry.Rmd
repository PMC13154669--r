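---
title: "Quantifying two-species pellet populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-species pellet populations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletpop)
```

## The measurement problem

Filamentous microorganisms in submerged culture grow as compact pellets:
*Aspergillus niger* forms large (hundreds of micrometres to millimetres)
spherical pellets with a single dense, dark core surrounded by a loose,
bright hyphal corona; *Streptomyces coelicolor* forms much smaller pellets
(around 250 µm) with a proportionally larger dark centre, and can fuse into
irregular multi-lobed aggregates. In co-culture, neither cell dry weight nor
metabolite profiles resolve which species is growing; the pellet morphology
does. `pelletpop` turns stereo-microscopy images of diluted culture samples
into per-species population statistics: counts, number-frequency (q0) size
distributions, D10/D50/D90 percentiles, the normalized span width, and the
aggregation frequency of the bacterial population.

## The pipeline

Each image passes through a fixed sequence of operators. All tunable
parameters live in `run_config()` and are serialised with every output.

1. **Coarse segmentation** (`coarse_mask()`). Pellets image dark in the red
   channel against the bluish background, while the lateral illumination
   casts one-sided *bright* shadows next to each pellet. A three-class
   multi-level Otsu threshold (`three_level_threshold()`) therefore
   separates dark pellets, mid-intensity background, and bright shadows;
   the darkest layer, cleaned by disk opening (radius 2 px), closing
   (3 px) and hole filling, is the coarse mask. The channel index is
   configurable for other optics.
2. **Gating** (`gate_and_extract()`). Connected components strictly larger
   than 0.0165 mm² (converted to pixels via the µm/px calibration) become
   candidates; each is cropped along its bounding box with a 5 px margin.
   The gate is strict: a component exactly at the gate is discarded.
   Candidates touching the image border are flagged and excluded from
   population statistics by default, because their sizes are truncated by
   the field of view.
3. **Contour refinement** (`refine_contour()`). The same three-class
   threshold is recomputed on the crop alone; because the local histogram
   lacks most of the background, the thresholds shift and delineate the
   contour more precisely. Crops with fewer than three distinct values
   fall back to the coarse mask with a warning.
4. **Grayscale surface** (`to_grayscale()`, `correct_illumination()`,
   `smooth_and_normalize()`). The BT.601 luma image is corrected for
   location-dependent brightness, smoothed with a disk median filter
   whose radius is one-twentieth of the candidate's equivalent diameter
   (the refined per-instance diameter does not exist yet at this stage,
   so the coarse candidate diameter is used; rounding is to the nearest
   integer with a 1 px floor), and min-max normalised to [0, 1].
5. **Core detection** (`detect_cores()`). Otsu's threshold on the in-mask
   normalised gray values separates the dark, hyphal-dense core; core
   components below 9 px are discarded as noise.
6. **Instance separation** (`split_touching()`). The flooding surface is
   the sum of the normalised grayscale image and the inverted normalised
   distance transform (1 at the boundary, 0 at the morphological centre,
   computed per component), so both the bright hyphal edge between
   adjacent pellets and the geometric neck contribute to the ridge. Core
   regions act as imposed minima: a marker-controlled watershed floods
   from them, restricted to the mask, producing exactly one instance per
   core component; coreless components stay whole. Flooding claims every
   mask pixel (no watershed-line pixels are dropped); a boundary pixel
   joins the instance whose flood arrives first, with ties resolved
   toward the lower label id, so the labeling is deterministic.
7. **Features and classification** (`compute_features()`,
   `classify_pellets()`). Per instance: area, equivalent diameter,
   perimeter, circularity, solidity, aspect ratio, core count, core-area
   fraction, mean normalised gray, border contact. The rule table
   (`class_rules()`) assigns one of three classes; defaults are derived
   from the qualitative species morphology (see below).
8. **Population statistics** (`summarize_population()`). Per class: n,
   D10/D50/D90 by linear interpolation of the empirical CDF, normalized
   span width `(D90 − D10)/D50`, standard deviation, optional
   concentration, and the bacterial aggregation frequency.

## Classification rules and their defaults

The published criteria behind the original classifier are not available in
the main text, so the rule table is a reconstruction from the qualitative
descriptions: the fungus forms *large* spherical single-core pellets with a
*small* core-area fraction and *bright* body; the bacterium stays around
250 µm; aggregates are *irregular* and *multi-core*. The decision sequence:

1. `core_count >= 2`, or `solidity < 0.85` with diameter ≤ 400 µm →
   bacterial aggregate;
2. otherwise diameter ≥ 400 µm with at most one core → fungal pellet;
3. otherwise diameter ≤ 350 µm → bacterial pellet;
4. in the remaining 350–400 µm band: fungal iff core-area fraction ≤ 0.3
   and mean gray ≥ 0.6, else bacterial.

All six thresholds are fields of `class_rules()`, serialisable as YAML, and
are stored with results for provenance. Two consequences are worth
understanding:

* Because the watershed produces one instance per core component, an
  aggregate whose subunit cores image as *separate* dark regions is split
  into its subunits before classification; the aggregate class is then
  recoverable only through the low-solidity branch. Aggregates whose dense
  centres have fused into one connected dark region survive as single
  multi-lobed instances and are classified by solidity.
* A two-subunit fused pair is geometrically near-convex (solidity around
  0.9 even for strongly overlapping circle pairs), so it sits at the
  classifier's ambiguity boundary and is typically called a single
  bacterial pellet. This is the synthetic analogue of the early-cultivation
  ambiguity regime where classification accuracy is reduced.

The perimeter is a corrected chain-code contour length (axial steps
weighted 0.948, diagonal steps 1.340); circularity is estimator-dependent,
which is why the estimator is stated here and in the docs. Solidity uses
the convex hull of pixel corners so it cannot exceed 1.

## The synthetic-data generator

The raw cultivation images are not deposited, so validation rests on a
seeded generator (`generate_field()`) that emulates the imaging physics the
pipeline exploits:

* a bluish background (RGB 140/150/210) with a smooth multiplicative
  illumination gradient (±12%);
* fungal pellets 600–1500 µm with a single dark elliptical core occupying
  5–20% of the area; bacterial pellets 150–350 µm with 30–60% cores;
  bodies and cores are jointly dark in the red channel while the
  core/body contrast lives in luma, reproducing the contrast structure
  the two thresholding stages rely on;
* a radially decaying bright hyphal corona with band-limited angular
  texture, and a one-sided bright shadow crescent (lateral lighting);
* aggregates built as bent chains of 2–6 deeply overlapping elliptical
  subunits whose cores are fused by dark necks, with a total equivalent
  diameter of 250–380 µm (subunit sizes are derived from that target so
  aggregates stay in the bacterial size regime);
* additive Gaussian sensor noise (sd 3 on the 8-bit scale), added after
  the ground truth is recorded.

Default fields are 1200×1200 px at 5 µm/px with 5 fungal pellets, 20
bacterial pellets and 3 aggregates — the well-separated, late-cultivation
morphology regime. The `"overlapping"` preset narrows the size gap between
the species to probe the early-cultivation regime; accuracy is expected to
(and does) degrade there. Overlap between pellets is controlled by
`overlap_prob` (default 0.15 for bacterial pellets attaching to existing
particles), which exercises the watershed's small-attached-to-large case.

What the generator does **not** emulate: true hyphal texture inside the
pellet body, out-of-focus blur, debris and dispersed mycelium, Petri-dish
edges, and condition-dependent morphology shifts (clumping at low shear).
Passing the synthetic benchmark therefore demonstrates that the operators
are implemented correctly and interact as designed — not that the default
thresholds transfer to any particular microscope without recalibration.

`generate_series()` re-renders the *same* population (same seed) at scaled
diameters, emulating paired growth of one population over cultivation time
rather than fresh populations per timepoint; this makes diameter-ratio
checks exact in expectation.

## Shake-flask oxygen transfer and kinetics

`otr_max_unbaffled()` implements the power-law correlation for non-baffled
Erlenmeyer flasks,
OTRmax = 3.72×10⁻⁷ · Osmol^0.05 · n^(1.18−Osmol/10.1) · V_L^−0.74 ·
d₀^0.33 · d^1.88 · p_R · y_O2, with the default osmolarity 0.505 osmol/L
chosen so the frequency exponent equals 1.13 (LB-type media). The
correlation's absolute scale depends on the unit system of the source
correlation, which the printed symbols alone do not fix — with V_L in mL
and diameters in mm the product is ~0.03, far from the reference value of
15 mmol/(L h) for the standard configuration. The absolute scale therefore
sits behind an explicit `calibration` factor (default 1), and only ratios
and monotonicity (increasing in rpm, decreasing in filling volume) are
treated as reliable outputs.

`otr_max_baffled()` implements the Gaussian correlation for the baffled
500 mL sensor-flask geometry, OTRmax = c*·a·exp(−0.5[((n−x₀)/b)² +
((V−y₀)/c)²]) with the published coefficients (x₀ = 235.32, y₀ = 276.87,
a = 333.95, b = 59.23, c = 347.81, c* = 0.21 mmol/L). The `V` term is
interpreted as the filling volume in mL (a config field, not hard-coded):
with V = 100 this reproduces the reported relative OTR reductions when
slowing from 250 rpm (to ~25% at 136 rpm and ~1.3% at 60 rpm). The
reported absolute values for this flask are ~8% below c*·a times the
Gaussian, so the ratios — which are independent of c* and a — are the
quantity this package stands behind.

`fit_kinetics()` uses the standard window-based definitions: µ is the OLS
slope of ln(CDW) vs time, r_S the negative OLS slope of substrate
concentration, q_S = r_S divided by the window-mean CDW, and Y_X/S the
endpoint ratio ΔCDW/(−Δglucose) (glucose basis, so values above 0.5 occur
when a second substrate is co-consumed). Windows are user-specified; there
is no automatic growth-phase detection. The recovery benchmark uses a
realistic design — 10 samples over 30 h, glucose 10 g/L almost fully
consumed, 1% multiplicative measurement noise — under which both µ and r_S
are recovered within 2% across 100 seeded replicates; sparser or shorter
designs are fundamentally noisier and should not be expected to meet that
bound.

## Numerical choices and degenerate inputs

* Multi-level thresholds are placed at the midpoint of the empty intensity
  gap between the classes; ties in the between-class variance break toward
  the lexicographically smallest pair. The implementation (prefix sums
  over the unique-value histogram) is verified against a brute-force scan
  of all threshold pairs.
* Rasters with fewer than three distinct values cannot be three-level
  thresholded and raise an error at the whole-image stage; at the crop
  stage the coarse mask is used as a fallback with a warning.
* A constant raster after median filtering normalises to all zeros with a
  warning; constant in-mask intensities yield an empty core set.
* The illumination estimator fits a degree-2 polynomial surface to a
  per-pixel median taken on a 64×64 subgrid; it is approximately
  idempotent and preserves each raster's mean. It is a deliberately
  simple retrospective estimator with a plug-in interface
  (`estimator` argument) for more sophisticated alternatives.
* The q0 histogram uses left-closed bins aligned to multiples of the bin
  width; percentiles use the default linear-interpolation quantile, which
  reproduces exact order statistics on odd-length samples. Default bin
  widths are 100 µm for the fungal and 25 µm for the bacterial classes,
  matching the granularity at which the two populations are usually
  displayed. The normalized span width defaults to `(D90 − D10)/D50`,
  the standard particle-sizing definition; `(D90 − D10)/(2·D50)` is
  available via `span_denominator`.
* Evaluation matches instances one-to-one, greedily by descending IoU
  with a 0.5 default threshold (centroid containment for centroid-style
  annotations). Because the reference protocol for the headline accuracy
  is ambiguous about unmatched objects, both accuracy over matched pairs
  and accuracy over all annotated objects are reported.
* Concentration requires a user-supplied analysed volume; the imaged
  fraction of the sample dish is acquisition-specific and is never
  guessed. Without it, only counts and class fractions are reported.

## Problem sizes used in the validation suite

The end-to-end benchmark analyses 20 default-sized synthetic fields
(~28 particles each, 560 total) and pools the confusion matrix; the
thresholding oracle check uses 1000 random rasters with up to 64 gray
levels; the kinetics benchmark uses 100 seeded replicates of the 10-point
design above. Unit tests use smaller fields (500–700 px, coarser pixel
size) so the whole suite stays fast.

## Known limitations

* The classifier is a fixed rule table, not a learned model; texture
  descriptors (gray-value variance, local entropy) are an extension
  point, not implemented.
* Two-subunit aggregates are systematically ambiguous (see above).
* Fungal clumping at very low shear produces morphologies outside the
  three-class vocabulary; such particles are forced into the nearest
  class by the total rule table rather than flagged.
* The shading estimator assumes slowly varying illumination; it will not
  remove structured artefacts (dust, scratches).
* Absolute OTR values for the non-baffled correlation require an external
  calibration; only ratios are validated.
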