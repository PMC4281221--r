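---
title: "Counting savannah ungulates from 0.5 m satellite imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting savannah ungulates from 0.5 m satellite imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdspot)
```

## The detection problem

At 0.5 m ground resolution an adult wildebeest or zebra (1.5–2.5 m
head-to-body) images as an elongated blob 3–4 pixels long and 1–2
pixels wide, dark against sunlit grass, with a small attached shadow
that cannot be resolved away from the body.  A purely spectral
(per-pixel) classifier can find such blobs but also fires on every
other dark target — above all tree shadows, which are spectrally
inseparable from the animal-plus-shadow mixture.  A purely object-based
approach fails in the other direction: no general-purpose segmentation
reliably isolates 4-pixel point targets against textured backgrounds.

`herdspot` therefore runs the two stages in series.  The pixel stage is
tuned for recall: it may over-detect (Type I errors) because everything
it emits is re-examined.  The object stage applies ecological and
radiometric knowledge — animals stand in open terrain, occur in herds,
have a bounded body size and bounded brightness — to remove the false
positives.  This asymmetry (inflate recall first, then restore
precision) is the central design commitment of the package, and the
per-stage counts in the run manifest let you watch it work.

## Pixel stage

**Class scheme.**  Six classes: trees, grassland, bare soil, sand,
water, and *mixture of animals and shadow*.  The merged class is not a
convenience but a measurement: `separability_matrix()` computes
pairwise Jeffries–Matusita distances from Gaussian class models
(`class_stats()`), and on every scene we generate, JM(animal, shadow)
falls below 1.40 — the conventional "poor separability" bound — while
every animal–landscape pair exceeds 1.90.  `run_pipeline()` performs
this audit at run time and merges whatever classes are poorly separable
from the animal class, rather than hard-coding the merge.

JM is computed as `2 * (1 - exp(-B))` with `B` the Gaussian
Bhattacharyya distance.  Some texts define JM as the square root of
this quantity; the convention here is fixed by the requirement that the
statistic range over \[0, 2\] and saturate at 2.  Covariances from tiny
or constant samples are ridge-regularized (`1e-6 * trace/dim` added to
the diagonal) so the Mahalanobis term stays defined.

**Classifier.**  One hidden layer (16 units by default — the input is
only 4 band DNs and the output at most a few classes), logistic
activations in hidden and output layers, inputs min–max scaled to
\[0, 1\] from the training split (without scaling, 11-bit DNs saturate
the logistic immediately).  Training is full-batch gradient descent
with momentum 0.8 and training rate 0.02, configurable within
\[0.01, 0.05\]; the gradient uses the cross-entropy delta for logistic
outputs (`dO = output - target`).  With the squared-error delta the
extra `O(1-O)` factor stalls training at these rates for thousands of
epochs; the cross-entropy form converges within the default cap of
3000 epochs while keeping the same architecture, activation and
momentum semantics.  Training stops early if the output RMS error
drops below 0.01.  Weight initialization is uniform and seeded, so
training is bit-reproducible.

Classes with multimodal spectra can be pre-split into subclasses
(`subclass_split()`): Gaussian mixtures with 1–3 components are fitted
to the class samples and the component count chosen by BIC; subclasses
collapse back to their parent at prediction time.  `classify_pixels()`
optionally adds an activation margin to the animal class (default 0;
ties already break toward it) to push recall further.

## Object stage

**Segmentation.**  `multiresolution_segment()` implements bottom-up
region merging under the combined color/shape heterogeneity criterion:
merging regions 1 and 2 costs

\[
f = (1-w_s)\sum_b w_b\,(n_m\sigma_{b,m} - n_1\sigma_{b,1} - n_2\sigma_{b,2})
  + w_s\,\Delta h_{shape},
\]

where the shape term mixes compactness ($\ell/\sqrt{n}$) and smoothness
($\ell$ / bounding-box perimeter), each entering $n$-weighted.  A merge
is allowed while $f < \mathrm{scale}^2$ — the squared-scale threshold is
the convention under which the two published parameter rows (landscape:
scale 20, weights 1,1,1,2, shape 0.2; animals: scale 6, weights
1,1,1,1, shape 0.1) are meaningful.  Scheduling is local mutual best
fitting: each region picks its cheapest neighbor (ties to the smallest
region id), mutually-choosing pairs merge, and sweeps repeat to a fixed
point.  The exact scheduler of commercial OBIA software is proprietary;
ours is an approximation chosen to be *deterministic* — the id
tie-break and the survivor-keeps-smaller-id rule make the partition a
pure function of the input.  The merging core is C++; the test suite
checks it against a naive R implementation that recomputes every
statistic from the pixel grid at every sweep, on 100 random 6×6 and
8×8 fixtures.

Object features follow OBIA conventions: band means; brightness (mean
of band means); NDVI and blue ratio computed *from the band means*,
not as pixelwise ratio averages (numerically stabler and standard);
max difference = (max − min band mean)/brightness — the normalization
matters, since an absolute DN difference of 1.45 would be meaningless
on an 11-bit scale; area-weighted centroids in map meters;
4-connectivity adjacency.

**Step A — masking the surroundings** (on the 3×3 low-pass smoothed
image, which suppresses within-crown texture): rules fire in the fixed
order vegetation → water → shadow, because the shadow rule ("dark and
vegetation within 1 m") needs vegetation labels first.  All three
classes require at least 20 px — an animal-sized object can never be
absorbed into the mask.  The vegetation distance is the minimum
pixel-center distance from the object to a vegetation pixel.

**Step B — refining the candidates**, in order:

1. *Clip*: candidate pixels on vegetation/shadow/water are relabeled to
   that class.
2. *Object formation*: the candidate mask is segmented at the animal
   parameters with the mask as a thematic constraint, and the objects
   taken forward are the thematic polygons themselves — the 8-connected
   components of the mask (8-connectivity so a diagonally attached
   shadow joins its animal).  Region merging at scale 6 under pixel
   noise leaves candidate blobs over-fragmented, and treating fragments
   as objects creates duplicate detections per animal; assigning the
   thematic polygons as the objects resolves this, and the sub-object
   count is retained in the audit trail.
3. *Vegetation adjacency*: objects sharing a boundary with (or centered
   within one cell of) vegetation are dropped — animals against canopy
   cannot be separated from it, so these are treated as shadow debris.
4. *Size rule*: objects above 10 px (2.5 m² at 0.5 m — the upper bound
   of one body with shadow) are split by marker-based watershed on
   their pixel-brightness surface.  Markers are regional minima after
   merging minima shallower than 25 DN.  The tolerance is set to about
   twice the per-pixel brightness noise of the rendered imagery: a
   smaller value (we tried the literal "any local minimum" reading,
   tolerance ≈ 2 DN) splits at pure noise minima and re-fragments
   single animals.  Oversized objects with no admissible interior
   minimum — e.g. two animals touching through equally dark pixels —
   are kept and flagged rather than dropped, consistent with the
   recall-first philosophy.
5. *Buffer merge*: 0.5 m (one cell) disks around centroids are unioned
   transitively; each union becomes one detection at the area-weighted
   centroid, removing redundant centroids from over-segmentation.
6. *Herd rule*: detections whose nearest neighbor is beyond 10 m are
   removed, in a single pass against the pre-filter set.  Iterative
   re-filtering (available as `iterative_herd_filter`) can cascade a
   herd away from its edge inward, which is why the single pass is the
   default.  A lone detection in a scene has no neighbor and is treated
   as infinitely isolated.  Distances are centroid-to-centroid; an
   edge-to-edge reading of the 10 m rule would differ by at most one
   body length and is not separately implemented.
7. *Brightness gate*: keep if brightness < 315, or if brightness lies
   in the closed band \[315, 325\] with max difference > 1.45 (an
   animal object that swallowed bright surrounding pixels shows strong
   local color contrast).  The audit trail records the admitting
   branch.

Every stage is non-increasing in detection count except the size rule;
the merge, herd and gate stages are idempotent, and the whole pipeline
is deterministic given the seed.

## Pan-sharpening

`gram_schmidt_pansharpen()` is classical component substitution: a
simulated low-resolution pan (weighted band mean; default weights
0.1/0.3/0.4/0.2 for B/G/R/NIR — the sensor's pan spectral response is
not public, and the weights are configurable), Gram–Schmidt
orthogonalization of `[sim_pan, blue, green, red, nir]` with image-wide
statistics, cubic upsampling of the components, substitution of the
real pan, inverse transform, clip to the radiometric range.  Two
choices are worth recording: the real pan is matched in *mean and
standard deviation* to the **upsampled** simulated pan (matching the
2 m statistics instead leaves a resampling-dependent bias, and the
upsampled reference makes "pan equals the upsampled simulated pan" an
exact no-op, which the tests verify to float precision); and the
resampling is Keys cubic convolution with a = −0.5, evaluated at target
pixel centers with replicate borders, which reproduces constants
everywhere and linear ramps away from the border.  On generated scenes
the sharpened band means stay within 2 % of the 2 m originals and the
2 m re-aggregation correlates with the input above 0.98 per band.

## Accuracy assessment

`match_detections()` pairs detections with reference animals greedily
by increasing centroid distance, one-to-one, within 2 m (about one
body length).  A human-consensus protocol has no algorithmic
equivalent, so the tolerance is exposed.  From the matched counts,
`error_rates()` computes count error |C−R|/R, omission (R−correct)/R
and commission (C−correct)/C, with zero denominators reported as
undefined rather than zero, and aggregates always formed from summed
counts, never averaged percentages.  The count error is reported as an
absolute value by default (a signed variant is a flag).
`chi2_error_independence()` builds the 2×2 \[error, non-error\] ×
\[area, area\] table — omission errors against reference totals,
commission against classified totals — and applies Pearson's chi-square
*without* continuity correction; with Yates' correction the test
statistic on the bundled census counts would not reproduce its
published value.  `interpreter_cv()` (sample SD / mean × 100)
quantifies agreement between independent manual counts.

## The synthetic scene generator

`generate_scene()` emulates the statistical structure the pipeline
assumes, not the physics of imaging:

- **Landscape**: contiguous elliptical patches of bare soil and sand on
  a grassland matrix, an optional water body (3 % of the scene by
  default), and ~5 tree crowns/ha (radius 2–3.5 m) with cast shadows
  offset 1.5 m.  Class DNs are Gaussian around per-class band means on
  an 11-bit scale.  The default spectra are a *calibration*, not a
  measurement: they are chosen so that the sampled JM structure on the
  pan-sharpened image reproduces the separability regime the method is
  designed for (animal–shadow < 1.40, animal–landscape > 1.90), and so
  that every rule threshold (NDVI 0.6, blue ratio 0.18, brightness
  315) falls on the intended side of the intended classes with margin
  comparable to the class noise.
- **Animals**: herds are Thomas-process clusters.  Each herd's spread
  scales with the square root of its size, keeping within-herd packing
  density constant — large aggregations occupy more ground rather than
  packing tighter, which is also the regime in which detection errors
  are independent of total abundance.  An anisotropy factor elongates
  clusters along a herd axis to approximate animals moving in lines.
  Every animal is a digital line blob 3–4 px long, 1–2 px wide
  (footprint 3–8 px), at uniform random orientation, with a 1-px
  attached shadow; placement enforces open terrain, a 2.5 m minimum
  centroid spacing (animals are 2 m long; closer packing would overlap
  bodies), and chain cohesion within 8 m so within-herd
  nearest-neighbor distances never exceed the 10 m herd rule.
- **Imaging**: the 0.5 m panchromatic band is the weighted band mean
  plus sensor noise; the 2 m multispectral image is exact 4×4 block
  aggregation.  This is the scale-coupling the pan-sharpener assumes.

What the generator does **not** emulate — sensor PSF/MTF, BRDF and
terrain illumination, mixed pixels from sub-pixel cover gradients,
georegistration error between the pan and multispectral grids, herds
under canopy — bounds what green tests mean: they demonstrate that the
pipeline recovers the truth under its own stated assumptions, not that
it would achieve the same rates on an arbitrary real scene.

## Problem sizes and run times

Default scenes are 250 m × 250 m (500 × 500 pan pixels) with two herds
of 30–100 animals — large enough for the landscape rules, the herd
geometry and the density contrast to be non-trivial, small enough that
the full ten-scene recovery experiment (five high-density, five
low-density scenes) completes in about a minute on one core.  The
segmentation oracle runs on 6×6 and 8×8 rasters because the naive
reference implementation is quadratic per sweep.  Training samples
default to 150 animal pixels (30 held out) and 50 pixels per landscape
class, mirroring the sampling design the classifier was built around.

## Known limitations

- Adjacent animals whose blobs touch through equally dark pixels merge
  into one detection; the size rule can only split at brightness
  ridges.  This is the dominant omission mode in dense herds.
- Tree shadows whose crowns fail the vegetation rule (small or mixed
  crowns) can survive to the herd filter; isolated ones are removed
  there, but shadow debris inside a herd's 10 m envelope becomes
  commission.
- The herd rule removes genuinely solitary animals by design; disabling
  it trades that omission for shadow commission.
- Rasters are held in memory as dense arrays; scenes far beyond ~1 km²
  at 0.5 m need tiling, which is out of scope.
- GeoTIFF support is TIFF + world file; CRS metadata is carried through
  untouched, and reprojection is out of scope.
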