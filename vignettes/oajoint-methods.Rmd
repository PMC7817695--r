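---
title: "Quantitative knee-joint phenotyping and the osteoarthritis gene screen"
author: "oajoint package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative knee-joint phenotyping and the osteoarthritis gene screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oajoint)
```

# Overview

`oajoint` implements a rapid-throughput phenotyping pipeline for the mouse
knee: quantitation of articular-cartilage surface damage from
joint-surface-replica (JSR) images, relative subchondral bone mineral
content (BMC) from calibrated microradiographs, cartilage and subchondral
bone morphometry from contrast-enhanced density volumes, and a
three-criterion statistical screen that calls mutant mouse lines as joint
phenotype outliers and feeds a 21-point gene prioritization score. Seeded
synthetic-data generators stand in for the mice, molds, and scanners, so
every stage can be exercised end-to-end with known ground truth.

This vignette records the models, the parameters that matter, and the
design decisions taken where the underlying protocols leave choices open.

# Damage quantitation in joint surface replicas

A replica image is a calibrated grayscale field (default geometry:
1536 x 1536 px over an 1800 x 1800 um field, i.e. 1.3733 um^2 per pixel).
The chain is:

1. **Plateau selection** — a polygon (explicit input; default full frame).
   Pixels outside are excluded from all measurements. The whole-plateau
   area is the summed area of selected components larger than 100 px.
2. **Bright-outlier removal** — bright connected components smaller than
   4 px (5.5 um^2) and exceeding the background median by a
   `brightness_delta` (default twice the background MAD) are replaced by
   their local median. This despeckling never touches genuine damage,
   which is always larger.
3. **Edge detection** — 3x3 Sobel magnitude, clipped to the bit depth. An
   ideal step of height *h* responds with 4*h* on the two pixels flanking
   the step.
4. **Debris erasure** — an explicit mask zeroes soft-tissue and bubble
   artifacts in the edge image; the plateau area is unaffected.
5. **Thresholding** — manual value, Otsu, or (automated default) a robust
   background rule, `median + 8 * MAD` of the edge magnitudes. Otsu
   assumes the histogram splits into two comparably sized classes; on a
   sparse-damage edge image damage occupies a percent or less of the
   pixels and Otsu's threshold collapses into the background texture (or
   into the clipped tail), so it is not the default here although it
   remains available.
6. **Particle analysis** — 8-connected components with enclosed holes
   filled; keep area > 20 px (27.5 um^2) and circularity
   4&pi;A/P^2 in [0, 0.5]. Perimeters come from a Moore boundary walk
   (straight steps 1, diagonal steps sqrt(2)); circularity is capped at 1.
   Elongated cracks pass the filter; compact debris (circularity near 1)
   does not. Hole filling matters twice: a thresholded outline measures
   the object it encloses, and a debris *ring* would otherwise have a
   deceptively low circularity.
7. **Edge deflation** — the Sobel response extends exactly one pixel
   beyond a boundary, so the thresholded selection is a one-pixel
   dilation of the damage. After hole filling the selection is eroded by
   one pixel (`edge_deflate_px = 1`), which removes a +10–20% bias in
   recovered crack area on the synthetic surfaces. Setting it to 0
   reproduces the raw thresholded measurement.

Damage is reported as a percentage of the total plateau area. Lowering
the manual threshold can only grow the damage area (monotonicity), and
the result is invariant to any number of sub-4-px bright speckles.

Coordinates everywhere in the package are 1-based (row, col) / (x, y, z),
the R convention.

# Subchondral X-ray microradiography

Raw grays are stretched between the plastic (minimum) and steel (maximum)
standards into 256 bins: `bin = round(255 * (g - plastic) / (steel -
plastic))`, rounded half up and clipped to [0, 255]; an aluminium
standard, when present in an image, plays no role in the calibration.
Standard levels are explicit inputs (patch medians over user-given
boxes). The subchondral region of interest is scaled to the tibia: height
9% and width 34% of the growth-plate width (rounded half up), centred on
the plateau columns, with its top edge at the topmost pixel at or above
`bone_bin_threshold` (default bin 48, the top of the lowest pseudocolour
band of the conventional 16-colour LUT) — the bone directly beneath the
plateau. Relative BMC is the median calibrated bin: the smallest bin at
which the cumulative pixel count reaches 50%. Calibrated bins depend only
on `(g - plastic)/(steel - plastic)`, so joint affine changes of
acquisition leave the BMC unchanged up to rounding.

# Contrast-enhanced CT morphometry

Density volumes carry mineral density in mg HA/cm^3 on isotropic voxels
(x medial–lateral, y anterior–posterior, z proximal–distal). Thresholds
are always applied to densities, never raw gray. The chain:

* **Gaussian filtration**, sigma 0.8 voxels, support 1 (a normalised
  3-tap separable kernel), per the scanning protocol.
* **VOI scaling** from explicit tibial landmarks: width 14% of the
  medial–lateral axis, depth 33% of the anterior–posterior axis; medial
  VOI centred on its plateau midpoint with its anterior–posterior
  midpoint at 61.5% of the AP axis; lateral VOI at 68.5% AP (a 7%
  posterior shift) and additionally shifted 7% of the ML axis towards
  medial. Axially a VOI spans from the articular surface landmark to the
  growth plate. Landmark determination (standard-position rotation) is an
  acquisition step; landmarks are inputs here.
* **Cartilage segmentation** — voxels below 200 mg HA/cm^3 in the VOI,
  keep the five largest 26-connected components, then a morphological
  closing with a five-voxel spherical element. A kept component must
  reach the articular-surface face of the VOI (within `surface_tol`
  voxels); in iodine-bath geometry this is what stops contrast-free
  marrow pockets under the subchondral plate from masquerading as
  cartilage.
* **Subchondral bone segmentation** — voxels above 300 mg HA/cm^3 in the
  slab between the cartilage base and the growth plate, keep the twenty
  largest components, three-voxel closing. The slab bound excludes the
  contrast bath, whose density also exceeds 300.
* **Metrics** — cartilage volume (voxel count x voxel volume), median and
  maximum cartilage thickness, bone volume fraction BV/TV (bone voxels /
  slab voxels), trabecular thickness Tb.Th, trabecular number Tb.N, and
  tissue mineral density TMD.

"Dilation/erosion" is read as closing (dilate then erode) with a
discretised spherical element of the stated radius; space beyond the
volume counts as background for erosion.

**Thickness** is the maximal-inscribed-sphere (distance-transform)
definition: the value at a voxel is the diameter of the largest sphere
containing it that fits inside the structure. The implementation paints
the distance-transform sphere of every foreground voxel (exact for
sphere centres on the voxel grid) and is cross-checked against a
brute-force sphere search in the tests. Discretisation makes structures
of odd voxel width read one voxel thick-high; even widths are exact.

**Tb.N** uses the direct, model-independent convention
`1 / (Tb.Th + Tb.Sp)`, with Tb.Sp the maximal-sphere thickness of the
marrow space — the mean spacing between trabecular mid-axes. The
plate-model alternative `BV/TV / Tb.Th` is also reported.

**TMD** is the mean density over the bone mask after a one-voxel peel,
which removes the partial-volume surface voxels mixed by the Gaussian
filtration; without the peel the filtration biases TMD several percent
low.

**Context margins.** Thickness and spacing spheres are fitted in a
segmentation that extends `margin_voxels` (default 24) laterally beyond
the VOI and are then summarised over the VOI voxels only. At desk scale
the VOI can be narrower than a single marrow cell, and without the
margin the VOI faces truncate the spheres (spacing reads ~30% low on the
synthetic lattice).

The pipeline reproduces *relative* comparisons: the iodine bath has
bone-like absorption and systematically, predictably inflates
subchondral parameters, so absolute agreement with scanner software is
not claimed.

# The statistical screen

Eighteen parameters per animal (nine per plateau: Cg.V, median and
maximum Cg.Th, damage area, BV/TV, Tb.Th, Tb.N, TMD, BMC) are screened
against a wild-type reference cohort (nominally 100 animals). Three
criteria:

1. **Reference range.** Shapiro–Wilk at alpha 0.05 picks the branch:
   normal parameters get mean ± 2.0 SD, non-normal ones the 2.5th–97.5th
   percentile range (type-7 linear interpolation). A line is a range
   outlier for a parameter when its mean lies outside the range.
2. **Wilcoxon rank sum**, two-tailed, line animals vs all reference
   animals, with a Bonferroni correction for the effective number of
   tests `N_eff = N - sum over eigenvalues > 1 of (lambda - 1)` of the
   reference correlation matrix. At alpha 0.05 and N_eff 8.8 the
   threshold is P < 0.00568; a second fixed threshold of P < 0.0001 also
   corrects for the number of lines screened. The exact/approximate
   switch follows `wilcox.test`'s convention (exact for small untied
   samples; normal approximation with tie and continuity correction
   otherwise) and is configurable.
3. **Robust Mahalanobis.** The minimum volume ellipsoid (MVE) seeks the
   ellipsoid of minimal volume containing h = floor((n+p+1)/2) points
   (59 for n = 100, p = 18 — the bracket is read as a floor). Candidates
   grow from random (p+1)-point elemental subsets (10,000 by default,
   exhaustive when the subset count is no larger); the best candidate's h
   points give the robust mean and covariance, rescaled by the standard
   chi-square consistency factor so that squared distances of clean
   normal data are approximately chi-square(p). Animals with
   MD^2 above the 0.975 chi-square quantile are flagged; a line is called
   only when at least 50% of its animals are flagged (inclusive). A QQ
   diagnostic of ordered reference MD^2 against chi-square quantiles is
   returned for the multivariate-normality check.

Severity points are the number of criteria met (max 3) plus the number
of abnormal pathology categories (max 3): cartilage morphology (volume,
thickness), cartilage integrity (damage area), and subchondral structure
(BV/TV, Tb.Th, Tb.N, TMD, BMC), each across both plateaux; a parameter
counts towards a category when it is abnormal by the range or Wilcoxon
criterion. Animals with missing values are excluded from the affected
parameter only, and from the Mahalanobis criterion (complete rows
required), with a warning.

**Known behaviour.** At p = 18 and n = 100 the raw chi-square 0.975
cutoff is anti-conservative: the robust fit's estimation noise puts
roughly 15–20% of clean animals past it even though the median MD^2 is
almost perfectly calibrated. This is a property of the published method
(and one reason for the 50%-of-line gate), so no small-sample correction
is applied.

# Scores, precision, power, prioritization

* **Weighted OARSI score** for incomplete section sets:
  `score + (5 - N) * score / N`, rounded to the nearest 0.5 with ties
  (x.25 / x.75) rounded up — the protocol states the grid but not the tie
  rule. Sums and maxima aggregate the four compartments (MTP, MFC, LTP,
  LFC), each graded 0–6 per section over up to five sections.
* **Synovitis severity** is the sum of pannus (0–3), lining hyperplasia
  (0–3), and sub-synovial inflammation (0–3).
* **Precision** per sample over replicates: PE(SD) and PE(%CV) =
  100·SD/mean; parameter-level averages are root mean squares.
  Repeatability uses the two-way, single-measure, absolute-agreement ICC
  with the standard F-based confidence interval; ICC > 0.8 is reported as
  the conventional bar for excellent reproducibility.
* **Power**: index (Z_(1-alpha/2) + Z_(1-beta))^2 (7.85 at 80% power),
  group size N = ceiling(2·index·sigma^2/d^2) (4 mice for d = 2 sigma),
  and the inverse minimum detectable effect d = sigma·sqrt(2·index/n).
  MAD replaces sigma for non-normal parameters. At 95% power the formula
  gives 6.498, i.e. 7 mice after the ceiling; only the 80% figure is
  asserted in the tests.
* **Prioritization**: joint severity (max 6) + skeletal phenotype
  sources, one point per database over five databases (max 5) +
  expression in skeleton/chondrocytes/osteoblasts–osteocytes/osteoclasts
  (max 4) + disease association (MGI monogenic, OMIM monogenic, GWAS
  arthritis, GWAS skeletal — one point each, a reading of the stated
  cap of 4) + literature bins (PubMed: 0 / 0.5 for 1–24 / 1 for 25 or
  more; Scholar: 0 / 0.5 for 100–999 / 1 for 1000 or more; the printed
  bin edges leave exactly 25 and exactly 1000 unassigned — both resolve
  upward with a warning). Total maximum 21.
* **Enrichment** is the standard two-sided Fisher exact test (sum of
  hypergeometric probabilities no larger than the observed table's).

# Synthetic data: what it emulates, and what it does not

The generators produce inputs with known ground truth under a single
master seed; sub-streams are split with a counter so adding one generator
call never perturbs another's stream, and identical specs and seeds give
bit-identical outputs.

* **Surfaces**: a smooth textured background, dark crack-like polylines
  dilated to width = length/aspect (aspect at least 6 keeps digital
  circularity under 0.5) with a noisy interior (the high local gradient
  that edge detection keys on), dark compact debris blobs, and bright
  sub-4-px speckle. Crack bounding boxes are kept disjoint so the damage
  mask has exactly one component per crack, and speckle avoids the damage
  neighbourhood so despeckling cannot perturb a lesion. No physical
  BSE-SEM image formation is modelled; the texture amplitude is a free
  knob.
* **Radiographs**: uniform plastic/steel patches (exact before noise), a
  bone shaft of the stated width with a top-edge anchor row, Gaussian
  noise.
* **Volumes**: a contrast bath above a cartilage slab, a solid
  subchondral plate, and a trabecular lattice with soft marrow, over a
  soft growth-plate layer. The plate is anatomically motivated and
  necessary: without it the (contrast-free) marrow is 26-connected to the
  cartilage slab and cartilage segmentation is ill-posed. Default
  densities are chosen so the support-1 Gaussian filtration cannot move a
  boundary voxel across the 200/300 thresholds (a boundary voxel blends
  about a quarter of its neighbour). Two lattice variants: `"crossed"`
  orthogonal walls (area fraction 1-(1-t/s)^2) and `"parallel"` walls
  (t/s). Under the maximal-sphere definition only the parallel variant
  has exactly thickness t and spacing s-t; crossed-wall junctions admit
  larger spheres and closing adds corner fillets, inflating Tb.Th and
  BV/TV on that geometry — an intrinsic property of the definitions, not
  an implementation artifact. Recovery checks therefore use the parallel
  phantom and evaluate the trabecular compartment clear of the plate.
* **Cohorts**: a Gaussian copula couples 18 marginals (normal or
  lognormal, mirroring the normal/non-normal split of real reference
  data) with a two-block correlation (0.55 within a plateau, 0.15
  across), whose effective number of tests is about 8.6 — emulating the
  substantial inter-parameter correlation of real joint data. Mutant
  effects are applied in SD units on the latent normal scale, so effect
  size is well-defined for skewed parameters.

Passing tests on these phantoms show the arithmetic and the recovery
behaviour of the chain; they do not show robustness to the things the
generators leave out — real replica artifacts, beam hardening and
contrast diffusion, anatomical orientation error in the VOI percentages,
or non-Gaussian dependence between phenotype parameters.

# Numerical choices and problem sizes

Rounding of bins and ROI/VOI dimensions is half-up. The median bin is
the smallest bin whose cumulative count reaches half the ROI. Degenerate
inputs (constant reference samples, empty masks, all-covering debris)
warn and return degenerate-but-typed results rather than failing.
Closing pads by the element radius so the crop boundary does not clip
the element.

The test-suite phantoms are sized for quick iteration: surfaces
256–1024 px square, volumes up to 128 x 128 x 96 voxels, screen
simulations of 100 reference + 4–6 line animals over up to 1000
replicate cohorts; each preserves the governing ratios of the full-scale
setup (crack size relative to the field, VOI fractions, effect sizes in
SD units). The power simulation detects +2 SD lines at n = 4 in about
68% of cohorts through the univariate reference-range/Wilcoxon criteria
and about 93% through the full three-criterion screen, bracketing the
80% figure of the normal-theory design formula — the corrected Wilcoxon
threshold costs power that the multivariate criterion restores.

# Known limitations

* Absolute subchondral values carry the contrast-bath inflation;
  comparisons are relative.
* The MVE per-animal flags are anti-conservative at p = 18, n = 100 (see
  above).
* Maximal-sphere thickness has ±1 voxel discretisation and reads
  junctions of crossing structures as locally thicker — both shared with
  the standard implementations of the method.
* The effective number of tests of real data depends on the reference
  cohort's correlation matrix; the published value (N_eff ≤ 8.8) cannot
  be recomputed without the underlying animals, so the formula is tested
  on constructed correlation structures and the default synthetic cohort
  is calibrated to the same regime.
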