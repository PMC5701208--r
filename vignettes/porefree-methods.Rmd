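---
title: "Methods: recognizing and quantifying pore-free islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognizing and quantifying pore-free islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The nuclear envelope (NE) of interphase mammalian cells contains two kinds
of subdomain. Pore-rich regions carry mature nuclear pore complexes (NPCs),
visible in pan-NPC immunofluorescence (an mAb414-class antibody) as a dense
field of diffraction-limited puncta. Pore-free islands are subdomains from
which mature NPCs are excluded; they appear as dark patches surrounded by
the punctate texture, are largest in early G1, and shrink as interphase NPC
assembly proceeds. Individual nucleoporins (NUP93, NUP107, POM121) form
sparse foci inside these islands -- candidate NPC assembly intermediates.

`porefree` measures three things from two-channel images of the NE bottom
surface: (1) the area of each pore-free island, (2) the appearance
frequency of single-Nup foci inside islands (foci per square micron), and
(3) the distribution of focus distances from the island/pore-rich boundary,
compared against a Monte-Carlo complete-spatial-randomness (CSR) null.
Conditions (e.g. CDK inhibition by roscovitine vs. an aphidicolin control)
are compared with the Brunner-Munzel rank test.

# Island recognition

## Features

Islands have no hard edge -- they differ from pore-rich NE only in texture
-- so recognition is cast as pixel clustering in a local-statistics space.
For every pixel whose full 3x3 window lies inside the nucleus ROI we
compute, over the window:

* **mean** intensity (brightness),
* **population variance** of intensity (contrast),
* **spread**: the trace of the intensity-normalized second-order central
  spatial moment matrix about the window's intensity-weighted centroid, in
  px^2 (how spatially concentrated the window's light is). A window with
  zero total intensity has spread 0 by convention; a flat window has spread
  4/3 px^2.

The moment matrix trace is used because the scalar is rotation invariant;
the three features are z-scored over the valid pixels before clustering
because their units are incommensurate and K-means is scale sensitive.
Windows that would straddle the ROI edge are excluded (`valid_mask`) rather
than padded, because fabricated rim intensities would concentrate exactly
where edge-blur artifacts live.

## Clustering and the cluster-number rule

Pixels are clustered by K-means (k-means++ initialization, Lloyd updates,
best of `kmeans_restarts` restarts) for every k in 2..20. At each k the
cluster whose pixels are darkest in the pan-NPC channel is the *island
class* (ties break to the smaller label, with a warning). For the island
class we record the within-class variation (WCV): the population variance
of each standardized feature over the class's pixels. Each feature's WCV
sequence is min-max normalized across k, and the total WCV is their
unweighted mean (no weighting is privileged a priori). The selected k is
the smallest k at which the first difference of the total WCV changes sign
from minus to plus -- the first strict local minimum of the trace. Zero
differences continue the previous sign, so a plateau minimum selects the
plateau's smallest k; a trace with no sign change (e.g. monotone) falls
back to the argmin and is flagged `FALLBACK`.

On the synthetic study conditions below this rule lands at k = 3 almost
always: the three stable texture populations are puncta, the halo plateau
between puncta, and dark pixels. Larger k mostly splits shot noise, which
is visible in the trace as the point where the island class's WCV stops
improving.

## From class to islands

The island class is never the islands alone: between puncta the texture
contains interstitial pixels that are locally indistinguishable from island
interior, and they form a thin connected lace throughout the pore-rich
region. The mask is therefore cleaned morphologically before component
analysis:

1. **opening** with a disc of radius `cleanup_radius` (default 4 px)
   removes the lace (its strands are 1--4 px wide) while leaving the wide,
   smooth island blobs intact -- without this step the lace bridges the
   islands to the ROI rim and the rim filter below would delete them;
2. 3x3 **closing** and **hole filling** smooth the island outline
   (K-means label maps are pixel noisy, real island boundaries are smooth
   closed contours);
3. 8-connected components are extracted; components smaller than
   `min_island_area` (default 4 um^2) or touching the border of the valid
   region are dropped. The rim rule exists because the analysis concerns
   islands fully surrounded by pore-rich NE; the area rule is the "minute
   island" rejection: below about 4 um^2, at this pixel size and NPC
   density, a real island cannot be told from an interstitial void.

Island boundaries are the island pixels 4-adjacent to a non-island pixel,
and sit at Euclidean distance 1 in the distance field.

# Focus detection

Single-Nup foci are dim and sit in noise, so raw thresholding fails. The
counterstain is translated into **mean curvature** of the intensity
surface z = I(x, y):

$$H = \frac{(1+I_y^2)\,I_{xx} - 2 I_x I_y I_{xy} + (1+I_x^2)\,I_{yy}}
           {2\,(1+I_x^2+I_y^2)^{3/2}}$$

with derivatives estimated by Gaussian-derivative filters at scale
`curvature_sigma` (default 1 px). The kernels are moment-calibrated so that
polynomials up to degree 2 differentiate exactly; the flat image gives
H = 0 to machine precision and a sampled hemisphere interior returns
|H| = 1/R within 0.2%.

Two sign/scale conventions matter:

* Intensity peaks are caps with H < 0, so quantization uses v = -H to make
  foci bright before Otsu.
* The image is affinely rescaled to unit range before the curvature is
  computed. On raw camera counts the gradient terms grow with the square of
  the intensity scale and suppress exactly the foci one wants; at unit
  range slopes are gentle and the translation behaves like a
  curvature-weighted blob detector. A welcome corollary is that detection
  is exactly invariant under affine intensity rescaling of the input.

v is rescaled to 0..255 over the evaluation region (min -> 0, max -> 255,
rounding half-up), the 256-bin histogram of in-region pixels goes through
Otsu's method (maximize between-class variance; ties take the smallest
threshold; foreground is strictly above threshold), and foreground
8-connected components within `[min_focus_area, max_focus_area]`
(defaults 2 and 100 px; sub-resolution single pixels and merged clumps are
excluded) become foci with intensity-weighted centroids. In `islands` mode
the evaluation region is the union of recognized islands (the islands are
the initial region of detection, and restricting the histogram to them
prevents background domination); in `roi` mode it is the nucleus eroded by
the curvature kernel radius, which supports whole-nucleus NPC-density
estimation. Touching foci closer than roughly twice the combined PSF and
derivative scale merge into one component and are counted once; no
watershed splitting is attempted.

# Quantification and the CSR null

Per island: area in px and um^2 (`area_px * pixel_size^2`), focus count,
and frequency = count / area. The island's exact Euclidean distance
transform (against its complement; rim pixels at distance 1) assigns each
focus the distance of its centroid's containing pixel; pixel centers sit at
integer 0-based coordinates, so that pixel is `round(coord)`. Counts and
pixel counts are accumulated in half-open bins `(lo, hi]` of width
`distance_bin` (default 1 px), and the raw frequency is count/pixels per
bin. Condition-level profiles average the per-island raw frequencies
bin-wise -- an island contributes only up to its own maximum distance --
and normalize the averaged curve to sum 1.0.

The null re-places each island's observed focus count uniformly at random
over that island's own pixels (sampling with replacement; observed counts
are tiny relative to island areas, and no exclusion rule is claimed by the
model), bins the draws identically, and averages over `sim_reps`
repetitions (default 33,029, the reference repetition count; validation
experiments use 10,000 or fewer with Monte-Carlo error bounds). All draws
use R's Mersenne-Twister; each island gets a reproducible substream derived
from (`sim_seed`, stable island id), so reordering islands changes nothing
and runs parallelize safely.

For the bias test each profile is split at `proximal_fraction` (default
0.5; the cutoff is a declared assumption, not a measured constant) of its
own maximum distance: proximal bins have upper edge at or below the
cutoff (never fewer than one bin), distal bins are the rest. Each island
reduces to its observed and simulated distal (or proximal) *share* of
foci, and the two per-island samples are compared with the Brunner-Munzel
test. Islands with zero observed foci carry no positional information and
are excluded with a message.

# Statistics

The Brunner-Munzel test estimates stochastic superiority
$\hat p = P(X<Y) + 0.5\,P(X=Y)$ from pooled midranks, studentizes with
rank-based per-group variances, and uses Satterthwaite degrees of freedom
with a two-sided t p-value. It is preferred over Wilcoxon because island
size and frequency distributions differ in shape and spread across
conditions. Labels follow the ladder ***, **, * at 0.001/0.01/0.05, else
N.S. Two degenerate inputs are distinguished: all values tied in both
groups is an error (`DEGENERATE_SAMPLES`), while complete separation of
the two samples returns statistic +-Inf with p = 0 -- the evidence is
overwhelming, not absent. No multiple-testing correction is applied,
matching per-panel reporting conventions; the comparison tables carry the
raw p-values so any correction can be applied downstream.

# The synthetic generator

Because the original microscopy images are not public, every stage is
validated on a generator whose defaults are chosen once to emulate the real
imaging regime:

* geometry: 320x320 px at 0.0645 um/px (100x objective, 6.45-um camera
  pixels), nucleus ROI radius 9 um, two islands of 8--20 um^2 (early-G1
  scale), islands kept at least 1 um inside the ROI edge and at least 2 px
  apart; island outlines are low-order Fourier perturbations of discs;
* the imaged NE surface extends `ne_margin` = 1 um beyond the ROI: a
  manually outlined nuclear region sits inside the flat bottom surface, so
  the punctate texture must run to (and past) the ROI edge;
* channel A: pan-NPC foci at 2.5 foci/um^2 with a 0.3-um hard core
  (lamina-anchored NPCs are spatially more regular than Poisson; the hard
  core is also what makes the pore-rich texture confluent as in real
  mAb414 staining). Islands contain zero channel-A foci by construction;
* channel B: single-Nup foci inside islands at 0.4 foci/um^2 (uniform CSR
  or boundary-biased via a logistic acceptance in boundary distance,
  steepness `bias_strength`), plus pore-rich channel-B foci at the same
  density;
* rendering: each focus is a unit point mass splatted bilinearly at a
  subpixel position (so centroid-recovery tests are nontrivial), blurred
  with a 1.5-px Gaussian PSF, with half its flux emitted as a wide
  out-of-focus halo (sigma 3 px) -- widefield imaging always carries
  defocused light, and the halo is what lifts the texture between puncta
  above the island level; 40,000 expected photons per focus
  (antibody-amplified immunofluorescence is bright), a uniform Poisson
  background of 100 counts/px, Gaussian read noise (sd 3), clipping and
  16-bit quantization.

Focus counts are Poisson at the stated density, so a generated image's
realized count differs from the nominal intensity by sampling noise;
recovery is always judged against the realized ground truth.

What the generator does **not** emulate: chromatic shift between channels,
camera gain maps, z-dependence or partial defocus across the field,
non-uniform illumination, autofluorescent debris, and biological island
morphologies beyond smooth perturbed discs. Passing the validation suite
therefore demonstrates correctness of the algorithms under controlled
conditions, not performance on any particular real dataset.

# Automated QC

The visual accept/reject step of a manual workflow is replaced by flags:
`SATURATED` (fraction of in-ROI pan-NPC pixels at the dtype maximum above
`saturation_fraction_limit`, default 0.001), `EDGE_BLUR` (normalized
gradient energy at the nucleus rim -- computed on a lightly smoothed copy
so shot noise does not mask defocus -- below `blur_metric_limit`, default
0.02, roughly an order of magnitude below well-focused synthetic images),
`NO_ISLANDS`, and `MINUTE_ISLANDS` (components existed but all fell below
`min_island_area` or touched the rim). A sample is accepted iff no flag is
raised; rejected samples still appear in `qc.csv`, and overlay PNGs are
written for optional human review.

# Validation experiments and problem sizes

The test suite validates: exact oracle equivalence for Otsu (exhaustive
search over 256 thresholds), the distance transform (brute-force minimum
distances on random masks up to 32x32), and the moment features (loop-based
window oracle at 1e-10); closed-form curvature on paraboloid and
hemisphere; the k rule on hand-constructed traces; island recovery on 20
default-parameter images (median per-island intersection-over-union at
least 0.7) with specificity on 10 homogeneous fields; focus
precision/recall of at least 0.9 at a 1.5-px greedy one-to-one match radius
over 20 islands, and density recovery within 10% at 1--4 foci/um^2;
CSR-null flatness by chi-square at 10,000 repetitions; Brunner-Munzel
against an exhaustive pair-count oracle with type-I calibration at n = 50
per group over 200 replicates; distal-bias detection in at least 90% of
experiments with 50 boundary-biased islands (steepness 3) and a matching
N.S. rate under uniform placement; and byte-identical pipeline reruns.
These sizes are the package's validation operating points; the same
experiments at larger n only sharpen the estimates.

# Known limitations

* Islands below ~4 um^2 are indistinguishable from interstitial texture
  voids at this pixel size and NPC density; the minute-island QC threshold
  makes that explicit.
* Foci closer than about 2 x sqrt(psf_sigma^2 + curvature_sigma^2) merge;
  at 4 foci/um^2 with Poisson placement this biases counts noticeably, and
  the density validation relies on the (realistic) spatial regularity of
  NPCs.
* The WCV rule can select a k at which the island class fragments on
  unusual images; the result is an empty island set and a QC flag rather
  than a wrong measurement.
* The proximal/distal cutoff (0.5 of the island's maximum distance) is a
  convention; conclusions about "distal" enrichment are relative to it.
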