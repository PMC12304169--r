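---
title: "Methods: from seafloor photographs to spatial ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from seafloor photographs to spatial ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`benthoscan` analyses photographic transect surveys of the deep seafloor:
a towed camera platform triggers at a fixed frequency while altitude and
speed vary, yielding images, navigation fixes, and per-image taxon
detections. This vignette documents the models and procedures behind each
stage, the parameters that matter, the synthetic data the package validates
itself against, and the design choices that were genuinely open.

## Image visibility improvement

Raw deep-sea photographs carry three systematic degradations: a radial
intensity fall-off towards the edges (vignetting of the artificial light
cone), a green–blue colour cast from wavelength-dependent attenuation, and
image-to-image brightness differences driven by altitude changes. The
enhancement workflow addresses them in three ordered steps applied to
chronologically sorted batches:

1. **Batch z-score normalisation.** For each pixel position and channel,
   the mean and standard deviation are computed *across* the batch, and
   every image is standardised against them. Any spatial pattern common to
   the whole batch — the vignette, a constant haze level — appears in both
   the mean and the image and cancels out of the z-score. We rescale z from
   $[-3, 3]$ to $[0, 1]$ affinely, clipping the tails. The batch size
   (default 32) is a trade-off: batches must be short enough that altitude
   and water conditions are effectively constant within them, and long
   enough that the pixel-wise moments are stable. A trailing batch of one
   image is merged into its predecessor. The statistics could alternatively
   be computed per image over all pixels; we use per-pixel-across-batch
   because the stated goal is removing *static spatial* patterns, which
   per-image statistics cannot see.
2. **Contrast-limited adaptive histogram equalisation** on a tile grid
   (default 8 × 8, clip limit 0.04 of tile pixels per histogram bin, 256
   bins), with bilinear interpolation between tile mappings. The clip limit
   of 0.04 is the point where, in our experiments, local equalisation
   reliably raises global contrast on low-contrast input without amplifying
   noise; much smaller limits clip so aggressively that a two-level image
   is barely changed. Images whose dimensions are not multiples of the tile
   grid are reflect-padded and cropped back.
3. **Histogram matching** against one reference image, as a monotone
   quantile map per channel: a pixel at the $q$-th quantile of its own
   channel takes the reference's $q$-th quantile value. The reference is a
   required configuration input — choosing a representative frame is an
   operator decision the package does not automate — though
   `run_pipeline()` defaults to the collection's middle image as a
   deterministic stand-in.

All outputs live in $[0, 1]$. One caveat worth knowing: for *textured*
images, the correlation between an image and the vignette mask never
reaches zero even for images that were never vignetted, because any smooth
texture correlates with a smooth radial field by chance. The package's
tests therefore measure vignette removal against that chance level rather
than against zero.

## Habitat clustering

Each image is encoded by a deterministic feature vector with four blocks:
per-channel intensity statistics (mean, sd, five quantiles), grey-level
co-occurrence summaries (contrast, energy, homogeneity, entropy; levels
quantised to 16, offsets in four directions averaged, making them invariant
to 90° rotation), radial spectral-energy summaries (fractions of power
spectrum energy at low and mid radial frequency, peak concentration), and
an 8 × 8 mean-pooled intensity grid. The spectral block exists because
co-occurrence summaries alone cannot separate oriented periodic bedforms
from isotropic bioturbation mounds of similar contrast. Before clustering,
columns are standardised and each block is weighted so all four contribute
equally to squared distance — otherwise the 64 grid cells numerically drown
the dozen texture summaries. A CNN embedding can be plugged in behind the
same `extract_features()` interface; nothing downstream depends on the
extractor.

The number of habitat classes is scanned over k = 2…20 with multi-restart
k-means. "Maximising the k-means objective" is not by itself an actionable
selection rule — the within-cluster sum of squares decreases monotonically
in k — so the package selects the k with the highest mean silhouette width
and retains the full (k, silhouette, WCSS) curve so users can apply an
elbow criterion instead. Cluster exemplars (nearest-to-centroid images) are
reported for manual semantic labelling; naming the substrate classes
remains a human step.

## Sampling units and abundance standardisation

A downward camera at altitude $h$ with opening angles $H = 48°$ and
$V = 33°$ observes a footprint of

$$A(h) = \bigl(2h\tan\tfrac{H}{2}\bigr)\,\bigl(2h\tan\tfrac{V}{2}\bigr)
\approx 0.528\,h^2 \ \mathrm{m}^2 .$$

The vertical (33°) axis is taken as oriented along-track — that is the
smaller image dimension compared against image spacing in the overlap
diagnostic — and is configurable. Successive images overlap when the mean
along-track image length exceeds the mean spacing (strict inequality;
equality counts as no overlap).

Transects are partitioned into successive 100-m along-track intervals
(along-track position = cumulative haversine distance between fixes, sphere
radius 6371 km; adequate for tracks of a few kilometres). A trailing
remainder of at least half a unit becomes its own unit, a shorter one is
merged into the previous unit; both the unit length and this rule are
configurable. Abundance is pooled counts divided by summed member-image
footprints, in individuals/m². Double-counting from overlapping images
inflates counts and observed area by the same factor and leaves abundances
unchanged — this invariance is tested explicitly. Per-unit terrain
covariates (slope, topographic position index, terrain ruggedness) come
from centred finite differences of the unit depth sequence over a 3-unit
window.

## Hotspot analysis

Spatial weights connect each sampling unit to its k = 6 geographically
nearest units (row-standardised, no self-neighbours, distance ties broken
by ascending unit id). Cross-dive neighbours are excluded by default:
transects lie kilometres apart, and pooling them would let one dive's
abundance level masquerade as local structure on another. The
`neighbourhood_curve()` operation recomputes global Moran's *I* for
k = 1…k_max and suggests the smallest k whose change stays below a
threshold (default 0.02) for two consecutive steps, falling back to 6.

For standardised values $z$, the local Moran of unit $i$ is
$I_i = z_i \sum_j w_{ij} z_j$; with row-standardised weights the mean of
the local statistics equals global *I* (asserted to 1e-10 in tests).
Significance uses *conditional* permutation — unit $i$'s value is held
fixed while the others are shuffled among the remaining units — with a
two-sided pseudo p-value $(\#\{|I^{perm}| \ge |I^{obs}|\} + 1)/(n_{perm}+1)$,
default 999 permutations. Quadrants of the Moran scatterplot (value vs
spatial lag) classify significant units as hotspot (high–high), coldspot
(low–low) or outlier (high–low / low–high). No multiple-testing correction
is applied by default, matching common LISA practice of reporting raw
significance; under complete spatial randomness the classification's
type-I error sits at the nominal α (tested at n = 200). Abundances are
binned at the octile boundaries (ties to the lower bin) for choropleth
display.

## Community statistics

Abundances are fourth-root transformed (the "double root": a square root
applied twice, severely down-weighting dominant taxa; a single square root
is available). Bray–Curtis dissimilarity
$d(x,y) = \sum_j |x_j - y_j| / \sum_j (x_j + y_j)$ is computed on the
transformed matrix. Sampling units with no megafauna at all have no defined
dissimilarity to anything; they are retained through standardisation but
excluded from dissimilarity-based analyses with a warning.

ANOSIM ranks all $M = n(n-1)/2$ dissimilarities (mid-ranks for ties) and
computes $R = (\bar r_B - \bar r_W)/(n(n-1)/4)$, which is 1 exactly when
every within-group pair is closer than every between-group pair; the
one-sided p-value permutes group labels. SIMPER decomposes the average
between-group dissimilarity into per-taxon contributions
$\delta_j = |x_j - y_j| / \sum_k (x_k + y_k)$ averaged over between-group
pairs; the contributions sum to the mean between-group dissimilarity by
construction (asserted to 1e-12), and SIMPER runs on the same transformed
matrix as the dissimilarities for internal consistency. Group membership
defaults to the survey region, but a dendrogram cut from the UPGMA tree
(group-average linkage) can supply groups instead — both routes are
exposed because either is defensible.

Ordination is two-dimensional non-metric MDS minimising Kruskal stress-1
with monotone-regressed disparities, best of 20 starts, centred and
PCA-rotated. The package evaluates stress-1 independently
(`kruskal_stress()`, isotonic regression via pool-adjacent-violators) to
assert the optimiser's reported stress and its invariance under rotation,
reflection and scaling. Environmental and taxa vectors are fitted by least
squares with permutation p-values; constant variables are skipped with a
warning.

## The synthetic survey generator

The generator is first-class, tested code. Its defaults are the study
conditions every validation runs under: seven dives — four over a western
basin at −3400 m, three over an eastern area at −2700 m, giving the ~700 m
regional depth offset — with lengths 0.7–2.6 km (≈11.2 km of track,
≈112 sampling units of 100 m, ≈1570 images), trigger frequencies 0.07, 0.1
and 0.2 Hz, tow speed 0.7 m/s except 0.35 m/s on the 0.2 Hz dive (so that
dive, and only that dive, has overlapping images), altitude 3.5 ± 0.4 m
truncated at 0.1 m, camera 48° × 33°, images 128 × 128. These sizes are
the package's desk-scale choice: large enough for ≈40 units per region in
the statistical fixtures, small enough that the full pipeline runs in
minutes.

Bathymetric features are Gaussian bumps (seamounts 200 m and 80 m high, a
pair of 40 m hills) and a flat-bottomed canyon notch with steep smoothed
tanh walls (20 m deep, 500 m wide) — the exact wall shape is cosmetic; only
the depth extremes are asserted. Detection counts are Poisson with mean
intensity × footprint area. Per-taxon intensity is a regional base rate
times a topographic multiplier $1 + (e_t - 1)\,\mathrm{relief}(x)$, where
relief is the normalised feature elevation and $e_t$ the taxon's
enhancement factor; the mechanism linking food supply or temperature to
abundance is deliberately *not* modelled — the generator exposes only
region × topography multipliers and labels them as such. The per-region
taxon rates are calibrated at configuration time so the track-averaged
total intensities equal the configured regional means — by default 0.44
(East) and 0.03 (West) individuals/m², the regional contrast the generator
emulates. Ground truth (intensity surfaces, hotspot intervals where relief
exceeds 0.5, true regional means) is returned alongside, enabling
parameter-recovery tests: the East/West ratio is recovered within 15% over
20 seeds, planted seamount intervals are flagged as hotspots with
sensitivity ≥ 0.8 over 10 seeds.

Images are procedural textures of three classes — smooth ooze (bilinearly
upsampled coarse noise), bioturbated sediment (Gaussian pits and mounds),
rippled bedforms (oriented sinusoids) — assigned deterministically from
region and relief, then degraded by a radial vignette, a green cast
(channel gains plus a small additive green term), truncated-Gaussian
brightness jitter and additive noise. What the generator does *not*
emulate: real optics (wavelength-dependent attenuation with range,
scattering blur), continuous substrate gradients, taxon-specific body
sizes and shapes, detection error of an object detector (detections are
taken as given, as they are for real surveys annotated upstream), and 2-D
track curvature beyond a straight geodesic. Passing tests therefore
demonstrate correctness of the *computations* under known ground truth,
not robustness to every property of cruise imagery.

## Numerical and reproducibility choices

* All randomness flows from integer seeds through a single child-seed
  derivation; a fixed seed reproduces surveys, permutation tests and
  pipeline artefacts bit for bit.
* The z-score denominator carries an epsilon floor (1e-6) so constant
  pixel positions map to mid-grey instead of NaN.
* k-means falls back to an exact assignment when k equals the number of
  distinct feature vectors (the objective is then exactly 0), and k
  values exceeding the number of distinct points are rejected.
* Quantile-bin ties go to the lower bin; duplicate bin edges reduce the
  number of bins with a warning.
* kNN distance ties break by ascending unit id; permutation p-values use
  the +1 correction and are invariant under affine rescaling of the data.
* Degenerate inputs fail loudly: zero-variance values for Moran
  statistics, all-zero abundance vectors for Shannon, batches of one
  image, altitudes ≤ 0.

## Known limitations

* The silhouette rule tends to prefer coarse cluster structure; for image
  collections whose habitat classes grade into each other the retained
  WCSS curve and the exemplar images are the better guide.
* Conditional-permutation LISA treats units as exchangeable under the
  null; along-track units are serially correlated in area and image count,
  so pseudo p-values on strongly autocorrelated *covariates* (not
  abundances) would be optimistic.
* nm-MDS stress from the best of 20 starts is an upper bound on the global
  optimum; degenerate (near-zero stress) solutions on tiny n are accepted
  silently.
* The 100-m unit length is a resolution choice, not an estimate; slope,
  TPI and TRI are one-dimensional along-track derivatives, not grid-based
  terrain derivatives from a bathymetric raster.
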