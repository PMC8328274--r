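---
title: "Counting and clustering enteric neurons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and clustering enteric neurons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexuscount)
```

## The model of the data

A HuC/D-immunostained myenteric wholemount imaged in widefield
fluorescence is, to first approximation, a dim, noisy background (the gut
wall) carrying bright, roughly disc-shaped somata 10–20 µm across, spatially
organized into ganglia: groups of three or more somata packed closer to one
another than to any neighboring group. `plexuscount` operationalizes
exactly this picture. Neurons are *intensity peaks* separated by at least
one soma's breadth; ganglia are *density-connected groups* of peaks; and
everything below an adaptive intensity threshold is tissue background. The
pipeline makes no attempt to delineate soma boundaries — a ganglion is
quantified by its neuron count, not its area.

Two physical parameters tie pixel space to tissue space. The pixel density
ρ (pixels/µm) comes from the objective and camera and is **required**; every
spatial default scales with it. The smoothing parameter σ (pixels, default
7) sets the scale of the Gaussian de-noising filter: larger values suppress
faint extraganglionic somata, smaller values under-smooth staining texture
into spurious maxima.

## The four steps and their conventions

**Thresholding.** The threshold is computed by Otsu's method on the center
cell of a floor-based 3×3 partition (rows `floor(h/3)..floor(2h/3)`), then
applied globally; the center is used because mosaic borders often contain
torn tissue or empty glass that would bias a whole-image histogram. Otsu
runs on a 256-bin histogram — integer-valued 8-bit regions are binned at
their values, deeper or float-valued regions are min–max scaled first — and
exactly tied optima (identical class partitions, e.g. across the empty gap
of a two-mode region) are averaged, so a two-level region thresholds midway
between the levels. Foreground is *strictly above* the threshold. A
constant center cell (no signal reaching the middle ninth — common in
sparse synthetic fields and possible at tissue edges) is degenerate for
Otsu; `otsu_threshold()` errors, and `count_plexus()` falls back to a
whole-image threshold with a warning rather than aborting the image.

**Peak detection.** A centroid is any pixel of the smoothed image not
exceeded within a circular neighborhood of radius δₘ = 2.5 µm × ρ,
restricted to the foreground mask. Restricting to the mask is a deliberate
choice where the step description alone would be ambiguous: without it the
threshold would have no effect on counts, and background texture far from
tissue would be counted as neurons. Maxima closer than δₘ (including plateau
pixels of exactly equal intensity) are grouped transitively and replaced by
their coordinate mean; because averaging can itself create a new
sub-δₘ pair, merging iterates to a fixed point, after which the minimum
pairwise separation ≥ δₘ is guaranteed. Connected-component grouping is the
only order-independent reading of "average the co-neighborhood peaks".
Border peaks are kept: stitched mosaics legitimately place tissue at the
frame edge.

**Smoothing numerics.** Separable convolution with kernel radius ⌈4σ⌉ and
*symmetric reflection* at the borders — zero padding would create a dark
frame and spurious edge maxima on mosaics. σ is taken as the kernel standard
deviation by default. The parameter's textbook name ("full width at half
maximum") and its conventional symbol disagree; we default to the σ = sd
reading, which reproduces concordant counts on our fixtures, and expose
`interpretation = "fwhm"` (sd = FWHM/2.3548) for users who prefer the
literal reading.

**Clustering.** Textbook DBSCAN with Euclidean pixel distances,
εₘ = 20.6 µm × ρ and N₉ = 3, with the point itself counted toward the
N₉ neighbors — the convention under which three mutually close neurons form
a minimal ganglion, matching the operational definition "a ganglion is ≥ 3
neurons". Core/noise status is order-independent; the one genuinely
ambiguous case, a border point reachable from two clusters, is pinned by
processing points in row-major order (it joins the cluster discovered
first), making the labeling reproducible. Noise points are *extraganglionic
neurons*: they count toward neuronal density but toward no ganglion
statistic. The 20.6 µm constant is treated as a fixed, user-overridable
default; like σ it is a calibration constant of the protocol, not a derived
quantity.

**Segmentation.** Foreground connected components that contain no ganglion
peak (debris, extraganglionic somata) are flooded to background; kept
components are divided among the ganglia seeded in them by geodesic
propagation restricted to the mask, so one blob shared by two ganglia is
split rather than double-counted. Region colors derive from the ganglion id
by golden-ratio hue stepping — rerunning an analysis reproduces the figure
exactly.

## Tissue metrics and the size model

Densities divide counts by the imaged area `(h/ρ)(w/ρ)/10⁶` mm²; a
user-supplied area can replace it when a tissue mask is available, since
mosaics routinely include empty glass. The ganglia-size distribution is
summarized two ways: a frequency histogram in bins of three neurons
starting at size 3 ([3–5], [6–8], …), and a maximum-likelihood fit of the
shifted negative binomial, size ~ 3 + NB(r, p) with
P(K=k) = C(k+r−1, k) pʳ(1−p)ᵏ. The shift encodes the size-3 minimum; the
fit uses the raw sizes, not the histogram, which is display-only. The MLE
is computed by profile likelihood: for fixed r the mean MLE is the sample
mean, so p = r/(r + k̄) and r is found by a deterministic one-dimensional
search over log r ∈ [log 1e−6, log 1e6]. Equal sizes (zero variance) are
rejected as degenerate. On ileal data of this kind the fitted law is
strongly overdispersed (r ≈ 0.58, p ≈ 0.035), implying a model mean of
r(1−p)/p + 3 ≈ 19 neurons/ganglion, consistent in magnitude with reported
per-tissue means of ~18–20 — small ganglia are the most frequent and the
tail is long. Agreement with manual counts is quantified by OLS regression
of automated on manual counts with r².

## The synthetic generator

`fixture_params()` + `sample_layout()` + `render_image()` produce
micrographs with known ground truth. Defaults are fixed once, as the
conditions the tests run under:

* ρ = 1.5442 px/µm (a typical 20× widefield pixel pitch of ~0.65 µm/px);
* soma radius 7 µm; somata rendered as Gaussian profiles with sd = half the
  soma radius, i.e. a bright core whose rim has decayed to ~13% — this also
  keeps adjacent somata separable as distinct maxima after σ = 7 smoothing;
* ganglion members on a jittered hexagonal lattice, spacing 17 µm, jitter
  ±1 µm: pairwise distances stay above one soma diameter (14 µm, no
  overlap) and nearest-neighbor distances below εₘ = 20.6 µm (the planted
  ganglion is DBSCAN-connected by construction);
* ganglion sizes drawn from the shifted NB(0.58, 0.035) law (or a fixed
  list); centers rejection-sampled so inter-ganglion gaps exceed
  `separation_factor` (default 2) × εₘ; isolated extraganglionic neurons
  farther than that from everyone; bounded rejections raise a capacity
  error rather than looping forever;
* one seed drives layout and noise; rendering clips and rounds to the 8- or
  16-bit range.

The generator emulates what the pipeline *assumes* — blob-like somata,
separated ganglia, uniform background — and deliberately not what real
tissue adds: uneven illumination, fiber tracts and glia, touching or
overlapping ganglia, staining gradients, folded tissue. Passing the
recovery suite therefore demonstrates algorithmic correctness (no neuron
invented, none lost, partitions exact under the stated geometry), not
field performance on adverse tissue; on real data the relevant check
remains concordance with a trained rater.

## Problem sizes and test design

The test suite cross-checks every nontrivial operation against an
independent brute-force oracle (exhaustive threshold search, direct
density-connectivity enumeration, single-linkage component merging, dense
convolution, closed-form OLS, direct log-pmf summation) on randomized small
instances, and validates the whole pipeline on rendered fixtures. Default
problem sizes — 1024–1536 px fixtures, 20 end-to-end seeds, 50,000-draw NB
recovery, 100–200 oracle instances per operation — were chosen to exercise
realistic mosaic scales while keeping a full run around two minutes on a
single core; `scripts/acceptance.R` re-runs the headline computations at
the same sizes.

## Known limitations

2-D only (ganglia are 3-D structures; confocal stacks must be projected
upstream); single-channel analysis (one immunolabel); no illumination-field
correction beyond Gaussian smoothing; no soma-area or subtype measurement;
density denominators use the full imaged extent unless the caller supplies
a tissue area. Heavily folded or overlapping tissue violates the
peak-separation model and should be excluded at imaging time.
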