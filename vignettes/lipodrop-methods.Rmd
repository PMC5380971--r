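---
title: "Quantifying lipid droplet morphology, clustering and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid droplet morphology, clustering and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipodrop)
```

## The problem

Lipid droplets (LDs) are the neutral-lipid storage organelles of the
cell. In non-adipocytic cells they are numerous and small, they cluster,
fuse, and dissociate, and the balance of these processes sets the LD
size distribution and, through the surface-to-volume ratio, the access
of lipases to the stored triacylglycerol. Quantitative questions about
this balance — how many LDs a cell holds, how their projected areas
distribute across size classes, how often LDs sit in boundary-contact
clusters, whether clustered pairs are static or dynamic over a few
minutes of live imaging, and whether cytoskeletal marker proteins
accumulate at the sites where pairs separate — all require an automated,
reproducible image-analysis pipeline. `lipodrop` implements that
pipeline end to end, together with a synthetic-image generator that
plants complete ground truth so every stage can be validated without
access to any particular microscope.

## The analysis model

### Hierarchical segmentation

Still-image morphometry proceeds in three tiers, each conditioning the
next:

1. **Nuclei** (`segment_nuclei`): the nuclear-stain channel is smoothed,
   thresholded by windowed ("adaptive") Otsu — an Otsu threshold per
   window, bilinearly interpolated between window centres and clamped to
   0.7–1.5× the global threshold so empty windows cannot hallucinate
   foreground — hole-filled, and declumped by an intensity watershed.
   Objects are kept only if their equivalent diameter falls in a
   configurable range (default 100–250 px, the typical nucleus at
   ~0.13 µm/px).
2. **Cell bodies** (`segment_cells`): the cytoplasm channel above its
   global Otsu threshold is partitioned among the nuclei by seeded
   intensity propagation (`EBImage::propagate`): each foreground pixel
   joins the seed with minimal geodesic cost blending spatial distance
   and local intensity difference, weighted by `propagation_lambda`
   (default 0.05). With uniform intensity this reduces to a geodesic
   Voronoi partition, which is exactly how it is tested.
3. **Lipid droplets** (`detect_droplets`): described next. Each LD is
   assigned to the cell containing its centroid; LDs outside every cell
   are kept but excluded from per-cell statistics.

### À-trous wavelet spot detection

The LD channel (a maximum projection, `max_project`) is decomposed with
the undecimated à-trous B3-spline wavelet (`atrous_decompose`): level
*j* smooths with the separable kernel (1/16, 1/4, 3/8, 1/4, 1/16) whose
taps are spaced 2^(j−1) pixels, and detail plane *j* is the difference
of successive smoothings. The transform is exactly invertible (planes +
residual = image), which the tests assert to machine precision. Low
planes respond to diffraction-limited droplets, higher planes to large
ones; small-LD and large-LD candidate maps are built separately
(defaults: planes 2–3 and 3–4) so both ends of the heavily right-skewed
size distribution are detected.

A pixel is a candidate when **every** selected plane exceeds
`wavelet_k` (default 3) times that plane's robust noise scale
(MAD × 1.4826, floored relative to the plane maximum so noise-free
images produce no candidates). Candidate components must additionally
peak above (k+1.5)× the noise of the summed planes; connected noise
excursions that merely graze the per-pixel threshold are thereby
rejected. Level 1 is excluded by default: at a realistic PSF width
(σ ≈ 0.8 px) it carries mostly pixel noise, and including it costs
recall on sub-resolution droplets.

Each candidate region is then refined locally. The local background is
the median of a surrounding ring; the region's support is subdivided by
a watershed on the smoothed intensity (tolerance 0.05 of the local
amplitude) so that a dim droplet on a bright neighbour's shoulder keeps
its own peak; each subcomponent is cut at its own half-maximum above
background. For a blurred disc the half-maximum contour approximates
the disc's own support, so areas come out close to truth without any
deconvolution. A windowed-grid Otsu refinement was evaluated for this
step and rejected: with droplets occupying a fraction of a percent of a
window, the window histogram is effectively unimodal and the threshold
lands in the noise, inflating areas severalfold.

### Fragment-merge correction

Large LDs are occasionally reported as several abutting fragments.
`merge_fragmented` merges two detections when (i) their masks are within
`merge_gap_px` (default 2 px — at most one background pixel between
them), (ii) the intensity path between their centroids shows no true
valley (minimum above `merge_valley_fraction` = 0.75 of the dimmer
fragment's background-subtracted mean), and (iii) the union stays
disc-like (maximal radius ≤ 1.3× the equivalent-disc radius plus half a
pixel). The shape gate is what distinguishes "one droplet split in two"
from "two genuinely adjacent droplets": fragments reassemble into a
disc, neighbours form a dumbbell. For unions of at most 12 px the valley
test is skipped — at that size it is noise-dominated while the shape
gate is still decisive. Merging runs to a fixed point; it can only
decrease the droplet count and never shrinks any droplet.

### Boundary-gap clustering

Two LDs are linked when the minimum distance between their pixel
centres is at most `threshold_px` (default 2 px, i.e. 0.266 µm at the
default calibration of 0.133 µm/px); clusters are the connected
components of this relation within one cell (`find_clusters`). The gap
is measured between pixel centres on the full masks — the minimum is
attained at boundary pixels, so only boundaries are searched — and no
sub-pixel interpolation is used, matching a pixel-based criterion.
Components of size one are singletons, not clusters. Per cluster the
member count, mean area and size heterogeneity (sample s.d., divisor
n−1 by default and switchable) are reported; per cell,
`clusters_per_100_lds` normalises cluster abundance by cardinality
(2, 3, 4, 5, ≥6) per 100 LDs, and `size_histogram` bins areas into
left-closed classes (default edges 0, 0.5, 1, 1.5, 2, ∞ µm²). The
implementation is continuously validated against an independent
brute-force transitive-closure oracle.

### Marker patches at droplets and contacts

`detect_foci` finds per-section local maxima of a marker z-stack above a
preset minimum intensity (an absolute value, or a stack percentile
floored at median + 3 MAD), and merges maxima appearing in nearby
sections into one focus at its brightest section — making the manual
"inspect every section, count each patch once" procedure explicit.
`assign_foci` attaches each focus to every LD with equivalent diameter
≥ 1 µm whose boundary lies within `assign_radius_um` (default 0.3 µm,
the order of the lateral resolution); a focus attached to exactly two
LDs whose mutual gap satisfies the cluster criterion is a contact-site
patch. With three or more candidates the two nearest win (ties to the
lower id).

### Time-lapse dynamics

Frames are segmented per time point (the wavelet detector, or a faster
robust-background threshold with the same local half-maximum refinement
for high-contrast label-free recordings), and detections are linked by
exact minimum-cost matching of centroid displacements under a gate
(default 1.2 µm per frame). Because the gate restricts confusion to
immediate neighbours, the assignment graph decomposes into tiny
components that are solved by exhaustive enumeration — exact and
deterministic. Tracks tolerate short detection dropouts (`max_missing`,
default 4 frames) and a gap-closing pass stitches identities across
them.

Pair association states follow from the boundary gap per frame. For
live frames the association threshold defaults to 4 px: the fixed-cell
cluster criterion (2 px) plus two pixels of tolerance, because
per-frame masks jitter by a pixel under noise while dissociating pairs
separate far beyond it. State sequences are cleaned with a
majority-of-three filter — single-frame flickers are measurement noise,
while true dissociations persist. A pair associated at the window start
and in every observed frame of the 5-minute window is *static*;
otherwise *dynamic*. A dissociation event is an
associated-to-dissociated transition whose run persists
`persistence_frames` (default 3) observed frames after at least as many
associated frames; re-association and repeated events are allowed. The
event site is the centroid midpoint at the last associated frame.

Marker co-occurrence follows a 3σ rule: an event is marker-positive
when the mean marker intensity in a disc of `roi_radius_um` (default
0.3 µm) at the site exceeds the frame's robust background mean by three
robust standard deviations in any frame from `pre_window_frames` before
the event to the end of the dissociated run; timing is "before" when
the first exceedance precedes the event frame, else "during". The
persistence and 3σ definitions operationalise what was originally a
visual judgement; both are parameters, not claims about the original
counts.

The static-fraction estimator censors pairs whose observation ends
early (lost identity or fusion): they enter neither the static nor the
dynamic class. Without censoring, a track lost just before its pair's
dissociation would masquerade as a static pair and bias the fraction
upward. A pair still counts as fully observed if only a
persistence-sized tail of frames is missing.

## The synthetic-data generator

`generate_field` emulates the statistical structure the analysis
assumes: cells with one nucleus each (diameter 100–140 px, cell radius
1.9× the nucleus), ~100 LDs per cell with log-normal projected areas
(~90% below 0.5 µm², truncated to 0.07–4 µm² — the lower cut is the
optical resolution floor), a configurable fraction of LDs in clusters
of 2–5 with decreasing weights, diffraction-limited marker foci at LD
surfaces and contacts, Gaussian PSF blur (σ 0.8 px) and
Poisson–Gaussian noise (background 100 photons, read noise 3, foreground
gain set by the requested peak SNR; the background s.d. is therefore
√109 counts, which the tests verify). Planted intra-cluster neighbours
are rasterised at a pixel-centre gap of exactly 2.0 px — the only
rasterisable configuration that both satisfies the 2-px criterion and
keeps one background pixel between the masks, so the planted partition
is unambiguous and recoverable; non-mates stay at least 4 px apart.
Ground truth (label maps, areas, the cluster partition, planted foci)
is returned alongside the rendered channels and can be written to TIFF
+ JSON sidecars.

`generate_timelapse` plants droplet pairs on a jittered grid that
switch between association (gap 2 px) and dissociation (gap 10 px) as a
continuous-time two-state Markov process sampled at the frame interval
— the simplest kinetic model with controllable static/dynamic fractions
(the closed-form static fraction over a window T is exp(−k_d·T), which
the validation exploits). Pairs can also fuse (one droplet of summed
area, conserving planted area up to rasterisation). Dissociations are
marker-positive with a set probability; positive events receive a focus
at the pair midpoint whose onset leads the separation ("before", 3
frames) or coincides with it ("during"). Pair radii span 0.15–0.9 µm²
and every planted pair is verified to be optically resolvable in its
associated state (the clean blurred bridge stays below 0.45× the dimmer
peak) — pairs below the resolution limit cannot be tracked by any
intensity-based method and would only measure the optics, not the
kinetics.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatially varying PSFs, CARS non-resonant
background, photobleaching, droplet motion within a state, out-of-focus
light, irregular droplet shapes (discs suffice because the analysis is
area-based), and cell-to-cell heterogeneity beyond Poisson counts.
Recovery rates measured here are upper bounds for real recordings.

## Numerical and design choices

- **Calibration.** 0.133 µm/px by default, so that a 2-px gap is
  exactly the 0.266 µm criterion; everywhere a parameter.
- **Connectivity.** Droplet masks are 8-connected components; the gap
  between distinct non-touching masks is therefore ≥ 2 px, which makes
  the cluster criterion a knife-edge deliberately respected by the
  generator (see above).
- **Ties.** Overlap resolution between scale maps assigns a small
  detection to the large one it overlaps; focus assignment ties break
  by lower LD id; cluster ids are ordered deterministically — identical
  input always yields identical output, which the determinism tests
  assert byte-for-byte on the CSVs.
- **TIFF storage.** All package TIFFs are 32-bit on a fixed
  1/65536-count grid: integer counts up to 65535 round-trip exactly.
- **Problem sizes.** The validation suite uses 11 rendered fields
  (~2,100 planted LDs, 22 cells), 3–4 movies of 80 pairs per kinetic
  condition and ≥200 dissociation events per marker fraction — large
  enough for binomial intervals to be meaningful, small enough to run
  routinely.
- **Event-count accounting.** Planted dissociations in the first or
  last `persistence_frames` of a recording cannot satisfy the event
  definition (no room for the required associated or dissociated run),
  so recovery is assessed against the observable planted events; at the
  fastest validated rate this excludes ~9% of the log.

## Limitations

Detection recall at the low end of realistic contrast (peak SNR 5) is
~0.88–0.90:
the smallest planted droplets (4–6 px) then have an *effective* peak
SNR near 3 after PSF dilution, and clustered unequal pairs at the
resolution limit merge irreversibly. At the generator's default SNR 10
the pipeline operates at F1 ≈ 0.95 with median area error ≈ 17%. Area
quantisation dominates the error for the smallest droplets (±1 px is
±25% at 4 px²). The t-test helper (`compare_groups`) is a convenience
summary, not a statistics framework; clustering and tracking make no
attempt at sub-pixel boundary localisation.
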