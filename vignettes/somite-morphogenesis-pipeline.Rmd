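---
title: "Quantifying somite morphogenesis from 4D membrane imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somite morphogenesis from 4D membrane imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somitedyn)
```

# Scope and models

`somitedyn` quantifies cellular dynamics in developing chick somites imaged by
long-term two-photon microscopy of membrane-GFP tissue: volume growth of whole
somites and their central cavity (the somitocoel), the rate of morphological
change, the distribution of cell divisions, directed versus random cell
motion in the dermomyotome, and cell counts/sizes in fixed medial (MD) and
lateral (LD) domain boxes. Because raw microscopy from such experiments is
rarely deposited, the package ships a ground-truthed synthetic generator that
emulates membrane-labelled tissue; every analysis stage is validated against
the generator's known truth.

All positions and lengths are micrometres, volumes are cubic micrometres,
time is minutes and rates are per hour. Voxels default to
0.25 x 0.25 x 0.51 um with frames every 20 minutes, matching the acquisition
the pipeline targets. Arrays are ordered `(t, z, y, x)` with 0-based,
half-open voxel indexing for ROI boxes; track angles are measured
counter-clockwise from +x in degrees on `(-180, 180]`, with +x the
lateral-to-medial axis and +y caudal-to-rostral in dorsal view. These
conventions are fixed here because a reproducible frame is needed for
testability even where the original measurements did not state one.

## Somite growth (sphere model)

A somite's central optical slice is segmented (Otsu threshold on the lightly
smoothed slice, largest connected component, holes filled) and its outer
contour length measured at the 0.5 level of the blurred mask, which is
sub-pixel accurate for smooth shapes. Treating the somite as a sphere whose
great circle is that contour, `r = P/(2*pi)` and `V = (4/3)*pi*r^3`. An
alternative area-based route (`sphere_volume_from_area()`) is provided; the
perimeter route is the default since the measurement protocol starts from a
perimeter. Growth rates are ordinary least-squares slopes of volume against
time, converted to per hour, with the residual-based standard error.

If growth `g` (um^3/hr) were achieved purely by proliferation of cells of
volume `v_c`, the tissue would need `round(g / v_c)` divisions per hour.
The "cell size of 6" entering this model is interpreted as a cell volume of
6 um^3, because only that reading reproduces the printed 3 cells/hr from
g = 19 um^3/hr; a 6-um diameter (about 113 um^3) would contradict that
arithmetic. The fraction of growth attributable to proliferation is
`min(1, observed_rate * v_c / g)`.

## Morphological change (pixel correlation)

Change between two time points is one minus nothing fancier than the Pearson
correlation of corresponding pixels of raw (unregistered) slices; identical
images score 1, and greater rearrangement lowers the score. Depths are
specified as fractions of the z-extent (defaults 0.25, 0.5, 0.75 labelled
dorsal/centre/ventral) because absolute depths vary between somites. No
drift correction is applied, replicating the original overlay measurement;
a pixel mask argument exists for restricting to the somite.

## Division detection

Rounded mitotic cells are detected per slice: Gaussian denoising (sigma 1 px),
Otsu threshold, a binary opening (disc radius 5 px) that detaches thin
membrane outlines from a mitotic disk, connected components, then the
published gates - equivalent diameter >= 12 um and circularity
(`4*pi*A/P^2`) >= 0.85. Perimeters are measured on the sub-pixel boundary
contour, so an ideal disk measures circularity near 1 and a square pi/4;
discretization overshoot above 1 is clipped. The original protocol denoised
with a median filter; the default here is the Gaussian because it is an
order of magnitude faster at identical downstream behaviour on rendered
tissue (the median remains available via `median_radius_px`).

Because a ~25-minute rounding phase sampled every 20 minutes appears in one
or two consecutive frames, detections within 5 um in consecutive frames
(with at most one missing frame) are merged into a single division event,
and one event may span at most two frames. Rates are events x 60 /
observation minutes, reported per analysed volume.

## Tracking

The tracking pipeline mirrors the common ImageJ workflow: intensity
inversion (dark cell interiors become bright blobs), difference-of-Gaussians
band-pass, rolling-ball background subtraction (grey-scale opening, radius
20 px), Laplacian-of-Gaussian spot detection at the expected cell diameter
with sub-pixel quadratic refinement, and frame-to-frame linking by a simple
linear assignment problem: squared link distances compete against a
non-link alternative cost of `max_link^2`, solved exactly by a shortest
augmenting-path assignment solver written for this package, with no merge or
split costs and optional single-frame gap closing. The automatic spot
quality threshold is an Otsu split of the log response values (robust to a
few very bright mitotic disks) with a floor of 2% of the strongest response.

Per track, the mean direction is the circular mean of step headings (the
net-displacement bearing is available via the reported displacement vector),
length is reported both as net displacement and path length, and mean speed
is path length over elapsed time. The directionality of a population is the
mean resultant length `R = |mean unit vector of track directions|`, 1 for
perfectly aligned tracks, 0 when opposite directions cancel, and about
`0.886/sqrt(N)` in expectation for uniform random directions. Normalising by
N makes R comparable across stages with different track counts; the
unnormalised sum is `R * N`. Tracks shorter than 3 detections are excluded
from directional statistics as noise. Defaults that the original protocol
left unstated (spot diameter 8 um, maximum link distance 5 um, single-slice
tracking) are configuration, not claims; analyses of faster tissue should
raise the link gate to roughly the mean step plus three standard deviations
(the packaged scenarios use 12 um).

## Domain segmentation (watershed stand-in)

Cell counts and volumes in the fixed 32 x 41 x 20 um MD/LD boxes are
produced by a membrane-based seeded 3D watershed written for this package:
smooth, Otsu-threshold the membrane, label the non-membrane space in 3D,
treat large components touching the box faces as outside background, use the
remaining interior components as seeds, and priority-flood all voxels along
ascending membrane intensity with the background competing as its own basin,
so membranes are split at their intensity ridge. Labels outside
[min_volume, max_volume] are discarded and counting follows the centroid
rule (a cell clipped by a box face counts if its centroid is inside). This
is an explicit stand-in for dedicated cell-shape extraction software
(RACE); equivalence to that software is not claimed, and validation is
against synthetic truth only, where counts are recovered within a few
percent and volumes within about 15% (partial-volume effects at the coarse
z-step bias volumes slightly low).

Cell-size populations are compared by fitting 1- and 2-component Gaussian
mixtures to log volume (EM via `mclust`) and selecting by BIC; log volume is
used because volumes are positive and right-skewed. This provides a model
for the two-population medial-domain structure that histograms alone display.

## Statistics

All pairwise stage comparisons use the two-tailed Welch t-test with
Satterthwaite degrees of freedom (`stats::t.test`, unequal variances). No
multiple-testing correction is applied, matching the original analysis; raw
p-values are reported as such. The report generator states its sampling
unit (per movie) explicitly.

# The synthetic generator

The generator emulates: random sequential sphere packing (bounded overlap
10% of summed radii, so neighbouring membranes may share a wall); motion by
truncated-normal step lengths (`mean_speed * dt`, `speed_sd * dt`) with
uniform (random), sink-blended (directed, weight `drift_weight`,
renormalised) or centre-directed (inward) headings and reflecting
boundaries; divisions as a homogeneous Poisson process in which a cell
rounds up for 25 minutes, stops migrating (as mitotic cells do), is rendered
as a filled bright disk of >= 12 um so the published detector gates are
exercised, and then splits into two daughters of half volume; and linear
total-volume growth at `rate_um3_per_hr`, enforced by rescaling radii so the
true volume series is exactly linear. Membranes are rendered as Gaussian
shells (thickness 0.5 um) with dark interiors, blurred by an isotropic PSF
(sigma 0.3 um) and corrupted by Poisson shot noise plus Gaussian read noise
scaled to a requested peak SNR. A truncated-normal step model is the
simplest two-parameter match to speeds reported only as mean +/- SD; the
generator does not model persistent random walks (no autocorrelation data
exist to calibrate one), biomechanical forces, extracellular-matrix
patches, or signalling gradients. Motion is simulated in the dorsal plane
(z fixed) because the tracking measurement is in-plane; axes thinner than
one cell diameter hold a centred monolayer.

Consequences for interpretation: passing recovery tests shows the pipeline
is correct for tissue whose statistics match these models - it does not
establish performance on real microscopy, where membranes are dimmer in
depth, cells deform, and motion is correlated between neighbours.

## Study conditions used by the packaged checks

The packaged recovery checks run at the study's stated conditions: growth
slope 19 um^3/hr (noise SD 4, n = 10 points, 100 seeds); mid-stage speed
0.21 +/- 0.11 um/min (100 cells, 10 frames, 200 x 200 um monolayer, peak
SNR 8); mid-stage division rate 4.4/hr over 180 minutes (60 cells in a
96 x 96 um field, 100 seeds); the mid-stage LD complement of 212 cells in
the 32 x 41 x 20 um box (radius 1.5 +/- 0.15 um, SNR 8); and a somitocoel
rendered at its 126 um^3 t0 volume. The three-stage scenario combines
random/0.14, directed/0.21 (drift 0.7 towards a rostro-medial sink placed
beyond the subfield, where the forming dermomyotome lip lies) and
inward/0.06 um/min motion with division rates 1.7/4.4/0.3 per hour at a
reduced size (60 cells, 120 x 120 um, 8 frames) chosen so the full
image-level pipeline runs in seconds per stage while each ordering retains a
wide margin. Field sizes for division movies are a realistic imaged
subregion of a mid-stage somite; they are this package's choice, as the
original counts did not state their exact analysed volume.

# Numerical choices and degenerate inputs

* Thresholding is Otsu (256 bins) throughout; ties in the watershed flood
  are broken first-in-first-out, making segmentation deterministic.
* Perimeters are contour lengths at the 0.5 level of a sigma-1-pixel blurred
  mask: near-exact for disks, and a square's corners are rounded by well
  under 1% of its perimeter. The pure formula `circularity(area, perimeter)`
  is exact.
* The LAP cost matrix forbids links beyond the gate by a large finite cost;
  dummy-dummy assignments are free, which reduces the padded square problem
  exactly to "link if it beats two non-link alternatives".
* Blurs replicate edges and clamp kernels to the image size; tiny negative
  filter ringing is clipped at zero before Poisson sampling.
* Degenerate inputs error early and loudly: empty foreground in perimeter
  extraction, constant images in correlation, sub-2-spot tracks,
  zero-variance Welch samples, identical-time growth series. Identical cell
  volumes are flagged `degenerate` and reported as one component.
* Seeds: every stochastic generator takes a `seed` and is bit-reproducible
  given one; simulated movies record their seed and configuration in the
  ground truth, and reports carry the seed in their metadata.

# Known limitations

* The sphere model understates volumes of non-spherical somites; no
  ellipsoidal or mesh-based estimate is attempted.
* Segmentation volumes are biased a few percent low by partial-volume
  effects at 0.51-um z-steps; counts are unaffected.
* The correlation measure conflates tissue drift with genuine rearrangement,
  by design (no registration).
* Printed somite volumes of order 10^2-10^3 um^3 are anatomically small for
  whole somites; all computations treat published numbers at face value and
  this unit question is flagged rather than resolved.
* 3D tracking through z, lineage trees and optical flow are out of scope.
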