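# somitedyn

Quantitative analysis of somite morphogenesis from 4D (3D + time)
membrane-labelled fluorescence imaging, with a ground-truthed synthetic
tissue generator for validation.

Somites are the transient, near-spherical epithelial segments of the
vertebrate embryo that give rise to the musculoskeletal trunk lineages. As
they differentiate, their growth is fed by some mix of cell proliferation
and cell-size increase, divisions are unevenly distributed between the
medial and lateral domains, and dermomyotome progenitors switch from random
wandering to a collective, directed migration towards the rostro-medial
corner where myogenesis begins. `somitedyn` is for developmental biologists
and image analysts who want to measure those processes from time-lapse
stacks of membrane-GFP tissue — and to know how well the measurements work,
via simulations with known truth.

## What it computes

- **Growth**: somite/somitocoel volume per frame via the sphere model
  (perimeter *P* of the central slice → *r = P/2π*, *V = 4/3 πr³*), OLS
  growth rates *g* (µm³ hr⁻¹), the division rate `round(g / v_c)` needed if
  growth were proliferation alone, and the proliferation share
  `min(1, rate·v_c / g)` of observed growth.
- **Morphological change**: pixel-wise Pearson correlation *r* between
  time-separated slices at dorsal/centre/ventral depths; identical images
  give *r* = 1, faster rearrangement gives lower *r*.
- **Cell divisions**: rounded mitotic cells gated by equivalent diameter
  ≥ 12 µm and circularity 4πA/P² ≥ 0.85, de-duplicated across the 1–2 frames
  a ~25-min rounding phase spans at 20-min sampling, converted to
  events hr⁻¹.
- **Tracking**: invert → band-pass → rolling-ball preprocessing, LoG spot
  detection with sub-pixel refinement, exact simple-LAP frame-to-frame
  linking, per-track circular-mean direction, net/path length and speed, and
  the population directionality *R* ∈ [0, 1] (mean resultant length; ≈
  0.886/√N under random directions).
- **Domain cells**: membrane-based seeded 3D watershed (an explicit stand-in
  for RACE-style software) counting cells and measuring volumes in the fixed
  32 × 41 × 20 µm medial/lateral boxes, plus a BIC-selected Gaussian-mixture
  split of log cell volume into size populations.
- **Statistics**: Welch two-tailed t-tests and a JSON report aggregating all
  stages, plus a packaged three-stage (early/mid/late) synthetic scenario.

## Worked example

Simulate a mid-stage-like movie (60 cells, directed motion at
0.21 µm min⁻¹ towards a rostro-medial sink, 4.4 divisions hr⁻¹), then run
the image-level tracking and division pipelines:

```r
library(somitedyn)

cfg <- default_config()
cfg$seed <- 42
cfg$tissue$n_cells   <- 60
cfg$tissue$domain_um <- c(120, 120, 0.5)
cfg$tissue$radius_mean_um <- 3.5
cfg$motion <- list(mode = "directed", mean_speed = 0.21, speed_sd = 0.11,
                   sink = c(180, 180), drift_weight = 0.7)
cfg$division$rate_per_hr <- 4.4

sim <- simulate_somite_movie(cfg, n_frames = 8)
trk <- track_movie(sim$seq, diameter_um = 7, max_link_um = 12)
div <- detect_divisions(sim$seq)
```

This prints (via the obvious `cat()` calls):

```
tracks kept: 81
mean speed: 0.216 um/min
directionality R: 0.81
mean angle: 48 deg
division events: 11 (4.7 per hr; 11 true)
required divisions for 19 um^3/hr at 6 um^3 cells: 3 per hr
proliferation fraction at 1.7 divisions/hr: 0.54
```

Read: the pipeline recovered the generated mean speed (0.216 vs 0.21
µm min⁻¹), a strongly directed population (R = 0.81) heading 48° — towards
the rostro-medial sink at 45° — and all 11 simulated division events
(4.7 hr⁻¹ against a generated 4.4 hr⁻¹ rate). The last two lines are the
growth model: a 19 µm³ hr⁻¹ somite growth rate corresponds to 3 new
6-µm³ cells per hour, and an observed 1.7 divisions hr⁻¹ explains about half
of that growth, attributing the rest to cell-size increase.

See `vignettes/somite-morphogenesis-pipeline.Rmd` for the models,
parameter meanings, generator assumptions and limitations.

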