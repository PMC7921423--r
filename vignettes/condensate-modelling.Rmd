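---
title: "Modelling crowding-driven condensation and quantifying condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crowding-driven condensation and quantifying condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensim)
```

# The scientific problem

Hyperosmotic stress shrinks cells, concentrating every macromolecule at
once. For condensate-forming proteins such as the osmoresponsive kinase
ASK3, this raises two coupled questions: does the crowding produced by
shrinkage alone explain the appearance of condensates, and why do
condensates become *more numerous but smaller* under stronger shrinkage?
`condensim` packages a minimal lattice model that answers both
qualitatively, together with the quantification pipelines used to compare
the model with live-cell data: a FRAP-rate computation for fast-moving
condensates and particle-based condensate counting in fluorescence
images. Synthetic-data generators with known ground truth make the whole
chain testable without any microscope.

# The lattice model

## State and moves

The simulator evolves a bounded `width x height` square lattice whose
squares are empty, hold one protein *unit* (the condensate-forming
species), or hold one *obstacle* (a virtually integrated crowder
representing the averaged motion of many background macromolecules). Each
molecule occupies exactly one square and squares hold at most one
molecule.

One rejection-kinetic-Monte-Carlo iteration:

1. pick one molecule uniformly from the whole population;
2. pick one of its 4 von Neumann neighbour squares uniformly;
3. classify the proposed move and look up its rate `k`;
4. draw `r` uniform on `[0, 1)` and accept iff `k > r`.

The move classes and rates are:

| class                   | condition                                       | rate |
|-------------------------|-------------------------------------------------|------|
| `unit_free`             | unit to empty square, no contacts lost          | `k1 = 1` |
| `unit_penalized`        | unit to empty square, `n_lost > 0`              | `A exp(-n_lost dE/theta)` |
| `unit_exchange`         | unit onto unit                                  | stays (no draw) |
| `obstacle_free`         | obstacle to empty square                        | `k5 = 0.01` |
| `reflect_out_of_bounds` | destination off the grid                        | stays (no draw) |
| `reflect_occupied`      | destination blocked (obstacle, or unit for an obstacle mover) | stays (no draw) |

`n_lost` is the net number of unit–unit nearest-neighbour contacts a move
would lose: `max(0, contacts(origin) - contacts(destination, mover
excluded))`. Moves that keep or gain contacts travel at the free rate, so
the maximum speed of a unit *inside* a cluster equals its free-diffusion
speed; only contact-breaking moves are exponentially suppressed. This is
the attractive interaction that drives clustering: with `dE/theta = 1`, a
move breaking two contacts is accepted with probability `exp(-2)`.

With `k1 = 1` free unit moves are always accepted, so the only sources of
slowing are walls, excluded volume, contact loss and the hundredfold
slower obstacles — crowding enters purely through excluded volume and
slow-moving barriers, with no unit–obstacle or obstacle–obstacle
attraction.

## Design choices the model text leaves open

* **Neighbourhood.** Moves, contacts and cluster connectivity all use the
  same 4-neighbour (von Neumann) convention; mixing conventions would let
  units touch diagonally without interacting.
* **Boundary.** Hard walls: off-grid proposals are rejected (the molecule
  stays). Periodic boundaries would remove the wall effects that the
  grid-size sweep depends on.
* **`n_lost` convention.** Net change rather than gross contacts at the
  origin, for the reason above (in-cluster mobility at full speed).
* **Random-number discipline.** Exactly one uniform for the target, one
  for the direction, and one for `r` only when the class carries a rate.
  Exchange and reflection classes consume no acceptance draw. This fixed
  discipline makes trajectories bit-identical for a given seed, and the
  compiled loop (`lattice_run()`) is draw-for-draw identical to the pure-R
  reference step (`lattice_step()`), which the tests exploit.
* **Expansion anchoring.** `expand_lattice()` keeps molecule coordinates
  and adds empty rows/columns beyond them; with hard walls, anchoring at
  the origin corner is translation-equivalent to centering.

## Cluster statistics

A *cluster* is a 4-connected component of at least `min_size = 6` units,
mimicking the smallest assembly visible as a condensate by confocal
microscopy; smaller components are invisible and contribute to neither
count nor mean size. When nothing qualifies the mean size is recorded as
0 so time series stay defined. Obstacles never join components.
Replicate summaries are mean ± SEM (`sd/sqrt(n)`; 0 with a warning for a
single replicate).

```{r clusters}
fx <- make_lattice_fixture(10, 10, units = cbind(0:6, 0))
cluster_summary(fx)
```

# The two in-silico experiments

`run_shrink_sweep()` holds the molecule numbers fixed while shrinking the
grid (both densities rise together, as in a shrinking cell) and reports
final-step cluster count and mean size per grid size.
`run_no_obstacle_control()` removes the obstacles, isolating the pure
excluded-volume effect. `run_expansion()` grows clusters on a small grid,
expands the grid, and follows the dissolution over time.

## Scaling and the preset problem sizes

The full-scale protocols (500 units, 1500 obstacles, grids 50–120, 5e6
steps, 18 replicates; expansion 55 → 120 with 35e6 steps, 12 replicates)
are provided as the `"full"` presets but take hours of CPU. The `"desk"`
presets quarter the molecule numbers (125 units, 375 obstacles) and halve
the grid edges, preserving the occupancy fractions at the reference
dilute grid (60×60 matches 120×120: ~3.5% units + ~10.4% obstacles), and
run 1.25e6 steps — the same 2500 attempted moves per molecule as the
full protocol. A desk sweep takes seconds.

Characterizing the model showed that its two crowding regimes separate
at high occupancy: cluster size grows as the grid shrinks while units
can still rearrange, and turns over only once roughly two-thirds of the
lattice is filled, where obstacle cages fragment the unit population and
freeze many small clusters. The desk grid list
(`24, 25, 26, 27, 28, 30, 35, 60`) therefore samples the crowded end
finely — grid 24 is 87% occupied, grid 27 sits near the size maximum —
and was verified to give the same qualitative picture across independent
base seeds and longer runs before being frozen. The qualitative claims
(non-monotone size with obstacles, monotone size without, post-expansion
decay with a transient size overshoot) are asserted by the test suite at
exactly these preset conditions.

## What passing these tests shows — and what it does not

The orderings demonstrate that excluded volume plus slow crowders
reproduce the observed direction of condensate changes under shrinkage
and recovery. They do not calibrate the lattice to physical units: a grid
square is not a nanometre, a step is not a second, and no mapping from
grid size to osmolality is attempted.

# The FRAP pipeline

For condensates too mobile for classic single-spot FRAP, many condensates
are bleached at once and tracked afterwards. From a long-format track
table (`track_id, frame, time, x, y, intensity`), `frap_quantify()`:

1. **retains** tracks present in both phases with ≥ 25 frames
   (`filter_tracks()`);
2. **classifies** each track by whether its mean Before-phase position
   falls inside the bleach rectangle, closed bounds
   (`classify_bleached()`);
3. converts intensities to the **relative change** `F_i(t)/F_i,Before`
   (`relative_change()`);
4. **drops false positives**: geometrically bleached tracks whose mean
   relative change over their first three After frames exceeds 0.85,
   i.e. that lost less than 15% (`drop_false_positives()`; a drop of
   exactly 15% is retained);
5. **quench-corrects**: divides by the non-bleached group mean at each
   time point, cancelling acquisition photobleaching exactly when all
   tracks share the frame grid (`quench_correct()`);
6. pools bleached tracks into `G(t)` and rescales to
   `FRAP rate [%] = (G - G_Min)/(1 - G_Min) * 100`, with `G_Min` the
   minimum of `G` over the first three After time points
   (`frap_rate_curve()`).

Cohorts of cells are cleaned with the shared extreme-outlier rule
(values outside `[Q1 - 5 IQR, Q3 + 5 IQR]`, quartiles by linear
interpolation, R's default type 7) applied to the final-time FRAP rate
(`trim_outlier_cells()`); with fewer than four cells nothing is trimmed.

Open details were resolved as follows: the Before-phase *mean* position
(not a single frame) decides group membership, for robustness to
localization jitter; the false-positive window mirrors the `G_Min`
window (first three After frames); gaps in tracks stay missing — group
means use whichever tracks are present at each time point, and times
with no non-bleached coverage are dropped and logged; the outlier
statistic is the final-time FRAP rate.

```{r frap}
g <- make_frap_tracks(seed = 1)
res <- frap_quantify(g$tracks, frap_params_for(g$truth))
res
frap_plateau(res)          # estimates 100 * mobile fraction (truth: 60)
```

## The synthetic FRAP generator

`make_frap_tracks()` emits Before + After frames per track with Brownian
positional jitter; bleached tracks follow
`(1 - d) + m d (1 - exp(-(t - t_b)/tau))`, everything is multiplied by a
global quench `exp(-lambda t)`, and relative Gaussian noise is added.
Recovery is measured from the first After frame, so the noiseless
pipeline output equals `100 m (1 - exp(-(t - t_b)/tau))` exactly and the
plateau estimates `100 m`.

Defaults (chosen once, as a realistic acquisition for this assay, and
not revisited): 5 Before frames and 100 After frames at 2.1 s interval;
12 bleached and 20 non-bleached tracks; bleach depth `d = 0.8` (an ~80%
drop is typical for a successful bleach); mobile fraction `m = 0.6`
(recovery that is clear but incomplete); `tau = 30 s`, placing the
plateau well inside the 210 s acquisition; quench `lambda = 0.002/s`
(~35% loss over the acquisition, large enough that an uncorrected
pipeline would visibly fail); relative noise sd 0.05. The generator uses
single-exponential kinetics as a test-harness choice — the pipeline fits
no model, so nothing downstream depends on that form. It does not
emulate detection/linking failures, z-drift, or intensity-dependent
localization bias; the track filters are therefore exercised by targeted
fixtures rather than by the generator.

# Image-based condensate quantification

`detect_condensates()` mirrors a standard particle-analysis macro:
Gaussian smoothing (`sigma = 1.5` px), adaptive mean thresholding (a
pixel is foreground when the smoothed image exceeds its `15x15`
neighbourhood mean by `offset = 0.02`), restriction to the cell mask,
4-connected labelling, and a `min_area = 4` px² filter. The local
threshold makes detection exactly invariant to image-wide additive
offsets. The cell ROI is an input mask; deriving it from transmitted
light images is out of scope. Sizes are reported in px²; the original
macro's parameters were tuned per instrument and are likewise exposed
here, with defaults calibrated once against the synthetic spot generator
(exact counts at its default SNR).

`quantify_invitro()` implements the in vitro assay summary: per field, a
background correction subtracting a heavily blurred copy of the image (a
smoothing equivalent of a rolling-ball correction; EBImage provides no
rolling ball), particle detection, and the total corrected intensity
over particles; the sample amount is the mean over (by default five)
fields. `normalize_to_standard()` divides by the internal-standard
sample and optionally by the control mean, the two-stage ratio used to
compare constructs across experiments.

```{r spots}
g <- make_spot_image(n_spots = 7, seed = 42)
detect_condensates(g$image, g$mask)$count
```

# Numerical and degenerate-input choices

* Rates live in `[0, 1]`; acceptance is the strict comparison `k > r`
  with `r` uniform on `[0, 1)`, so a rate of exactly 1 is always
  accepted and a rate of 0 never is.
* The compiled kernel uses R's own RNG stream; seeding with `set.seed()`
  reproduces whole trajectories bit-for-bit, and chunked runs equal
  unchunked runs of the same length.
* Zero-step runs record exactly the initial snapshot; zero qualifying
  clusters report `mean_size = 0`; a single replicate reports `SEM = 0`
  with a warning; fewer than four cells skip the outlier trim with a
  warning; a cohort with no bleach depth (`G_Min >= 1`) yields `NA` FRAP
  rates with a warning rather than an error.
* Time points are grouped by their numeric values (never by character
  keys), so irregular frame intervals survive exactly.

# Known limitations

* The lattice model is 2D, single-occupancy and dimensionless; it makes
  qualitative, not quantitative, predictions.
* Obstacles are inert and uniform; real crowders are polydisperse and
  interact.
* Cluster "size" is units per cluster, not an imaging-convolved area.
* The FRAP pipeline assumes the bleach falls cleanly between the Before
  and After phases and applies no diffusion-model fitting or
  bleach-geometry correction.
* Spot detection assumes single-channel 2D images and compact spots;
  elongated or overlapping condensates will be under-segmented.
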