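---
title: "The woundsim model and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The woundsim model and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

woundsim simulates re-epithelialization of a partial-thickness scratch
wound in back-skin epidermis and re-implements the quantitative analyses
used on intravital time-lapse data of that process: track-based motility
metrics, Delaunay neighbour-retention statistics, membrane segmentation
with particle filters, and zone-binned Fucci proliferation analysis. This
vignette describes the model, its parameters, the numerical choices, and
what the synthetic data can and cannot validate.

## The agent-based model

The tissue is a 2-D plane. The wound is the axis-aligned strip
`|x| < wound_half_width`; distance to the wound is distance to the nearest
strip edge, `max(0, |x| - wound_half_width)`, and 0 inside the strip.
Scratch wounds in this system are long and narrow (full widths of 50-200
µm), so a strip with distance bands parallel to it is the natural geometry.
Three cell populations share the plane:

* **Basal keratinocytes** are the motile, proliferative population.
  Each step they receive (i) a drift of magnitude `v(d) * dt` toward the
  wound, (ii) isotropic Gaussian positional noise, and (iii) soft-core
  pairwise repulsion.
* **Suprabasal keratinocytes** receive positional noise only. They are a
  separate population on the same plane (no z mechanics); their observed
  behaviour in vivo is to stay in place while the basal layer migrates
  underneath.
* **Hair-follicle cells** populate circular obstacle disks and never move;
  the disks are impassable to all other cells. Because they are immobile
  they double as fiducials for drift correction (`estimate_drift()`).

**Speed field.** Measured median speeds anchor the drift at 0.05 µm/min
within 0.5 mm of the wound edge and 0.025 µm/min beyond 1 mm. Between
`d_near` (500 µm) and `d_far` (1000 µm) the speed interpolates linearly —
the simplest monotone field through the two anchors.

**Heading wobble.** The drift direction is wound-ward plus a Gaussian
angular deviation (`heading_sigma`, default 0.35 rad, redrawn each step).
The rotation leaves the step length — and therefore path-length speeds —
unchanged, but it makes the relative motion of neighbouring cells scale
with their drift speed. This is what lets the model reproduce the observed
swarming phenotype, in which faster cells exchange neighbours more: with a
purely parallel drift field a uniformly translating sheet would retain all
neighbours regardless of speed.

**Jamming.** No keratinocyte enters the wound bed during the first ~20 h
in vivo, although the sheet starts moving immediately. The mechanism is
unknown (loss of contact inhibition of locomotion has been suggested), so
the model does not assert one: the wound edge is a reflecting boundary
until `t_unjam` (default 20 h) and a global switch opens it afterwards.
Inside the strip the drift points toward the centreline, so the two fronts
advance until they meet. `closure_time()` declares closure when every
point of a 10-µm lattice spanning the strip lies within `coverage_radius`
(default 15 µm, about one basal cell diameter) of a basal cell; with
default parameters closure occurs around 35-40 h, consistent with the
observed 1-2 days.

**Repulsion.** Pairs of basal cells closer than `repulsion_radius` (9 µm,
matching the initial minimum spacing) repel with speed
`repulsion_strength * (1 - d/r)`. The default strength (0.15 µm/min, three
times the near-wound drift speed) is set so that (a) the advancing sheet
compresses only moderately at the jammed edge, and (b) the transient
neighbourhood relaxation after a division perturbs path lengths by less
than the drift displacement scale. The second point matters: the
population's own observation is that proliferative state does not alter
migration, so division side-effects must stay below the measurement scale
(see "Phase-stratified motility" below). Per-step repulsion displacement is
capped at half the radius for numerical stability.

**Cell cycle.** Basal cells follow a two-state cycle: G1 with a constant
per-step entry hazard into S/G2, a fixed `sg2_duration` (6 h) in S/G2, then
division. The daughter is placed `repulsion_radius` away in a uniform
random direction; both cells revert to G1. The hazard is zone-specific so
that the stationary S/G2 fraction is ~5% at 0-200 µm from the wound, ~10%
at 200-400 µm (the proliferative zone), and a 2% baseline beyond —
`sg2_hazard()` documents the renewal closed form
`h = f / (n_s (1 - f))`. The simulator itself uses a growth-corrected
calibration: since each division returns *two* G1 cells the population
grows exponentially and young (G1) cells are over-represented, so the
renewal form under-delivers S/G2 by roughly half a percentage point at
f = 0.10. The corrected hazard solves the Euler-Lotka equation
`2 rho^{-n_s} h / (rho - 1 + h) = 1` jointly with the stable-age S/G2
fraction (see the comments in `R/simulate.R`). Initial phases are drawn
from the per-zone stationary mix with uniform residual S/G2 ages.

**Initial positions** are seeded uniform samples thinned by a
minimum-spacing rule (`0.7 * sqrt(mean target area)`), the standard
hard-core point process; densities are one cell per mean target area
(basal 175 µm², suprabasal 450 µm²), with the wound strip excluded — the
scratch removes the tissue it crosses — and follicle disks reserved for
follicle cells.

**Units.** Tables use hours and µm; speeds are µm/min (the persistence
gate is quoted in µm/h, following the source convention, and converted
internally). The integrator works in minutes.

**Domain size.** `domain_half_extent` (1500 µm) covers the farthest
distance band (>1 mm); `domain_height` (500 µm) is chosen so the 200-400
µm zone holds >500 basal cells per frame, the sample size at which zone
fractions are estimated to about ±1 percentage point from one run. This is
the package's default problem size (~11,000 agents, 96 frames, a few
seconds per simulation).

## What the simulator does and does not emulate

The generator reproduces: the two-step closure (immediate directed
migration, jamming, delayed wound-bed entry), the distance-dependent speed
field, static suprabasal and follicle populations, size-separated basal
and suprabasal layers, zone-structured proliferation with stationary
fractions, neighbour exchange increasing with migration speed, and 30-min
frame spacing. It does not emulate: 3-D tissue mechanics or the basement
membrane, immune signalling or any unjamming mechanism, tile-scan
stitching or microscope optics (renders are idealized Voronoi
tessellations with a flat background), EdU chemistry (divisions within a
look-back window serve as the proxy, `edu_proxy_counts()`), or biological
heterogeneity between animals. Passing tests therefore show that the
*pipeline* recovers known ground truth from data with the right structure
and scale — not that the model captures every property of real epidermis.

## The analysis pipeline

**Tracks.** The exchange format is a long CSV (`track_id, frame, time_h,
x_um, y_um, compartment, phase, ch1, ch2`). `link_detections()` is a
nearest-neighbour linker in the MTrack2 tradition: greedy mutual-nearest
matching between consecutive frames, bounded by `max_disp`, ties broken by
detection index. `estimate_drift()` uses the follicle compartment as
static fiducials and accumulates per-step median displacement vectors; the
median makes it robust to a minority of moving outliers. The in-vivo
pipeline corrected XYZ drift with custom software on volumetric scans; the
fiducial-median scheme is a declared 2-D stand-in, not a reconstruction.

**Motility.** "Velocity" in the distance-binned analyses
(`velocity_by_distance()`) is path length / duration — the source
separately reports displacement and persistence, which implies speed here;
the alternative reading (net/duration) exists as the `velocity` argument of
`compare_by_phase()`. "Migratory" gates on net displacement > 10 µm per
8 h (strict), evaluated from the first windowed point to the point nearest
8 h later. Persistence is net/path in [0, 1] for cells whose mean speed
exceeds 5 µm/h; the unbounded reciprocal (the literal reading of
"deviation of total track length by total displacement") is available via
`ratio = "path_over_net"`. Direction angles are measured from the
wound-ward unit vector at the track start, and rose-plot sectors are
centred on 0° so the wound-ward mode falls inside one sector rather than
splitting across two.

**Neighbour retention.** Contact topology is approximated by the Delaunay
triangulation of centroids pruned at `max_edge` (default twice the median
nearest-neighbour distance at `t0`, held fixed over the follow-up) — the
standard centroid proxy for epithelial contact neighbourhoods; the imaging
study inferred contacts from membrane signal instead. Retention is
instantaneous: `fraction(t) = |N0 ∩ N(t)| / |N0|`, so re-acquired
neighbours count again; this follows the phrase "fraction of original
neighbors that remain". Cells whose tracks end early are censored at their
last frame. Degenerate inputs (collinear, < 3 points) fall back to
distance-cutoff adjacency; exactly duplicated positions are perturbed
deterministically by ~1e-6 µm with a warning. `group_retention()` reports
mean ± SEM (sample SD / sqrt(n)) per group; the aggregation unit is the
cell unless an imaging-position assignment is supplied, in which case
cells are averaged within position first — mirroring designs that average
over imaging positions in a few animals.

**Segmentation.** `pixel_classify()` is a fixed classical stand-in for a
trained pixel classifier, adequate for bright-membrane images: smoothing at
the membrane scale plus a rectified difference-of-Gaussians ridge term,
normalized to [0, 1] between robust percentile bounds. `segment_membrane()`
labels 4-connected sub-threshold components (ties at the threshold count
as membrane). Perimeters use the weighted border-pixel estimator
(isothetic/diagonal/corner weights 1, √2, (1+√2)/2), which is unbiased for
smooth shapes where a plain border count overestimates a disk's perimeter
by ~27%; circularity `4πA/P²` is capped at 1 after discretization. The
60-2500 size filter is interpreted in µm² (applied after pixel scaling):
the source does not state units, but the adjacent cell-area analyses are
reported in µm². Uncovered background in a render segments into
background-grey regions; they are distinguished from tissue by interior
intensity, as a practitioner would.

**Proliferation.** `fucci_classify()` calls S/G2 when the S/G2-reporter
channel exceeds the G1-reporter channel, ties to G1. Zone fractions use
edges {0, 200, 400, 600, 800, 1000} µm, time-averaged per frame over the
16-24 h analysis window by default (`average = "pooled"` pools counts
instead; the source window phrasing admits both readings and the two
differ negligibly here). Statistical tests (Welch t, Kruskal-Wallis) are
delegated to the standard routines; the package's contribution is the
upstream quantities.

**Phase-stratified motility.** Comparing migration between S/G2 and G1
cells needs care in a simulation, because every cell in S/G2 at the start
of an 8-h window divides inside it (S/G2 lasts 6 h), and the neighbourhood
relaxation around each division adds direction-random micro-steps. These
inflate *path* length by ~1% in proportion to local division activity,
which correlates with phase through zone residence — a census-scale t-test
(n > 1000) flags this reliably even though it is far below the biological
scale of interest. The package's comparison design therefore (i) assigns
phase at the window end and excludes cells that divided inside the window
(the division is directly observable in Fucci data as an S/G2-to-G1
colour switch, and such cells have an ambiguous label anyway), (ii) uses
net-displacement velocity, which is insensitive to direction-random
micro-steps, and (iii) caps cohorts at `max_per_phase` records per phase
(100 in the pipeline), matching the scale of a tracked intravital cohort
rather than a simulation census. Under this design the phase comparison
is null to within test resolution, as the biology dictates.

## Orchestration and reproducibility

`run_pipeline()` drives simulate → tracks → Fucci intensities → motility →
neighbours → proliferation → segmentation → report from one configuration
document and one master seed. Each stage draws from `stage_seed(master,
stage_name)` — a small polynomial hash — so adding or skipping a stage
never shifts another stage's random stream; reruns with identical inputs
reproduce identical CSVs byte for byte. The manifest (`manifest.json`)
records the configuration snapshot, per-stage seeds, timings, outputs and
warnings. A thin command-line wrapper (`inst/cli/woundsim.R`) exposes
`simulate`, `run` and `report` subcommands; individual analysis stages are
run through `run --stages`. CSVs are UTF-8 with `.` decimal and LF line
endings.

## Known limitations

* The unjamming transition is a clock, not a mechanism; entry time is an
  input (`t_unjam`), and only its downstream consequences are emergent.
* Zone S/G2 fractions are advected: cells crossing zone boundaries carry
  their phase history, producing a thin (~15 µm) boundary layer where the
  realized fraction deviates from the target by a fraction of a
  percentage point.
* The Voronoi renders have polygonal cells with uniform intensities; the
  segmentation defaults are tuned to this geometry and will need
  re-tuning (σ, threshold) for real membrane images.
* Delaunay adjacency over-connects across small gaps relative to true
  membrane contact; the `max_edge` prune mitigates but does not remove
  this.
* With `domain_height` = 500 µm, single-run zone-fraction estimates carry
  ~1 percentage point of seed-to-seed spread; multi-seed averaging is
  advised for tighter comparisons.
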