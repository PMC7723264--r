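# woundsim

Agent-based simulation and quantitative analysis of partial-thickness
scratch-wound re-epithelialization in skin epidermis.

Superficial scratch wounds (50–200 µm wide, hair follicles spared) heal
differently from full-thickness wounds: only the basal keratinocyte layer
migrates — immediately, as a cohesive but internally rearranging
("swarming") sheet — while suprabasal cells stay in place; the sheet jams
at the wound edge for ~20 h before entering the wound bed, and cell loss
is replenished from a proliferative zone 200–400 µm behind the wound
margin. `woundsim` is for researchers quantifying this kind of intravital
time-lapse data: it implements the full measurement pipeline (tracking,
drift correction, motility metrics, neighbour-exchange statistics,
membrane segmentation, cell-cycle zone analysis) together with an
agent-based model of the process that serves as a ground-truth generator
for validating every stage.

## The model in brief

Basal cells at distance $d$ from the wound edge drift wound-ward with speed

$$v(d) = \begin{cases} v_\text{near} & d \le d_\text{near} \\
\text{linear} & d_\text{near} < d < d_\text{far} \\
v_\text{far} & d \ge d_\text{far}\end{cases}
\qquad (0.05 \to 0.025\ \mu\text{m/min over } 0.5 \to 1\ \text{mm}),$$

with Gaussian angular wobble on the heading (so neighbour exchange scales
with speed), isotropic positional noise, and short-range soft-core
repulsion. The wound strip reflects cells until an unjamming time
(default 20 h); hair-follicle disks are immobile obstacles. Cells cycle
G1 → S/G2 → division with zone-specific hazards calibrated (closed form,
growth-corrected) so stationary S/G2 fractions are ~5% at 0–200 µm,
~10% at 200–400 µm, 2% beyond. Key track statistics: mean speed =
path length/duration; persistence = net displacement/path length (gated
at 5 µm/h); "migratory" = net displacement > 10 µm per 8 h; neighbour
retention $|N_0 \cap N(t)|/|N_0|$ over pruned Delaunay adjacency;
circularity $4\pi A/P^2$ with the 0.2–1 / 60–2500 µm² particle filter.
See `vignettes/wound-model.Rmd` for the full account.

## Worked example

```r
library(woundsim)

cfg <- sim_config(seed = 1)          # defaults reproduce the study conditions
sim <- simulate_wound(cfg)
sim
#> <wound_sim>
#>   97 frames over 48 h; 11277 agents initially, 14086 finally (2809 divisions)
entry_time(sim); closure_time(sim)
#> [1] 20.5        # first basal cell enters the wound bed after the 20-h jam
#> [1] 37          # wound strip covered by basal cells at 37 h (~1.5 days)

tracks <- export_tracks(sim)
rec <- track_metrics(tracks, wound_half_width = 75, window = c(16, 24))
velocity_by_distance(rec)
#> # A tibble: 3 x 5
#>   bin      median_speed    q25    q75     n
#> 1 <500           0.0515 0.0495 0.0539  3461
#> 2 500-1000       0.0397 0.0334 0.0459  2831
#> 3 >1000          0.0276 0.0263 0.0292  2078

zone_fraction_window(tracks, wound_half_width = 75, window = c(16, 24))
#> # A tibble: 5 x 5
#>   zone_lo zone_hi n_total n_sg2 fraction_sg2
#> 1       0     200   29449  1587       0.0540
#> 2     200     400   24664  2496       0.101
#> 3     400     600   20136   414       0.0206
#> 4     600     800   19247   362       0.0188
#> 5     800    1000   19512   403       0.0207
```

Migratory basal cells within 0.5 mm of the wound move at a median
0.0515 µm/min and those beyond 1 mm at 0.0276 µm/min (the configured
0.05/0.025 anchors plus a small noise contribution to path length); 10.1%
of basal cells in the 200–400 µm zone are in S/G2 versus 5.4% directly at
the wound — the proliferative zone sits behind the margin, not at it.

The whole pipeline (simulation → tracks → Fucci intensities → motility →
neighbour retention → proliferation → segmentation → figures) runs from
one seed with `run_pipeline(cfg, seed = 1, out_dir = "out")`, or from a
shell via `Rscript inst/cli/woundsim.R run --config cfg.yaml --seed 1
--out out`.

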