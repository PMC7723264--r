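# Heavy simulation products are computed once and shared across test files
# (test files run in one process; the acceptance file, first alphabetically,
# pays most of the cost).
.run_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) assign(key, force(expr), envir = .run_cache)
  .run_cache[[key]]
}

DEFAULT_SEED <- 101L
ANALYSIS_WINDOW <- c(16, 24)

default_sim <- function() {
  .cached("sim", simulate_wound(sim_config(seed = DEFAULT_SEED)))
}

default_tracks <- function() {
  .cached("tracks", export_tracks(default_sim()))
}

default_records <- function() {
  .cached("records",
          track_metrics(default_tracks(), wound_half_width = 75,
                        window = ANALYSIS_WINDOW))
}

default_fucci_tracks <- function() {
  .cached("fucci", {
    tr <- default_tracks()
    wf <- sort(unique(tr$frame[tr$time_h >= ANALYSIS_WINDOW[1] - 1e-9 &
                                 tr$time_h <= ANALYSIS_WINDOW[2] + 1e-9]))
    set.seed(DEFAULT_SEED + 1L)
    add_fucci_intensities(tr, default_sim(), frames = wf)
  })
}

# 10-seed battery: entry time plus distance-grouped retention ordering at
# the final time point; only the summary is kept in memory.
seed_battery <- function(seeds = 1:10) {
  .cached("battery", {
    rows <- lapply(seeds, function(s) {
      sim <- simulate_wound(sim_config(seed = s))
      tr <- export_tracks(sim)
      ent <- entry_time(sim)
      ser <- retention_fraction(tr, t0 = ANALYSIS_WINDOW[1],
                                horizon = diff(ANALYSIS_WINDOW))
      rec <- track_metrics(tr, 75, window = ANALYSIS_WINDOW)
      cur <- group_retention(ser,
                             setNames(rec$initial_distance_to_wound,
                                      rec$track_id),
                             grouping = "distance")
      fin <- cur[cur$time_rel_h == diff(ANALYSIS_WINDOW), ]
      fr <- setNames(fin$mean_fraction, as.character(fin$group))
      data.frame(seed = s, entry = ent,
                 ret_near = fr[["<0.5 mm"]], ret_mid = fr[["0.5-1 mm"]],
                 ret_far = fr[[">1 mm"]],
                 t0_all_one = all(ser$fraction[ser$time_rel_h == 0] == 1))
    })
    do.call(rbind, rows)
  })
}

# 20-run phase-null battery (24-h horizon; the analysis window is 16-24 h).
phase_battery <- function(seeds = 1:20) {
  .cached("phase_battery", {
    vapply(seeds, function(s) {
      sim <- simulate_wound(sim_config(seed = s, t_end = 24))
      rec <- track_metrics(export_tracks(sim), 75, window = ANALYSIS_WINDOW)
      mig <- rec[rec$compartment == "basal" & rec$migratory %in% TRUE &
                   !rec$divided, ]
      mig$phase <- mig$phase_end
      set.seed(s + 5000L)
      cmp <- compare_by_phase(mig, zone_edges = c(200, 400),
                              max_per_phase = 100)
      cmp$p_value[cmp$metric == "velocity"]
    }, numeric(1))
  })
}

# dense noise-free basal render + its segmentation, reused by the
# segmentation tests
basal_render_case <- function() {
  .cached("render_case", {
    set.seed(42)
    P <- woundsim:::.rsa_sample(230, c(0, 200, 0, 200), 0.7 * sqrt(175))
    fr <- mk_frame(seq_len(nrow(P)), "basal", P[, 1], P[, 2])
    rd <- render_membrane(fr, "basal", render_params(), bbox = c(0, 200, 0, 200))
    pm <- pixel_classify(rd$image)
    seg <- segment_membrane(pm)
    list(frame = fr, render = rd, prob = pm, seg = seg)
  })
}
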