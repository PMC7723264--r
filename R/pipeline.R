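#' Derive a per-stage seed from the master seed
#'
#' `seed(stage) = (master * 7919 + hash(stage name)) mod (2^31 - 1)`, where
#' the hash is a small polynomial over the stage-name bytes. Adding a stage
#' never shifts another stage's random stream.
#' @param master Master seed (integer).
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1e6
  as.integer((abs(as.numeric(master)) %% 1e6 * 7919 + h * 1009) %% 2147483647)
}

.pl_log <- function(quiet, ...) {
  if (!quiet) message(sprintf(...))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Orchestrates simulate -> export tracks -> Fucci intensities -> motility
#' -> neighbour retention -> proliferation -> segmentation -> report from a
#' single configuration and seed. Outputs are CSV files (plus figures from
#' the report stage) under `out_dir`; a JSON run manifest records the
#' configuration snapshot, per-stage seeds, outputs, timings and warnings.
#' Reruns with identical inputs reproduce identical CSV outputs.
#'
#' @param config A `sim_config`, a named list, or a path to a YAML/JSON
#'   config file.
#' @param seed Master seed; overrides the config seed. Every stage draws
#'   from its own [stage_seed()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "tracks", "fucci", "motility", "neighbors",
#'   "proliferation", "segmentation", "report")`. Analysis stages re-read
#'   `tracks.csv` from `out_dir` when the simulation stage is skipped.
#' @param window Analysis window `c(start, end)` in hours.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir, force = FALSE,
                         stages = c("simulate", "tracks", "fucci", "motility",
                                    "neighbors", "proliferation",
                                    "segmentation", "report"),
                         window = c(16, 24), quiet = FALSE) {
  all_stages <- c("simulate", "tracks", "fucci", "motility", "neighbors",
                  "proliferation", "segmentation", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  cfg <- if (is.character(config)) read_sim_config(config) else as_sim_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("'", out_dir, "' exists and is not empty; use force = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master <- cfg$seed
  manifest <- list(package = "woundsim",
                   version = as.character(packageVersion("woundsim")),
                   seed = master,
                   window = window,
                   config = unclass(cfg),
                   stages = list())
  paths <- list(tracks = file.path(out_dir, "tracks.csv"))
  sim <- NULL
  tracks <- NULL
  windows_frames <- NULL

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) {
        .write_manifest(manifest, out_dir)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      seed = stage_seed(master, name),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      warnings = warns)
    .pl_log(quiet, "[%s] done in %ss", name,
            manifest$stages[[name]]$seconds)
    res
  }

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() {
      cfg$seed <- stage_seed(master, "simulate")
      simulate_wound(cfg)
    })
    tracks <- export_tracks(sim)
  } else if (file.exists(paths$tracks)) {
    tracks <- read_tracks(paths$tracks)
    .pl_log(quiet, "[simulate] skipped; using existing %s", paths$tracks)
  } else {
    stop("simulation stage skipped but ", paths$tracks, " not found",
         call. = FALSE)
  }
  wf <- which(tracks$time_h >= window[1] - 1e-9 &
                tracks$time_h <= window[2] + 1e-9)
  window_frames <- sort(unique(tracks$frame[wf]))

  if ("fucci" %in% stages && !is.null(sim)) {
    tracks <- run_stage("fucci", function() {
      set.seed(stage_seed(master, "fucci"))
      add_fucci_intensities(tracks, sim, frames = window_frames)
    })
  }
  if ("tracks" %in% stages) {
    run_stage("tracks", function() write_tracks(tracks, paths$tracks))
  }

  if ("motility" %in% stages) {
    run_stage("motility", function() {
      rec <- track_metrics(tracks, cfg$wound_half_width, window = window)
      readr::write_csv(rec, file.path(out_dir, "metrics.csv"), eol = "\n")
      vbd <- velocity_by_distance(rec)
      readr::write_csv(vbd, file.path(out_dir, "velocity_by_distance.csv"),
                       eol = "\n")
      bas <- rec[rec$compartment %in% "basal" & rec$migratory %in% TRUE &
                   !is.na(rec$direction_angle), ]
      rose <- rose_histogram(bas$direction_angle)
      readr::write_csv(rose, file.path(out_dir, "rose.csv"), eol = "\n")
      dbc <- displacement_by_compartment(rec)
      readr::write_csv(dbc, file.path(out_dir,
                                      "displacement_by_compartment.csv"),
                       eol = "\n")
      NULL
    })
  }
  if ("neighbors" %in% stages) {
    run_stage("neighbors", function() {
      ser <- retention_fraction(tracks, t0 = window[1],
                                horizon = window[2] - window[1])
      rec <- track_metrics(tracks, cfg$wound_half_width, window = window)
      vals <- setNames(rec$initial_distance_to_wound, rec$track_id)
      cur <- group_retention(ser, vals, grouping = "distance")
      readr::write_csv(cur, file.path(out_dir, "retention.csv"), eol = "\n")
      NULL
    })
  }
  if ("proliferation" %in% stages) {
    run_stage("proliferation", function() {
      has_ch <- any(!is.na(tracks$ch1))
      zf <- zone_fraction_window(tracks, cfg$wound_half_width, window,
                                 phase_from = if (has_ch) "channels" else "column")
      readr::write_csv(zf, file.path(out_dir, "zone_fractions.csv"),
                       eol = "\n")
      rec <- track_metrics(tracks, cfg$wound_half_width, window = window)
      # phase-stratified comparison on migratory cells with an unambiguous
      # phase over the window (no in-window division), labelled by end phase
      mig <- rec[rec$compartment %in% "basal" & rec$migratory %in% TRUE &
                   !rec$divided %in% TRUE, ]
      mig$phase <- mig$phase_end
      if (length(unique(mig$phase[mig$phase %in% c("G1", "SG2")])) == 2) {
        set.seed(stage_seed(master, "proliferation"))
        cmp <- compare_by_phase(mig, zone_edges = c(0, 200, 400),
                                max_per_phase = 100)
        readr::write_csv(cmp, file.path(out_dir, "phase_comparison.csv"),
                         eol = "\n")
      } else {
        warning("phase comparison skipped: fewer than two phases present")
      }
      NULL
    })
  }
  if ("segmentation" %in% stages && !is.null(sim)) {
    run_stage("segmentation", function() {
      set.seed(stage_seed(master, "segmentation"))
      k <- max(window_frames) + 1L
      fr <- sim$frames[[min(k, length(sim$frames))]]
      bbox <- c(-250, 250, 0, min(300, cfg$domain_height))
      tabs <- lapply(c("basal", "suprabasal"), function(layer) {
        rd <- render_membrane(fr, layer, render_params(), bbox = bbox)
        write_render(rd, file.path(out_dir, paste0(layer, "_membrane.tif")),
                     file.path(out_dir, paste0(layer, "_labels.tif")))
        pm <- pixel_classify(rd$image)
        seg <- segment_membrane(pm)
        props <- region_props(seg, rd$pixel_size, origin = rd$bbox[c(1, 3)],
                              wound_half_width = cfg$wound_half_width,
                              layer = layer)
        filter_regions(props)
      })
      readr::write_csv(dplyr::bind_rows(tabs),
                       file.path(out_dir, "regions.csv"), eol = "\n")
      NULL
    })
  }
  if ("report" %in% stages) {
    run_stage("report", function() make_report(out_dir, quiet = quiet))
  }
  manifest$outputs <- dir(out_dir)
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Build summary figures and a headline-number table from pipeline outputs
#'
#' Reads the stage CSVs in `out_dir` and writes a rose plot, retention
#' curves with SEM bands, velocity-by-distance summaries and zone-fraction
#' bars (PNG), plus `summary.csv` with the headline numbers. Figures whose
#' inputs are missing are skipped with a warning.
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @param quiet Suppress messages.
#' @return Invisibly, the summary tibble.
#' @export
make_report <- function(out_dir, quiet = FALSE) {
  p <- function(f) file.path(out_dir, f)
  summary_rows <- list()
  if (file.exists(p("velocity_by_distance.csv"))) {
    vbd <- readr::read_csv(p("velocity_by_distance.csv"),
                           show_col_types = FALSE)
    gg <- ggplot2::ggplot(vbd, ggplot2::aes(x = .data$bin,
                                            y = .data$median_speed)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                            ymax = .data$q75)) +
      ggplot2::labs(x = "distance to wound (um)",
                    y = "median speed (um/min)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(p("fig_velocity_by_distance.png"), gg,
                    width = 4, height = 3, dpi = 150)
    for (i in seq_len(nrow(vbd))) {
      summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
        quantity = paste0("median_speed_um_min_", vbd$bin[i]),
        value = vbd$median_speed[i], n = vbd$n[i])
    }
  } else {
    warning("velocity_by_distance.csv missing; figure skipped")
  }
  if (file.exists(p("rose.csv"))) {
    rose <- readr::read_csv(p("rose.csv"), show_col_types = FALSE)
    gg <- ggplot2::ggplot(rose, ggplot2::aes(x = .data$mid_deg,
                                             y = .data$count)) +
      ggplot2::geom_col(width = 360 / nrow(rose)) +
      ggplot2::coord_polar(start = -pi / nrow(rose)) +
      ggplot2::scale_x_continuous(limits = c(-360 / nrow(rose) / 2,
                                             360 - 360 / nrow(rose) / 2),
                                  breaks = c(0, 90, 180, 270)) +
      ggplot2::labs(x = "angle to wound-ward direction (deg)", y = "cells") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(p("fig_rose.png"), gg, width = 4, height = 4, dpi = 150)
  } else {
    warning("rose.csv missing; figure skipped")
  }
  if (file.exists(p("retention.csv"))) {
    ret <- readr::read_csv(p("retention.csv"), show_col_types = FALSE)
    ret <- ret[ret$n_units > 0, ]
    if (nrow(ret)) {
      gg <- ggplot2::ggplot(ret, ggplot2::aes(x = .data$time_rel_h,
                                              y = .data$mean_fraction,
                                              colour = .data$group,
                                              fill = .data$group)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_fraction - .data$sem,
                                          ymax = .data$mean_fraction + .data$sem),
                             alpha = 0.2, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time since t0 (h)",
                      y = "fraction of original neighbours") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(p("fig_retention.png"), gg, width = 5, height = 3,
                      dpi = 150)
      fin <- ret[ret$time_rel_h == max(ret$time_rel_h), ]
      for (i in seq_len(nrow(fin))) {
        summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
          quantity = paste0("retention_final_", fin$group[i]),
          value = fin$mean_fraction[i], n = fin$n_units[i])
      }
    } else {
      warning("retention.csv has no populated groups; figure skipped")
    }
  } else {
    warning("retention.csv missing; figure skipped")
  }
  if (file.exists(p("zone_fractions.csv"))) {
    zf <- readr::read_csv(p("zone_fractions.csv"), show_col_types = FALSE)
    zf$zone <- sprintf("%g-%g", zf$zone_lo, zf$zone_hi)
    gg <- ggplot2::ggplot(zf, ggplot2::aes(x = .data$zone,
                                           y = 100 * .data$fraction_sg2)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "distance to wound (um)", y = "% S/G2 cells") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(p("fig_zone_fractions.png"), gg, width = 4, height = 3,
                    dpi = 150)
    for (i in seq_len(nrow(zf))) {
      summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
        quantity = sprintf("sg2_percent_%g_%g", zf$zone_lo[i], zf$zone_hi[i]),
        value = 100 * zf$fraction_sg2[i], n = zf$n_total[i])
    }
  } else {
    warning("zone_fractions.csv missing; figure skipped")
  }
  summary <- dplyr::bind_rows(summary_rows)
  readr::write_csv(summary, p("summary.csv"), eol = "\n")
  if (!quiet) message("report written to ", out_dir)
  invisible(summary)
}
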