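.check_track <- function(track, min_points = 2L) {
  if (nrow(track) < min_points) {
    stop(sprintf("track needs >= %d points", min_points), call. = FALSE)
  }
  if (is.unsorted(track$time_h, strictly = TRUE)) {
    stop("track times must be strictly increasing", call. = FALSE)
  }
  invisible(track)
}

.step_lengths <- function(track) {
  sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
}

#' Mean (path-length) speed of a track
#'
#' Total path length — the sum of consecutive displacement magnitudes —
#' divided by total elapsed time. This is the "migration velocity" reported
#' by the distance-binned analyses; net-displacement-based measures are
#' reported separately (see [track_metrics()]).
#'
#' @param track Data frame with `time_h`, `x_um`, `y_um` (>= 2 rows,
#'   strictly increasing times).
#' @return Speed in µm/min.
#' @export
mean_speed <- function(track) {
  .check_track(track)
  sum(.step_lengths(track)) /
    ((track$time_h[nrow(track)] - track$time_h[1]) * 60)
}

#' Is a track migratory?
#'
#' A track is migratory when its net displacement over an observation window
#' strictly exceeds a threshold — the ">10 µm per 8 h" gate. The end point
#' is the track point closest in time to `start + window`.
#'
#' @param track As in [mean_speed()].
#' @param window Window length (hours).
#' @param threshold Net displacement threshold (µm); strict `>`.
#' @return `TRUE`/`FALSE`.
#' @export
is_migratory <- function(track, window = 8, threshold = 10) {
  .check_track(track)
  span <- track$time_h[nrow(track)] - track$time_h[1]
  if (span < window - 1e-9) {
    stop("track is shorter than the migratory window; pass a smaller 'window'",
         call. = FALSE)
  }
  j <- which.min(abs(track$time_h - (track$time_h[1] + window)))
  net <- sqrt((track$x_um[j] - track$x_um[1])^2 +
                (track$y_um[j] - track$y_um[1])^2)
  net > threshold
}

#' Directional persistence of a track
#'
#' Net displacement divided by total path length, in `[0, 1]` (1 = perfectly
#' straight). Defined only for tracks whose mean speed strictly exceeds the
#' speed gate (default 5 µm/h); `NA` otherwise. The unbounded reciprocal
#' (path/net) is available via `ratio = "path_over_net"`.
#'
#' @param track As in [mean_speed()].
#' @param speed_gate Gate in µm/h (note the unit; speeds elsewhere are
#'   µm/min).
#' @param ratio `"net_over_path"` (default, bounded) or `"path_over_net"`.
#' @return Persistence, or `NA` if the gate fails.
#' @export
persistence <- function(track, speed_gate = 5,
                        ratio = c("net_over_path", "path_over_net")) {
  ratio <- match.arg(ratio)
  .check_track(track)
  if (mean_speed(track) * 60 <= speed_gate) return(NA_real_)
  path <- sum(.step_lengths(track))
  stopifnot(path > 0) # gate implies movement
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                (track$y_um[nrow(track)] - track$y_um[1])^2)
  if (ratio == "net_over_path") net / path else path / net
}

#' Migration direction relative to the wound
#'
#' Angle in degrees between a track's net-displacement vector and the
#' wound-ward unit vector at the track start (pointing from the start toward
#' the nearest wound edge): 0° = straight at the wound, 180° = straight
#' away. Angles are reported in `[0, 360)`.
#'
#' @param track As in [mean_speed()].
#' @param wound_half_width Wound strip half-width (µm).
#' @return Angle in degrees, or `NA` for zero net displacement.
#' @export
direction_angle <- function(track, wound_half_width = 75) {
  .check_track(track)
  nx <- track$x_um[nrow(track)] - track$x_um[1]
  ny <- track$y_um[nrow(track)] - track$y_um[1]
  if (nx == 0 && ny == 0) return(NA_real_)
  x0 <- track$x_um[1]
  wx <- if (x0 > 0) -1 else 1 # wound-ward: toward the centreline
  # components along the wound-ward axis and its perpendicular
  along <- nx * wx
  perp <- -ny * wx
  (atan2(perp, along) * 180 / pi) %% 360
}

#' Rose-plot histogram of direction angles
#'
#' Counts over `n_bins` equal sectors covering `[0, 360)`, with sectors
#' centred on the wound-ward direction (the first sector spans
#' `[-width/2, width/2)` around 0°).
#'
#' @param angles Angles in degrees.
#' @param n_bins Number of sectors (>= 4).
#' @return Tibble: `sector` (1-based), `mid_deg` (sector centre), `count`;
#'   counts sum to `length(angles)` (NA angles dropped with a warning).
#' @export
rose_histogram <- function(angles, n_bins = 24) {
  stopifnot(n_bins >= 4)
  if (anyNA(angles)) {
    warning("dropping NA angles")
    angles <- angles[!is.na(angles)]
  }
  width <- 360 / n_bins
  sector <- floor(((angles + width / 2) %% 360) / width) + 1L
  counts <- tabulate(sector, nbins = n_bins)
  tibble::tibble(sector = seq_len(n_bins),
                 mid_deg = (seq_len(n_bins) - 1L) * width,
                 count = counts)
}

#' Per-track motility metrics
#'
#' Computes one record per track over an analysis window: mean (path) speed,
#' net displacement, path length, persistence (speed-gated), migratory flag,
#' initial distance to the wound edge, direction angle, compartment and
#' phase. `phase` is the phase at the first windowed point and `phase_end`
#' at the last; `divided` flags tracks showing an S/G2 -> G1 reporter switch
#' inside the window (i.e. a division; such cells have an ambiguous phase
#' label for phase-stratified comparisons). Tracks with fewer than two
#' points in the window are dropped; tracks shorter than the migratory
#' window get `migratory = NA`.
#'
#' @param tracks A track table.
#' @param wound_half_width Wound strip half-width (µm).
#' @param window `c(start, end)` in hours, or `NULL` for the full track
#'   table.
#' @param migratory_window,migratory_threshold See [is_migratory()].
#' @param speed_gate See [persistence()] (µm/h).
#' @return A tibble of motility records.
#' @export
track_metrics <- function(tracks, wound_half_width = 75, window = NULL,
                          migratory_window = 8, migratory_threshold = 10,
                          speed_gate = 5) {
  tab <- tracks
  if (!is.null(window)) {
    tab <- tab[tab$time_h >= window[1] - 1e-9 & tab$time_h <= window[2] + 1e-9, ]
  }
  tab <- tab[order(tab$track_id, tab$time_h), ]
  if (!nrow(tab)) return(tibble::tibble())
  g <- dplyr::group_by(tab, .data$track_id)
  step <- dplyr::mutate(
    g,
    dx = .data$x_um - dplyr::lag(.data$x_um),
    dy = .data$y_um - dplyr::lag(.data$y_um),
    step_len = sqrt(.data$dx^2 + .data$dy^2)
  )
  out <- dplyr::summarise(
    step,
    n_points = dplyr::n(),
    t0 = dplyr::first(.data$time_h),
    t1 = dplyr::last(.data$time_h),
    x0 = dplyr::first(.data$x_um), y0 = dplyr::first(.data$y_um),
    x1 = dplyr::last(.data$x_um), y1 = dplyr::last(.data$y_um),
    path_length = sum(.data$step_len, na.rm = TRUE),
    # migratory end point: closest in time to t0 + migratory_window
    jm = which.min(abs(.data$time_h - (dplyr::first(.data$time_h) +
                                         migratory_window))),
    xm = .data$x_um[jm], ym = .data$y_um[jm],
    compartment = dplyr::first(.data$compartment),
    phase = dplyr::first(.data$phase),
    phase_end = dplyr::last(.data$phase),
    # an S/G2 -> G1 reporter switch marks a division inside the window
    divided = any(.data$phase[-1] %in% "G1" &
                    .data$phase[-dplyr::n()] %in% "SG2"),
    .groups = "drop"
  )
  out <- out[out$n_points >= 2L, ]
  span <- out$t1 - out$t0
  net <- sqrt((out$x1 - out$x0)^2 + (out$y1 - out$y0)^2)
  net_m <- sqrt((out$xm - out$x0)^2 + (out$ym - out$y0)^2)
  speed <- out$path_length / (span * 60)
  pers <- ifelse(speed * 60 > speed_gate & out$path_length > 0,
                 net / out$path_length, NA_real_)
  wward_x <- ifelse(out$x0 > 0, -1, 1)
  ang <- (atan2(-(out$y1 - out$y0) * wward_x,
                (out$x1 - out$x0) * wward_x) * 180 / pi) %% 360
  ang[net == 0] <- NA_real_
  tibble::tibble(
    track_id = out$track_id,
    n_points = out$n_points,
    duration_h = span,
    mean_speed = speed,
    net_displacement = net,
    path_length = out$path_length,
    persistence = pers,
    migratory = ifelse(span >= migratory_window - 1e-9,
                       net_m > migratory_threshold, NA),
    initial_distance_to_wound = wound_distance(out$x0, wound_half_width),
    direction_angle = ang,
    compartment = out$compartment,
    phase = out$phase,
    phase_end = out$phase_end,
    divided = out$divided
  )
}

.bin_labels <- function(bin_edges) {
  e <- c(0, bin_edges, Inf)
  lab <- character(length(e) - 1L)
  for (j in seq_along(lab)) {
    lab[j] <- if (j == 1) {
      sprintf("<%g", e[2])
    } else if (is.infinite(e[j + 1])) {
      sprintf(">%g", e[j])
    } else {
      sprintf("%g-%g", e[j], e[j + 1])
    }
  }
  lab
}

#' Median migration velocity by distance to the wound
#'
#' Median and interquartile range of per-track mean speeds of migratory
#' basal records, binned by initial distance to the wound edge (default
#' bins: <0.5 mm, 0.5-1 mm, >1 mm).
#'
#' @param records Output of [track_metrics()].
#' @param bin_edges Inner bin edges (µm); bins are `[0, e1), [e1, e2), ...,
#'   [ek, Inf)`.
#' @return Tibble: `bin`, `median_speed`, `q25`, `q75`, `n` (µm/min).
#' @export
velocity_by_distance <- function(records, bin_edges = c(500, 1000)) {
  if (!nrow(records)) stop("empty records", call. = FALSE)
  rec <- records[records$compartment %in% "basal" &
                   records$migratory %in% TRUE, ]
  e <- c(0, bin_edges, Inf)
  lab <- .bin_labels(bin_edges)
  bin <- findInterval(rec$initial_distance_to_wound, e)
  out <- lapply(seq_along(lab), function(j) {
    v <- rec$mean_speed[bin == j]
    tibble::tibble(bin = lab[j],
                   median_speed = if (length(v)) median(v) else NA_real_,
                   q25 = if (length(v)) quantile(v, 0.25)[[1]] else NA_real_,
                   q75 = if (length(v)) quantile(v, 0.75)[[1]] else NA_real_,
                   n = length(v))
  })
  dplyr::bind_rows(out)
}

#' Net displacement summaries by compartment and distance bin
#'
#' Mirrors the follicle-versus-basal displacement comparison: follicle cells
#' do not migrate, basal cells do.
#'
#' @param records Output of [track_metrics()].
#' @param bin_edges Inner bin edges (µm), as in [velocity_by_distance()].
#' @return Tibble: `compartment`, `bin`, `median_displacement`, `q25`,
#'   `q75`, `n`.
#' @export
displacement_by_compartment <- function(records, bin_edges = c(500, 1000)) {
  e <- c(0, bin_edges, Inf)
  lab <- .bin_labels(bin_edges)
  comps <- sort(unique(records$compartment))
  out <- list()
  for (cp in comps) {
    rec <- records[records$compartment %in% cp, ]
    bin <- findInterval(rec$initial_distance_to_wound, e)
    for (j in seq_along(lab)) {
      v <- rec$net_displacement[bin == j]
      out[[length(out) + 1L]] <- tibble::tibble(
        compartment = cp, bin = lab[j],
        median_displacement = if (length(v)) median(v) else NA_real_,
        q25 = if (length(v)) quantile(v, 0.25)[[1]] else NA_real_,
        q75 = if (length(v)) quantile(v, 0.75)[[1]] else NA_real_,
        n = length(v))
    }
  }
  dplyr::bind_rows(out)
}
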