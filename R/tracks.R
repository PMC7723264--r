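#' Read a track table from CSV
#'
#' The on-disk schema is the canonical column order `track_id, frame,
#' time_h, x_um, y_um, compartment, phase, ch1, ch2`; `phase`, `ch1` and
#' `ch2` may be absent and are filled with `NA`. Rows are returned sorted by
#' `(track_id, frame)`.
#'
#' @param path CSV path.
#' @return A tibble with the canonical track columns.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("track_id", "frame", "time_h", "x_um", "y_um", "compartment")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("phase", "ch1", "ch2")) {
    if (!col %in% names(tab)) {
      tab[[col]] <- if (col == "phase") NA_character_ else NA_real_
    }
  }
  for (col in c("time_h", "x_um", "y_um", "ch1", "ch2")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab$phase <- as.character(tab$phase)
  tab$compartment <- as.character(tab$compartment)
  bad <- which(!is.finite(tab$x_um) | !is.finite(tab$y_um) |
                 !is.finite(tab$time_h) | is.na(tab$track_id) |
                 is.na(tab$frame))
  if (length(bad)) {
    stop("malformed row(s) at line ", paste(head(bad + 1L, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5L),
         call. = FALSE)
  }
  validate_tracks(tab[, .track_cols])
}

#' Validate a track table
#'
#' Checks the `(track_id, frame)` key for uniqueness and sorts rows so
#' frames increase within each track.
#' @param tracks A track table.
#' @return The validated tibble, sorted by `(track_id, frame)`.
#' @export
validate_tracks <- function(tracks) {
  key <- paste(tracks$track_id, tracks$frame, sep = "/")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (track_id, frame) key: ", key[which(dup)[1]],
         call. = FALSE)
  }
  out <- tracks[order(tracks$track_id, tracks$frame), ]
  tibble::as_tibble(out)
}

#' Write a track table to CSV
#'
#' @param tracks A track table (canonical columns).
#' @param path Output path. UTF-8, `.` decimal, LF line endings.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  missing <- setdiff(.track_cols, names(tracks))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(tracks[, .track_cols], path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour matching between consecutive frames:
#' a pair is linked when each detection is the other's nearest unmatched
#' detection and their distance is at most `max_disp`; matching repeats
#' until no mutual pair remains. Unmatched detections start new tracks. Ties
#' are broken by the lowest detection index.
#'
#' @param detections List (one element per frame) of data frames or
#'   matrices with columns/col-1:2 `x`, `y` in µm.
#' @param max_disp Maximum linking displacement (µm).
#' @param times Frame times in hours (default `(0:(n-1)) * dt / 60`).
#' @param dt Frame interval in minutes, used if `times` is `NULL`.
#' @return A track table (canonical columns; `compartment` `NA`).
#' @export
link_detections <- function(detections, max_disp, times = NULL, dt = 30) {
  if (!length(detections)) stop("empty frame list", call. = FALSE)
  stopifnot(max_disp > 0)
  as_xy <- function(d) {
    m <- if (is.matrix(d)) d[, 1:2, drop = FALSE] else cbind(d$x, d$y)
    matrix(as.numeric(m), ncol = 2)
  }
  frames <- lapply(detections, as_xy)
  if (is.null(times)) times <- (seq_along(frames) - 1) * dt / 60
  n1 <- nrow(frames[[1]])
  track_of <- seq_len(n1) # track id of each detection in the current frame
  next_track <- n1 + 1L
  rows <- list(tibble::tibble(track_id = track_of, frame = 0L,
                              time_h = times[1],
                              x_um = frames[[1]][, 1], y_um = frames[[1]][, 2]))
  for (k in seq_len(length(frames) - 1L)) {
    A <- frames[[k]]; B <- frames[[k + 1L]]
    match_b <- rep(NA_integer_, nrow(B)) # index into A
    if (nrow(A) && nrow(B)) {
      D <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j) {
        sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
      })
      free_a <- rep(TRUE, nrow(A)); free_b <- rep(TRUE, nrow(B))
      repeat {
        ia <- which(free_a); ib <- which(free_b)
        if (!length(ia) || !length(ib)) break
        sub <- D[ia, ib, drop = FALSE]
        nn_a <- ib[apply(sub, 1, which.min)] # nearest free B for each free A
        nn_b <- ia[apply(sub, 2, which.min)] # nearest free A for each free B
        mutual <- which(nn_b[match(nn_a, ib)] == ia &
                          D[cbind(ia, nn_a)] <= max_disp)
        if (!length(mutual)) break
        match_b[nn_a[mutual]] <- ia[mutual]
        free_a[ia[mutual]] <- FALSE
        free_b[nn_a[mutual]] <- FALSE
      }
    }
    new_track_of <- integer(nrow(B))
    linked <- !is.na(match_b)
    new_track_of[linked] <- track_of[match_b[linked]]
    n_new <- sum(!linked)
    if (n_new) {
      new_track_of[!linked] <- next_track - 1L + seq_len(n_new)
      next_track <- next_track + n_new
    }
    track_of <- new_track_of
    rows[[k + 1L]] <- tibble::tibble(track_id = track_of, frame = k,
                                     time_h = times[k + 1L],
                                     x_um = B[, 1], y_um = B[, 2])
  }
  out <- dplyr::bind_rows(rows)
  out$compartment <- NA_character_
  out$phase <- NA_character_
  out$ch1 <- NA_real_
  out$ch2 <- NA_real_
  validate_tracks(out[, .track_cols])
}

#' Estimate stage drift from static reference tracks
#'
#' Per-frame translation is the cumulative sum of the per-step median
#' displacement vector of the reference agents (hair-follicle cells by
#' default, which do not migrate); the median makes the estimate robust to a
#' minority of outlier references.
#'
#' @param tracks A track table.
#' @param reference_compartment Compartment used as fiducials.
#' @return A drift series tibble: `frame`, `time_h`, `dx_um`, `dy_um`, with
#'   zero translation at the first frame.
#' @export
estimate_drift <- function(tracks, reference_compartment = "follicle") {
  ref <- tracks[tracks$compartment %in% reference_compartment, ]
  n_ref <- length(unique(ref$track_id))
  if (n_ref < 3) {
    stop(sprintf("need >= 3 reference tracks, found %d", n_ref),
         call. = FALSE)
  }
  frames <- sort(unique(tracks$frame))
  times <- tracks$time_h[match(frames, tracks$frame)]
  dx <- dy <- numeric(length(frames))
  for (k in seq_len(length(frames) - 1L)) {
    a <- ref[ref$frame == frames[k], ]
    b <- ref[ref$frame == frames[k + 1L], ]
    common <- intersect(a$track_id, b$track_id)
    if (!length(common)) {
      stop("no reference agent spans frames ", frames[k], " -> ",
           frames[k + 1L], call. = FALSE)
    }
    ia <- match(common, a$track_id); ib <- match(common, b$track_id)
    dx[k + 1L] <- dx[k] + median(b$x_um[ib] - a$x_um[ia])
    dy[k + 1L] <- dy[k] + median(b$y_um[ib] - a$y_um[ia])
  }
  tibble::tibble(frame = frames, time_h = times, dx_um = dx, dy_um = dy)
}

#' Apply (subtract) a drift series from a track table
#'
#' @param tracks A track table.
#' @param drift A drift series from [estimate_drift()].
#' @return The corrected track table; all non-coordinate columns untouched.
#' @export
apply_drift <- function(tracks, drift) {
  m <- match(tracks$frame, drift$frame)
  if (anyNA(m)) {
    stop("drift series missing frame(s): ",
         paste(head(unique(tracks$frame[is.na(m)]), 5), collapse = ", "),
         call. = FALSE)
  }
  tracks$x_um <- tracks$x_um - drift$dx_um[m]
  tracks$y_um <- tracks$y_um - drift$dy_um[m]
  tracks
}
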