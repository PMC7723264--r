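#' Classify Fucci reporter intensities into cell-cycle phases
#'
#' A cell is called S/G2 when its S/G2-reporter channel exceeds its
#' G1-reporter channel; ties go to G1.
#'
#' @param ch1 G1-reporter intensities (>= 0).
#' @param ch2 S/G2-reporter intensities (>= 0).
#' @return Character vector `"G1"`/`"SG2"`.
#' @export
fucci_classify <- function(ch1, ch2) {
  if (length(ch1) != length(ch2)) {
    stop("'ch1' and 'ch2' must have equal length", call. = FALSE)
  }
  if (anyNA(ch1) || anyNA(ch2) || any(ch1 < 0) || any(ch2 < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  ifelse(ch2 > ch1, "SG2", "G1")
}

#' S/G2 fraction by distance zone
#'
#' @param distance Distances to the wound edge (µm, >= 0).
#' @param phase Phases (`"G1"`/`"SG2"`), same length.
#' @param edges Zone edges (µm); zones are `[e1, e2), ..., [e_{k-1}, e_k)`.
#'   Cells at or beyond the last edge are excluded and counted in attribute
#'   `n_excluded`.
#' @return Tibble: `zone_lo`, `zone_hi`, `n_total`, `n_sg2`, `fraction_sg2`
#'   (`NA` for empty zones).
#' @export
fraction_by_zone <- function(distance, phase,
                             edges = c(0, 200, 400, 600, 800, 1000)) {
  stopifnot(length(distance) == length(phase), all(distance >= 0))
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be strictly ascending", call. = FALSE)
  }
  zone <- findInterval(distance, edges, rightmost.closed = FALSE)
  zone[distance >= edges[length(edges)] | zone == 0] <- NA
  k <- length(edges) - 1L
  n_total <- n_sg2 <- integer(k)
  for (j in seq_len(k)) {
    inz <- !is.na(zone) & zone == j
    n_total[j] <- sum(inz)
    n_sg2[j] <- sum(inz & phase == "SG2")
  }
  out <- tibble::tibble(zone_lo = edges[-length(edges)], zone_hi = edges[-1],
                        n_total = n_total, n_sg2 = n_sg2,
                        fraction_sg2 = ifelse(n_total > 0, n_sg2 / n_total,
                                              NA_real_))
  attr(out, "n_excluded") <- sum(is.na(zone))
  out
}

#' Time-averaged zone fractions over an analysis window
#'
#' Computes [fraction_by_zone()] per frame over a time window and averages
#' the per-frame fractions (`average = "frame"`, default) or pools the
#' counts (`average = "pooled"`). Phases come from the `phase` column, or
#' are classified from `ch1`/`ch2` with [fucci_classify()] when
#' `phase_from = "channels"`.
#'
#' @param tracks A track table.
#' @param wound_half_width Wound strip half-width (µm).
#' @param window `c(start, end)` hours.
#' @param edges Zone edges (µm).
#' @param compartment Compartment to keep (default basal).
#' @param phase_from `"column"` or `"channels"`.
#' @param average `"frame"` or `"pooled"`.
#' @return Tibble as [fraction_by_zone()], with `n_total`/`n_sg2` summed
#'   over frames and `fraction_sg2` averaged accordingly.
#' @export
zone_fraction_window <- function(tracks, wound_half_width = 75,
                                 window = c(16, 24),
                                 edges = c(0, 200, 400, 600, 800, 1000),
                                 compartment = "basal",
                                 phase_from = c("column", "channels"),
                                 average = c("frame", "pooled")) {
  phase_from <- match.arg(phase_from)
  average <- match.arg(average)
  tab <- tracks[tracks$compartment %in% compartment &
                  tracks$time_h >= window[1] - 1e-9 &
                  tracks$time_h <= window[2] + 1e-9, ]
  if (!nrow(tab)) stop("no rows in the analysis window", call. = FALSE)
  phase <- if (phase_from == "column") {
    tab$phase
  } else {
    fucci_classify(tab$ch1, tab$ch2)
  }
  d <- wound_distance(tab$x_um, wound_half_width)
  times <- sort(unique(tab$time_h))
  per_frame <- lapply(times, function(tt) {
    i <- abs(tab$time_h - tt) < 1e-9
    fraction_by_zone(d[i], phase[i], edges)
  })
  tot <- Reduce(`+`, lapply(per_frame, function(z) z$n_total))
  sg2 <- Reduce(`+`, lapply(per_frame, function(z) z$n_sg2))
  frac <- if (average == "pooled") {
    ifelse(tot > 0, sg2 / tot, NA_real_)
  } else {
    fr <- sapply(per_frame, function(z) z$fraction_sg2)
    rowMeans(matrix(fr, nrow = length(tot)), na.rm = TRUE)
  }
  tibble::tibble(zone_lo = edges[-length(edges)], zone_hi = edges[-1],
                 n_total = tot, n_sg2 = sg2, fraction_sg2 = frac)
}

#' EdU-positive fraction
#'
#' Fraction of EdU-positive cells among total basal keratinocytes.
#' @param n_positive,n_total Counts with `0 <= n_positive <= n_total`,
#'   `n_total > 0`.
#' @return `n_positive / n_total`.
#' @export
edu_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0)) stop("'n_total' must be > 0", call. = FALSE)
  if (any(n_positive < 0) || any(n_positive > n_total)) {
    stop("need 0 <= n_positive <= n_total", call. = FALSE)
  }
  n_positive / n_total
}

#' Count simulated cells that divided within a look-back window
#'
#' An EdU-incorporation proxy for simulated data: mothers and daughters of
#' divisions in `(t - lookback, t]` count as positive.
#'
#' @param result A `wound_sim`.
#' @param t Evaluation time (hours).
#' @param lookback Look-back (hours); 4 h mirrors an EdU pulse given 4 h
#'   before sampling.
#' @return List with `n_positive` and `n_total` (basal cells at `t`).
#' @export
edu_proxy_counts <- function(result, t, lookback = 4) {
  stopifnot(inherits(result, "wound_sim"))
  k <- which.min(abs(result$times - t))
  fr <- result$frames[[k]]
  div <- result$divisions
  recent <- div[div$time_h > t - lookback & div$time_h <= t + 1e-9, ]
  pos_ids <- unique(c(recent$mother_id, recent$daughter_id))
  bas <- fr$compartment == "basal"
  list(n_positive = sum(fr$agent_id[bas] %in% pos_ids),
       n_total = sum(bas))
}

#' Ordinary least-squares regression with R-squared
#'
#' Simple OLS of `y` on `x` (e.g. scratch size versus proliferating
#' fraction), reporting slope, intercept and `R^2 = 1 - SS_res / SS_tot`
#' (defined as 0 when `y` is constant).
#'
#' @param x,y Numeric vectors, `length >= 3`; `x` must not be constant.
#' @return List of class `wound_ols`: `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @export
regress_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0) stop("'x' is constant", call. = FALSE)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(fit$residuals^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n = length(x)),
            class = "wound_ols")
}

#' @export
print.wound_ols <- function(x, ...) {
  cat(sprintf("<wound_ols> y = %.4g x + %.4g, R^2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Compare motility between cell-cycle phases
#'
#' Within each distance zone, compares migration velocity (unpaired Welch t
#' test) and persistence (Kruskal-Wallis rank test) between S/G2 and G1
#' records. Statistical testing is intentionally delegated to the standard
#' routines; the scientific content is the upstream quantities.
#'
#' Velocity can be the path-length speed (`velocity = "path"`) or the
#' net-displacement speed (`"net"`, default here). For phase-stratified
#' comparisons the net measure is preferable: short-range neighbourhood
#' relaxations around divisions add direction-random micro-steps that
#' inflate path length in proportion to local division activity, which
#' correlates with phase; net displacement is insensitive to them.
#'
#' @param records Output of [track_metrics()] (basal records with phase).
#' @param zone_edges Zone edges (µm), or `NULL` for a single pooled zone.
#' @param max_per_phase Maximum records per phase per zone; when a zone
#'   holds more, a random cohort of this size is drawn (from the session
#'   RNG). Simulated censuses can be orders of magnitude larger than a
#'   tracked intravital cohort, which gives the tests power to flag
#'   micron-scale side effects of division that are far below the
#'   biological scale of interest; capping the cohort reproduces the
#'   sampling of a tracking experiment. `Inf` disables capping.
#' @return Tibble: `zone_lo`, `zone_hi`, `metric`, `mean_g1`, `mean_sg2`,
#'   `n_g1`, `n_sg2`, `statistic`, `p_value`. Tests are skipped (with a
#'   warning, `NA` results) when a phase has fewer than 2 usable records in
#'   a zone.
#' @export
#' @param velocity `"net"` (net displacement / duration) or `"path"`
#'   (path length / duration).
compare_by_phase <- function(records, zone_edges = c(0, 200, 400, 600, 800, 1000),
                             max_per_phase = Inf,
                             velocity = c("net", "path")) {
  velocity <- match.arg(velocity)
  rec <- records[records$phase %in% .phases, ]
  if (length(unique(rec$phase)) < 2) {
    stop("both phases must be present", call. = FALSE)
  }
  if (is.null(zone_edges)) zone_edges <- c(0, Inf)
  out <- list()
  for (j in seq_len(length(zone_edges) - 1L)) {
    inz <- rec$initial_distance_to_wound >= zone_edges[j] &
      rec$initial_distance_to_wound < zone_edges[j + 1L]
    z <- rec[inz, ]
    if (is.finite(max_per_phase)) {
      keep <- unlist(lapply(.phases, function(ph) {
        i <- which(z$phase == ph)
        if (length(i) > max_per_phase) sample(i, max_per_phase) else i
      }))
      z <- z[sort(keep), ]
    }
    for (metric in c("velocity", "persistence")) {
      v <- if (metric == "velocity") {
        if (velocity == "net") {
          z$net_displacement / (z$duration_h * 60)
        } else {
          z$mean_speed
        }
      } else {
        z$persistence
      }
      ok <- !is.na(v)
      g1 <- v[ok & z$phase == "G1"]
      sg2 <- v[ok & z$phase == "SG2"]
      stat <- p <- NA_real_
      if (length(g1) >= 2 && length(sg2) >= 2) {
        if (metric == "velocity") {
          tt <- t.test(g1, sg2)
          stat <- unname(tt$statistic); p <- tt$p.value
        } else {
          kw <- kruskal.test(list(g1, sg2))
          stat <- unname(kw$statistic); p <- kw$p.value
        }
      } else if (length(g1) >= 1 && length(sg2) >= 1) {
        warning(sprintf("zone [%g, %g) %s: too few records per phase, test skipped",
                        zone_edges[j], zone_edges[j + 1L], metric))
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        zone_lo = zone_edges[j], zone_hi = zone_edges[j + 1L],
        metric = metric,
        mean_g1 = if (length(g1)) mean(g1) else NA_real_,
        mean_sg2 = if (length(sg2)) mean(sg2) else NA_real_,
        n_g1 = length(g1), n_sg2 = length(sg2),
        statistic = stat, p_value = p)
    }
  }
  dplyr::bind_rows(out)
}
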