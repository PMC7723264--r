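#' Per-step S/G2 entry hazard for a target stationary fraction
#'
#' The cell cycle is modelled as a two-state chain: cells wait in G1 with a
#' constant per-step entry hazard `h`, then spend a fixed `sg2_duration` in
#' S/G2 before dividing. The expected G1 residence is `1/h` steps, the S/G2
#' residence `n_s = sg2_duration * 60 / dt` steps, so the stationary S/G2
#' fraction is `f = n_s / (1/h + n_s)`. Solving for `h` gives
#' `h = f / (n_s * (1 - f))`, the closed form used here.
#'
#' @param f Target stationary S/G2 fraction in `[0, 1)`.
#' @param sg2_duration S/G2 duration (hours).
#' @param dt Step length (minutes).
#' @return Per-step hazard of a G1 cell entering S/G2.
#' @examples
#' sg2_hazard(0.10, 6, 30) # 1/108
#' @export
sg2_hazard <- function(f, sg2_duration, dt) {
  stopifnot(is.numeric(f), all(f >= 0), all(f < 1))
  n_s <- sg2_duration * 60 / dt
  ifelse(f == 0, 0, f / (n_s * (1 - f)))
}

# Growth-corrected hazard. Because every division returns two G1 cells, the
# population grows exponentially and young (G1) cells are over-represented
# relative to the fixed-size renewal chain, so the renewal closed form above
# under-delivers S/G2 cells. This solves for h such that the S/G2 fraction of
# the stable exponentially growing population equals f.
#
# With per-step growth factor rho, generation time T = G + n_s (G ~
# Geometric(h), support >= 1), Euler-Lotka reads
#     2 rho^{-n_s} h / (rho - 1 + h) = 1,
# and with S = 1/(1 - 1/rho) - 1/(1 - (1-h)/rho) the stable-age S/G2
# fraction is
#     p = S (1 - rho^{-n_s}) / (1/(1 - 1/rho) - rho^{-n_s} S).
.sg2_hazard_growth <- function(f, sg2_duration, dt) {
  n_s <- sg2_duration * 60 / dt
  vapply(f, function(fi) {
    if (fi <= 0) return(0)
    p_of_h <- function(h) {
      rho <- stats::uniroot(function(r) 2 * r^(-n_s) * h / (r - 1 + h) - 1,
                            c(1 + 1e-12, 2), tol = 1e-14)$root
      S <- 1 / (1 - 1 / rho) - 1 / (1 - (1 - h) / rho)
      S * (1 - rho^(-n_s)) / (1 / (1 - 1 / rho) - rho^(-n_s) * S)
    }
    h0 <- fi / (n_s * (1 - fi))
    hi <- h0
    while (p_of_h(hi) < fi && hi < 0.5) hi <- hi * 2
    stats::uniroot(function(h) p_of_h(h) - fi, c(h0 / 2, hi),
                   tol = 1e-12)$root
  }, numeric(1))
}

# Wound-ward drift speed at distance d (µm) from the wound edge:
# v_near for d <= d_near, v_far for d >= d_far, linear in between.
.drift_speed <- function(d, cfg) {
  frac <- pmin(1, pmax(0, (d - cfg$d_near) / (cfg$d_far - cfg$d_near)))
  cfg$v_near - (cfg$v_near - cfg$v_far) * frac
}

# Target stationary S/G2 fraction by distance-to-wound zone.
.sg2_target <- function(d, cfg) {
  e <- cfg$prolif_zone_edges
  ifelse(d < e[1], cfg$p_sg2_inner,
         ifelse(d < e[2], cfg$p_sg2_zone, cfg$p_sg2_baseline))
}

#' Distance to the nearest wound edge
#'
#' The wound is the axis-aligned strip `|x| < wound_half_width`; the distance
#' of a point to the wound is `max(0, |x| - wound_half_width)` (0 inside the
#' strip).
#' @param x x-coordinates (µm).
#' @param wound_half_width Strip half-width (µm).
#' @return Distances (µm).
#' @export
wound_distance <- function(x, wound_half_width) {
  pmax(0, abs(x) - wound_half_width)
}

# Seeded uniform sampling thinned by a minimum-spacing rule. Proposes points
# in small batches, rejects those closer than `dmin` to an accepted point
# (RANN radius query against accepted set, tiny sequential pass for
# intra-batch conflicts). Returns up to n_target points.
.rsa_sample <- function(n_target, bbox, dmin, accept_fn = NULL,
                        max_rounds = 400) {
  if (n_target <= 0) return(matrix(numeric(0), 0, 2))
  acc <- matrix(NA_real_, n_target, 2)
  n_acc <- 0L
  batch <- max(64L, min(512L, n_target))
  for (round in seq_len(max_rounds)) {
    if (n_acc >= n_target) break
    px <- runif(batch, bbox[1], bbox[2])
    py <- runif(batch, bbox[3], bbox[4])
    keep <- if (is.null(accept_fn)) rep(TRUE, batch) else accept_fn(px, py)
    px <- px[keep]; py <- py[keep]
    if (!length(px)) next
    P <- cbind(px, py)
    if (n_acc > 0L) {
      nn <- RANN::nn2(acc[seq_len(n_acc), , drop = FALSE], P, k = 1)
      P <- P[nn$nn.dists[, 1] >= dmin, , drop = FALSE]
      if (!nrow(P)) next
    }
    # intra-batch conflicts: symmetric, so only flagged points need the
    # sequential pass
    if (nrow(P) > 1L) {
      nnb <- RANN::nn2(P, P, k = min(8L, nrow(P)))
      flagged <- which(nnb$nn.dists[, 2] < dmin)
      if (length(flagged) > 1L) {
        kept_flag <- logical(nrow(P))
        for (i in flagged) {
          prev <- flagged[flagged < i & kept_flag[flagged]]
          ok <- TRUE
          if (length(prev)) {
            dd <- sqrt((P[prev, 1] - P[i, 1])^2 + (P[prev, 2] - P[i, 2])^2)
            ok <- all(dd >= dmin)
          }
          kept_flag[i] <- ok
        }
        drop <- flagged[!kept_flag[flagged]]
        if (length(drop)) P <- P[-drop, , drop = FALSE]
      }
    }
    n_new <- min(nrow(P), n_target - n_acc)
    if (n_new > 0L) {
      acc[n_acc + seq_len(n_new), ] <- P[seq_len(n_new), , drop = FALSE]
      n_acc <- n_acc + n_new
    }
  }
  acc[seq_len(n_acc), , drop = FALSE]
}

.in_any_follicle <- function(x, y, follicles, slack = 0) {
  inside <- rep(FALSE, length(x))
  for (f in follicles) {
    inside <- inside |
      ((x - f$center[1])^2 + (y - f$center[2])^2 < (f$radius + slack)^2)
  }
  inside
}

# Remove the inward radial component of the step for agents whose tentative
# position falls inside a follicle disk, then radially clamp any remainder.
.deflect_follicles <- function(nx, ny, ox, oy, follicles) {
  for (f in follicles) {
    cx <- f$center[1]; cy <- f$center[2]; r <- f$radius
    inside <- which((nx - cx)^2 + (ny - cy)^2 < r^2)
    if (!length(inside)) next
    ux <- ox[inside] - cx; uy <- oy[inside] - cy
    nrm <- sqrt(ux^2 + uy^2)
    nrm[nrm < 1e-12] <- 1e-12
    ux <- ux / nrm; uy <- uy / nrm
    dx <- nx[inside] - ox[inside]; dy <- ny[inside] - oy[inside]
    rad <- dx * ux + dy * uy
    rad <- pmin(rad, 0) # keep only the inward part for removal
    nx[inside] <- nx[inside] - rad * ux
    ny[inside] <- ny[inside] - rad * uy
    # residual overlap (e.g. tangential slide past the silhouette): clamp
    still <- which((nx[inside] - cx)^2 + (ny[inside] - cy)^2 < r^2)
    if (length(still)) {
      i2 <- inside[still]
      vx <- nx[i2] - cx; vy <- ny[i2] - cy
      nv <- sqrt(vx^2 + vy^2); nv[nv < 1e-12] <- 1e-12
      nx[i2] <- cx + vx / nv * (r + 1e-9)
      ny[i2] <- cy + vy / nv * (r + 1e-9)
    }
  }
  list(x = nx, y = ny)
}

# Reflect positions that crossed into the wound strip back across the edge
# they came from. `side` is the sign of the pre-step x.
.reflect_strip <- function(nx, side, hw) {
  crossed <- which(side * nx < hw & side != 0)
  nx[crossed] <- 2 * side[crossed] * hw - nx[crossed]
  nx
}

.reflect_interval <- function(v, lo, hi) {
  v <- ifelse(v > hi, 2 * hi - v, v)
  v <- ifelse(v < lo, 2 * lo - v, v)
  pmin(pmax(v, lo), hi)
}

# Pairwise soft-core repulsion displacement for one step (µm). Linear
# force kernel s * (1 - d/r) for pair distances d < r, radius-limited via a
# RANN radius query; total per-agent displacement capped at r/2 for
# stability.
.repulsion_step <- function(P, radius, strength, dt_min) {
  n <- nrow(P)
  out <- matrix(0, n, 2)
  if (n < 2L || strength <= 0) return(out)
  k <- min(13L, n)
  nn <- RANN::nn2(P, P, k = k, searchtype = "radius", radius = radius)
  for (j in 2:k) {
    idx <- nn$nn.idx[, j]
    d <- nn$nn.dists[, j]
    ok <- idx > 0L & d < radius & d > 1e-9
    if (!any(ok)) next
    i <- which(ok)
    mag <- strength * (1 - d[i] / radius) * dt_min
    out[i, 1] <- out[i, 1] + mag * (P[i, 1] - P[idx[i], 1]) / d[i]
    out[i, 2] <- out[i, 2] + mag * (P[i, 2] - P[idx[i], 2]) / d[i]
  }
  cap <- radius / 2
  nrm <- sqrt(out[, 1]^2 + out[, 2]^2)
  over <- nrm > cap
  if (any(over)) out[over, ] <- out[over, ] * (cap / nrm[over])
  out
}

#' Simulate scratch-wound re-epithelialization
#'
#' Runs the agent-based model: basal cells drift toward the wound (speed set
#' by distance to the wound edge, direction wound-ward with angular wobble),
#' are blocked by a reflecting wound edge until `t_unjam` and by impassable
#' hair-follicle disks throughout, repel each other at short range (allowing
#' slip-past and neighbour exchange), and progress through a G1 -> S/G2 ->
#' division cycle whose per-zone hazard is calibrated with [sg2_hazard()] so
#' the stationary S/G2 fraction matches the configured zone fractions.
#' Suprabasal cells receive positional noise only; follicle cells are
#' immobile.
#'
#' @param config A [sim_config()].
#' @return A `wound_sim` object: list with `times` (hours), `frames` (one
#'   data frame per frame: `agent_id`, `compartment`, `x`, `y`, `phase`,
#'   `phase_entry_time`, `target_area`), `divisions` (time, mother, daughter),
#'   `config`, and `ground_truth` (realized per-band median step speeds and
#'   per-zone S/G2 fractions).
#' @examples
#' cfg <- sim_config(t_end = 1, domain_half_extent = 300, domain_height = 120,
#'                   follicles = list())
#' sim <- simulate_wound(cfg)
#' length(sim$frames)
#' @export
simulate_wound <- function(config) {
  cfg <- validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  hw <- cfg$wound_half_width
  E <- cfg$domain_half_extent
  H <- cfg$domain_height
  dt_min <- cfg$dt
  dt_h <- cfg$dt / 60
  n_steps <- floor(cfg$t_end / dt_h + 1e-9)
  times <- (0:n_steps) * dt_h

  ## ---- initial populations -------------------------------------------------
  mean_basal <- mean(cfg$basal_target_area_range)
  mean_supra <- mean(cfg$suprabasal_target_area_range)
  fol_area <- sum(vapply(cfg$follicles, function(f) pi * f$radius^2, 0))
  free_area <- max(0, 2 * (E - hw) * H - fol_area)
  n_basal <- max(1L, round(free_area / mean_basal))
  n_supra <- max(1L, round(free_area / mean_supra))

  bbox <- c(-E, E, 0, H)
  outside <- function(px, py) {
    abs(px) >= hw & !.in_any_follicle(px, py, cfg$follicles)
  }
  Pb <- .rsa_sample(n_basal, bbox, 0.70 * sqrt(mean_basal), outside)
  Ps <- .rsa_sample(n_supra, bbox, 0.70 * sqrt(mean_supra), outside)
  Pf <- matrix(numeric(0), 0, 2)
  for (f in cfg$follicles) {
    fb <- c(f$center[1] - f$radius, f$center[1] + f$radius,
            f$center[2] - f$radius, f$center[2] + f$radius)
    nf <- max(3L, round(pi * f$radius^2 / mean_basal))
    keep_fn <- local({
      fc <- f
      function(px, py) (px - fc$center[1])^2 + (py - fc$center[2])^2 <
        fc$radius^2
    })
    Pf <- rbind(Pf, .rsa_sample(nf, fb, 0.70 * sqrt(mean_basal), keep_fn))
  }

  n <- nrow(Pb) + nrow(Ps) + nrow(Pf)
  x <- c(Pb[, 1], Ps[, 1], Pf[, 1])
  y <- c(Pb[, 2], Ps[, 2], Pf[, 2])
  comp <- rep(1:3, c(nrow(Pb), nrow(Ps), nrow(Pf)))
  id <- seq_len(n)
  area <- numeric(n)
  area[comp == 1L] <- runif(sum(comp == 1L), cfg$basal_target_area_range[1],
                            cfg$basal_target_area_range[2])
  area[comp == 2L] <- runif(sum(comp == 2L),
                            cfg$suprabasal_target_area_range[1],
                            cfg$suprabasal_target_area_range[2])
  area[comp == 3L] <- mean_basal

  # phases start at the per-zone stationary mix; S/G2 ages uniform over the
  # deterministic S/G2 residence so the initial condition is stationary
  phase <- rep(1L, n)
  entry <- rep(0, n)
  bas0 <- which(comp == 1L)
  f0 <- .sg2_target(wound_distance(x[bas0], hw), cfg)
  in_sg2 <- runif(length(bas0)) < f0
  phase[bas0[in_sg2]] <- 2L
  entry[bas0[in_sg2]] <- -runif(sum(in_sg2), 0, cfg$sg2_duration)

  # per-zone S/G2 entry hazards, growth-corrected (divisions return two G1
  # cells, so the plain renewal form would under-deliver S/G2 cells)
  zone_fracs <- c(cfg$p_sg2_inner, cfg$p_sg2_zone, cfg$p_sg2_baseline)
  zone_haz <- .sg2_hazard_growth(zone_fracs, cfg$sg2_duration, dt_min)

  make_frame <- function() {
    data.frame(agent_id = id,
               compartment = .compartments[comp],
               x = x, y = y,
               phase = .phases[phase],
               phase_entry_time = entry,
               target_area = area)
  }
  frames <- vector("list", n_steps + 1L)
  frames[[1L]] <- make_frame()
  next_id <- n + 1L
  div_time <- div_mother <- div_daughter <- integer(0)
  div_time <- numeric(0)

  ## ---- time stepping -------------------------------------------------------
  for (k in seq_len(n_steps)) {
    t_prev <- times[k]
    t_new <- times[k + 1L]
    jam <- t_prev < cfg$t_unjam

    bas <- which(comp == 1L)
    sup <- which(comp == 2L)
    mov <- c(bas, sup)
    ox <- x; oy <- y

    # wound-ward drift with heading wobble (basal only); step magnitude is
    # v(d)*dt, so the wobble changes direction, not path length
    dwound <- wound_distance(x[bas], hw)
    v <- .drift_speed(dwound, cfg)
    base_ang <- ifelse(x[bas] > 0, pi, 0)
    th <- base_ang + rnorm(length(bas), 0, cfg$heading_sigma)
    mag <- v * dt_min
    mag[x[bas] == 0] <- 0
    ddx <- mag * cos(th)
    ddy <- mag * sin(th)

    # isotropic positional noise for basal and suprabasal
    ns <- cfg$noise_sigma * dt_min
    nx_noise <- rnorm(length(mov), 0, ns)
    ny_noise <- rnorm(length(mov), 0, ns)

    rep_d <- .repulsion_step(cbind(x[bas], y[bas]), cfg$repulsion_radius,
                             cfg$repulsion_strength, dt_min)

    x[bas] <- x[bas] + ddx + rep_d[, 1]
    y[bas] <- y[bas] + ddy + rep_d[, 2]
    x[mov] <- x[mov] + nx_noise
    y[mov] <- y[mov] + ny_noise

    if (jam) {
      side <- sign(ox[mov])
      x[mov] <- .reflect_strip(x[mov], side, hw)
    }
    x[mov] <- .reflect_interval(x[mov], -E, E)
    y[mov] <- .reflect_interval(y[mov], 0, H)
    defl <- .deflect_follicles(x[mov], y[mov], ox[mov], oy[mov], cfg$follicles)
    x[mov] <- defl$x
    y[mov] <- defl$y

    # cell cycle: G1 -> S/G2 with zone hazard, division after sg2_duration
    bas <- which(comp == 1L)
    dnew <- wound_distance(x[bas], hw)
    zi <- findInterval(dnew, cfg$prolif_zone_edges) + 1L
    haz <- zone_haz[zi]
    g1 <- phase[bas] == 1L
    enter <- bas[g1 & runif(length(bas)) < haz]
    phase[enter] <- 2L
    entry[enter] <- t_new

    ripe <- bas[phase[bas] == 2L &
                  (t_new - entry[bas] >= cfg$sg2_duration - 1e-9)]
    if (length(ripe)) {
      nd <- length(ripe)
      phase[ripe] <- 1L
      entry[ripe] <- t_new
      phi <- runif(nd, 0, 2 * pi)
      dx <- x[ripe] + cfg$repulsion_radius * cos(phi)
      dy <- y[ripe] + cfg$repulsion_radius * sin(phi)
      if (t_new < cfg$t_unjam) {
        dx <- .reflect_strip(dx, sign(x[ripe]), hw)
      }
      dx <- .reflect_interval(dx, -E, E)
      dy <- .reflect_interval(dy, 0, H)
      dfl <- .deflect_follicles(dx, dy, x[ripe], y[ripe], cfg$follicles)
      dids <- next_id - 1L + seq_len(nd)
      next_id <- next_id + nd
      x <- c(x, dfl$x); y <- c(y, dfl$y)
      comp <- c(comp, rep(1L, nd))
      phase <- c(phase, rep(1L, nd))
      entry <- c(entry, rep(t_new, nd))
      area <- c(area, runif(nd, cfg$basal_target_area_range[1],
                            cfg$basal_target_area_range[2]))
      id <- c(id, dids)
      div_time <- c(div_time, rep(t_new, nd))
      div_mother <- c(div_mother, id[ripe])
      div_daughter <- c(div_daughter, dids)
    }

    frames[[k + 1L]] <- make_frame()
  }

  res <- structure(
    list(times = times,
         frames = frames,
         divisions = data.frame(time_h = div_time, mother_id = div_mother,
                                daughter_id = div_daughter),
         config = cfg,
         ground_truth = NULL),
    class = "wound_sim")
  res$ground_truth <- .sim_ground_truth(res)
  res
}

# Realized per-band median step speeds and per-zone S/G2 fractions, for
# sanity-checking parameter recovery. Agents are appended only, so frame k is
# a prefix of frame k+1 and step displacements align by row.
.sim_ground_truth <- function(res) {
  cfg <- res$config
  nf <- length(res$frames)
  if (nf < 2L) return(list(median_speed_by_band = NULL,
                           sg2_fraction_by_zone = NULL))
  speeds <- vector("list", nf - 1L)
  bands <- vector("list", nf - 1L)
  for (k in seq_len(nf - 1L)) {
    a <- res$frames[[k]]
    b <- res$frames[[k + 1L]][seq_len(nrow(a)), ]
    bi <- a$compartment == "basal"
    d <- sqrt((b$x[bi] - a$x[bi])^2 + (b$y[bi] - a$y[bi])^2)
    speeds[[k]] <- d / cfg$dt
    bands[[k]] <- cut(wound_distance(a$x[bi], cfg$wound_half_width),
                      c(-Inf, 500, 1000, Inf),
                      labels = c("<0.5 mm", "0.5-1 mm", ">1 mm"))
  }
  sp <- unlist(speeds)
  bd <- unlist(lapply(bands, as.character))
  med <- tapply(sp, bd, stats::median)
  band_tab <- tibble::tibble(band = names(med),
                             median_speed_um_min = as.numeric(med),
                             n = as.integer(table(bd)[names(med)]))

  tmax <- max(res$times)
  win <- if (tmax >= 24) c(16, 24) else c(tmax / 2, tmax)
  use <- which(res$times >= win[1] - 1e-9 & res$times <= win[2] + 1e-9)
  edges <- c(0, cfg$prolif_zone_edges, Inf)
  tot <- sg2 <- numeric(length(edges) - 1L)
  for (k in use) {
    fr <- res$frames[[k]]
    bi <- fr$compartment == "basal"
    z <- findInterval(wound_distance(fr$x[bi], cfg$wound_half_width), edges,
                      rightmost.closed = FALSE)
    for (j in seq_along(tot)) {
      inz <- z == j
      tot[j] <- tot[j] + sum(inz)
      sg2[j] <- sg2[j] + sum(inz & fr$phase[bi] == "SG2")
    }
  }
  zone_tab <- tibble::tibble(zone_lo = edges[-length(edges)],
                             zone_hi = edges[-1],
                             n_total = as.integer(tot),
                             fraction_sg2 = ifelse(tot > 0, sg2 / tot, NA))
  list(median_speed_by_band = band_tab, sg2_fraction_by_zone = zone_tab)
}

#' @export
print.wound_sim <- function(x, ...) {
  cat("<wound_sim>\n")
  n0 <- nrow(x$frames[[1]])
  nN <- nrow(x$frames[[length(x$frames)]])
  cat(sprintf("  %d frames over %g h; %d agents initially, %d finally (%d divisions)\n",
              length(x$frames), max(x$times), n0, nN, nrow(x$divisions)))
  invisible(x)
}

#' Time of first basal entry into the wound strip
#'
#' @param result A `wound_sim` from [simulate_wound()].
#' @return Time (hours) of the first frame in which a basal centroid lies
#'   strictly inside the wound strip, or `Inf` ("never") if none does.
#' @export
entry_time <- function(result) {
  stopifnot(inherits(result, "wound_sim"))
  if (length(result$frames) < 2L) {
    stop("result must contain at least 2 frames", call. = FALSE)
  }
  hw <- result$config$wound_half_width
  any_basal <- FALSE
  for (k in seq_along(result$frames)) {
    fr <- result$frames[[k]]
    bi <- fr$compartment == "basal"
    any_basal <- any_basal || any(bi)
    if (any(bi & abs(fr$x) < hw)) return(result$times[k])
  }
  if (!any_basal) stop("result contains no basal agents", call. = FALSE)
  Inf
}

#' Wound closure time
#'
#' The wound is considered closed at the first frame in which every point of
#' a regular 10-µm lattice spanning the wound strip lies within
#' `coverage_radius` of some basal agent.
#'
#' @param result A `wound_sim`.
#' @param coverage_radius Coverage radius (µm); default 15, roughly one
#'   basal cell diameter.
#' @return Closure time in hours, or `Inf` if the strip is not covered by
#'   the end of the simulation.
#' @export
closure_time <- function(result, coverage_radius = 15) {
  stopifnot(inherits(result, "wound_sim"))
  if (coverage_radius <= 0) {
    stop("'coverage_radius' must be > 0", call. = FALSE)
  }
  if (length(result$frames) < 2L) {
    stop("result must contain at least 2 frames", call. = FALSE)
  }
  cfg <- result$config
  hw <- cfg$wound_half_width
  gx <- seq(-hw, hw, by = 10)
  gy <- seq(0, cfg$domain_height, by = 10)
  lattice <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  any_basal <- FALSE
  for (k in seq_along(result$frames)) {
    fr <- result$frames[[k]]
    bi <- fr$compartment == "basal"
    any_basal <- any_basal || any(bi)
    near <- bi & abs(fr$x) <= hw + coverage_radius
    if (!any(near)) next
    nn <- RANN::nn2(cbind(fr$x[near], fr$y[near]), lattice, k = 1)
    if (max(nn$nn.dists[, 1]) <= coverage_radius) return(result$times[k])
  }
  if (!any_basal) stop("result contains no basal agents", call. = FALSE)
  Inf
}

#' Export simulated trajectories as a track table
#'
#' One row per agent per frame; agent identity becomes the track id and
#' daughters start new tracks at their birth frame. The `ch1`/`ch2` intensity
#' columns are left `NA` (see [add_fucci_intensities()]).
#'
#' @param result A `wound_sim`.
#' @return A tibble with the canonical track columns `track_id`, `frame`,
#'   `time_h`, `x_um`, `y_um`, `compartment`, `phase`, `ch1`, `ch2`.
#' @export
export_tracks <- function(result) {
  stopifnot(inherits(result, "wound_sim"))
  parts <- lapply(seq_along(result$frames), function(k) {
    fr <- result$frames[[k]]
    data.frame(track_id = fr$agent_id,
               frame = k - 1L,
               time_h = result$times[k],
               x_um = fr$x,
               y_um = fr$y,
               compartment = fr$compartment,
               phase = fr$phase,
               ch1 = NA_real_,
               ch2 = NA_real_)
  })
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
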