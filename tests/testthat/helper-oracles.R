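# Brute-force empty-circumcircle Delaunay oracle: an edge (i, j) is Delaunay
# iff some triangle (i, j, k) has a circumcircle empty of all other points.
# O(n^4); independent of the build_graph implementation.
brute_delaunay_edges <- function(px, py) {
  n <- length(px)
  stopifnot(n >= 3)
  E <- matrix(0L, 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]; cx <- px[k]; cy <- py[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    dd <- (px - ux)^2 + (py - uy)^2
    if (all(dd >= r2 - 1e-9 * r2 | seq_len(n) %in% c(i, j, k))) {
      E <- rbind(E, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(E[order(E[, 1], E[, 2]), , drop = FALSE])
}

graph_edge_matrix <- function(graph) {
  e <- cbind(graph$edges$from, graph$edges$to)
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# Brute-force minimum-cost assignment between two point sets (n <= 7),
# pairs farther than max_disp forbidden; unmatched points allowed at zero
# cost. Returns the B-index matched to each A point (NA = unmatched).
brute_assignment <- function(A, B, max_disp) {
  nA <- nrow(A); nB <- nrow(B)
  D <- as.matrix(dist(rbind(A, B)))[seq_len(nA), nA + seq_len(nB),
                                    drop = FALSE]
  allowed <- D <= max_disp
  best <- NULL; best_cost <- Inf; best_n <- -1L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (sa in subsets(seq_len(nA))) {
    if (length(sa) > nB) next
    for (sb in subsets(seq_len(nB))) {
      if (length(sb) != length(sa)) next
      for (p in perms(sb)) {
        if (length(sa) && !all(allowed[cbind(sa, p)])) next
        cost <- if (length(sa)) sum(D[cbind(sa, p)]) else 0
        n_matched <- length(sa)
        # maximise matches, then minimise cost
        if (n_matched > best_n ||
            (n_matched == best_n && cost < best_cost - 1e-12)) {
          best_n <- n_matched; best_cost <- cost
          best <- rep(NA_integer_, nA)
          if (length(sa)) best[sa] <- p
        }
      }
    }
  }
  best
}

# minimal track constructor: times in hours, coordinates in µm
mk_track <- function(t, x, y) {
  data.frame(time_h = t, x_um = x, y_um = y)
}

# hand-built wound_sim with given frames (list of data.frames) for
# entry/closure unit tests
mk_sim <- function(frames, times, config = sim_config()) {
  structure(list(times = times, frames = frames,
                 divisions = data.frame(time_h = numeric(0),
                                        mother_id = integer(0),
                                        daughter_id = integer(0)),
                 config = config, ground_truth = NULL),
            class = "wound_sim")
}

mk_frame <- function(id, comp, x, y, phase = "G1") {
  data.frame(agent_id = id, compartment = comp, x = x, y = y,
             phase = phase, phase_entry_time = 0,
             target_area = 175)
}
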