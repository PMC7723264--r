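#' Build a cell-neighbour graph from centroids
#'
#' Neighbourhood is defined by Delaunay triangulation of the centroids with
#' edges longer than `max_edge` pruned — a standard proxy for epithelial
#' contact topology. Degenerate inputs (fewer than 3 points, or collinear
#' points) fall back to plain distance-cutoff adjacency. Exactly duplicated
#' positions are perturbed deterministically by ~1e-6 µm (with a warning)
#' before triangulating.
#'
#' @param positions Data frame with `x`, `y` and optionally `id` (defaults
#'   to row number), or a 2-column matrix.
#' @param max_edge Maximum edge length (µm); `NULL` uses twice the median
#'   nearest-neighbour distance.
#' @return A list of class `neighbor_graph`: `nodes` (tibble `id`, `x`,
#'   `y`), `edges` (tibble `from`, `to` in node ids, `from < to`),
#'   `max_edge`.
#' @export
build_graph <- function(positions, max_edge = NULL) {
  if (is.matrix(positions)) {
    positions <- data.frame(x = positions[, 1], y = positions[, 2])
  }
  if (is.null(positions$id)) positions$id <- seq_len(nrow(positions))
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  x <- as.numeric(positions$x)
  y <- as.numeric(positions$y)

  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    warning(sum(dup), " duplicated position(s) perturbed by ~1e-6 um")
    k <- which(dup)
    ang <- 2 * pi * 0.61803398875 * seq_along(k) # deterministic spiral
    x[k] <- x[k] + 1e-6 * seq_along(k) * cos(ang)
    y[k] <- y[k] + 1e-6 * seq_along(k) * sin(ang)
  }

  if (is.null(max_edge)) {
    nn <- FNN::get.knn(cbind(x, y), k = 1)
    max_edge <- 2 * median(nn$nn.dist[, 1])
  }
  stopifnot(max_edge > 0)

  collinear <- n < 3 || {
    dx <- x - x[1]; dy <- y - y[1]
    all(abs(dx * dy[2] - dy * dx[2]) < 1e-9 * (max(abs(c(dx, dy))) + 1)^2) &&
      (any(dx != 0) || any(dy != 0))
  }
  edges <- NULL
  if (!collinear) {
    tm <- tryCatch(suppressWarnings(interp::tri.mesh(x, y)),
                   error = function(e) NULL)
    if (!is.null(tm)) {
      tri <- interp::triangles(tm)
      edges <- unique(cbind(pmin(c(tri[, 1], tri[, 1], tri[, 2]),
                                 c(tri[, 2], tri[, 3], tri[, 3])),
                            pmax(c(tri[, 1], tri[, 1], tri[, 2]),
                                 c(tri[, 2], tri[, 3], tri[, 3]))))
    }
  }
  if (is.null(edges)) {
    # distance-cutoff fallback for degenerate configurations
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- (x[pr[, 1]] - x[pr[, 2]])^2 + (y[pr[, 1]] - y[pr[, 2]])^2 <=
      max_edge^2
    edges <- pr[keep, , drop = FALSE]
  } else {
    len2 <- (x[edges[, 1]] - x[edges[, 2]])^2 +
      (y[edges[, 1]] - y[edges[, 2]])^2
    edges <- edges[len2 <= max_edge^2, , drop = FALSE]
  }
  from <- pmin(edges[, 1], edges[, 2])
  to <- pmax(edges[, 1], edges[, 2])
  o <- order(from, to)
  structure(
    list(nodes = tibble::tibble(id = positions$id, x = x, y = y),
         edges = tibble::tibble(from = positions$id[from[o]],
                                to = positions$id[to[o]]),
         max_edge = max_edge),
    class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges (max_edge %.2f um)\n",
              nrow(x$nodes), nrow(x$edges), x$max_edge))
  invisible(x)
}

#' Neighbour sets of a graph
#' @param graph A `neighbor_graph`.
#' @return Named list mapping node id to the vector of neighbour ids.
#' @export
graph_neighbors <- function(graph) {
  ids <- as.character(graph$nodes$id)
  out <- split(c(graph$edges$to, graph$edges$from),
               factor(as.character(c(graph$edges$from, graph$edges$to)),
                      levels = ids))
  lapply(out, unique)
}

#' Original-neighbour retention over time
#'
#' For each focal cell with at least one neighbour at `t0`, computes the
#' fraction of its original (t0) neighbours that are again among its
#' instantaneous neighbours at each later frame: `|N0 intersect N(t)| /
#' |N0|`. Re-acquired neighbours count again (instantaneous adjacency).
#' Cells whose track ends early are reported up to their last frame
#' (censored thereafter).
#'
#' @param tracks A track table (typically pre-filtered to one compartment;
#'   default keeps `compartment == "basal"` if the column is present).
#' @param t0 Reference time (hours).
#' @param horizon Follow-up duration (hours).
#' @param max_edge Edge prune length (µm); `NULL` derives it at `t0` (twice
#'   the median nearest-neighbour distance) and reuses it for all frames.
#' @param compartment Compartment to keep, or `NULL` for all rows.
#' @return Tibble: `track_id`, `time_h`, `time_rel_h`, `fraction`; attribute
#'   `n_zero_neighbors` counts focal cells excluded for having no t0
#'   neighbours. `fraction` is 1 at `t0` for every focal cell by
#'   construction.
#' @export
retention_fraction <- function(tracks, t0, horizon, max_edge = NULL,
                               compartment = "basal") {
  tab <- tracks
  if (!is.null(compartment) && "compartment" %in% names(tab)) {
    tab <- tab[tab$compartment %in% compartment, ]
  }
  tab <- tab[tab$time_h >= t0 - 1e-9 & tab$time_h <= t0 + horizon + 1e-9, ]
  times <- sort(unique(tab$time_h))
  if (!length(times) || abs(times[1] - t0) > 1e-9) {
    stop("frames at t0 not present in the track table", call. = FALSE)
  }
  frames <- lapply(times, function(tt) tab[abs(tab$time_h - tt) < 1e-9, ])
  g0 <- build_graph(data.frame(id = frames[[1]]$track_id,
                               x = frames[[1]]$x_um, y = frames[[1]]$y_um),
                    max_edge = max_edge)
  max_edge <- g0$max_edge
  adj0 <- .adjacency_by_position(g0, frames[[1]]$track_id)
  n0_sizes <- lengths(adj0)
  focal_pos <- which(n0_sizes > 0)
  focal <- frames[[1]]$track_id[focal_pos]
  nb0 <- adj0[focal_pos]
  n_zero <- sum(n0_sizes == 0)

  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    fr <- frames[[k]]
    pos <- match(focal, fr$track_id)
    here <- which(!is.na(pos))
    if (k == 1L) {
      frac <- rep(1, length(here))
    } else {
      gk <- build_graph(data.frame(id = fr$track_id, x = fr$x_um,
                                   y = fr$y_um), max_edge = max_edge)
      adjk <- .adjacency_by_position(gk, fr$track_id)
      frac <- vapply(here, function(i) {
        n0 <- nb0[[i]]
        mean(n0 %in% adjk[[pos[i]]])
      }, numeric(1))
    }
    out[[k]] <- tibble::tibble(track_id = focal[here],
                               time_h = times[k],
                               time_rel_h = times[k] - t0,
                               fraction = as.numeric(frac))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_zero_neighbors") <- n_zero
  attr(res, "max_edge") <- max_edge
  res
}

# adjacency as a list of neighbour-id vectors aligned to `ids` (the node
# order of the frame); linear-time, unlike name-based list lookup
.adjacency_by_position <- function(graph, ids) {
  fi <- match(graph$edges$from, ids)
  ti <- match(graph$edges$to, ids)
  unname(split(c(graph$edges$to, graph$edges$from),
               factor(c(fi, ti), levels = seq_along(ids))))
}

#' Group retention series and summarise mean +/- SEM
#'
#' Groups per-cell retention series by initial distance to the wound
#' (default edges 0.5 and 1 mm) or by migration speed (default edges 0.08
#' and 0.18 µm/min), and returns the mean fraction with its standard error
#' per time point per group. The aggregation unit is the cell by default; if
#' `positions` assigns cells to imaging positions, cells are first averaged
#' within position and the SEM is taken across positions.
#'
#' @param series Output of [retention_fraction()].
#' @param values Named vector or tibble (`track_id`, `value`) giving each
#'   focal cell's grouping covariate (initial distance in µm, or speed in
#'   µm/min, typically from [track_metrics()]).
#' @param grouping `"distance"` or `"speed"` (sets default `edges` and
#'   labels), or `"custom"`.
#' @param edges Two ascending inner edges defining three groups.
#' @param positions Optional tibble (`track_id`, `position`) for
#'   position-level aggregation.
#' @return Tibble: `group`, `time_rel_h`, `mean_fraction`, `sem`, `n_units`
#'   (`sem` is sample-SD/sqrt(n); 0 when `n_units` is 1).
#' @export
group_retention <- function(series, values,
                            grouping = c("distance", "speed", "custom"),
                            edges = NULL, positions = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(edges)) {
    edges <- switch(grouping,
                    distance = c(500, 1000),
                    speed = c(0.08, 0.18),
                    stop("'edges' required for custom grouping", call. = FALSE))
  }
  stopifnot(length(edges) == 2, edges[1] < edges[2])
  labs <- .bin_labels(edges)
  if (grouping == "distance") labs <- c("<0.5 mm", "0.5-1 mm", ">1 mm")
  if (!is.data.frame(values)) {
    values <- tibble::tibble(track_id = type.convert(names(values), as.is = TRUE),
                             value = as.numeric(values))
  }
  v <- values$value[match(series$track_id, values$track_id)]
  grp <- factor(labs[findInterval(v, c(-Inf, edges, Inf))], levels = labs)
  ser <- series
  ser$group <- grp
  ser <- ser[!is.na(ser$group), ]
  if (!is.null(positions)) {
    ser$unit <- positions$position[match(ser$track_id, positions$track_id)]
  } else {
    ser$unit <- ser$track_id
  }
  # average within unit first, then mean +/- SEM across units
  per_unit <- dplyr::summarise(
    dplyr::group_by(ser, .data$group, .data$time_rel_h, .data$unit),
    fraction = mean(.data$fraction), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_unit, .data$group, .data$time_rel_h),
    mean_fraction = mean(.data$fraction),
    sem = if (dplyr::n() > 1) sd(.data$fraction) / sqrt(dplyr::n()) else 0,
    n_units = dplyr::n(), .groups = "drop")
  # groups with no members still get rows (n_units = 0)
  full <- tidyr::complete(out, .data$group,
                          time_rel_h = sort(unique(series$time_rel_h)),
                          fill = list(n_units = 0L))
  dplyr::arrange(full, .data$group, .data$time_rel_h)
}
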