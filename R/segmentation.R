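#' Membrane probability map
#'
#' A fixed classical stand-in for a trained pixel classifier, for images in
#' which the membrane is the bright thin structure: the image is
#' Gaussian-smoothed at the membrane scale, a rectified
#' difference-of-Gaussians ridge term is added (emphasizing thin bright
#' lines over broad plateaus), and the response is normalized to `[0, 1]`
#' between its robust (1st / 99.9th percentile) bounds.
#'
#' @param image 2-D numeric matrix (rows index x, as produced by
#'   [render_membrane()] / [read_membrane_image()]).
#' @param sigma Smoothing scale (px) matched to the membrane width.
#' @param bg_sigma Background scale (px) of the ridge term.
#' @return Matrix of membrane probabilities in `[0, 1]`, same shape as
#'   `image`. A constant image gives a constant (zero) map.
#' @export
pixel_classify <- function(image, sigma = 0.7, bg_sigma = 8) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a 2-D numeric matrix", call. = FALSE)
  }
  stopifnot(sigma > 0, bg_sigma > sigma)
  s <- EBImage::gblur(image, sigma)
  ridge <- s - EBImage::gblur(image, bg_sigma)
  ridge[ridge < 0] <- 0
  resp <- s + ridge
  lo <- as.numeric(quantile(resp, 0.01))
  hi <- as.numeric(quantile(resp, 0.999))
  if (hi <= lo) return(matrix(0, nrow(image), ncol(image)))
  pmin(pmax((resp - lo) / (hi - lo), 0), 1)
}

#' Segment cells from a membrane probability map
#'
#' Labels the 4-connected components of the sub-threshold (non-membrane)
#' region; pixels at or above the threshold (ties included) are treated as
#' membrane and get label 0.
#'
#' @param prob_map Matrix with values in `[0, 1]` (from [pixel_classify()]).
#' @param threshold Membrane threshold in `[0, 1]`.
#' @return Integer label matrix (0 = membrane).
#' @export
segment_membrane <- function(prob_map, threshold = 0.5) {
  if (!is.matrix(prob_map) || min(prob_map) < 0 || max(prob_map) > 1) {
    stop("'prob_map' must be a matrix with values in [0, 1]", call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  mask <- prob_map < threshold
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(lab), nrow(mask))
}

#' Circularity of a region
#'
#' `4 * pi * area / perimeter^2`: 1 for a disk, `pi/4` for a square, lower
#' for irregular shapes.
#' @param area Region area.
#' @param perimeter Region perimeter (same length unit).
#' @return Dimensionless circularity (uncapped; [region_props()] caps its
#'   values at 1 after discretization).
#' @export
circularity <- function(area, perimeter) {
  4 * pi * area / perimeter^2
}

# Perimeter of a binary mask in pixel units, via the weighted border-pixel
# estimator: border pixels (those 4-connected to the outside) are classified
# by their neighbourhood pattern and weighted 1 (isothetic), sqrt(2)
# (diagonal) or (1+sqrt(2))/2 (corner), which is asymptotically unbiased for
# smooth shapes (a plain border count would overestimate a disk's perimeter
# by ~27%).
.perimeter_px <- function(mask) {
  m <- mask * 1
  er <- mask &
    .shift_mat(m, 1L, 0L) & .shift_mat(m, -1L, 0L) &
    .shift_mat(m, 0L, 1L) & .shift_mat(m, 0L, -1L)
  B <- (mask & !er) * 1
  if (!any(B == 1)) return(0)
  code <- 10 * (.shift_mat(B, -1L, -1L) + .shift_mat(B, -1L, 1L) +
                  .shift_mat(B, 1L, -1L) + .shift_mat(B, 1L, 1L)) +
    2 * (.shift_mat(B, -1L, 0L) + .shift_mat(B, 1L, 0L) +
           .shift_mat(B, 0L, -1L) + .shift_mat(B, 0L, 1L)) +
    1 * B
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  sum(w[code[B == 1] + 1])
}

#' Region properties of a label map
#'
#' Computes per-region geometry: area (pixel count times `pixel_size^2`),
#' perimeter (weighted border-pixel estimator), circularity (capped at 1),
#' centroid in µm, and optionally distance to the wound.
#'
#' @param labels Integer label matrix (0 = background), e.g. from
#'   [segment_membrane()] or a `membrane_render`'s ground-truth labels.
#' @param pixel_size Pixel size (µm/px).
#' @param origin µm coordinates of the lower corner of pixel (1,1) — for a
#'   `membrane_render`, `bbox[c(1, 3)]`.
#' @param wound_half_width If given, `distance_to_wound` is computed from
#'   the centroid x as `max(0, |x| - wound_half_width)`.
#' @param layer Optional layer tag carried into the table.
#' @return Tibble: `region_id`, `x_um`, `y_um`, `area_um2`, `perimeter_um`,
#'   `circularity`, `layer`, `distance_to_wound`.
#' @export
region_props <- function(labels, pixel_size = 0.5, origin = c(0, 0),
                         wound_half_width = NULL, layer = NA_character_) {
  if (inherits(labels, "membrane_render")) {
    origin <- labels$bbox[c(1, 3)]
    pixel_size <- labels$pixel_size
    layer <- labels$layer
    labels <- labels$labels
  }
  if (!is.matrix(labels) || any(labels != round(labels))) {
    stop("'labels' must be an integer label matrix", call. = FALSE)
  }
  stopifnot(pixel_size > 0)
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(tibble::tibble(region_id = integer(0), x_um = numeric(0),
                          y_um = numeric(0), area_um2 = numeric(0),
                          perimeter_um = numeric(0), circularity = numeric(0),
                          layer = character(0),
                          distance_to_wound = numeric(0)))
  }
  nr <- nrow(labels)
  vals <- labels[idx]
  by_lab <- split(idx, vals)
  rows <- lapply(names(by_lab), function(L) {
    ii <- by_lab[[L]]
    ri <- (ii - 1L) %% nr + 1L
    ci <- (ii - 1L) %/% nr + 1L
    r0 <- range(ri); c0 <- range(ci)
    mask <- matrix(FALSE, r0[2] - r0[1] + 3L, c0[2] - c0[1] + 3L)
    mask[cbind(ri - r0[1] + 2L, ci - c0[1] + 2L)] <- TRUE
    per <- .perimeter_px(mask) * pixel_size
    area <- length(ii) * pixel_size^2
    data.frame(region_id = as.integer(L),
               x_um = origin[1] + (mean(ri) - 0.5) * pixel_size,
               y_um = origin[2] + (mean(ci) - 0.5) * pixel_size,
               area_um2 = area,
               perimeter_um = per,
               circularity = if (per > 0) min(1, circularity(area, per)) else NA_real_)
  })
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  out$layer <- layer
  out$distance_to_wound <- if (is.null(wound_half_width)) {
    NA_real_
  } else {
    wound_distance(out$x_um, wound_half_width)
  }
  out[order(out$region_id), ]
}

#' Filter regions by circularity and size
#'
#' Keeps regions whose circularity and area lie inside the closed ranges
#' (boundaries inclusive); the classical particle filter with circularity
#' 0.2-1 and size 60-2500. Sizes are interpreted in µm^2 (i.e. after
#' `pixel_size` scaling). Row order is preserved; the operation is
#' idempotent.
#'
#' @param table A [region_props()] table.
#' @param circularity_range,area_range Closed intervals `c(lo, hi)`.
#' @return The filtered table.
#' @export
filter_regions <- function(table, circularity_range = c(0.2, 1),
                           area_range = c(60, 2500)) {
  if (length(circularity_range) != 2 || circularity_range[1] > circularity_range[2]) {
    stop("'circularity_range' must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  if (length(area_range) != 2 || area_range[1] > area_range[2]) {
    stop("'area_range' must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  keep <- table$circularity >= circularity_range[1] &
    table$circularity <= circularity_range[2] &
    table$area_um2 >= area_range[1] &
    table$area_um2 <= area_range[2]
  table[which(keep), ]
}

#' Cell-area summaries by distance to the wound
#'
#' @param table A [region_props()] table with `distance_to_wound`.
#' @param bin_edges Sorted distance bin edges (µm); bins are
#'   `[e1, e2), [e2, e3), ...`.
#' @return Tibble with one row per bin: `bin_lo`, `bin_hi`, `mean_area`,
#'   `median_area`, `n`; regions outside all bins are excluded and their
#'   count stored in attribute `n_excluded`.
#' @export
area_by_distance <- function(table, bin_edges = c(0, 200, 400, 600, 800, 1000)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("'bin_edges' must be strictly ascending", call. = FALSE)
  }
  if (nrow(table) == 0) {
    warning("empty region table; returning empty summary")
    out <- tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                          bin_hi = bin_edges[-1],
                          mean_area = NA_real_, median_area = NA_real_,
                          n = 0L)
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  d <- table$distance_to_wound
  bin <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  bin[d >= bin_edges[length(bin_edges)]] <- NA
  bin[bin == 0] <- NA
  out <- lapply(seq_len(length(bin_edges) - 1L), function(j) {
    a <- table$area_um2[!is.na(bin) & bin == j]
    tibble::tibble(bin_lo = bin_edges[j], bin_hi = bin_edges[j + 1],
                   mean_area = if (length(a)) mean(a) else NA_real_,
                   median_area = if (length(a)) median(a) else NA_real_,
                   n = length(a))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "n_excluded") <- sum(is.na(bin))
  out
}
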