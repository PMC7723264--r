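#' Rendering parameters for synthetic membrane images
#'
#' Controls rasterization of simulator frames into membrane-reporter-like
#' grayscale images (a stand-in for an E-cadherin-CFP channel).
#'
#' @param pixel_size Pixel size (µm/px).
#' @param membrane_width Membrane line width (px, >= 2; the line straddles
#'   the cell boundary).
#' @param membrane_intensity,interior_intensity,background_intensity Gray
#'   levels (arbitrary units); must satisfy membrane > interior >= background
#'   >= 0.
#' @param noise_sd SD of additive Gaussian noise (same units).
#' @param max_cell_radius Voronoi clipping radius (µm). `NULL` (default)
#'   derives it per layer from the configured target-area upper bound,
#'   `sqrt(max_area / pi)`, which reproduces the basal vs suprabasal size
#'   separation without a mechanical area model.
#' @return A list of class `render_params`.
#' @export
render_params <- function(pixel_size = 0.5,
                          membrane_width = 2,
                          membrane_intensity = 200,
                          interior_intensity = 40,
                          background_intensity = 10,
                          noise_sd = 0,
                          max_cell_radius = NULL) {
  stopifnot(pixel_size > 0, membrane_width >= 1)
  if (!(membrane_intensity > interior_intensity &&
        interior_intensity >= background_intensity &&
        background_intensity >= 0)) {
    stop("need membrane_intensity > interior_intensity >= background_intensity >= 0",
         call. = FALSE)
  }
  if (!is.null(max_cell_radius)) stopifnot(max_cell_radius > 0)
  structure(list(pixel_size = pixel_size,
                 membrane_width = membrane_width,
                 membrane_intensity = membrane_intensity,
                 interior_intensity = interior_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 max_cell_radius = max_cell_radius),
            class = "render_params")
}

.shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- max(1, 1 - di):min(nr, nr - di)
  sj <- max(1, 1 - dj):min(nc, nc - dj)
  out[si, sj] <- m[si + di, sj + dj]
  out
}

# default per-layer Voronoi clip radius: disk of the layer's maximal target
# area (basal 50-300 um^2 -> ~9.8 um, suprabasal 300-600 um^2 -> ~13.8 um)
.default_clip_radius <- function(layer) {
  hi <- switch(layer, basal = 300, suprabasal = 600, follicle = 300)
  sqrt(hi / pi)
}

#' Render a synthetic membrane image of one layer
#'
#' Rasterizes a clipped Voronoi tessellation of the layer's centroids:
#' every pixel within `max_cell_radius` of its nearest centroid belongs to
#' that cell; boundary pixels between cells (and between a cell and
#' background) are drawn at `membrane_intensity`, interiors at
#' `interior_intensity`, the rest at `background_intensity`, plus optional
#' Gaussian noise. The returned label map assigns interior pixels their
#' generating `agent_id` (0 = background or membrane).
#'
#' @param frame A simulator frame (data frame with `agent_id`, `compartment`,
#'   `x`, `y`) — one element of `wound_sim$frames`.
#' @param layer `"basal"` or `"suprabasal"`.
#' @param params A [render_params()].
#' @param bbox Image extent `c(xmin, xmax, ymin, ymax)` in µm; default spans
#'   the layer's centroids plus one clip radius.
#' @return A list of class `membrane_render`: `image` and `labels` matrices
#'   (rows index x, columns y), `pixel_size`, `bbox`, `layer`, `params`.
#' @export
render_membrane <- function(frame, layer = "basal", params = render_params(),
                            bbox = NULL) {
  stopifnot(inherits(params, "render_params"))
  layer <- match.arg(layer, .compartments)
  cells <- frame[frame$compartment == layer, , drop = FALSE]
  if (nrow(cells) == 0) {
    stop("frame contains no agents of layer '", layer, "'", call. = FALSE)
  }
  r_clip <- params$max_cell_radius %||% .default_clip_radius(layer)
  ps <- params$pixel_size
  if (is.null(bbox)) {
    bbox <- c(min(cells$x) - r_clip, max(cells$x) + r_clip,
              min(cells$y) - r_clip, max(cells$y) + r_clip)
  }
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / ps))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / ps))
  if (nx * ny > 3e7) stop("requested image is too large", call. = FALSE)
  cx <- bbox[1] + (seq_len(nx) - 0.5) * ps
  cy <- bbox[3] + (seq_len(ny) - 0.5) * ps
  grid <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  nn <- RANN::nn2(cbind(cells$x, cells$y), grid, k = 1)
  lab <- matrix(ifelse(nn$nn.dists[, 1] <= r_clip, nn$nn.idx[, 1], 0L),
                nx, ny)

  # boundary pixels: label differs from any 4-neighbour (off-image counts as
  # background), taken on both sides of the boundary
  memb <- (lab != .shift_mat(lab, 1L, 0L)) |
    (lab != .shift_mat(lab, -1L, 0L)) |
    (lab != .shift_mat(lab, 0L, 1L)) |
    (lab != .shift_mat(lab, 0L, -1L))
  extra <- ceiling((params$membrane_width - 2) / 2)
  if (extra > 0) {
    brush <- EBImage::makeBrush(2L * extra + 1L, shape = "diamond")
    memb <- EBImage::dilate(memb * 1, brush) > 0
  }

  labels <- matrix(0L, nx, ny)
  keep <- lab > 0L & !memb
  labels[keep] <- cells$agent_id[lab[keep]]

  img <- matrix(params$background_intensity, nx, ny)
  img[lab > 0L & !memb] <- params$interior_intensity
  img[memb & (lab > 0L | .adjacent_to_label(lab))] <- params$membrane_intensity
  if (params$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, params$noise_sd)
  }
  structure(list(image = img, labels = labels, pixel_size = ps, bbox = bbox,
                 layer = layer, params = params),
            class = "membrane_render")
}

# background pixels that touch a labelled pixel (membrane straddles the
# cell/background boundary)
.adjacent_to_label <- function(lab) {
  (.shift_mat(lab, 1L, 0L) > 0L) | (.shift_mat(lab, -1L, 0L) > 0L) |
    (.shift_mat(lab, 0L, 1L) > 0L) | (.shift_mat(lab, 0L, -1L) > 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.membrane_render <- function(x, ...) {
  cat(sprintf("<membrane_render> %s layer, %d x %d px (%g um/px), %d cells\n",
              x$layer, nrow(x$image), ncol(x$image), x$pixel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Write a membrane render to TIFF
#'
#' The image is written as 32-bit float on a 0-65535 intensity scale, the
#' label map as 16-bit unsigned integers.
#' @param render A `membrane_render`.
#' @param image_path,labels_path Output TIFF paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_render <- function(render, image_path = NULL, labels_path = NULL) {
  stopifnot(inherits(render, "membrane_render"))
  if (!is.null(image_path)) {
    img <- pmin(pmax(render$image, 0), 65535) / 65535
    tiff::writeTIFF(t(img), image_path, bits.per.sample = 32L)
  }
  if (!is.null(labels_path)) {
    if (max(render$labels) > 65535L) {
      stop("label ids exceed 16-bit range", call. = FALSE)
    }
    tiff::writeTIFF(t(render$labels) / 65535, labels_path,
                    bits.per.sample = 16L)
  }
  invisible(c(image_path, labels_path))
}

#' Read a grayscale TIFF as an image matrix
#'
#' Returns the image in the row-indexes-x convention used by
#' [render_membrane()] and [pixel_classify()], on the native 0-65535
#' intensity scale (TIFF data are stored normalized to `[0, 1]`).
#' @param path TIFF path.
#' @param integer_labels If `TRUE`, round to integer labels as written by
#'   [write_render()].
#' @return A numeric (or integer) matrix.
#' @export
read_membrane_image <- function(path, integer_labels = FALSE) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- t(m) * 65535
  if (integer_labels) m <- matrix(as.integer(round(m)), nrow(m))
  m
}

#' Simulate two-channel Fucci reporter intensities for one frame
#'
#' G1 cells draw a high channel-1 (G1 reporter) and low channel-2 (S/G2
#' reporter) intensity; S/G2 cells the reverse. Intensities are log-normal
#' with the given geometric means and common `sdlog`. Draws come from the
#' session RNG, so results are reproducible under `set.seed()`.
#'
#' @param frame A simulator frame (element of `wound_sim$frames`).
#' @param high_mean,low_mean Geometric means of the expressed and repressed
#'   channel (arbitrary units); defaults are 10x apart, giving essentially
#'   error-free classification by [fucci_classify()].
#' @param sdlog Log-scale SD.
#' @return Tibble with `agent_id`, `compartment`, `phase_true`, `ch1`, `ch2`.
#' @export
render_fucci <- function(frame, high_mean = 200, low_mean = 20, sdlog = 0.2) {
  stopifnot(high_mean > 0, low_mean > 0, sdlog >= 0)
  n <- nrow(frame)
  g1 <- frame$phase == "G1"
  ch1 <- rlnorm(n, log(ifelse(g1, high_mean, low_mean)), sdlog)
  ch2 <- rlnorm(n, log(ifelse(g1, low_mean, high_mean)), sdlog)
  tibble::tibble(agent_id = frame$agent_id,
                 compartment = frame$compartment,
                 phase_true = frame$phase,
                 ch1 = ch1, ch2 = ch2)
}

#' Attach simulated Fucci intensities to an exported track table
#'
#' Fills the `ch1`/`ch2` columns of a track table for the selected frames
#' using [render_fucci()] on the corresponding simulator frames.
#'
#' @param tracks Track table from [export_tracks()].
#' @param result The `wound_sim` the tracks came from.
#' @param frames Integer frame numbers (0-based, as in the track table);
#'   default all.
#' @inheritParams render_fucci
#' @return The track table with `ch1`/`ch2` filled for the selected frames.
#' @export
add_fucci_intensities <- function(tracks, result, frames = NULL,
                                  high_mean = 200, low_mean = 20,
                                  sdlog = 0.2) {
  stopifnot(inherits(result, "wound_sim"))
  if (is.null(frames)) frames <- seq_along(result$frames) - 1L
  parts <- lapply(frames, function(f) {
    ft <- render_fucci(result$frames[[f + 1L]], high_mean, low_mean, sdlog)
    ft$frame <- f
    ft
  })
  intens <- dplyr::bind_rows(parts)
  key_tr <- paste(tracks$track_id, tracks$frame)
  key_in <- paste(intens$agent_id, intens$frame)
  m <- match(key_tr, key_in)
  hit <- !is.na(m)
  tracks$ch1[hit] <- intens$ch1[m[hit]]
  tracks$ch2[hit] <- intens$ch2[m[hit]]
  tracks
}
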