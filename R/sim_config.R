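#' Simulation configuration
#'
#' Builds the parameter set for [simulate_wound()]. Defaults reproduce the
#' intravital scratch-wound conditions the simulator is meant to emulate:
#' a 150 µm wide wound strip (half-width 75 µm, full widths of 50-200 µm are
#' legal), basal cells drifting wound-ward at 0.05 µm/min within 0.5 mm of
#' the wound edge falling linearly to 0.025 µm/min beyond 1 mm, a jammed
#' phase with no wound-bed entry before 20 h, 30-min frames, static
#' suprabasal cells, immobile hair-follicle cells inside circular obstacles,
#' and S/G2 fractions of ~5% at 0-200 µm, ~10% at 200-400 µm and ~2%
#' elsewhere.
#'
#' @param wound_half_width Half-width of the wound strip `|x| < w` (µm).
#' @param domain_half_extent Half-extent of the simulated field along x (µm).
#' @param domain_height Extent of the field along y (µm).
#' @param dt Frame interval (minutes).
#' @param t_end Simulated duration (hours).
#' @param t_unjam Time at which the wound edge stops reflecting and basal
#'   cells may enter the strip (hours).
#' @param v_near,v_far Drift speeds (µm/min) at distances `<= d_near` and
#'   `>= d_far` from the wound edge; linear interpolation in between.
#' @param d_near,d_far Distance anchors for the speed field (µm).
#' @param noise_sigma Isotropic positional noise, expressed as a speed
#'   (µm/min); per-step displacement noise SD is `noise_sigma * dt`.
#' @param heading_sigma SD (radians) of the Gaussian wobble applied to the
#'   wound-ward drift direction each step. Leaves the step length (and hence
#'   path-length speeds) unchanged but makes neighbour exchange scale with
#'   drift speed.
#' @param basal_target_area_range,suprabasal_target_area_range Sampling
#'   ranges for per-cell target areas (µm^2); these set the layer densities.
#' @param follicles List of hair-follicle obstacles, each
#'   `list(center = c(x, y), radius = r)` in µm.
#' @param prolif_zone_edges Two distances (µm) bounding the elevated
#'   proliferation zone; the S/G2 target fraction is `p_sg2_inner` below the
#'   first edge, `p_sg2_zone` between them, `p_sg2_baseline` beyond.
#' @param p_sg2_inner,p_sg2_zone,p_sg2_baseline Stationary S/G2 fractions per
#'   distance zone.
#' @param sg2_duration Time spent in S/G2 before division (hours).
#' @param repulsion_radius Pair distance (µm) below which basal cells repel.
#' @param repulsion_strength Peak repulsion speed (µm/min) at full overlap.
#' @param seed Integer seed; identical `(config, seed)` give bit-identical
#'   results.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(t_end = 2, domain_half_extent = 400, domain_height = 150)
#' @export
sim_config <- function(wound_half_width = 75,
                       domain_half_extent = 1500,
                       domain_height = 500,
                       dt = 30,
                       t_end = 48,
                       t_unjam = 20,
                       v_near = 0.05,
                       v_far = 0.025,
                       d_near = 500,
                       d_far = 1000,
                       noise_sigma = 0.01,
                       heading_sigma = 0.35,
                       basal_target_area_range = c(50, 300),
                       suprabasal_target_area_range = c(300, 600),
                       follicles = default_follicles(),
                       prolif_zone_edges = c(200, 400),
                       p_sg2_inner = 0.05,
                       p_sg2_zone = 0.10,
                       p_sg2_baseline = 0.02,
                       sg2_duration = 6,
                       repulsion_radius = 9,
                       repulsion_strength = 0.15,
                       seed = 1L) {
  cfg <- list(
    wound_half_width = wound_half_width,
    domain_half_extent = domain_half_extent,
    domain_height = domain_height,
    dt = dt, t_end = t_end, t_unjam = t_unjam,
    v_near = v_near, v_far = v_far, d_near = d_near, d_far = d_far,
    noise_sigma = noise_sigma, heading_sigma = heading_sigma,
    basal_target_area_range = basal_target_area_range,
    suprabasal_target_area_range = suprabasal_target_area_range,
    follicles = follicles,
    prolif_zone_edges = prolif_zone_edges,
    p_sg2_inner = p_sg2_inner, p_sg2_zone = p_sg2_zone,
    p_sg2_baseline = p_sg2_baseline,
    sg2_duration = sg2_duration,
    repulsion_radius = repulsion_radius,
    repulsion_strength = repulsion_strength,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' Default hair-follicle obstacle layout
#'
#' Three 40-µm follicle disks on either side of the wound, one pair inside
#' the proliferative zone (cells bypass follicles at 200-400 µm from the
#' wound in vivo).
#' @return List of `list(center, radius)` entries.
#' @export
default_follicles <- function() {
  list(
    list(center = c(-350, 150), radius = 40),
    list(center = c(350, 350), radius = 40),
    list(center = c(900, 250), radius = 40)
  )
}

.check_num <- function(x, field, n = 1, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != n || any(!is.finite(x))) {
    stop(sprintf("'%s' must be %d finite numeric value(s)", field, n),
         call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("'%s' must be strictly positive", field), call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", field), call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, field) {
  .check_num(x, field, nonneg = TRUE)
  if (x > 1) stop(sprintf("'%s' must lie in [0, 1]", field), call. = FALSE)
  invisible(x)
}

#' Validate a simulation configuration
#'
#' @param cfg A list with the fields of [sim_config()].
#' @return The validated config, classed `sim_config`.
#' @export
validate_sim_config <- function(cfg) {
  for (f in c("wound_half_width", "domain_half_extent", "domain_height",
              "dt", "t_end", "sg2_duration", "repulsion_radius")) {
    .check_num(cfg[[f]], f, positive = (f != "t_end"))
  }
  .check_num(cfg$t_end, "t_end", nonneg = TRUE)
  .check_num(cfg$t_unjam, "t_unjam", nonneg = TRUE)
  .check_num(cfg$v_near, "v_near", nonneg = TRUE)
  .check_num(cfg$v_far, "v_far", nonneg = TRUE)
  if (cfg$v_near < cfg$v_far) {
    stop("'v_near' must be >= 'v_far'", call. = FALSE)
  }
  .check_num(cfg$d_near, "d_near", positive = TRUE)
  .check_num(cfg$d_far, "d_far", positive = TRUE)
  if (cfg$d_near >= cfg$d_far) {
    stop("'d_near' must be < 'd_far'", call. = FALSE)
  }
  .check_num(cfg$noise_sigma, "noise_sigma", nonneg = TRUE)
  .check_num(cfg$heading_sigma, "heading_sigma", nonneg = TRUE)
  .check_num(cfg$repulsion_strength, "repulsion_strength", nonneg = TRUE)
  for (f in c("basal_target_area_range", "suprabasal_target_area_range")) {
    .check_num(cfg[[f]], f, n = 2, positive = TRUE)
    if (cfg[[f]][1] > cfg[[f]][2]) {
      stop(sprintf("'%s' must be sorted ascending", f), call. = FALSE)
    }
  }
  .check_num(cfg$prolif_zone_edges, "prolif_zone_edges", n = 2, positive = TRUE)
  if (is.unsorted(cfg$prolif_zone_edges, strictly = TRUE)) {
    stop("'prolif_zone_edges' must be strictly ascending", call. = FALSE)
  }
  for (f in c("p_sg2_inner", "p_sg2_zone", "p_sg2_baseline")) {
    .check_fraction(cfg[[f]], f)
  }
  if (cfg$wound_half_width >= cfg$domain_half_extent) {
    stop("'wound_half_width' must be < 'domain_half_extent'", call. = FALSE)
  }
  if (cfg$t_end > 0 && cfg$dt / 60 >= cfg$t_end) {
    stop("'dt' must be shorter than 't_end'", call. = FALSE)
  }
  if (!is.list(cfg$follicles)) {
    stop("'follicles' must be a list of list(center, radius)", call. = FALSE)
  }
  for (fol in cfg$follicles) {
    .check_num(fol$center, "follicles$center", n = 2)
    .check_num(fol$radius, "follicles$radius", positive = TRUE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The document must mirror the [sim_config()] field names; missing fields
#' fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_sim_config(raw)
}

#' Coerce a list to a sim_config
#' @param x A named list (e.g. parsed YAML) or an existing `sim_config`.
#' @return A validated `sim_config`.
#' @export
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  if (!is.list(x)) stop("config must be a named list", call. = FALSE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(x$follicles)) {
    x$follicles <- lapply(x$follicles, function(f) {
      list(center = as.numeric(unlist(f$center)), radius = as.numeric(f$radius))
    })
  }
  do.call(sim_config, x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  wound strip   : |x| < %g um (domain %g x %g um)\n",
              x$wound_half_width, 2 * x$domain_half_extent, x$domain_height))
  cat(sprintf("  time          : %g h in %g-min steps, unjam at %g h\n",
              x$t_end, x$dt, x$t_unjam))
  cat(sprintf("  drift         : %g -> %g um/min over %g-%g um\n",
              x$v_near, x$v_far, x$d_near, x$d_far))
  cat(sprintf("  S/G2 fractions: %g / %g / %g (inner / zone / baseline)\n",
              x$p_sg2_inner, x$p_sg2_zone, x$p_sg2_baseline))
  cat(sprintf("  follicles     : %d, seed %d\n", length(x$follicles), x$seed))
  invisible(x)
}
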