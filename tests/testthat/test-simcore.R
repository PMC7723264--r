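# a small, fast configuration used by several tests
small_cfg <- function(..., t_end = 6) {
  sim_config(domain_half_extent = 400, domain_height = 150,
             follicles = list(list(center = c(200, 75), radius = 30)),
             t_end = t_end, t_unjam = 2, ...)
}

test_that("pure drift moves basal agents wound-ward at exactly v*dt", {
  cfg <- sim_config(domain_half_extent = 800, domain_height = 120,
                    follicles = list(), noise_sigma = 0, heading_sigma = 0,
                    repulsion_strength = 0, v_near = 0.05, v_far = 0.05,
                    p_sg2_inner = 0, p_sg2_zone = 0, p_sg2_baseline = 0,
                    t_end = 10, seed = 3)
  sim <- simulate_wound(cfg)
  a <- sim$frames[[1]]
  b <- sim$frames[[length(sim$frames)]]
  bas <- a$compartment == "basal" & abs(a$x) > 75 + 0.05 * 600 + 1
  # every basal agent not reaching the edge advances 0.05 um/min * 600 min
  expect_equal(b$x[bas], a$x[bas] - sign(a$x[bas]) * 30, tolerance = 1e-9)
  expect_equal(b$y[bas], a$y[bas], tolerance = 1e-12)
  # suprabasal agents are exactly static without noise
  sup <- a$compartment == "suprabasal"
  expect_equal(b$x[sup], a$x[sup], tolerance = 1e-12)
})

test_that("the wound strip reflects all epidermal agents until t_unjam", {
  sim <- simulate_wound(small_cfg(seed = 5))
  hw <- sim$config$wound_half_width
  for (k in seq_along(sim$times)) {
    if (sim$times[k] < sim$config$t_unjam) {
      fr <- sim$frames[[k]]
      epi <- fr$compartment %in% c("basal", "suprabasal")
      expect_equal(sum(epi & abs(fr$x) < hw), 0)
    }
  }
})

test_that("no agent centroid ever enters a follicle disk", {
  sim <- simulate_wound(small_cfg(seed = 6))
  fol <- sim$config$follicles[[1]]
  for (fr in sim$frames) {
    non_fol <- fr$compartment != "follicle"
    d2 <- (fr$x - fol$center[1])^2 + (fr$y - fol$center[2])^2
    expect_equal(sum(non_fol & d2 < fol$radius^2), 0)
  }
})

test_that("agent counts change only through division (mass balance)", {
  sim <- simulate_wound(small_cfg(seed = 7))
  n <- vapply(sim$frames, nrow, integer(1))
  divs <- sim$divisions
  for (k in seq_len(length(n) - 1)) {
    born <- sum(abs(divs$time_h - sim$times[k + 1]) < 1e-9)
    expect_equal(n[k + 1], n[k] + born)
  }
  expect_equal(n[length(n)], n[1] + nrow(divs))
})

test_that("identical config and seed give bit-identical exported tracks", {
  t1 <- export_tracks(simulate_wound(small_cfg(seed = 11)))
  t2 <- export_tracks(simulate_wound(small_cfg(seed = 11)))
  expect_identical(t1, t2)
  t3 <- export_tracks(simulate_wound(small_cfg(seed = 12)))
  expect_false(identical(t1$x_um, t3$x_um))
})

test_that("zone S/G2 fractions recover their targets in a static population", {
  cfg <- sim_config(domain_half_extent = 600, domain_height = 300,
                    v_near = 0, v_far = 0, noise_sigma = 0, heading_sigma = 0,
                    follicles = list(), t_end = 30, seed = 13)
  sim <- simulate_wound(cfg)
  gt <- sim$ground_truth$sg2_fraction_by_zone
  expect_gte(min(gt$n_total), 500)
  targets <- c(0.05, 0.10, 0.02)
  expect_true(all(abs(gt$fraction_sg2 - targets) < 0.02))
})

test_that("sg2_hazard solves the stationary two-state chain", {
  for (f in c(0.02, 0.05, 0.10, 0.3)) {
    h <- sg2_hazard(f, sg2_duration = 6, dt = 30)
    n_s <- 12
    expect_equal(n_s / (1 / h + n_s), f, tolerance = 1e-12)
  }
  expect_equal(sg2_hazard(0, 6, 30), 0)
})

test_that("entry_time and closure_time handle hand-built and degenerate cases", {
  cfg <- sim_config()
  frames <- list(
    mk_frame(1:2, "basal", c(200, -300), c(10, 20)),
    mk_frame(1:2, "basal", c(150, -300), c(10, 20)),
    mk_frame(1:2, "basal", c(50, -300), c(10, 20)) # enters at frame 3
  )
  sim <- mk_sim(frames, times = c(0, 0.5, 1), config = cfg)
  expect_equal(entry_time(sim), 1)
  # static agents never enter
  static <- mk_sim(frames[c(1, 1, 1)], times = c(0, 0.5, 1), config = cfg)
  expect_equal(entry_time(static), Inf)
  expect_equal(closure_time(static), Inf)
  expect_error(entry_time(mk_sim(frames[1], 0, cfg)), "2 frames")
  no_basal <- lapply(1:2, function(k) mk_frame(1:3, "follicle",
                                               c(100, 200, 300), c(1, 2, 3)))
  expect_error(entry_time(mk_sim(no_basal, c(0, 0.5), cfg)), "no basal")
  expect_error(closure_time(sim, coverage_radius = -1), "coverage_radius")
})

test_that("exported tracks preserve identity and start daughters at birth", {
  sim <- simulate_wound(small_cfg(seed = 21, t_end = 12))
  tr <- export_tracks(sim)
  expect_equal(nrow(tr), sum(vapply(sim$frames, nrow, integer(1))))
  expect_false(any(duplicated(paste(tr$track_id, tr$frame))))
  # each daughter's first frame is its birth frame
  divs <- sim$divisions
  if (nrow(divs)) {
    first_frame <- tapply(tr$frame, tr$track_id, min)
    birth_frame <- match(divs$time_h, sim$times) - 1L
    expect_equal(as.vector(first_frame[as.character(divs$daughter_id)]),
                 birth_frame)
  }
  # frames strictly increasing within each track
  expect_true(all(tapply(tr$frame, tr$track_id,
                         function(f) all(diff(f) > 0))))
})
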