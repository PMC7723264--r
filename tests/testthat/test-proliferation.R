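test_that("fucci_classify is threshold-at-equality with G1 tie-break", {
  expect_equal(fucci_classify(100, 10), "G1")
  expect_equal(fucci_classify(10, 100), "SG2")
  expect_equal(fucci_classify(50, 50), "G1")
  expect_equal(fucci_classify(0, 0), "G1")
  expect_equal(fucci_classify(c(1, 2), c(2, 1)), c("SG2", "G1"))
  expect_error(fucci_classify(-1, 5), "non-negative")
  expect_error(fucci_classify(1:3, 1:2), "equal length")
})

test_that("fraction_by_zone counts, excludes, and handles empty zones", {
  d <- c(rep(50, 20), rep(1500, 3))
  ph <- c(rep("SG2", 2), rep("G1", 18), rep("SG2", 3))
  z <- fraction_by_zone(d, ph)
  expect_equal(z$fraction_sg2[1], 0.10)
  expect_equal(z$n_total[1], 20L)
  expect_true(is.na(z$fraction_sg2[3])) # empty zone
  expect_equal(z$n_total[3], 0L)
  expect_equal(attr(z, "n_excluded"), 3L) # beyond the last edge
  expect_error(fraction_by_zone(c(-5), "G1"), "distance")
})

test_that("zone fractions are invariant under cell relabelling", {
  tr <- default_fucci_tracks()
  z1 <- zone_fraction_window(tr, phase_from = "channels")
  perm <- tr
  ids <- unique(perm$track_id)
  set.seed(10)
  remap <- setNames(sample(ids), ids)
  perm$track_id <- unname(remap[as.character(perm$track_id)])
  z2 <- zone_fraction_window(perm, phase_from = "channels")
  expect_equal(z1$fraction_sg2, z2$fraction_sg2)
  expect_equal(z1$n_total, z2$n_total)
})

test_that("edu_fraction validates its bounds", {
  expect_equal(edu_fraction(5, 50), 0.1)
  expect_equal(edu_fraction(0, 50), 0)
  expect_equal(edu_fraction(50, 50), 1)
  expect_error(edu_fraction(5, 0), "n_total")
  expect_error(edu_fraction(-1, 10), "n_positive")
  expect_error(edu_fraction(11, 10), "n_positive")
})

test_that("the simulated EdU proxy counts recent divisions", {
  sim <- simulate_wound(sim_config(domain_half_extent = 400,
                                   domain_height = 200, follicles = list(),
                                   t_end = 12, seed = 15))
  cts <- edu_proxy_counts(sim, t = 12, lookback = 4)
  recent <- sim$divisions[sim$divisions$time_h > 8, ]
  expect_equal(cts$n_positive, length(unique(c(recent$mother_id,
                                               recent$daughter_id))))
  expect_gt(cts$n_total, 0)
  expect_lte(edu_fraction(cts$n_positive, cts$n_total), 1)
})

test_that("regress_linear matches the closed-form normal equations", {
  exact <- regress_linear(1:10, 2 * (1:10) + 1)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$intercept, 1, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  flat <- regress_linear(1:5, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(regress_linear(rep(2, 5), 1:5), "constant")
  expect_error(regress_linear(1:2, 1:2), "n >= 3")
  # random instances against the matrix solution
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    fit <- regress_linear(x, y)
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
    expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  }
})

test_that("compare_by_phase sees no difference between identical groups", {
  set.seed(12)
  n <- 60
  rec <- tibble::tibble(
    track_id = 1:(2 * n),
    duration_h = 8,
    mean_speed = rep(rnorm(n, 0.05, 0.005), 2),
    net_displacement = rep(rnorm(n, 20, 3), 2),
    path_length = 25,
    persistence = rep(runif(n, 0.4, 0.9), 2),
    migratory = TRUE,
    initial_distance_to_wound = rep(runif(n, 0, 300), 2),
    compartment = "basal",
    phase = rep(c("G1", "SG2"), each = n))
  cmp <- compare_by_phase(rec, zone_edges = c(0, 400))
  expect_lt(abs(cmp$statistic[cmp$metric == "velocity"]), 1e-9)
  expect_gt(min(cmp$p_value), 0.99)
})

test_that("a lone record per phase yields summaries but no test", {
  rec <- tibble::tibble(
    track_id = 1:2, duration_h = 8,
    mean_speed = c(0.05, 0.06), net_displacement = c(20, 22),
    path_length = 25, persistence = c(0.8, 0.7), migratory = TRUE,
    initial_distance_to_wound = c(100, 150), compartment = "basal",
    phase = c("G1", "SG2"))
  w <- capture_warnings(cmp <- compare_by_phase(rec, zone_edges = c(0, 400)))
  expect_true(all(grepl("skipped", w)))
  expect_true(all(is.na(cmp$p_value)))
  # default velocity measure is net displacement / duration
  expect_equal(cmp$mean_g1[cmp$metric == "velocity"], 20 / (8 * 60))
  expect_error(compare_by_phase(rec[1, ], zone_edges = c(0, 400)),
               "both phases")
})
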