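test_that("mean_speed follows the path-length definition", {
  expect_equal(mean_speed(mk_track(c(0, 1), c(0, 0), c(0, 0))), 0)
  # zig-zag: out 1 um and back over 60 min
  expect_equal(mean_speed(mk_track(c(0, 0.5, 1), c(0, 1, 0), c(0, 0, 0))),
               2 / 60, tolerance = 1e-12)
  expect_error(mean_speed(mk_track(0, 0, 0)), ">= 2 points")
  expect_error(mean_speed(mk_track(c(1, 0), c(0, 1), c(0, 0))), "increasing")
})

test_that("the migratory gate is strict at 10 um per 8 h", {
  over <- mk_track(c(0, 8), c(0, 12), c(0, 0))
  expect_true(is_migratory(over))
  exactly <- mk_track(c(0, 8), c(0, 10), c(0, 0))
  expect_false(is_migratory(exactly))
  # 20 um path but zero net displacement is not migratory
  loop <- mk_track(c(0, 4, 8), c(0, 10, 0), c(0, 0, 0))
  expect_false(is_migratory(loop))
  expect_error(is_migratory(mk_track(c(0, 4), c(0, 0), c(0, 20))), "window")
})

test_that("persistence is net/path, speed-gated, and bounded", {
  straight <- mk_track(c(0, 0.1, 0.2), c(0, 5, 10), c(0, 0, 0))
  expect_equal(persistence(straight), 1)
  back <- mk_track(c(0, 0.1, 0.2), c(0, 5, 0), c(0, 0, 0))
  expect_equal(persistence(back), 0)
  slow <- mk_track(c(0, 10), c(0, 1), c(0, 0)) # 0.1 um/h < 5 um/h gate
  expect_true(is.na(persistence(slow)))
  expect_equal(persistence(straight, ratio = "path_over_net"), 1)
  expect_equal(persistence(mk_track(c(0, 0.05, 0.1), c(0, 1, 1), c(0, 0, 1)),
                           ratio = "path_over_net"), 2 / sqrt(2),
               tolerance = 1e-12)
  # property: persistence in [0, 1] whenever defined
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    tr <- mk_track(cumsum(runif(n, 0.01, 0.1)), cumsum(rnorm(n, 0, 3)),
                   cumsum(rnorm(n, 0, 3)))
    p <- persistence(tr)
    if (!is.na(p)) expect_true(p >= 0 && p <= 1)
    # triangle inequality: path >= net
    net <- sqrt(diff(range(tr$x_um[c(1, n)]))^2 +
                  (tr$y_um[n] - tr$y_um[1])^2)
    expect_gte(sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)) + 1e-12, net)
  }
})

test_that("mean_speed is invariant under global translation and rotation", {
  set.seed(6)
  tr <- mk_track(cumsum(runif(6, 0.05, 0.2)), cumsum(rnorm(6)),
                 cumsum(rnorm(6)))
  v0 <- mean_speed(tr)
  shifted <- tr
  shifted$x_um <- tr$x_um + 123
  shifted$y_um <- tr$y_um - 456
  expect_equal(mean_speed(shifted), v0, tolerance = 1e-12)
  th <- 0.7
  rotated <- tr
  rotated$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um
  rotated$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um
  expect_equal(mean_speed(rotated), v0, tolerance = 1e-12)
})

test_that("direction angles are measured from the wound-ward axis", {
  expect_equal(direction_angle(mk_track(c(0, 8), c(500, 400), c(0, 0))), 0)
  expect_equal(direction_angle(mk_track(c(0, 8), c(500, 600), c(0, 0))), 180)
  expect_equal(direction_angle(mk_track(c(0, 8), c(500, 500), c(0, 100))), 90)
  # mirrored start on the negative side
  expect_equal(direction_angle(mk_track(c(0, 8), c(-500, -400), c(0, 0))), 0)
  expect_true(is.na(direction_angle(mk_track(c(0, 8), c(5, 5), c(7, 7)))))
})

test_that("rose histograms use sectors centred on the wound-ward direction", {
  rh <- rose_histogram(c(0, 0, 0))
  expect_equal(rh$count[1], 3)
  expect_equal(sum(rh$count), 3)
  uni <- rose_histogram(0:359, n_bins = 24)
  expect_true(all(uni$count == 15))
  expect_error(rose_histogram(1:10, n_bins = 3), "n_bins")
})

test_that("track_metrics + velocity_by_distance reproduce simple summaries", {
  rows <- list()
  mk_row <- function(id, t, x, y, comp) {
    tibble::tibble(track_id = id, frame = seq_along(t) - 1, time_h = t,
                   x_um = x, y_um = y, compartment = comp,
                   phase = "G1", ch1 = NA_real_, ch2 = NA_real_)
  }
  t <- seq(0, 8, by = 0.5)
  # three migratory basal tracks at distinct speeds in one bin
  for (i in 1:3) {
    v <- c(0.04, 0.05, 0.06)[i] # um/min
    rows[[i]] <- mk_row(i, t, 300 - v * 60 * t, rep(i * 10, length(t)),
                        "basal")
  }
  rows[[4]] <- mk_row(4, t, rep(1200, length(t)), rep(5, length(t)),
                      "follicle")
  tab <- dplyr::bind_rows(rows)
  rec <- track_metrics(tab, wound_half_width = 75)
  vbd <- velocity_by_distance(rec)
  expect_equal(vbd$median_speed[vbd$bin == "<500"], 0.05, tolerance = 1e-12)
  expect_equal(vbd$n, c(3L, 0L, 0L))
  expect_equal(vbd$q75[1] - vbd$q25[1], 0.01, tolerance = 1e-12)
  dbc <- displacement_by_compartment(rec)
  expect_equal(dbc$median_displacement[dbc$compartment == "follicle" &
                                         dbc$bin == ">1000"], 0)
  expect_gt(dbc$median_displacement[dbc$compartment == "basal" &
                                      dbc$bin == "<500"], 10)
})

test_that("single-record bins report their own value with zero IQR", {
  t <- seq(0, 8, by = 1)
  tab <- tibble::tibble(track_id = 1, frame = seq_along(t) - 1, time_h = t,
                        x_um = 300 - 2.5 * t, y_um = 0, compartment = "basal",
                        phase = "G1", ch1 = NA_real_, ch2 = NA_real_)
  vbd <- velocity_by_distance(track_metrics(tab, 75))
  one <- vbd[vbd$bin == "<500", ]
  expect_equal(one$n, 1L)
  expect_equal(one$q25, one$median_speed)
  expect_equal(one$q75, one$median_speed)
})
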