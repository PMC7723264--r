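test_that("track tables round-trip losslessly through CSV", {
  sim <- simulate_wound(sim_config(domain_half_extent = 300,
                                   domain_height = 100, follicles = list(),
                                   t_end = 2, seed = 8))
  tr <- export_tracks(sim)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
})

test_that("malformed track files are rejected informatively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,time_h,x_um,y_um,compartment",
               "1,0,0,10,20,basal",
               "1,0,0,11,21,basal"), path)
  expect_error(read_tracks(path), "duplicate.*1/0")
  writeLines(c("track_id,frame,time_h,x_um,y_um,compartment"), path)
  empty <- read_tracks(path)
  expect_equal(nrow(empty), 0)
  expect_true(all(woundsim:::.track_cols %in% names(empty)))
  writeLines(c("track_id,frame,time_h,x_um", "1,0,0,10"), path)
  expect_error(read_tracks(path), "y_um")
  writeLines(c("track_id,frame,time_h,x_um,y_um,compartment",
               "1,0,0,10,NA,basal"), path)
  expect_error(read_tracks(path), "line 2")
})

test_that("linking follows displacement within max_disp and splits beyond it", {
  one <- link_detections(list(data.frame(x = 0, y = 0),
                              data.frame(x = 1, y = 0)), max_disp = 5)
  expect_equal(length(unique(one$track_id)), 1)
  expect_equal(nrow(one), 2)
  two <- link_detections(list(data.frame(x = 0, y = 0),
                              data.frame(x = 6, y = 0)), max_disp = 5)
  expect_equal(length(unique(two$track_id)), 2)
  expect_error(link_detections(list(), 5), "empty")
  # one detection never feeds two tracks in the same frame
  set.seed(3)
  dets <- lapply(1:4, function(k) data.frame(x = runif(8) * 50,
                                             y = runif(8) * 50))
  tr <- link_detections(dets, max_disp = 20)
  expect_false(any(duplicated(paste(tr$frame, tr$x_um, tr$y_um))))
  expect_false(any(duplicated(paste(tr$track_id, tr$frame))))
})

test_that("drift estimation recovers known translations and resists outliers", {
  set.seed(4)
  base <- data.frame(x = runif(10) * 100, y = runif(10) * 100)
  mk <- function(shift_fun) {
    rows <- lapply(0:3, function(k) {
      s <- shift_fun(k)
      tibble::tibble(track_id = 1:10, frame = k, time_h = k * 0.5,
                     x_um = base$x + s[1], y_um = base$y + s[2],
                     compartment = "follicle")
    })
    dplyr::bind_rows(rows)
  }
  drift <- estimate_drift(mk(function(k) c(5 * k, -3 * k)))
  expect_equal(drift$dx_um, 5 * (0:3), tolerance = 1e-12)
  expect_equal(drift$dy_um, -3 * (0:3), tolerance = 1e-12)
  static <- mk(function(k) c(0, 0))
  expect_equal(estimate_drift(static)$dx_um, rep(0, 4))
  # 9 static references + 1 runaway: the median ignores the outlier
  out <- static
  runaway <- out$track_id == 10
  out$x_um[runaway] <- out$x_um[runaway] + 50 * out$frame[runaway]
  expect_equal(estimate_drift(out)$dx_um, rep(0, 4), tolerance = 1e-12)
  expect_error(estimate_drift(static[static$track_id < 3, ]), "found 2")
})

test_that("estimate + apply removes injected drift exactly", {
  sim <- simulate_wound(sim_config(domain_half_extent = 300,
                                   domain_height = 120, t_end = 3, seed = 14,
                                   follicles = list(list(center = c(150, 60),
                                                         radius = 35))))
  tr <- export_tracks(sim)
  drift_x <- 2.5; drift_y <- -1.5
  shifted <- tr
  shifted$x_um <- shifted$x_um + drift_x * shifted$frame
  shifted$y_um <- shifted$y_um + drift_y * shifted$frame
  est <- estimate_drift(shifted)
  corrected <- apply_drift(shifted, est)
  expect_equal(corrected$x_um, tr$x_um, tolerance = 1e-9)
  expect_equal(corrected$y_um, tr$y_um, tolerance = 1e-9)
  # zero drift is the identity; applying the negated series undoes it
  zero <- est; zero$dx_um <- 0; zero$dy_um <- 0
  expect_equal(apply_drift(tr, zero), tr)
  neg <- est; neg$dx_um <- -neg$dx_um; neg$dy_um <- -neg$dy_um
  expect_equal(apply_drift(apply_drift(tr, est), neg), tr, tolerance = 1e-12)
  expect_error(apply_drift(shifted, est[est$frame < 2, ]), "missing frame")
})
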