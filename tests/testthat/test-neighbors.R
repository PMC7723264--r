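test_that("build_graph handles simple and degenerate configurations", {
  tri <- build_graph(data.frame(x = c(0, 2, 1), y = c(0, 0, 1.5)),
                     max_edge = 10)
  expect_equal(nrow(tri$edges), 3)
  far <- build_graph(data.frame(x = c(0, 10), y = c(0, 0)), max_edge = 5)
  expect_equal(nrow(far$edges), 0)
  near2 <- build_graph(data.frame(x = c(0, 3), y = c(0, 0)), max_edge = 5)
  expect_equal(nrow(near2$edges), 1)
  # collinear points fall back to distance-cutoff adjacency
  col <- build_graph(data.frame(x = c(0, 1, 2, 3), y = rep(2, 4)),
                     max_edge = 1.5)
  expect_equal(nrow(col$edges), 3)
  expect_error(build_graph(data.frame(x = 1, y = 1)), "2 nodes")
  expect_warning(
    dup <- build_graph(data.frame(x = c(0, 0, 5), y = c(0, 0, 5)),
                       max_edge = 100),
    "duplicated")
  expect_equal(nrow(dup$nodes), 3)
})

test_that("the four-point example matches the brute-force oracle", {
  px <- c(0, 2, 1, 1); py <- c(0, 0, 1, 3)
  g <- build_graph(data.frame(x = px, y = py), max_edge = Inf)
  expect_identical(graph_edge_matrix(g), brute_delaunay_edges(px, py))
  # pruning removes the long edges
  g2 <- build_graph(data.frame(x = px, y = py), max_edge = 1.5)
  expect_true(all((g2$nodes$x[g2$edges$from] - g2$nodes$x[g2$edges$to])^2 +
                    (g2$nodes$y[g2$edges$from] - g2$nodes$y[g2$edges$to])^2
                  <= 1.5^2))
})

test_that("neighbourhoods are symmetric", {
  set.seed(8)
  g <- build_graph(data.frame(x = runif(30) * 100, y = runif(30) * 100))
  nb <- graph_neighbors(g)
  for (id in g$nodes$id) {
    for (j in nb[[as.character(id)]]) {
      expect_true(id %in% nb[[as.character(j)]])
    }
  }
})

test_that("retention drops to zero when a focal cell teleports away", {
  P <- cbind(c(0, 10, 5, 50), c(0, 0, 8, 50))
  f0 <- tibble::tibble(track_id = 1:4, frame = 0, time_h = 0,
                       x_um = P[, 1], y_um = P[, 2], compartment = "basal")
  f1 <- f0
  f1$frame <- 1; f1$time_h <- 0.5
  f1$x_um[1] <- 500; f1$y_um[1] <- 500 # cell 1 leaves everyone behind
  ser <- retention_fraction(dplyr::bind_rows(f0, f1), t0 = 0, horizon = 0.5,
                            max_edge = 15)
  expect_equal(ser$fraction[ser$track_id == 1 & ser$time_rel_h == 0.5], 0)
  expect_equal(ser$fraction[ser$time_rel_h == 0],
               rep(1, sum(ser$time_rel_h == 0)))
})

test_that("a hand-built six-cell sequence matches brute-force recomputation", {
  set.seed(9)
  base <- cbind(c(0, 12, 24, 3, 15, 27), c(0, 2, 0, 12, 14, 12))
  frames <- list(base,
                 base + matrix(rnorm(12, 0, 2), 6, 2),
                 base[c(1, 2, 3, 6, 5, 4), ]) # cells 4 and 6 swap places
  tracks <- dplyr::bind_rows(lapply(seq_along(frames), function(k) {
    tibble::tibble(track_id = 1:6, frame = k - 1, time_h = (k - 1) * 0.5,
                   x_um = frames[[k]][, 1], y_um = frames[[k]][, 2],
                   compartment = "basal")
  }))
  me <- 16
  ser <- retention_fraction(tracks, t0 = 0, horizon = 1, max_edge = me)
  # oracle: brute-force Delaunay adjacency per frame, pruned at max_edge
  adj <- lapply(frames, function(P) {
    E <- brute_delaunay_edges(P[, 1], P[, 2])
    keep <- (P[E[, 1], 1] - P[E[, 2], 1])^2 +
      (P[E[, 1], 2] - P[E[, 2], 2])^2 <= me^2
    E <- E[keep, , drop = FALSE]
    lapply(1:6, function(i) c(E[E[, 1] == i, 2], E[E[, 2] == i, 1]))
  })
  for (i in 1:6) {
    n0 <- adj[[1]][[i]]
    if (!length(n0)) next
    for (k in 1:3) {
      want <- length(intersect(n0, adj[[k]][[i]])) / length(n0)
      got <- ser$fraction[ser$track_id == i &
                            abs(ser$time_rel_h - (k - 1) * 0.5) < 1e-9]
      expect_equal(got, want)
    }
  }
})

test_that("group_retention averages and propagates SEM per group", {
  ser <- tibble::tibble(
    track_id = rep(1:2, each = 3),
    time_h = rep(c(0, 0.5, 1), 2),
    time_rel_h = rep(c(0, 0.5, 1), 2),
    fraction = c(1, 1, 1, 1, 0.5, 0))
  vals <- c("1" = 100, "2" = 120) # same group
  cur <- group_retention(ser, vals, grouping = "distance")
  near <- cur[cur$group == "<0.5 mm", ]
  expect_equal(near$mean_fraction, c(1, 0.75, 0.5))
  expect_equal(near$sem[3], sd(c(1, 0)) / sqrt(2), tolerance = 1e-12)
  expect_equal(near$n_units, rep(2L, 3))
  # empty groups are reported with n_units = 0
  expect_true(all(cur$n_units[cur$group == ">1 mm"] == 0))
  # identical series give zero SEM
  ser2 <- ser; ser2$fraction <- rep(c(1, 0.8, 0.6), 2)
  cur2 <- group_retention(ser2, vals, grouping = "distance")
  expect_equal(cur2$sem[cur2$group == "<0.5 mm"], rep(0, 3))
  # a single unit reports SEM 0
  cur3 <- group_retention(ser[ser$track_id == 1, ], vals, "distance")
  expect_equal(cur3$sem[cur3$group == "<0.5 mm"], rep(0, 3))
})

test_that("position-level aggregation changes the SEM unit", {
  ser <- tibble::tibble(
    track_id = rep(1:4, each = 2),
    time_h = rep(c(0, 0.5), 4),
    time_rel_h = rep(c(0, 0.5), 4),
    fraction = c(1, 1, 1, 0.5, 1, 0.8, 1, 0.3))
  vals <- setNames(rep(100, 4), 1:4)
  pos <- tibble::tibble(track_id = 1:4, position = c("a", "a", "b", "b"))
  cur <- group_retention(ser, vals, grouping = "distance", positions = pos)
  at_half <- cur[cur$group == "<0.5 mm" & cur$time_rel_h == 0.5, ]
  expect_equal(at_half$n_units, 2L)
  expect_equal(at_half$mean_fraction, mean(c(mean(c(1, 0.5)),
                                             mean(c(0.8, 0.3)))))
})
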