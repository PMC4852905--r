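test_that("state-space grid construction and areas follow from side length", {
  sp <- build_state_space(c(0, 10, 0, 10), side = 0.65)
  expect_equal(sp$nx, 16)
  expect_equal(sp$ny, 16)
  expect_equal(length(sp$x), 256)
  expect_equal(total_area(sp), 256 * 0.65^2)
  expect_equal(suitable_area(sp), total_area(sp))
  # centroids unique and on a regular lattice
  expect_equal(anyDuplicated(paste(sp$x, sp$y)), 0)
  expect_equal(sort(unique(sp$x)), 0.65 * (seq_len(16) - 0.5))
})

test_that("degenerate state spaces are rejected", {
  expect_error(build_state_space(c(0, 0, 0, 1), 0.5), "empty extent")
  expect_error(build_state_space(c(0, 1, 0, 1), -1), "side")
  expect_error(build_state_space(c(0, 1, 0, 1), 1, mask = c(FALSE)),
               "unsuitable")
})

test_that("masking partitions total area into suitable and unsuitable", {
  G <- 20 * 20
  mask <- rep(c(TRUE, FALSE), length.out = G)
  sp <- build_state_space(c(0, 20, 0, 20), side = 1, mask = mask)
  expect_equal(suitable_area(sp), G / 2)
  expect_equal(total_area(sp) - suitable_area(sp), G / 2)
  expect_equal(100 * (total_area(sp) - suitable_area(sp)) / total_area(sp), 50)
})

test_that("a state space round-trips through its serialized ASCII grid", {
  set.seed(4)
  mask <- runif(12 * 9) > 0.4
  sp <- build_state_space(c(0, 7.8, 0, 5.85), side = 0.65, mask = mask)
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(state_space_grid(sp, as.numeric(sp$suitable)), f, digits = 1)
  sp2 <- state_space_from_grid(read_ascii_grid(f))
  expect_equal(sp2$x, sp$x)
  expect_equal(sp2$y, sp$y)
  expect_identical(sp2$suitable, sp$suitable)
  expect_equal(sp2$side, sp$side)
})

test_that("ASCII grids round-trip values including NODATA", {
  g <- structure(list(ncols = 3L, nrows = 2L, xllcorner = 1, yllcorner = 2,
                      cellsize = 0.5, nodata = -9999,
                      values = matrix(c(1, NA, 3, 0.25, 5, 6), 2, 3,
                                      byrow = TRUE)),
                 class = "ascii_grid")
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  g2 <- read_ascii_grid(f)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cellsize, 0.5)
  # nearest-cell lookup: centre of top-left cell is (1.25, 2.75)
  expect_equal(scrsearch:::grid_value_at(g2, 1.25, 2.75), 1)
  expect_true(is.na(scrsearch:::grid_value_at(g2, 0, 0)))
})

test_that("distance matrix matches geometry and a brute-force loop", {
  sp <- build_state_space(c(0, 5, 0, 5), side = 1)
  tr <- build_trap_grid(c(0, 5, 0, 5), side = 1)
  D <- distance_matrix(sp, tr)
  expect_true(all(D >= 0))
  expect_equal(diag(D), rep(0, 25))  # identical grids: coincident centroids
  # 3-4-5 triangle: centroids 3 apart in x and 4 in y
  i <- which(sp$x == 0.5 & sp$y == 0.5)
  j <- which(tr$x == 3.5 & tr$y == 4.5)
  expect_equal(D[i, j], 5)
  # brute-force double loop oracle
  set.seed(1)
  ii <- sample(25, 5); jj <- sample(25, 5)
  for (a in ii) for (b in jj)
    expect_equal(D[a, b],
                 sqrt((sp$x[a] - tr$x[b])^2 + (sp$y[a] - tr$y[b])^2),
                 tolerance = 1e-12)
})

test_that("mismatched pixel geometries still give centroid distances only", {
  # two different resolutions, as used in practice (fine state space,
  # coarser traps): distances are centroid-to-centroid
  sp <- build_state_space(c(0, 2, 0, 2), side = 0.5)
  tr <- build_trap_grid(c(0, 2, 0, 2), side = 1)
  D <- distance_matrix(sp, tr)
  expect_equal(dim(D), c(16L, 4L))
  expect_equal(min(D), sqrt(2 * 0.25^2))
})

make_track <- function(id, date, xy, spacing_s = 10) {
  data.frame(searcher_id = id,
             timestamp = as.POSIXct(paste(date, "08:00:00"), tz = "UTC") +
               spacing_s * (seq_len(nrow(xy)) - 1),
             x_km = xy[, 1], y_km = xy[, 2])
}

test_that("a straight track inside one pixel assigns its full length there", {
  tr <- build_trap_grid(c(0, 3, 0, 3), side = 1)
  tk <- make_track("V1", "2014-08-02", cbind(c(0.1, 1.0, 2.1), c(0.5, 0.5, 0.5)))
  eff <- rasterize_effort(tk, tr,
                          seq(as.Date("2014-08-01"), by = "day", length.out = 3))
  expect_equal(sum(eff$effort), 2.0)
  # segment 1 midpoint (0.55, .5) -> pixel col 1; segment 2 midpoint (1.55,.5) col 2
  k <- 2  # occasion of 2014-08-02
  j1 <- scrsearch:::trap_index(tr, 0.55, 0.5); j2 <- scrsearch:::trap_index(tr, 1.55, 0.5)
  expect_equal(eff$effort[j1, k], 0.9)
  expect_equal(eff$effort[j2, k], 1.1)
  expect_equal(sum(eff$effort > 0), 2)
})

test_that("no tracks gives an all-zero, all-inactive effort grid", {
  tr <- build_trap_grid(c(0, 3, 0, 3), side = 1)
  tk <- make_track("V1", "2014-08-01", cbind(0.5, 0.5))[0, ]
  eff <- rasterize_effort(tk, tr, as.Date("2014-08-01") + 0:2)
  expect_equal(sum(eff$effort), 0)
  expect_false(any(eff$effort > 0))
})

test_that("segment midpoint assignment matches a hand computation", {
  tr <- build_trap_grid(c(0, 2, 0, 1), side = 1)
  # fixes at x = 0.2, 0.9, 1.8 on y = 0.5: segment A len 0.7 mid 0.55 (pix 1),
  # segment B len 0.9 mid 1.35 (pix 2)
  tk <- make_track("V1", "2014-08-01", cbind(c(0.2, 0.9, 1.8), c(0.5, 0.5, 0.5)))
  eff <- rasterize_effort(tk, tr)
  expect_equal(eff$effort[scrsearch:::trap_index(tr, 0.55, 0.5), 1], 0.7)
  expect_equal(eff$effort[scrsearch:::trap_index(tr, 1.35, 0.5), 1], 0.9)
})

test_that("effort is conserved for random multi-day multi-searcher tracks", {
  set.seed(42)
  tr <- build_trap_grid(c(0, 10, 0, 10), side = 1)
  tks <- list()
  for (v in 1:3) for (d in 1:4) {
    xy <- cbind(cumsum(c(runif(1, 0, 10), rnorm(60, 0, 0.2))),
                cumsum(c(runif(1, 0, 10), rnorm(60, 0, 0.2))))
    xy <- pmin(pmax(xy, 0.01), 9.99)
    tks[[length(tks) + 1]] <-
      make_track(paste0("V", v), as.Date("2014-08-01") + d - 1, xy)
  }
  tk <- do.call(rbind, tks)
  eff <- rasterize_effort(tk, tr)
  total <- sum(sapply(split(tk, tk$searcher_id), function(g) {
    g <- g[order(g$timestamp), ]
    len <- sqrt(diff(g$x_km)^2 + diff(g$y_km)^2)
    sum(len[diff(as.numeric(g$timestamp)) <= 3600])  # within-session only
  }))
  expect_equal(sum(eff$effort), total, tolerance = 1e-9)
})

test_that("tracks crossing midnight are split at the day boundary", {
  tr <- build_trap_grid(c(0, 4, 0, 1), side = 1)
  tk <- data.frame(
    searcher_id = "V1",
    timestamp = as.POSIXct(c("2014-08-01 23:30:00", "2014-08-02 00:30:00"),
                           tz = "UTC"),
    x_km = c(0.5, 2.5), y_km = c(0.5, 0.5))
  eff <- rasterize_effort(tk, tr, as.Date("2014-08-01") + 0:1)
  # half the 2 km segment before midnight (midpoint x = 1.0 -> pixel 1 edge),
  # half after (midpoint x = 2.0)
  expect_equal(sum(eff$effort[, 1]), 1)
  expect_equal(sum(eff$effort[, 2]), 1)
  expect_equal(sum(eff$effort), 2)
})

test_that("fixes outside the grid are dropped with a warning", {
  tr <- build_trap_grid(c(0, 2, 0, 2), side = 1)
  tk <- make_track("V1", "2014-08-01",
                   cbind(c(0.5, 1.5, 5.0, 1.5), c(0.5, 0.5, 0.5, 1.5)))
  expect_warning(eff <- rasterize_effort(tk, tr), "dropped")
  # remaining fixes: (0.5,.5) (1.5,.5) (1.5,1.5): lengths 1 and 1
  expect_equal(sum(eff$effort), 2)
})

test_that("unordered timestamps are an error", {
  tk <- make_track("V1", "2014-08-01", cbind(c(0.5, 1.5), c(0.5, 0.5)))
  tk$timestamp <- rev(tk$timestamp)
  expect_error(rasterize_effort(tk, build_trap_grid(c(0, 2, 0, 2))),
               "strictly increasing")
})

test_that("effort grids round-trip through long-format CSV", {
  set.seed(7)
  tr <- build_trap_grid(c(0, 5, 0, 5), side = 1)
  eff <- toy_effort(tr, matrix(rbinom(25 * 4, 1, 0.3) * runif(100, 0.1, 3),
                               25, 4))
  f <- tempfile(fileext = ".csv")
  write_effort(eff, f)
  eff2 <- read_effort(f, tr, eff$occasions)
  expect_equal(eff2$effort, eff$effort)
  expect_equal(eff2$occasions, eff$occasions)
})
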