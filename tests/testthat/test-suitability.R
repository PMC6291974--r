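# suitability: catchment masks, weighted KDE + bandwidth selection,
# reclassification, overlay, candidate extraction.

test_that("uncovered-catchment mask matches a per-cell distance oracle", {
  g <- make_grid(10, 10, 100)  # 1 km x 1 km
  expect_true(all(buffer_uncovered_mask(NULL, 300, g)$values == 1))
  expect_true(all(buffer_uncovered_mask(data.frame(x = numeric(), y = numeric()),
                                        300, g)$values == 1))

  center_fac <- data.frame(x = 450, y = 450)  # a cell center
  expect_true(all(buffer_uncovered_mask(center_fac, 2000, g)$values == 0))

  m <- buffer_uncovered_mask(center_fac, 300, g)
  cc <- cell_centers(g)
  for (r in seq_len(g$n_rows)) {
    for (c in seq_len(g$n_cols)) {
      d <- sqrt((cc$x[c] - 450)^2 + (cc$y[r] - 450)^2)
      expect_identical(unname(m$values[r, c]), as.numeric(d > 300))
    }
  }
  expect_true(all(m$values %in% c(0, 1)))
})

test_that("KDE matches the double-loop oracle and conserves total weight", {
  set.seed(21)
  g <- make_grid(20, 20, 10)
  pts <- data.frame(x = runif(20, 40, 160), y = runif(20, 40, 160),
                    w = runif(20, 0.5, 20))
  dens <- kde_density(pts, 100, g)
  oracle <- oracle_kde(pts, 100, g)
  expect_lt(max(abs(dens$values - oracle) / pmax(oracle, 1e-300)), 1e-10)

  # single point: integral over a grid padded >= 6h recovers the weight
  h <- 50
  pad <- make_grid(140, 140, 5, origin = c(-350, -350))  # 700 m box around origin
  d1 <- kde_density(data.frame(x = 0, y = 0, w = 7), h, pad)
  expect_lt(abs(sum(d1$values) * 25 - 7) / 7, 0.01)

  # mirror-symmetric points give a mirror-symmetric surface
  sym <- kde_density(data.frame(x = c(50, 150), y = c(100, 100), w = c(3, 3)), 40, g)
  expect_equal(sym$values, sym$values[, rev(seq_len(g$n_cols))], tolerance = 1e-12)

  expect_error(kde_density(pts[0, ], 100, g), "degenerate|weight")
  expect_error(kde_density(transform(pts, w = 0), 100, g), "degenerate")
  expect_error(kde_density(pts, "auto", g), "bandwidth")
})

test_that("LSCV bandwidth selection behaves sanely and tracks the analytic optimum", {
  set.seed(31)
  scatter <- data.frame(x = runif(40, 0, 2000), y = runif(40, 0, 2000), w = 1)
  cluster <- data.frame(x = rnorm(40, 500, 30), y = rnorm(40, 500, 30), w = 1)
  hg <- exp(seq(log(10), log(500), length.out = 12))
  expect_lt(select_bandwidth(cluster, hg), select_bandwidth(scatter, hg))

  expect_equal(select_bandwidth(scatter, 123), 123)
  expect_error(select_bandwidth(scatter[1:3, ], hg), "at least 5")
  expect_error(select_bandwidth(scatter, -1), "positive")

  # 200 draws from an isotropic Gaussian: AMISE-optimal h* = sigma * n^(-1/6)
  set.seed(99)
  sigma <- 300; n <- 200
  pts <- data.frame(x = rnorm(n, 0, sigma), y = rnorm(n, 0, sigma), w = 1)
  hstar <- sigma * n^(-1 / 6)
  hg <- exp(seq(log(20), log(1200), length.out = 25))
  hsel <- select_bandwidth(pts, hg)
  expect_gt(hsel, hstar / 2)
  expect_lt(hsel, hstar * 2)
})

test_that("equal-interval reclassification hits the stated classes", {
  v <- matrix(0:9, nrow = 1)  # ten cells, values 0..9
  g <- raster_grid(c(0, 0), 10, values = v)
  cls <- reclassify_density(g, 10)
  expect_equal(as.numeric(cls$values), 1:10)

  set.seed(41)
  rnd <- raster_grid(c(0, 0), 10, values = matrix(rexp(400), 20, 20))
  cls <- reclassify_density(rnd, 10)
  rng <- range(rnd$values)
  oracle <- pmin(1 + floor(10 * (rnd$values - rng[1]) / diff(rng)), 10)
  expect_equal(cls$values, oracle)
  expect_equal(min(cls$values[rnd$values == rng[1]]), 1)
  expect_equal(max(cls$values[rnd$values == rng[2]]), 10)

  flat <- raster_grid(c(0, 0), 10, values = matrix(3.3, 4, 4))
  expect_true(all(reclassify_density(flat, 10)$values == 1))
})

test_that("overlay is the cellwise product and respects the screens", {
  set.seed(51)
  g <- make_grid(8, 8, 10)
  mk <- function(v) raster_grid(c(0, 0), 10, values = matrix(v, 8, 8))
  land <- mk(rbinom(64, 1, 0.6)); cm <- mk(rbinom(64, 1, 0.7))
  km <- mk(rbinom(64, 1, 0.7)); dc <- mk(sample(1:10, 64, TRUE))
  s <- overlay_suitability(land, cm, km, dc)
  expect_equal(s$values, land$values * cm$values * km$values * dc$values)
  expect_true(all(s$values[land$values == 0] == 0))  # used ground can never host a site

  ones <- mk(1); seven <- mk(7)
  expect_true(all(overlay_suitability(ones, ones, ones, seven)$values == 7))

  misaligned <- make_grid(8, 8, 10, origin = c(5, 0))
  expect_error(overlay_suitability(land, cm, km,
                                   raster_grid(c(5, 0), 10, values = dc$values)),
               "alignment")

  # monotone in density class when the binaries are fixed
  dc2 <- mk(pmin(dc$values + 1, 10))
  s2 <- overlay_suitability(land, cm, km, dc2)
  expect_true(all(s2$values >= s$values))
})

test_that("candidate extraction filters the lattice by strict suitability", {
  g <- make_grid(10, 10, 10)  # 100 m x 100 m
  uniform10 <- raster_grid(c(0, 0), 10, values = matrix(10, 10, 10))
  cands <- extract_candidates(uniform10, spacing = 25, threshold = 4)
  expect_equal(nrow(cands), 25)  # 5 x 5 inclusive lattice
  expect_setequal(unique(cands$x), c(0, 25, 50, 75, 100))

  uniform4 <- raster_grid(c(0, 0), 10, values = matrix(4, 10, 10))
  expect_equal(nrow(extract_candidates(uniform4, 25, 4)), 0)  # strictly greater only

  set.seed(61)
  rnd <- raster_grid(c(0, 0), 10, values = matrix(sample(0:10, 100, TRUE), 10, 10))
  cands <- extract_candidates(rnd, 25, 4)
  # brute-force lattice filter
  expected <- 0
  for (y in c(0, 25, 50, 75, 100)) {
    for (x in c(0, 25, 50, 75, 100)) {
      idx <- cell_of_point(rnd, x, y)
      if (rnd$values[idx$row, idx$col] > 4) expected <- expected + 1
    }
  }
  expect_equal(nrow(cands), expected)
  expect_true(all(cands$suitability > 4))
  expect_false(any(duplicated(cands[c("x", "y")])))
  expect_warning(extract_candidates(rnd, 4, 4), "spacing")
})

test_that("the candidate set does not depend on facility input order", {
  set.seed(71)
  g <- make_grid(30, 30, 10)
  fac <- data.frame(x = runif(4, 0, 300), y = runif(4, 0, 300))
  m1 <- buffer_uncovered_mask(fac, 120, g)
  m2 <- buffer_uncovered_mask(fac[sample(4), ], 120, g)
  expect_identical(m1$values, m2$values)
})
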