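test_that("distance to nearest feature is Euclidean, in km, and NA when empty", {
  sites <- tibble::tibble(site_id = "s", x = 0, y = 0)
  # vertical line x = 3000 m
  vline <- tibble::tibble(road_id = "r", class = "major",
                          x0 = 3000, y0 = -1e5, x1 = 3000, y1 = 1e5)
  expect_equal(extract_distance_to_nearest(sites, vline), 3)
  # site lying on a road
  on_road <- tibble::tibble(road_id = "r", class = "major",
                            x0 = -10, y0 = 0, x1 = 10, y1 = 0)
  expect_equal(extract_distance_to_nearest(sites, on_road), 0)
  # nearest of two points
  pts <- tibble::tibble(id = c("a", "b"), x = c(1000, 5000), y = c(0, 0))
  expect_equal(extract_distance_to_nearest(sites, pts), 1)
  expect_warning(
    na_out <- extract_distance_to_nearest(sites, pts[0, ]), "empty")
  expect_true(is.na(na_out))
})

test_that("buffer averages match the exhaustive membership oracle", {
  sites <- tibble::tibble(site_id = "s", x = 5.2, y = 4.7)
  r <- lur_raster(matrix(1:100, 10, 10), 0, 0, 1)
  for (radius in c(0.8, 2.5, 4)) {
    got <- buffer_mean_for_test(r, 5.2, 4.7, radius)
    expect_equal(got, oracle_buffer_average(r, 5.2, 4.7, radius),
                 tolerance = 1e-12)
  }
  # constant raster: any radius gives the constant
  rc <- lur_raster(matrix(3, 20, 20), 0, 0, 500)
  sites2 <- tibble::tibble(site_id = "s", x = 5000, y = 5000)
  expect_equal(extract_buffer_average(sites2, rc, 1800), 3)
  # radius smaller than half a cell: containing cell's value
  r2 <- lur_raster(matrix(1:9, 3, 3), 0, 0, 1000)
  sites3 <- tibble::tibble(site_id = "s", x = 1500, y = 1500)
  expect_equal(extract_buffer_average(sites3, r2, 100), 5)
})

test_that("buffer average equals the oracle on random rasters (property)", {
  set.seed(31)
  for (case in 1:25) {
    nx <- sample(5:50, 1); ny <- sample(5:50, 1)
    cell <- sample(c(50, 100, 250), 1)
    vals <- matrix(rnorm(nx * ny), ny, nx)
    if (runif(1) < 0.3) vals[sample(length(vals), 5)] <- NA
    r <- lur_raster(vals, runif(1, -1e4, 1e4), runif(1, -1e4, 1e4), cell)
    ext <- raster_extent(r)
    px <- runif(1, ext[["xmin"]], ext[["xmax"]])
    py <- runif(1, ext[["ymin"]], ext[["ymax"]])
    radius <- runif(1, 0.3 * cell, 6 * cell)
    got <- buffer_mean_for_test(r, px, py, radius)
    want <- oracle_buffer_average(r, px, py, radius)
    if (is.na(want)) {
      # no centre in the disc: implementation falls back to point value
      expect_equal(got, raster_value_at(r, px, py))
    } else {
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("clipped road length matches chord geometry and the root-finding oracle", {
  sites <- tibble::tibble(site_id = "s", x = 0, y = 0)
  # long straight road through the site, radius 5000 -> full 10 km chord
  through <- tibble::tibble(road_id = "r", class = "major",
                            x0 = -1e6, y0 = 0, x1 = 1e6, y1 = 0)
  expect_equal(extract_buffer_sum_length(sites, through, 5000), 10,
               tolerance = 1e-9)
  # segment entirely inside the disc contributes its own length
  inside <- tibble::tibble(road_id = "r", class = "major",
                           x0 = -1000, y0 = 500, x1 = 1000, y1 = 500)
  expect_equal(extract_buffer_sum_length(sites, inside, 5000), 2,
               tolerance = 1e-12)
  expect_equal(extract_buffer_sum_length(sites, inside[0, ], 5000), 0)

  set.seed(32)
  for (case in 1:25) {
    seg <- tibble::tibble(road_id = "r", class = "major",
                          x0 = runif(1, -5e3, 5e3), y0 = runif(1, -5e3, 5e3),
                          x1 = runif(1, -5e3, 5e3), y1 = runif(1, -5e3, 5e3))
    radius <- runif(1, 200, 4000)
    got <- extract_buffer_sum_length(sites, seg, radius) * 1000
    want <- oracle_segment_disc_length(0, 0, seg$x0, seg$y0, seg$x1, seg$y1,
                                       radius)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("buffer sums are monotone and nested in radius", {
  cfg <- world_config(seed = 33)
  roads <- generate_roads(cfg)
  sites <- generate_sites(cfg, 10)
  radii <- c(500, 1000, 2000, 5000, 10000)
  lens <- vapply(radii, function(r) {
    extract_buffer_sum_length(sites, roads, r)
  }, numeric(10))
  expect_true(all(diff(t(lens)) >= 0))
  f <- generate_field(cfg, "vegetation")
  # nesting: every cell counted at r is counted at r' > r
  counts <- vapply(radii, function(r) {
    length(no2lur:::which_cells_in_disc(f, sites$x[1], sites$y[1], r))
  }, 0L)
  sets <- lapply(radii, function(r) {
    no2lur:::which_cells_in_disc(f, sites$x[1], sites$y[1], r)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  expect_true(all(diff(counts) >= 0))
})

test_that("screening drops missing-, zero-, and constant-heavy columns with reasons", {
  n <- 100
  m <- tibble::tibble(
    site_id = sprintf("S%03d", 1:n),
    good = rnorm(n),
    all_const = rep(5, n),
    mostly_zero = c(rep(0, 80), rnorm(20)),
    mostly_na = c(rnorm(20), rep(NA, 80)),
    boundary_const = c(rep(1, 75), rnorm(25))  # exactly 75%: kept (> rule)
  )
  s <- screen_predictors(m)
  log <- screen_log(s)
  expect_setequal(names(s), c("site_id", "good", "boundary_const"))
  expect_equal(log$rule[log$column == "all_const"], "repeating")
  expect_equal(log$rule[log$column == "mostly_zero"], "zero")
  expect_equal(log$rule[log$column == "mostly_na"], "missing")
})

test_that("a 270-candidate screening scenario retains 182", {
  # replicate the canonical screening tally: 270 candidates of which 88
  # violate the missing/repeating/zero rules
  set.seed(34)
  n <- 109
  m <- tibble::tibble(site_id = sprintf("S%03d", 1:n))
  for (i in 1:182) m[[sprintf("ok%03d", i)]] <- rnorm(n)
  for (i in 1:30) m[[sprintf("na%02d", i)]] <- c(rnorm(10), rep(NA, n - 10))
  for (i in 1:30) m[[sprintf("zr%02d", i)]] <- c(rnorm(15), rep(0, n - 15))
  for (i in 1:28) m[[sprintf("ct%02d", i)]] <- c(rep(i, 95), rnorm(14))
  s <- screen_predictors(m)
  expect_equal(ncol(s) - 1, 182)
  expect_equal(nrow(screen_log(s)), 88)
})

test_that("standardization is exact, persistent, and invertible", {
  m <- tibble::tibble(site_id = c("a", "b", "c"), v = c(1, 2, 3))
  z <- standardize_predictors(m)
  expect_equal(z$v, c(-1, 0, 1))
  stats <- standardization_stats(z)
  expect_equal(stats$mean, 2)
  expect_equal(stats$sd, 1)
  # round trip raw -> z -> raw
  back <- z$v * stats$sd + stats$mean
  expect_equal(back, m$v, tolerance = 1e-12)
  # applying persisted stats to the training matrix reproduces z
  expect_equal(apply_standardization(m, stats)$v, z$v, tolerance = 1e-12)
  # already-standard column passes through unchanged
  set.seed(35)
  v <- as.vector(scale(rnorm(50)))
  zs <- standardize_predictors(tibble::tibble(site_id = as.character(1:50),
                                              v = v))
  expect_equal(zs$v, v, tolerance = 1e-12)
  # zero-variance input is an error, not silent nonsense
  expect_error(standardize_predictors(
    tibble::tibble(site_id = c("a", "b"), v = c(1, 1))), "zero-variance")
})

test_that("standardized matrices have mean 0 and sample sd 1 per column", {
  cfg <- world_config(seed = 36)
  w <- generate_world(cfg)
  for (cn in setdiff(names(w$z), "site_id")) {
    expect_lt(abs(mean(w$z[[cn]])), 1e-9)
    expect_equal(sd(w$z[[cn]]), 1, tolerance = 1e-9)
  }
})
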