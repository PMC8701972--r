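toy_model <- function() {
  lur_model(
    27.4,
    tibble::tibble(column = "satellite", beta = 6),
    stats = tibble::tibble(column = "satellite", mean = 8, sd = 2))
}

toy_specs <- predictor_spec("satellite", kind = "point_value",
                            expected_sign = "+")

test_that("grid prediction matches a by-hand oracle on a 3x3 world", {
  sat <- lur_raster(matrix(c(6, 8, 10, 8, 8, 8, 4, 8, 12), 3, 3,
                           byrow = TRUE),
                    0, 0, 100)
  ext <- c(xmin = 0, xmax = 300, ymin = 0, ymax = 300)
  g <- predict_grid(toy_model(), list(satellite = sat), toy_specs, ext,
                    cell_size = 100)
  # by hand: pred = 27.4 + 6 * (value - 8) / 2
  want <- 27.4 + 6 * (sat$values - 8) / 2
  expect_equal(g$values, want, tolerance = 1e-12)
  # a cell at the training mean predicts exactly the intercept
  expect_equal(g$values[2, 2], 27.4)
})

test_that("standardized and raw-scale forms of the prediction agree", {
  set.seed(81)
  sat <- lur_raster(matrix(runif(100, 2, 14), 10, 10), 0, 0, 50)
  ext <- raster_extent(sat)
  m <- toy_model()
  g <- predict_grid(m, list(satellite = sat), toy_specs, ext, 50)
  # raw-scale affine identity: beta/sd slope, intercept - beta*mean/sd
  slope <- 6 / 2
  icept <- 27.4 - 6 * 8 / 2
  expect_equal(g$values, icept + slope * sat$values, tolerance = 1e-9)
})

test_that("missing layers fail before computation; missing cells become no-data", {
  expect_error(predict_grid(toy_model(), list(), toy_specs,
                            c(xmin = 0, xmax = 100, ymin = 0, ymax = 100)),
               "missing layer")
  sat <- lur_raster(matrix(c(NA, 8, 8, 8), 2, 2), 0, 0, 100)
  g <- predict_grid(toy_model(), list(satellite = sat), toy_specs,
                    raster_extent(sat), 100)
  expect_true(is.na(g$values[1, 1]))
  expect_equal(sum(is.na(g$values)), 1)
})

test_that("population weighting follows sum(p c)/sum(p) and degenerates correctly", {
  conc <- lur_raster(matrix(c(10, 20), 1, 2), 0, 0, 100)
  polys <- tibble::tibble(polygon_id = "P1",
                          x = c(0, 200, 200, 0, 0),
                          y = c(0, 0, 100, 100, 0))
  # two cells c = {10, 20}, p = {1, 3} -> 17.5
  pop <- lur_raster(matrix(c(1, 3), 1, 2), 0, 0, 100)
  agg <- pop_weighted_aggregate(conc, pop, polys)
  expect_equal(agg$weighted_mean_ppb, 17.5)
  expect_equal(agg$mean_ppb, 15)
  # uniform population: weighted = unweighted
  popu <- lur_raster(matrix(c(2, 2), 1, 2), 0, 0, 100)
  aggu <- pop_weighted_aggregate(conc, popu, polys)
  expect_equal(aggu$weighted_mean_ppb, aggu$mean_ppb)
  # zero population: weighted undefined, flagged, unweighted reported
  pop0 <- lur_raster(matrix(c(0, 0), 1, 2), 0, 0, 100)
  agg0 <- pop_weighted_aggregate(conc, pop0, polys)
  expect_true(is.na(agg0$weighted_mean_ppb))
  expect_true(agg0$zero_population)
  expect_equal(agg0$mean_ppb, 15)
})

test_that("cells on a shared boundary go to exactly one polygon, in stable order", {
  # 2-cell grid whose cell centres sit exactly on the shared edge x = 100
  conc <- lur_raster(matrix(c(5, 7), 1, 2), 50, 0, 100)
  expect_equal(tibble::as_tibble(conc)$x, c(100, 200))
  polys <- dplyr::bind_rows(
    tibble::tibble(polygon_id = "A", x = c(0, 100, 100, 0, 0),
                   y = c(-50, -50, 150, 150, -50)),
    tibble::tibble(polygon_id = "B", x = c(100, 300, 300, 100, 100),
                   y = c(-50, -50, 150, 150, -50)))
  cells <- tibble::as_tibble(conc)
  got <- assign_polygons(cells, polys)
  # centre (100, 50) lies on the A/B edge: first polygon in stable order
  expect_equal(got, c("A", "B"))
  expect_false(anyNA(got))
})

test_that("interior point-in-polygon agrees with mgcv::in.out", {
  set.seed(82)
  ring <- tibble::tibble(polygon_id = "P",
                         x = c(0, 80, 100, 40, 0),
                         y = c(0, -20, 90, 70, 0))
  pts <- tibble::tibble(x = runif(200, -30, 130), y = runif(200, -40, 110))
  ours <- !is.na(assign_polygons(pts, ring))
  bnd <- as.matrix(ring[, c("x", "y")])
  ref <- mgcv::in.out(bnd, as.matrix(pts))
  # ignore points within numerical reach of the boundary
  d_edge <- vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(seq_len(4), function(j) {
      no2lur:::point_segment_distance(pts$x[i], pts$y[i], ring$x[j],
                                      ring$y[j], ring$x[j + 1],
                                      ring$y[j + 1])
    }, 0))
  }, 0)
  interior <- d_edge > 1e-6
  expect_equal(ours[interior], ref[interior])
})

test_that("aggregation conserves population-weighted totals over a partition", {
  set.seed(83)
  conc <- lur_raster(matrix(runif(64, 5, 40), 8, 8), 0, 0, 100)
  pop <- lur_raster(matrix(rexp(64, 1 / 50), 8, 8), 0, 0, 100)
  polys <- generate_townships(raster_extent(conc), 2, 2)
  agg <- pop_weighted_aggregate(conc, pop, polys)
  lhs <- sum(agg$weighted_mean_ppb * agg$population)
  rhs <- sum(pop$values * conc$values)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(sum(agg$n_cells), 64)
  pct <- aggregate_percentiles(agg)
  expect_equal(pct$percentile, c(5, 25, 50, 75, 95))
})

test_that("historical prediction freezes coefficients and scales linearly", {
  set.seed(84)
  sat19 <- lur_raster(matrix(runif(36, 4, 14), 6, 6), 0, 0, 100)
  ext <- raster_extent(sat19)
  base <- list(satellite = sat19)
  m <- toy_model()
  # identical layers for all years -> identical grids
  hp <- historical_predict(m, base,
                           list(`2017` = base, `2018` = base),
                           2017:2019, toy_specs, ext, 100)
  expect_equal(hp[["2017"]]$values, hp[["2018"]]$values)
  expect_equal(attr(hp, "skipped_years"), 2019L)
  # scaling the satellite layer by 0.9 shifts predictions by beta/sd * dx
  sat_scaled <- sat19; sat_scaled$values <- 0.9 * sat19$values
  hp2 <- historical_predict(m, base,
                            list(`2014` = list(satellite = sat_scaled)),
                            2014, toy_specs, ext, 100)
  shift <- (6 / 2) * (0.9 * sat19$values - sat19$values)
  expect_equal(hp2[["2014"]]$values - hp[["2017"]]$values, shift,
               tolerance = 1e-9)
})

test_that("a drifting satellite field produces monotone population-weighted means", {
  set.seed(85)
  sat <- lur_raster(matrix(runif(36, 6, 12), 6, 6), 0, 0, 100)
  ext <- raster_extent(sat)
  pop <- lur_raster(matrix(rexp(36, 1 / 40), 6, 6), 0, 0, 100)
  polys <- generate_townships(ext, 2, 2)
  years <- 2015:2018
  by_year <- setNames(lapply(seq_along(years), function(i) {
    s <- sat; s$values <- sat$values * (0.85 + 0.05 * i)
    list(satellite = s)
  }), as.character(years))
  hp <- historical_predict(toy_model(), list(satellite = sat), by_year,
                           years, toy_specs, ext, 100)
  pw <- vapply(hp, function(g) {
    mean(pop_weighted_aggregate(g, pop, polys)$weighted_mean_ppb)
  }, 0)
  expect_true(all(diff(pw) > 0))
})
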