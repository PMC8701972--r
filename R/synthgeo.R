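#' Configure a synthetic study world
#'
#' Assembles the full recipe for a seeded synthetic study region: spatially
#' autocorrelated predictor fields, a road network, point sources, a monitor
#' network, a generative ("truth") annual-NO2 model, and the missingness
#' process applied to hourly series. Every generator in the package is
#' deterministic given `seed`.
#'
#' The defaults emulate a sparsely populated ~120 km study region monitored
#' by 105 sites whose annual NO2 has mean ~27.6 ppb and SD ~10 ppb, driven
#' by a satellite NO2 column, major-road density within 5 km, vegetation
#' within 1.8 km, and impervious surface within 7 km, with Gaussian noise
#' calibrated so the generating model explains ~63% of the spatial variance.
#'
#' @param seed Integer seed (< 2^31) controlling all randomness.
#' @param extent Named numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size Predictor-raster cell size in metres.
#' @param fine_cell_size Cell size for prediction/population grids (metres).
#' @param field_specs Tibble of raster-field recipes: `name`, `mean`, `sd`,
#'   `correlation_length_m`, `expected_sign` (`"+"`/`"-"`).
#' @param road_spec List: `n_major`, `n_minor`, `mean_segment_length_m`.
#' @param n_power_stations Number of point sources.
#' @param n_sites Number of monitoring sites.
#' @param site_margin_m Inset of sites from the extent edge so buffers stay
#'   inside the rasters.
#' @param truth A [truth_model()].
#' @param missingness List: `block_prob` (per-day probability that a
#'   multi-day outage starts), `block_length_days` (mean outage length),
#'   `hourly_drop_prob` (independent per-hour loss).
#' @param year Calendar year the hourly series covers.
#' @param seasonal_amplitude Relative amplitude of the winter-peaking
#'   seasonal cycle in the hourly series.
#' @param diurnal_amplitude Relative amplitude of the 12-h (rush-hour)
#'   diurnal cycle.
#' @param hourly_noise_frac SD of hourly measurement noise as a fraction of
#'   the site's annual mean.
#' @return A `lur_world_config` list.
#' @export
world_config <- function(seed = 1L,
                         extent = c(xmin = 0, xmax = 120000,
                                    ymin = 0, ymax = 120000),
                         cell_size = 1000,
                         fine_cell_size = 100,
                         field_specs = default_field_specs(),
                         road_spec = list(n_major = 60, n_minor = 150,
                                          mean_segment_length_m = 15000),
                         n_power_stations = 8L,
                         n_sites = 105L,
                         site_margin_m = 10000,
                         truth = default_truth_model(),
                         missingness = list(block_prob = 0.004,
                                            block_length_days = 10,
                                            hourly_drop_prob = 0.02),
                         year = 2019L,
                         seasonal_amplitude = 0.4,
                         diurnal_amplitude = 0.15,
                         hourly_noise_frac = 0.2) {
  stopifnot(extent[["xmax"]] > extent[["xmin"]],
            extent[["ymax"]] > extent[["ymin"]],
            cell_size > 0, fine_cell_size > 0,
            all(field_specs$correlation_length_m > 0),
            road_spec$n_major >= 0, road_spec$n_minor >= 0,
            n_sites >= nrow(truth$terms) + 10)
  structure(
    list(seed = as.integer(seed), extent = extent, cell_size = cell_size,
         fine_cell_size = fine_cell_size, field_specs = field_specs,
         road_spec = road_spec, n_power_stations = n_power_stations,
         n_sites = as.integer(n_sites), site_margin_m = site_margin_m,
         truth = truth, missingness = missingness, year = as.integer(year),
         seasonal_amplitude = seasonal_amplitude,
         diurnal_amplitude = diurnal_amplitude,
         hourly_noise_frac = hourly_noise_frac),
    class = "lur_world_config"
  )
}

#' @rdname world_config
#' @export
default_field_specs <- function() {
  tibble::tribble(
    ~name,           ~mean, ~sd,  ~correlation_length_m, ~expected_sign,
    "satellite",       8.0,  3.0,  30000,                "+",
    "vegetation",     30.0, 15.0,  20000,                "-",
    "impervious",     10.0,  8.0,  15000,                "+",
    "elevation",    1400.0, 300.0, 40000,                "-",
    "temperature",     9.0,  1.5,  50000,                "-",
    "precipitation", 300.0, 80.0,  50000,                "-",
    "population",    120.0, 100.0, 10000,                "+",
    "water",           5.0,  5.0,  15000,                "-",
    "trees",           8.0,  6.0,  20000,                "-",
    "barren",         20.0, 12.0,  25000,                "+"
  )
}

#' Generative annual-NO2 model of a synthetic world
#'
#' The ground truth downstream stages try to recover:
#' `y_i = intercept + sum_k beta_k * z_ik + eps_i`, with `z` the
#' standardized predictor columns named in `terms` and
#' `eps ~ Normal(0, noise_sd^2)`. If `noise_sd` is `NULL` it is calibrated
#' at generation time so that the generating model explains `target_r2`
#' of the variance of `y` across the sampled sites.
#'
#' @param intercept_ppb Intercept (equals the population mean of annual NO2
#'   since predictors are standardized).
#' @param terms Tibble with `column` (standardized-predictor column name,
#'   e.g. `"vegetation_1800"`) and `beta` (ppb per SD).
#' @param noise_sd Site-level noise SD in ppb, or `NULL` to calibrate.
#' @param target_r2 Fraction of variance explained by the generating model;
#'   used only when `noise_sd` is `NULL`.
#' @return A `lur_truth_model` list.
#' @export
truth_model <- function(intercept_ppb = 27.6,
                        terms = tibble(
                          column = c("satellite", "major_roads_5000",
                                     "vegetation_1800", "impervious_7000"),
                          beta = c(6.03, 3.02, -3.43, 1.87)),
                        noise_sd = NULL, target_r2 = 0.63) {
  stopifnot(is.null(noise_sd) || noise_sd >= 0,
            is.null(target_r2) || (target_r2 > 0 && target_r2 < 1))
  structure(list(intercept = intercept_ppb, terms = terms,
                 noise_sd = noise_sd, target_r2 = target_r2),
            class = "lur_truth_model")
}

#' @rdname truth_model
#' @export
default_truth_model <- function() truth_model()

#' Generate one spatially autocorrelated predictor field
#'
#' Seeded white noise on the world grid is smoothed with a separable
#' Gaussian kernel whose length scale is `correlation_length_m / 2`, then
#' affinely rescaled so the cell values have exactly the target mean and
#' (sample) SD. With `sd = 0` the field is constant at `mean`. Bit-identical
#' for a fixed `(seed, name)`.
#'
#' @param config A [world_config()].
#' @param name A field name present in `config$field_specs`.
#' @return A [lur_raster].
#' @export
generate_field <- function(config, name) {
  spec <- config$field_specs[config$field_specs$name == name, ]
  if (nrow(spec) != 1) {
    abort(sprintf("unknown field '%s' (not in field_specs)", name))
  }
  nx <- ceiling((config$extent[["xmax"]] - config$extent[["xmin"]]) /
                  config$cell_size)
  ny <- ceiling((config$extent[["ymax"]] - config$extent[["ymin"]]) /
                  config$cell_size)
  vals <- with_seed(op_seed(config$seed, paste0("field:", name)), {
    w <- matrix(rnorm(nx * ny), ny, nx)
    len <- spec$correlation_length_m / 2
    smooth <- gauss_kernel_matrix(ny, config$cell_size, len) %*% w %*%
      t(gauss_kernel_matrix(nx, config$cell_size, len))
    if (spec$sd == 0) {
      matrix(spec$mean, ny, nx)
    } else {
      (smooth - mean(smooth)) / sd(as.vector(smooth)) * spec$sd + spec$mean
    }
  })
  lur_raster(vals, config$extent[["xmin"]], config$extent[["ymin"]],
             config$cell_size, name = name)
}

# Row-normalized Gaussian smoothing matrix for one axis.
gauss_kernel_matrix <- function(n, cell, length_m) {
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * cell)
  k <- exp(-0.5 * (d / length_m)^2)
  k / rowSums(k)
}

#' Generate the synthetic road network
#'
#' Seeded random straight segments: uniform start point, uniform bearing,
#' exponentially distributed target length, clipped to the world extent.
#' Segments are classed `"major"` or `"minor"` per `config$road_spec`.
#'
#' @param config A [world_config()].
#' @return Segment tibble (`road_id`, `class`, `x0`, `y0`, `x1`, `y1`,
#'   `length_m`).
#' @export
generate_roads <- function(config) {
  gen_class <- function(n, class) {
    if (n == 0) {
      return(tibble(road_id = character(), class = character(),
                    x0 = double(), y0 = double(), x1 = double(),
                    y1 = double(), length_m = double()))
    }
    e <- config$extent
    with_seed(op_seed(config$seed, paste0("roads:", class)), {
      x0 <- runif(n, e[["xmin"]], e[["xmax"]])
      y0 <- runif(n, e[["ymin"]], e[["ymax"]])
      ang <- runif(n, 0, 2 * pi)
      len <- rexp(n, rate = 1 / config$road_spec$mean_segment_length_m)
      dx <- cos(ang); dy <- sin(ang)
      # param t (metres along the ray) at which each boundary is crossed
      t_exit <- pmin(
        ifelse(dx > 0, (e[["xmax"]] - x0) / dx,
               ifelse(dx < 0, (e[["xmin"]] - x0) / dx, Inf)),
        ifelse(dy > 0, (e[["ymax"]] - y0) / dy,
               ifelse(dy < 0, (e[["ymin"]] - y0) / dy, Inf))
      )
      t_end <- pmin(len, t_exit)
      tibble(road_id = sprintf("%s%04d", toupper(substr(class, 1, 1)),
                               seq_len(n)),
             class = class,
             x0 = x0, y0 = y0,
             x1 = x0 + t_end * dx, y1 = y0 + t_end * dy,
             length_m = t_end)
    })
  }
  bind_rows(gen_class(config$road_spec$n_major, "major"),
            gen_class(config$road_spec$n_minor, "minor"))
}

#' Generate synthetic point sources (power stations)
#'
#' @param config A [world_config()].
#' @return Tibble (`id`, `x`, `y`).
#' @export
generate_power_stations <- function(config) {
  n <- config$n_power_stations
  e <- config$extent
  with_seed(op_seed(config$seed, "power_stations"), {
    tibble(id = sprintf("P%02d", seq_len(n)),
           x = runif(n, e[["xmin"]], e[["xmax"]]),
           y = runif(n, e[["ymin"]], e[["ymax"]]))
  })
}

#' Generate the monitor network
#'
#' Sites are placed uniformly at random, inset by `site_margin_m` from the
#' extent edge so that buffer extractions up to 10 km remain inside the
#' predictor rasters.
#'
#' @param config A [world_config()].
#' @param n_sites Number of sites (defaults to `config$n_sites`).
#' @return Tibble (`site_id`, `x`, `y`).
#' @export
generate_sites <- function(config, n_sites = config$n_sites) {
  e <- config$extent
  m <- config$site_margin_m
  with_seed(op_seed(config$seed, "sites"), {
    tibble(site_id = sprintf("S%03d", seq_len(n_sites)),
           x = runif(n_sites, e[["xmin"]] + m, e[["xmax"]] - m),
           y = runif(n_sites, e[["ymin"]] + m, e[["ymax"]] - m))
  })
}

#' Generate true annual NO2 at the monitor sites
#'
#' Evaluates the generative linear model of [truth_model()] on the
#' standardized predictor matrix and adds seeded Gaussian site noise. When
#' the truth model's `noise_sd` is `NULL`, the noise SD is calibrated from
#' the realized signal variance so the generating model explains
#' `target_r2` of the variance of `y`.
#'
#' @param z Standardized predictor tibble (from
#'   [standardize_predictors()]); must contain every truth-term column.
#' @param config A [world_config()].
#' @return Tibble (`site_id`, `no2_ppb`) with attributes `truth` (the truth
#'   model, with the calibrated `noise_sd` filled in) and `signal`
#'   (noise-free site values).
#' @export
generate_truth_sites <- function(z, config) {
  truth <- config$truth
  missing_terms <- setdiff(truth$terms$column, names(z))
  if (length(missing_terms)) {
    abort(sprintf("predictor matrix lacks truth term column(s): %s",
                  paste(missing_terms, collapse = ", ")))
  }
  zm <- as.matrix(z[, truth$terms$column, drop = FALSE])
  signal <- truth$intercept + as.vector(zm %*% truth$terms$beta)
  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) {
    sig_sd <- sd(signal)
    noise_sd <- sig_sd * sqrt((1 - truth$target_r2) / truth$target_r2)
  }
  y <- with_seed(op_seed(config$seed, "truth_noise"), {
    signal + rnorm(length(signal), 0, noise_sd)
  })
  truth$noise_sd <- noise_sd
  out <- tibble(site_id = z$site_id, no2_ppb = y)
  attr(out, "truth") <- truth
  attr(out, "signal") <- signal
  out
}

#' Generate hourly monitor series with seasonal cycle and missingness
#'
#' Each site's complete series is
#' `annual_mean * s(day) * d(hour) + noise`, where `s` is a winter-peaking
#' sinusoid and `d` a 12-h-period (rush hour) sinusoid, both mean-centred
#' over the year so the complete series' annual mean matches the input;
#' noise is Gaussian with SD `hourly_noise_frac * annual_mean` and values
#' are truncated at zero. Multi-day outage blocks and independent hourly
#' drops are then deleted per `config$missingness`. Missing hours are
#' absent rows, matching the monitor-export convention.
#'
#' @param annual Tibble (`site_id`, `mean_ppb`) of target annual means.
#' @param config A [world_config()].
#' @return Tibble (`site_id`, `timestamp` (POSIXct UTC), `value_ppb`).
#' @export
generate_hourly_series <- function(annual, config) {
  stopifnot_cols(annual, c("site_id", "mean_ppb"), "annual")
  year <- config$year
  t0 <- ISOdatetime(year, 1, 1, 0, 0, 0, tz = "UTC")
  t1 <- ISOdatetime(year + 1, 1, 1, 0, 0, 0, tz = "UTC")
  n_hours <- as.integer(difftime(t1, t0, units = "hours"))
  n_days <- n_hours / 24L
  ts <- t0 + (seq_len(n_hours) - 1L) * 3600
  doy <- rep(seq_len(n_days), each = 24L)
  hod <- rep(0:23, times = n_days)
  seas_raw <- cos(2 * pi * (doy - 15) / n_days)
  seasonal <- 1 + config$seasonal_amplitude * (seas_raw - mean(seas_raw))
  diur_raw <- cos(2 * pi * (hod - 9) / 12)
  diurnal <- 1 + config$diurnal_amplitude * (diur_raw - mean(diur_raw))
  shape <- seasonal * diurnal

  mn <- config$missingness
  purrr::map2_dfr(annual$site_id, annual$mean_ppb, function(sid, mu) {
    with_seed(op_seed(config$seed, paste0("series:", sid)), {
      v <- mu * shape + rnorm(n_hours, 0, config$hourly_noise_frac * mu)
      v[v < 0] <- 0
      keep <- rep(TRUE, n_hours)
      if (mn$block_prob > 0) {
        starts <- which(runif(n_days) < mn$block_prob)
        for (s in starts) {
          len <- 1L + rgeom(1, 1 / mn$block_length_days)
          days_out <- s:min(n_days, s + len - 1L)
          keep[doy %in% days_out] <- FALSE
        }
      }
      if (mn$hourly_drop_prob > 0) {
        keep <- keep & runif(n_hours) >= mn$hourly_drop_prob
      }
      tibble(site_id = sid, timestamp = ts[keep], value_ppb = v[keep])
    })
  })
}

#' Generate a synthetic population raster
#'
#' A right-skewed (log-Gaussian) clustered population surface; cell values
#' are persons per cell.
#'
#' @param config A [world_config()].
#' @param cell_size Cell size in metres.
#' @param extent Extent to cover (defaults to the world extent).
#' @param mean_density_km2 Mean population density (persons per km2).
#' @return A [lur_raster] of persons per cell.
#' @export
generate_population <- function(config, cell_size = config$cell_size,
                                extent = config$extent,
                                mean_density_km2 = 108) {
  nx <- ceiling((extent[["xmax"]] - extent[["xmin"]]) / cell_size)
  ny <- ceiling((extent[["ymax"]] - extent[["ymin"]]) / cell_size)
  vals <- with_seed(op_seed(config$seed, "population"), {
    w <- matrix(rnorm(nx * ny), ny, nx)
    k <- gauss_kernel_matrix(ny, cell_size, 5000) %*% w %*%
      t(gauss_kernel_matrix(nx, cell_size, 5000))
    g <- (k - mean(k)) / sd(as.vector(k))
    dens <- exp(1.2 * g)
    dens <- dens / mean(dens) * mean_density_km2
    dens * (cell_size / 1000)^2
  })
  lur_raster(vals, extent[["xmin"]], extent[["ymin"]], cell_size,
             name = "population")
}

#' Generate a rectangular partition of township polygons
#'
#' Splits `extent` into an `nx` by `ny` grid of rectangular administrative
#' polygons, returned as closed vertex rings.
#'
#' @param extent Named numeric `c(xmin, xmax, ymin, ymax)`.
#' @param nx,ny Number of polygons along each axis.
#' @return Tibble (`polygon_id`, `x`, `y`) of ring vertices (5 per polygon,
#'   closed, counter-clockwise).
#' @export
generate_townships <- function(extent, nx = 4L, ny = 4L) {
  xs <- seq(extent[["xmin"]], extent[["xmax"]], length.out = nx + 1)
  ys <- seq(extent[["ymin"]], extent[["ymax"]], length.out = ny + 1)
  purrr::map_dfr(seq_len(nx), function(i) {
    purrr::map_dfr(seq_len(ny), function(j) {
      tibble(polygon_id = sprintf("T%02d%02d", i, j),
             x = c(xs[i], xs[i + 1], xs[i + 1], xs[i], xs[i]),
             y = c(ys[j], ys[j], ys[j + 1], ys[j + 1], ys[j]))
    })
  })
}

#' Generate a complete synthetic study world
#'
#' Runs every generator and the predictor-extraction chain: rasters, roads,
#' power stations, sites, the raw and standardized candidate predictor
#' matrix (see [default_predictor_specs()]), and true annual NO2 per site.
#'
#' @param config A [world_config()].
#' @param specs Candidate-predictor specification table; defaults to
#'   [default_predictor_specs()].
#' @return A `lur_world` list: `config`, `layers` (named list of rasters,
#'   `roads`, `power_stations`), `sites`, `predictors` (raw matrix), `z`
#'   (screened + standardized matrix), `annual` (site truth, with `truth`
#'   attribute), `specs`.
#' @export
generate_world <- function(config = world_config(),
                           specs = default_predictor_specs()) {
  layers <- purrr::map(setNames(config$field_specs$name,
                                config$field_specs$name),
                       function(nm) generate_field(config, nm))
  layers$roads <- generate_roads(config)
  layers$power_stations <- generate_power_stations(config)
  sites <- generate_sites(config)
  pm <- build_predictor_matrix(sites, layers, specs)
  z <- standardize_predictors(screen_predictors(pm))
  annual <- generate_truth_sites(z, config)
  structure(list(config = config, layers = layers, sites = sites,
                 predictors = pm, z = z, annual = annual, specs = specs),
            class = "lur_world")
}

#' Write a synthetic world to disk as plain-text geodata
#'
#' Rasters go to Esri ASCII grids, roads and power stations to GeoJSON,
#' sites and annual truth to CSV, and the truth model to a YAML sidecar.
#'
#' @param world A `lur_world` from [generate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in world$config$field_specs$name) {
    write_ascii_grid(world$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_roads_geojson(world$layers$roads, file.path(dir, "roads.geojson"))
  write_points_geojson(world$layers$power_stations,
                       file.path(dir, "power_stations.geojson"))
  readr::write_csv(world$sites, file.path(dir, "sites.csv"))
  readr::write_csv(world$annual, file.path(dir, "annual_truth.csv"))
  truth <- attr(world$annual, "truth")
  yaml::write_yaml(list(intercept_ppb = truth$intercept,
                        terms = purrr::transpose(as.list(truth$terms)),
                        noise_sd_ppb = truth$noise_sd,
                        seed = world$config$seed),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
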