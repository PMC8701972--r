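#' Gridded prediction from a fitted LUR model
#'
#' Evaluates the model at every cell centroid of a regular grid: each model
#' term is extracted at the centroid exactly as at a monitoring site (same
#' buffer semantics), standardized with the frozen training statistics,
#' and combined as `intercept + sum(beta_k z_k)`. Cells with any missing
#' term become no-data. Predictions are not truncated at zero by default
#' (the linear model may extrapolate below zero in remote cells); set
#' `clamp_zero = TRUE` to clamp.
#'
#' @param model A `lur_model` with frozen `stats`.
#' @param layers Named layer list (rasters / `roads` / point tibbles).
#' @param specs Predictor spec table covering at least the model terms.
#' @param extent Named `c(xmin, xmax, ymin, ymax)` of the prediction grid.
#' @param cell_size Grid cell size in metres (100 m in the reference
#'   workflow).
#' @param clamp_zero Truncate negative predictions at zero.
#' @return A [lur_raster] of predicted NO2 (ppb) with a `provenance`
#'   attribute.
#' @export
predict_grid <- function(model, layers, specs, extent, cell_size = 100,
                         clamp_zero = FALSE) {
  need <- model$terms$column
  specs_used <- specs[specs$column %in% need, , drop = FALSE]
  miss <- setdiff(need, specs_used$column)
  if (length(miss)) {
    abort(sprintf("specs lack model term(s): %s", paste(miss, collapse = ", ")))
  }
  miss_layer <- setdiff(unique(specs_used$layer), names(layers))
  if (length(miss_layer)) {
    abort(sprintf("missing layer(s): %s", paste(miss_layer, collapse = ", ")))
  }
  nx <- ceiling((extent[["xmax"]] - extent[["xmin"]]) / cell_size)
  ny <- ceiling((extent[["ymax"]] - extent[["ymin"]]) / cell_size)
  cells <- tibble(
    site_id = as.character(seq_len(nx * ny)),
    x = rep(extent[["xmin"]] + (seq_len(nx) - 0.5) * cell_size, each = ny),
    y = rep(extent[["ymin"]] + (seq_len(ny) - 0.5) * cell_size, times = nx)
  )
  raw <- build_predictor_matrix(cells, layers, specs_used)
  z <- apply_standardization(raw, model$stats)
  pred <- rep(NA_real_, nrow(cells))
  ok <- stats::complete.cases(z[, need, drop = FALSE])
  pred[ok] <- predict(model, z[ok, , drop = FALSE])
  if (clamp_zero) pred[!is.na(pred) & pred < 0] <- 0
  vals <- matrix(pred, nrow = ny, ncol = nx)
  out <- lur_raster(vals, extent[["xmin"]], extent[["ymin"]], cell_size,
                    name = "no2_ppb")
  attr(out, "provenance") <- list(terms = need, cell_size = cell_size)
  out
}

# Even-odd (crossing-number) point-in-polygon; boundary points are resolved
# by an explicit on-edge check so that, over a polygon partition, every
# point is assigned to exactly one polygon by first match in stable order.
point_in_ring <- function(px, py, rx, ry, edge_tol = 1e-9) {
  n <- length(rx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (ry[i] > py) != (ry[j] > py)
    if (any(crosses)) {
      xint <- rx[i] + (py - ry[i]) * (rx[j] - rx[i]) / (ry[j] - ry[i])
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    on_edge <- on_edge | point_segment_distance(px, py, rx[j], ry[j],
                                                rx[i], ry[i]) <= edge_tol
    j <- i
  }
  inside | on_edge
}

#' Assign grid cells to polygons
#'
#' Cell-centre-in-polygon assignment. A centre lying exactly on a shared
#' boundary is claimed by the first polygon (in the stable order of
#' `unique(polygons$polygon_id)`) whose closed ring contains it.
#'
#' @param cells Tibble with `x`, `y`.
#' @param polygons Ring tibble (`polygon_id`, `x`, `y`).
#' @return Character vector of polygon ids (`NA` where unassigned).
#' @export
assign_polygons <- function(cells, polygons) {
  ids <- unique(polygons$polygon_id)
  out <- rep(NA_character_, nrow(cells))
  for (pid in ids) {
    ring <- polygons[polygons$polygon_id == pid, ]
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- point_in_ring(cells$x[todo], cells$y[todo], ring$x, ring$y)
    out[todo][hit] <- pid
  }
  out
}

#' Population-weighted aggregation to administrative polygons
#'
#' Combines a prediction grid with a co-registered population raster:
#' per polygon, the unweighted mean of its member cells and the
#' population-weighted mean `sum(p_j c_j) / sum(p_j)`. Polygons whose total
#' population is zero get an `NA` weighted mean and are flagged. The
#' cross-polygon percentiles (5, 25, 50, 75, 95) of both summaries are
#' attached as the `percentiles` attribute.
#'
#' @param grid Prediction [lur_raster] (from [predict_grid()]).
#' @param population Population [lur_raster] on the identical grid.
#' @param polygons Ring tibble (`polygon_id`, `x`, `y`).
#' @return Tibble (`polygon_id`, `n_cells`, `population`, `mean_ppb`,
#'   `weighted_mean_ppb`, `zero_population`).
#' @export
pop_weighted_aggregate <- function(grid, population, polygons) {
  if (!isTRUE(all.equal(raster_extent(grid), raster_extent(population))) ||
        grid$cell != population$cell) {
    abort("population raster is not co-registered with the prediction grid")
  }
  cells <- as_tibble(grid) |> rename(conc = "value")
  cells$pop <- as_tibble(population)$value
  cells$polygon_id <- assign_polygons(cells, polygons)
  per <- cells |>
    filter(!is.na(.data$polygon_id), !is.na(.data$conc)) |>
    group_by(.data$polygon_id) |>
    summarise(
      n_cells = dplyr::n(),
      population = sum(.data$pop, na.rm = TRUE),
      mean_ppb = mean(.data$conc),
      weighted_mean_ppb = if (sum(.data$pop, na.rm = TRUE) > 0) {
        sum(.data$pop * .data$conc, na.rm = TRUE) /
          sum(.data$pop, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(zero_population = .data$population <= 0)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  attr(per, "percentiles") <- tibble(
    percentile = 100 * probs,
    unweighted = quantile(per$mean_ppb, probs, na.rm = TRUE),
    weighted = quantile(per$weighted_mean_ppb, probs, na.rm = TRUE)
  )
  per
}

#' @rdname pop_weighted_aggregate
#' @param summary Output of `pop_weighted_aggregate()`.
#' @export
aggregate_percentiles <- function(summary) attr(summary, "percentiles")

#' Historical prediction with frozen 2019-style coefficients
#'
#' One prediction grid per requested year: time-varying layers are taken
#' from `layers_by_year[[as.character(year)]]`, all other (time-invariant)
#' terms reuse the base training-era layers, and the model's coefficients
#' and standardization stay frozen. Years with no layer entry are skipped
#' and logged.
#'
#' @param model A `lur_model` with frozen `stats`.
#' @param base_layers Training-era layer list.
#' @param layers_by_year Named list (year as name) of layer lists that
#'   override `base_layers` for that year.
#' @param years Integer vector of years.
#' @inheritParams predict_grid
#' @return Named list of [lur_raster]s (one per produced year) with a
#'   `skipped_years` attribute.
#' @export
historical_predict <- function(model, base_layers, layers_by_year, years,
                               specs, extent, cell_size = 100) {
  out <- list()
  skipped <- integer()
  for (yr in years) {
    yl <- layers_by_year[[as.character(yr)]]
    if (is.null(yl)) {
      skipped <- c(skipped, yr)
      next
    }
    layers <- utils::modifyList(base_layers, yl)
    out[[as.character(yr)]] <-
      predict_grid(model, layers, specs, extent, cell_size)
  }
  attr(out, "skipped_years") <- skipped
  out
}
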