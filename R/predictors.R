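#' Candidate predictor specification table
#'
#' One row per candidate column. `kind` is one of `point_value`,
#' `distance_to_nearest`, `buffer_average`, `buffer_sum_value`,
#' `buffer_sum_length`; buffer kinds carry a `radius_m` drawn from the 22
#' canonical radii ([lur_buffer_radii()]), point kinds have `radius_m = NA`.
#' Every candidate carries a pre-defined expected coefficient direction
#' (`"+"` or `"-"`), following standard LUR practice of constraining
#' selection to empirically plausible signs.
#'
#' @param name Variable name (must match a layer name).
#' @param layer Name of the layer in the world's layer list.
#' @param kind Extraction kind (see above).
#' @param radii_m Radii (metres) for buffer kinds; `NA` for point kinds.
#' @param expected_sign `"+"` or `"-"`.
#' @param time_varying Whether annual versions of the layer exist.
#' @return Tibble with one row per (name, radius) column; column names are
#'   `name` for point kinds and `name_radius` for buffer kinds.
#' @export
#' @examples
#' predictor_spec("vegetation", "vegetation", "buffer_average",
#'                c(500, 1800), "-")
predictor_spec <- function(name, layer = name, kind, radii_m = NA,
                           expected_sign, time_varying = FALSE) {
  kind <- match.arg(kind, c("point_value", "distance_to_nearest",
                            "buffer_average", "buffer_sum_value",
                            "buffer_sum_length"))
  buffered <- kind %in% c("buffer_average", "buffer_sum_value",
                          "buffer_sum_length")
  if (buffered) {
    if (!length(radii_m) || all(is.na(radii_m))) {
      abort(sprintf("'%s': buffer kind '%s' requires radii", name, kind))
    }
    bad <- setdiff(radii_m, lur_buffer_radii())
    if (length(bad)) {
      abort(sprintf("'%s': radii not in the supported set: %s",
                    name, paste(bad, collapse = ", ")))
    }
  } else if (!all(is.na(radii_m))) {
    abort(sprintf("'%s': point kind '%s' must not have radii", name, kind))
  }
  stopifnot(expected_sign %in% c("+", "-"))
  tibble(
    column = if (buffered) paste0(name, "_", radii_m) else name,
    name = name, layer = layer, kind = kind,
    radius_m = if (buffered) as.numeric(radii_m) else NA_real_,
    expected_sign = expected_sign, time_varying = time_varying
  )
}

#' @rdname predictor_spec
#' @param decoy_radii Radii used for the non-truth buffer variables in the
#'   default synthetic candidate set.
#' @export
default_predictor_specs <- function(decoy_radii = c(200, 500, 1000, 1800,
                                                    2500, 4000, 7000,
                                                    10000)) {
  bind_rows(
    # variables carrying the generative signal (at their true radii)
    predictor_spec("satellite", kind = "point_value", expected_sign = "+",
                   time_varying = TRUE),
    predictor_spec("major_roads", layer = "roads", kind = "buffer_sum_length",
                   radii_m = 5000, expected_sign = "+"),
    predictor_spec("vegetation", kind = "buffer_average", radii_m = 1800,
                   expected_sign = "-"),
    predictor_spec("impervious", kind = "buffer_average", radii_m = 7000,
                   expected_sign = "+"),
    # decoy buffer variables at several well-spaced radii
    predictor_spec("population", kind = "buffer_average",
                   radii_m = decoy_radii, expected_sign = "+"),
    predictor_spec("water", kind = "buffer_average", radii_m = decoy_radii,
                   expected_sign = "-"),
    predictor_spec("trees", kind = "buffer_average", radii_m = decoy_radii,
                   expected_sign = "-"),
    predictor_spec("barren", kind = "buffer_average", radii_m = decoy_radii,
                   expected_sign = "+"),
    predictor_spec("minor_roads", layer = "roads", kind = "buffer_sum_length",
                   radii_m = decoy_radii, expected_sign = "+"),
    # decoy point variables
    predictor_spec("elevation", kind = "point_value", expected_sign = "-"),
    predictor_spec("temperature", kind = "point_value", expected_sign = "-"),
    predictor_spec("precipitation", kind = "point_value",
                   expected_sign = "-"),
    predictor_spec("dist_major_road", layer = "roads",
                   kind = "distance_to_nearest", expected_sign = "-"),
    predictor_spec("dist_power_station", layer = "power_stations",
                   kind = "distance_to_nearest", expected_sign = "-")
  )
}

#' Extract raster values at site locations
#'
#' @param sites Tibble with `x`, `y` columns (metres, planar CRS).
#' @param raster A [lur_raster].
#' @return Numeric vector (one value per site). See [raster_value_at()] for
#'   the containing-cell convention.
#' @export
extract_point_value <- function(sites, raster) {
  raster_value_at(raster, sites$x, sites$y)
}

#' Distance from each site to the nearest feature, in km
#'
#' Minimum Euclidean point-to-geometry distance over a segment table (road
#' network) or point table. An empty feature set yields `NA` (logged via a
#' warning), never zero.
#'
#' @param sites Tibble with `x`, `y`.
#' @param features Segment tibble (`x0`,`y0`,`x1`,`y1`) or point tibble
#'   (`x`,`y`).
#' @return Numeric vector of distances in km.
#' @export
extract_distance_to_nearest <- function(sites, features) {
  if (is.null(features) || nrow(features) == 0) {
    warn("distance_to_nearest: empty feature set; returning NA")
    return(rep(NA_real_, nrow(sites)))
  }
  px <- sites$x; py <- sites$y
  best <- rep(Inf, length(px))
  if (all(c("x0", "y0", "x1", "y1") %in% names(features))) {
    for (i in seq_len(nrow(features))) {
      best <- pmin(best, point_segment_distance(
        px, py, features$x0[i], features$y0[i],
        features$x1[i], features$y1[i]))
    }
  } else {
    stopifnot_cols(features, c("x", "y"), "features")
    for (i in seq_len(nrow(features))) {
      best <- pmin(best, sqrt((px - features$x[i])^2 + (py - features$y[i])^2))
    }
  }
  best / 1000
}

# Euclidean distance from points (px, py) to segment (x0,y0)-(x1,y1).
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# Linear indices (column-major) of the cells whose centres fall in the
# closed disc; used for nesting/membership introspection.
which_cells_in_disc <- function(raster, px, py, radius_m) {
  nx <- ncol(raster$values); ny <- nrow(raster$values)
  cx <- raster$xmin + (seq_len(nx) - 0.5) * raster$cell
  cy <- raster$ymin + (seq_len(ny) - 0.5) * raster$cell
  d2 <- outer(cy, cx, function(yy, xx) (xx - px)^2 + (yy - py)^2)
  which(d2 <= radius_m^2)
}

# Shared cell-membership walk for buffer_average / buffer_sum_value.
# Membership: cell CENTRE within the closed disc (<= radius) around the
# site. Cells outside the raster, and no-data cells, are excluded from both
# numerator and denominator.
buffer_cell_stat <- function(raster, x, y, radius_m, stat) {
  nxr <- ncol(raster$values); nyr <- nrow(raster$values)
  ix0 <- floor((x - raster$xmin) / raster$cell) + 1
  iy0 <- floor((y - raster$ymin) / raster$cell) + 1
  k <- ceiling(radius_m / raster$cell) + 1L
  total <- numeric(length(x))
  count <- numeric(length(x))
  for (di in -k:k) {
    cx <- raster$xmin + (ix0 + di - 0.5) * raster$cell
    dx2 <- (cx - x)^2
    for (dj in -k:k) {
      cy <- raster$ymin + (iy0 + dj - 0.5) * raster$cell
      inside <- dx2 + (cy - y)^2 <= radius_m^2
      ii <- ix0 + di; jj <- iy0 + dj
      ok <- inside & ii >= 1 & ii <= nxr & jj >= 1 & jj <= nyr
      if (!any(ok)) next
      v <- raster$values[cbind(jj[ok], ii[ok])]
      val_ok <- !is.na(v)
      idx <- which(ok)[val_ok]
      total[idx] <- total[idx] + v[val_ok]
      count[idx] <- count[idx] + 1
    }
  }
  if (stat == "mean") {
    out <- ifelse(count > 0, total / count, NA_real_)
    # no centre in the disc: fall back to the containing cell's value
    empty <- count == 0
    if (any(empty)) {
      idxc <- raster_cell_index(raster, x[empty], y[empty])
      inside <- !is.na(idxc$ix) & !is.na(idxc$iy)
      fb <- rep(NA_real_, sum(empty))
      fb[inside] <- raster$values[cbind(idxc$iy[inside], idxc$ix[inside])]
      out[empty] <- fb
    }
    out
  } else {
    total
  }
}

#' Buffer mean of a raster around each site
#'
#' Mean of the cells whose centres lie within Euclidean distance `radius_m`
#' of the site (closed disc; ties at exactly `radius_m` included). No-data
#' cells are excluded from numerator and denominator. If no cell centre
#' falls in the disc the containing cell's value is used.
#'
#' @param sites Tibble with `x`, `y`.
#' @param raster A [lur_raster].
#' @param radius_m Buffer radius in metres.
#' @return Numeric vector (one mean per site).
#' @export
extract_buffer_average <- function(sites, raster, radius_m) {
  buffer_cell_stat(raster, sites$x, sites$y, radius_m, "mean")
}

#' Buffer sum of raster cell values around each site
#'
#' Same closed-disc cell-centre membership rule as
#' [extract_buffer_average()], summing instead of averaging (used for
#' count/total-type rasters such as fire counts or emissions).
#'
#' @inheritParams extract_buffer_average
#' @return Numeric vector of in-disc sums.
#' @export
extract_buffer_sum_value <- function(sites, raster, radius_m) {
  buffer_cell_stat(raster, sites$x, sites$y, radius_m, "sum")
}

#' Total road length within a buffer, in km
#'
#' Sums the length of each segment clipped to the closed disc of radius
#' `radius_m` centred on the site. No intersecting segments yields 0.
#'
#' @param sites Tibble with `x`, `y`.
#' @param lines Segment tibble (`x0`,`y0`,`x1`,`y1`).
#' @param radius_m Buffer radius in metres.
#' @return Numeric vector of clipped lengths in km.
#' @export
extract_buffer_sum_length <- function(sites, lines, radius_m) {
  total <- numeric(nrow(sites))
  if (is.null(lines) || nrow(lines) == 0) return(total)
  px <- sites$x; py <- sites$y
  for (i in seq_len(nrow(lines))) {
    total <- total + segment_disc_length(
      px, py, lines$x0[i], lines$y0[i], lines$x1[i], lines$y1[i], radius_m)
  }
  total / 1000
}

# Length (m) of segment (x0,y0)-(x1,y1) inside the closed disc of radius r
# centred at each (cx, cy): solve |P(t) - C|^2 = r^2 for the unit-parameter
# interval, clamp to [0, 1].
segment_disc_length <- function(cx, cy, x0, y0, x1, y1, r) {
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx * dx + dy * dy)
  if (len == 0) return(numeric(length(cx)))
  fx <- x0 - cx; fy <- y0 - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  out <- numeric(length(cx))
  pos <- disc > 0
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    t1 <- pmax(0, (-b[pos] - sq) / (2 * a))
    t2 <- pmin(1, (-b[pos] + sq) / (2 * a))
    out[pos] <- pmax(0, t2 - t1) * len
  }
  out
}

#' Build the sites-by-candidates predictor matrix
#'
#' Runs every extraction in `specs` against the named `layers` list and
#' assembles the raw design matrix, one column per (variable, radius).
#' Attaches the spec table as the `predictor_info` attribute (retrievable
#' with [predictor_info()]), which travels through screening and
#' standardization.
#'
#' @param sites Tibble with `site_id`, `x`, `y`.
#' @param layers Named list of layers: [lur_raster]s, a `roads` segment
#'   tibble, point tibbles.
#' @param specs Spec table from [predictor_spec()] /
#'   [default_predictor_specs()].
#' @return Tibble `site_id` + one numeric column per candidate.
#' @export
build_predictor_matrix <- function(sites, layers, specs) {
  stopifnot_cols(sites, c("site_id", "x", "y"), "sites")
  out <- tibble(site_id = sites$site_id)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    layer <- layers[[s$layer]]
    if (is.null(layer)) {
      abort(sprintf("layer '%s' (for predictor '%s') not found",
                    s$layer, s$name))
    }
    seg <- if (is.data.frame(layer) && "class" %in% names(layer) &&
                 s$name %in% c("major_roads", "dist_major_road")) {
      layer[layer$class == "major", , drop = FALSE]
    } else if (is.data.frame(layer) && "class" %in% names(layer) &&
                 s$name == "minor_roads") {
      layer[layer$class == "minor", , drop = FALSE]
    } else {
      layer
    }
    out[[s$column]] <- switch(
      s$kind,
      point_value = extract_point_value(sites, seg),
      distance_to_nearest = extract_distance_to_nearest(sites, seg),
      buffer_average = extract_buffer_average(sites, seg, s$radius_m),
      buffer_sum_value = extract_buffer_sum_value(sites, seg, s$radius_m),
      buffer_sum_length = extract_buffer_sum_length(sites, seg, s$radius_m)
    )
  }
  attr(out, "predictor_info") <- specs
  out
}

#' @rdname build_predictor_matrix
#' @param matrix A predictor matrix tibble.
#' @export
predictor_info <- function(matrix) attr(matrix, "predictor_info")

#' Screen candidate predictor columns
#'
#' Drops a column iff more than `threshold` (default 75%) of its values
#' across sites are missing, identical (the modal value), or zero. The
#' triggered rule per dropped column is recorded in the `screen_log`
#' attribute ([screen_log()]).
#'
#' @param matrix Predictor matrix from [build_predictor_matrix()].
#' @param threshold Fraction above which a rule triggers (strictly `>`).
#' @return The matrix without the dropped columns.
#' @export
screen_predictors <- function(matrix, threshold = 0.75) {
  cols <- setdiff(names(matrix), "site_id")
  n <- nrow(matrix)
  stopifnot(n > 0)
  verdict <- purrr::map_chr(cols, function(cn) {
    v <- matrix[[cn]]
    if (sum(is.na(v)) / n > threshold) return("missing")
    vv <- v[!is.na(v)]
    if (sum(vv == 0) / n > threshold) return("zero")
    if (length(vv) && max(table(vv)) / n > threshold) return("repeating")
    NA_character_
  })
  dropped <- cols[!is.na(verdict)]
  log <- tibble(column = dropped, rule = verdict[!is.na(verdict)])
  out <- matrix[, c("site_id", setdiff(cols, dropped)), drop = FALSE]
  info <- attr(matrix, "predictor_info")
  if (!is.null(info)) {
    attr(out, "predictor_info") <- info[info$column %in% names(out), ]
  }
  attr(out, "screen_log") <- log
  out
}

#' @rdname screen_predictors
#' @export
screen_log <- function(matrix) attr(matrix, "screen_log")

#' Centre and standardize predictor columns
#'
#' Each retained column is transformed to `z = (x - mean) / sd` with the
#' sample SD (n-1 denominator). The per-column `(mean, sd)` pairs are
#' persisted in the `standardization` attribute
#' ([standardization_stats()]) for exact reuse at prediction and
#' external-evaluation time.
#'
#' @param matrix Screened predictor matrix.
#' @return Standardized tibble with the same columns.
#' @export
standardize_predictors <- function(matrix) {
  cols <- setdiff(names(matrix), "site_id")
  stats <- purrr::map_dfr(cols, function(cn) {
    v <- matrix[[cn]]
    tibble(column = cn, mean = mean(v, na.rm = TRUE),
           sd = sd(v, na.rm = TRUE))
  })
  if (any(!is.finite(stats$sd)) || any(stats$sd == 0)) {
    bad <- stats$column[!is.finite(stats$sd) | stats$sd == 0]
    abort(sprintf("zero-variance column(s) (should have been screened): %s",
                  paste(bad, collapse = ", ")))
  }
  out <- matrix
  for (i in seq_along(cols)) {
    out[[cols[i]]] <- (matrix[[cols[i]]] - stats$mean[i]) / stats$sd[i]
  }
  attr(out, "predictor_info") <- attr(matrix, "predictor_info")
  attr(out, "screen_log") <- attr(matrix, "screen_log")
  attr(out, "standardization") <- stats
  out
}

#' @rdname standardize_predictors
#' @export
standardization_stats <- function(matrix) attr(matrix, "standardization")

#' Apply persisted standardization to new raw predictors
#'
#' @param data Tibble of raw predictor columns.
#' @param stats Tibble (`column`, `mean`, `sd`) from
#'   [standardization_stats()] or a fitted model's `stats` element.
#' @return `data` with each listed column standardized by the frozen stats.
#' @export
apply_standardization <- function(data, stats) {
  for (i in seq_len(nrow(stats))) {
    cn <- stats$column[i]
    if (cn %in% names(data)) {
      data[[cn]] <- (data[[cn]] - stats$mean[i]) / stats$sd[i]
    }
  }
  data
}
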