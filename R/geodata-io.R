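#' Write and read road segments as GeoJSON
#'
#' Road networks are held as tidy segment tables: one row per straight
#' segment with columns `road_id`, `class` (`"major"`/`"minor"`), and
#' endpoint coordinates `x0, y0, x1, y1` in metres (planar CRS). On disk
#' they are a GeoJSON `FeatureCollection` of two-point `LineString`s.
#'
#' @param roads Tibble of segments (`road_id`, `class`, `x0`, `y0`, `x1`, `y1`).
#' @param path File path.
#' @return `write_roads_geojson()` returns `path` invisibly;
#'   `read_roads_geojson()` returns the segment tibble.
#' @export
write_roads_geojson <- function(roads, path) {
  stopifnot_cols(roads, c("road_id", "class", "x0", "y0", "x1", "y1"), "roads")
  features <- purrr::pmap(roads, function(road_id, class, x0, y0, x1, y1, ...) {
    list(
      type = "Feature",
      properties = list(road_id = road_id, class = class),
      geometry = list(
        type = "LineString",
        coordinates = list(c(x0, y0), c(x1, y1))
      )
    )
  })
  obj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  purrr::map_dfr(obj$features, function(f) {
    cc <- f$geometry$coordinates
    tibble(
      road_id = f$properties$road_id,
      class = f$properties$class,
      x0 = as.numeric(cc[[1]][[1]]), y0 = as.numeric(cc[[1]][[2]]),
      x1 = as.numeric(cc[[2]][[1]]), y1 = as.numeric(cc[[2]][[2]])
    )
  })
}

#' Write and read point features (e.g. power stations) as GeoJSON
#'
#' @param points Tibble with columns `id`, `x`, `y` (metres, planar CRS).
#' @param path File path.
#' @return `write_points_geojson()` returns `path` invisibly;
#'   `read_points_geojson()` the point tibble.
#' @export
write_points_geojson <- function(points, path) {
  stopifnot_cols(points, c("id", "x", "y"), "points")
  features <- purrr::pmap(points, function(id, x, y, ...) {
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(type = "Point", coordinates = c(x, y)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  purrr::map_dfr(obj$features, function(f) {
    tibble(id = f$properties$id,
           x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]]))
  })
}
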