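#' Write vector layers as GeoJSON
#'
#' Minimal GeoJSON emitters for the synthetic vector layers: stream
#' polylines (as `MultiLineString` features), harvest rectangles (as dated
#' `Polygon` features), and home-range isopleths (contour rings as
#' `Polygon` features).  Coordinates are written in the projected meter
#' system used throughout.
#'
#' @param streams list of polylines (2-column matrices).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_streams_geojson <- function(streams, path) {
  feats <- lapply(streams, function(line) {
    list(type = "Feature", properties = list(),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(line)), function(i) {
                           c(line[i, 1], line[i, 2])
                         })))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_streams_geojson
#' @param harvest data.frame from [gen_harvest()].
#' @export
write_harvest_geojson <- function(harvest, path) {
  feats <- lapply(seq_len(nrow(harvest)), function(i) {
    r <- harvest[i, ]
    ring <- list(c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
                 c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(type = "Feature",
         properties = list(date = format(r$date, "%Y-%m-%d")),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_streams_geojson
#' @param hr a [home_range()].
#' @export
write_range_geojson <- function(hr, path) {
  feats <- lapply(hr$polygons, function(p) {
    ring <- lapply(seq_along(p$x), function(i) c(p$x[i], p$y[i]))
    if (p$x[1] != p$x[length(p$x)] || p$y[1] != p$y[length(p$y)]) {
      ring <- c(ring, ring[1])
    }
    list(type = "Feature",
         properties = list(owl = paste(hr$owl_ids, collapse = "+"),
                           season = hr$season, level = hr$level,
                           h = hr$h),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stream polylines from GeoJSON
#'
#' Accepts `LineString` and `MultiLineString` features.
#'
#' @param path GeoJSON file path.
#' @return list of polylines (2-column matrices).
#' @export
read_streams_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  out <- list()
  for (f in fc$features) {
    geom <- f$geometry
    lines <- switch(geom$type,
                    LineString = list(geom$coordinates),
                    MultiLineString = geom$coordinates,
                    stop("unsupported geometry: ", geom$type))
    for (ln in lines) {
      out[[length(out) + 1L]] <-
        do.call(rbind, lapply(ln, function(pt) c(pt[[1]], pt[[2]])))
    }
  }
  out
}
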