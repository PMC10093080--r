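#' Export endpoints as GeoJSON or CSV
#'
#' GeoJSON output is a `FeatureCollection` of `Point` features in WGS84
#' lon-lat order with properties `source_id`, `kind`, `bearing_deg`,
#' `distance_m`. The CSV mirrors the endpoint tibble columns.
#'
#' @param endpoints a `geo_endpoints` tibble (see [project_endpoint()]).
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_endpoints_geojson <- function(endpoints, path) {
  endpoints <- as_tibble(endpoints)
  features <- lapply(seq_len(nrow(endpoints)), function(i) {
    e <- endpoints[i, ]
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(e$lon_deg, e$lat_deg)),
      properties = list(source_id = e$source_id, kind = e$kind,
                        bearing_deg = e$bearing_deg,
                        distance_m = e$distance_m)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(endpoints)
}

#' @rdname write_endpoints_geojson
#' @export
write_endpoints_csv <- function(endpoints, path) {
  readr::write_csv(as_tibble(endpoints), path, progress = FALSE)
  invisible(endpoints)
}
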