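# Plain-text readers/writers. Rasters travel as wide CSV (lon, lat, one
# column per field) plus a JSON metadata sidecar; occurrences and report
# tables as CSV; polygons as GeoJSON.

#' Read and write occurrence tables
#'
#' @param records data.frame(species, longitude, latitude, year, basis_flag).
#' @param path CSV file path.
#' @export
writeOccurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrences
#' @export
readOccurrences <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

stackMetaPath <- function(path) sub("\\.csv$", ".json", path)

#' Read and write environmental stacks as CSV + JSON metadata
#'
#' The CSV holds one row per grid cell (lon, lat and the seven variables);
#' the sidecar JSON records grid bounds, cell size and the (esm, scenario,
#' period) provenance.
#'
#' @param stack an [EnvStack-class].
#' @param path CSV path; metadata goes to the same path with .json.
#' @export
writeEnvStack <- function(stack, path) {
  g <- stack@grid
  nr <- nLat(g); nc <- nLon(g)
  df <- data.frame(lon = rep(lonCenters(g), each = nr),
                   lat = rep(latCenters(g), nc))
  for (v in ENV_VARS) df[[v]] <- as.numeric(stack@fields[[v]])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(latMin = g@latMin, latMax = g@latMax, lonMin = g@lonMin,
               lonMax = g@lonMax, cellSize = g@cellSize, esm = stack@esm,
               scenario = stack@scenario, period = stack@period)
  jsonlite::write_json(meta, stackMetaPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEnvStack
#' @export
readEnvStack <- function(path) {
  meta <- jsonlite::read_json(stackMetaPath(path), simplifyVector = TRUE)
  g <- gridSpec(meta$latMin, meta$latMax, meta$lonMin, meta$lonMax,
                meta$cellSize)
  df <- utils::read.csv(path)
  nr <- nLat(g); nc <- nLon(g)
  fields <- lapply(stats::setNames(ENV_VARS, ENV_VARS),
                   function(v) matrix(df[[v]], nr, nc))
  new("EnvStack", grid = g, fields = fields, esm = meta$esm,
      scenario = meta$scenario, period = meta$period)
}

#' Read and write suitability maps as CSV + JSON metadata
#'
#' @param map an [HsiMap-class].
#' @param path CSV path (columns lon, lat, hsi).
#' @export
writeHsiMap <- function(map, path) {
  g <- map@grid
  nr <- nLat(g); nc <- nLon(g)
  df <- data.frame(lon = rep(lonCenters(g), each = nr),
                   lat = rep(latCenters(g), nc),
                   hsi = as.numeric(map@values))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(latMin = g@latMin, latMax = g@latMax, lonMin = g@lonMin,
               lonMax = g@lonMax, cellSize = g@cellSize, species = map@species,
               esm = map@esm, scenario = map@scenario, period = map@period)
  jsonlite::write_json(meta, stackMetaPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeEnvStack
#' @export
readHsiMap <- function(path) {
  meta <- jsonlite::read_json(stackMetaPath(path), simplifyVector = TRUE)
  g <- gridSpec(meta$latMin, meta$latMax, meta$lonMin, meta$lonMax,
                meta$cellSize)
  df <- utils::read.csv(path)
  new("HsiMap", grid = g, values = matrix(df$hsi, nLat(g), nLon(g)),
      species = meta$species, esm = meta$esm, scenario = meta$scenario,
      period = meta$period)
}

#' Read and write protected-area polygons as GeoJSON
#'
#' Polygons are written as a FeatureCollection whose features carry a
#' \code{status} ("current"/"negotiated") and \code{name} property.
#'
#' @param pas a [ProtectedAreaSet-class].
#' @param path GeoJSON file path.
#' @export
writeGeoJson <- function(pas, path) {
  features <- lapply(seq_along(pas@polygons), function(i) {
    ring <- pas@polygons[[i]]
    list(type = "Feature",
         properties = list(status = pas@status[i], name = pas@names[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeGeoJson
#' @export
readGeoJson <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- list(); status <- character(); nms <- character()
  for (f in fc$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) unlist(pt)))
    colnames(ring) <- c("lon", "lat")
    polys[[length(polys) + 1]] <- ring
    status <- c(status, f$properties$status)
    nms <- c(nms, f$properties$name)
  }
  new("ProtectedAreaSet", polygons = polys, status = status, names = nms)
}

#' Write an association matrix and its significance mask as CSV
#'
#' @param assoc an [AssociationMatrix-class].
#' @param path CSV path for the correlations; the mask goes to the same
#'   path with suffix \code{_significant.csv}.
#' @export
writeAssociation <- function(assoc, path) {
  R <- assoc@correlation
  dimnames(R) <- list(assoc@species, assoc@species)
  utils::write.csv(R, path)
  M <- assoc@significant * 1
  dimnames(M) <- dimnames(R)
  utils::write.csv(M, sub("\\.csv$", "_significant.csv", path))
  invisible(path)
}
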