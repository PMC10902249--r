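#' Construct an analysis grid
#'
#' @param latMin,latMax latitude bounds in degrees (default -90, -35).
#' @param lonMin,lonMax longitude bounds in degrees (default -180, 180).
#' @param cellSize cell edge in degrees (default 1).
#' @return a [GridSpec-class] object.
#' @examples
#' g <- gridSpec()           # 55 x 360 circumpolar grid south of 35 S
#' nLat(g); nLon(g)
#' @export
gridSpec <- function(latMin = -90, latMax = -35, lonMin = -180, lonMax = 180,
                     cellSize = 1) {
  new("GridSpec", latMin = latMin, latMax = latMax, lonMin = lonMin,
      lonMax = lonMax, cellSize = cellSize)
}

#' @rdname gridSpec
#' @param grid a [GridSpec-class].
#' @export
nLat <- function(grid) as.integer(round((grid@latMax - grid@latMin) / grid@cellSize))

#' @rdname gridSpec
#' @export
nLon <- function(grid) as.integer(round((grid@lonMax - grid@lonMin) / grid@cellSize))

#' @rdname gridSpec
#' @export
latCenters <- function(grid)
  grid@latMin + (seq_len(nLat(grid)) - 0.5) * grid@cellSize

#' @rdname gridSpec
#' @export
lonCenters <- function(grid)
  grid@lonMin + (seq_len(nLon(grid)) - 0.5) * grid@cellSize

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %g..%g latitude x %g..%g longitude, %g deg cells (%d x %d)\n",
              object@latMin, object@latMax, object@lonMin, object@lonMax,
              object@cellSize, nLat(object), nLon(object)))
})

#' Row/column indices of the cells containing points
#'
#' Points on a cell edge belong to the cell to the north/east (half-open
#' cells), except at the domain's upper bounds where they fall in the last
#' cell. Points outside the grid get NA.
#'
#' @param grid a [GridSpec-class].
#' @param lon,lat point coordinates (degrees).
#' @return data.frame with integer columns \code{row} (latitude index,
#'   south-first) and \code{col} (longitude index), plus \code{cell}, the
#'   linearized single index \code{(col - 1) * nLat + row}.
#' @export
cellIndex <- function(grid, lon, lat) {
  row <- floor((lat - grid@latMin) / grid@cellSize) + 1
  col <- floor((lon - grid@lonMin) / grid@cellSize) + 1
  row[lat == grid@latMax] <- nLat(grid)
  col[lon == grid@lonMax] <- nLon(grid)
  bad <- lat < grid@latMin | lat > grid@latMax | lon < grid@lonMin |
    lon > grid@lonMax | is.na(lat) | is.na(lon)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1) * nLat(grid) + row))
}

#' Spherical cell areas
#'
#' Exact spherical area of each grid cell: for a cell spanning longitudes of
#' width dlon degrees between latitudes phi1 < phi2,
#' A = (pi/180) * dlon * R^2 * (sin(phi2) - sin(phi1)). Because the grid is
#' regular in lon/lat, area depends on latitude only; summing a full
#' latitude band reproduces the spherical-zone closed form
#' 2*pi*R^2*(sin(phi2)-sin(phi1)) exactly. These areas are what an equal-area
#' projection would preserve, so all area and centroid statistics computed
#' with them are equal-area by construction.
#'
#' @param grid a [GridSpec-class].
#' @param R Earth radius in km (default 6371).
#' @return nLat x nLon matrix of areas in km^2.
#' @export
cellAreas <- function(grid, R = 6371) {
  lats <- grid@latMin + (seq_len(nLat(grid)) - 1) * grid@cellSize
  phi1 <- lats * pi / 180
  phi2 <- (lats + grid@cellSize) * pi / 180
  band <- (pi / 180) * grid@cellSize * R^2 * (sin(phi2) - sin(phi1))
  matrix(band, nrow = nLat(grid), ncol = nLon(grid))
}
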