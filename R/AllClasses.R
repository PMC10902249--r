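#' @import methods
NULL

ENV_VARS <- c("sea_ice", "sst", "sss", "t200", "s200", "depth", "npp")

#' Regular longitude/latitude analysis grid
#'
#' Defines the rectilinear grid every raster object in the package lives on.
#' Cells are \code{cellSize} degrees on a side with centers at half-cell
#' offsets; the default covers the Southern Ocean south of 35 degrees S at
#' 1-degree resolution (55 x 360 cells). All raster fields are stored as
#' \code{nLat x nLon} matrices with row 1 at the southernmost latitude.
#'
#' @slot latMin,latMax southern and northern bounds in degrees.
#' @slot lonMin,lonMax western and eastern bounds in degrees (half-open on
#'   the east so the default covers [-180, 180)).
#' @slot cellSize cell edge in degrees.
#' @export
setClass("GridSpec",
  representation(latMin = "numeric", latMax = "numeric",
                 lonMin = "numeric", lonMax = "numeric",
                 cellSize = "numeric"),
  prototype(latMin = -90, latMax = -35, lonMin = -180, lonMax = 180,
            cellSize = 1))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (object@latMin >= object@latMax) msg <- c(msg, "latMin must be < latMax")
  if (object@lonMin >= object@lonMax) msg <- c(msg, "lonMin must be < lonMax")
  if (length(msg) == 0) {
    nl <- (object@latMax - object@latMin) / object@cellSize
    nn <- (object@lonMax - object@lonMin) / object@cellSize
    if (abs(nl - round(nl)) > 1e-9 || abs(nn - round(nn)) > 1e-9)
      msg <- c(msg, "grid extent must be an integer number of cells")
  }
  if (length(msg)) msg else TRUE
})

#' Environmental variable stack for one (ESM, scenario, period)
#'
#' Holds the seven model covariates — sea-ice fraction (%), SST (deg C),
#' sea-surface salinity, temperature and salinity at 200 m, bathymetry (m,
#' negative below sea level) and primary productivity — as matrices on a
#' shared [GridSpec]. Land cells (depth >= 0) are the ocean mask; dynamic
#' fields are NA there.
#'
#' @slot grid the [GridSpec] all fields share.
#' @slot fields named list of nLat x nLon numeric matrices, one per variable.
#' @slot esm,scenario,period provenance labels (e.g. "BGC", "RCP85",
#'   "long_future").
#' @export
setClass("EnvStack",
  representation(grid = "GridSpec", fields = "list",
                 esm = "character", scenario = "character",
                 period = "character"))

setValidity("EnvStack", function(object) {
  msg <- character()
  if (!setequal(names(object@fields), ENV_VARS))
    msg <- c(msg, sprintf("fields must be exactly {%s}",
                          paste(ENV_VARS, collapse = ", ")))
  dims <- c(nLat(object@grid), nLon(object@grid))
  for (v in names(object@fields)) {
    f <- object@fields[[v]]
    if (!is.matrix(f) || !all(dim(f) == dims))
      msg <- c(msg, sprintf("field '%s' must be a %d x %d matrix", v,
                            dims[1], dims[2]))
  }
  if (length(msg) == 0) {
    land <- object@fields$depth >= 0
    ice <- object@fields$sea_ice
    ok <- is.na(ice) | (ice >= 0 & ice <= 100)
    if (!all(ok)) msg <- c(msg, "sea_ice must lie in [0, 100]")
    for (v in setdiff(ENV_VARS, "depth"))
      if (any(!is.na(object@fields[[v]][land])))
        msg <- c(msg, sprintf("dynamic field '%s' must be NA on land", v))
  }
  if (length(msg)) msg else TRUE
})

#' Continuous habitat suitability map
#'
#' Cell values in [0, 1] on ocean cells (NA elsewhere), with provenance
#' identifying the species and the (esm, scenario, period) combination or
#' \code{"ensemble"} for cross-ESM means.
#'
#' @slot grid the [GridSpec].
#' @slot values nLat x nLon matrix of suitabilities in [0, 1] (NA = masked).
#' @slot species,esm,scenario,period provenance labels.
#' @export
setClass("HsiMap",
  representation(grid = "GridSpec", values = "matrix", species = "character",
                 esm = "character", scenario = "character",
                 period = "character"))

setValidity("HsiMap", function(object) {
  v <- object@values
  msg <- character()
  if (!all(dim(v) == c(nLat(object@grid), nLon(object@grid))))
    msg <- c(msg, "values matrix does not match grid dimensions")
  vv <- v[!is.na(v)]
  if (length(vv) && (min(vv) < -1e-12 || max(vv) > 1 + 1e-12))
    msg <- c(msg, "HSI values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Binary suitable/unsuitable habitat map
#'
#' Result of thresholding an [HsiMap] at the top-5% rule; \code{threshold}
#' records the HSI cutoff actually used (minimum suitable value).
#'
#' @slot grid the [GridSpec].
#' @slot suitable logical nLat x nLon matrix (NA = masked cell).
#' @slot threshold HSI cutoff.
#' @slot provenance named list carried from the source map.
#' @export
setClass("BinaryHabitat",
  representation(grid = "GridSpec", suitable = "matrix",
                 threshold = "numeric", provenance = "list"))

setValidity("BinaryHabitat", function(object) {
  msg <- character()
  if (!is.logical(object@suitable))
    msg <- c(msg, "suitable must be a logical matrix")
  if (!all(dim(object@suitable) == c(nLat(object@grid), nLon(object@grid))))
    msg <- c(msg, "suitable matrix does not match grid dimensions")
  if (length(msg)) msg else TRUE
})

#' Species-association (residual correlation) matrix
#'
#' Posterior-mean residual correlations between species from the latent-factor
#' joint model, with a significance mask from 99% highest-posterior-density
#' intervals.
#'
#' @slot correlation J x J symmetric matrix, unit diagonal.
#' @slot significant logical J x J matrix (HPD interval excludes zero).
#' @slot species character vector of species names (row/col order).
#' @export
setClass("AssociationMatrix",
  representation(correlation = "matrix", significant = "matrix",
                 species = "character"))

setValidity("AssociationMatrix", function(object) {
  R <- object@correlation
  msg <- character()
  J <- length(object@species)
  if (!all(dim(R) == c(J, J)))
    msg <- c(msg, "correlation must be J x J for J species")
  else {
    if (max(abs(R - t(R))) > 1e-8) msg <- c(msg, "correlation must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (min(R) < -1 - 1e-8 || max(R) > 1 + 1e-8)
      msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (!all(dim(object@significant) == dim(R)))
    msg <- c(msg, "significance mask must match correlation dimensions")
  if (length(msg)) msg else TRUE
})

#' Protected-area polygon set
#'
#' Simple lon/lat polygons tagged \code{current} (established MPAs) or
#' \code{negotiated} (proposed MPAs). Each polygon is a closed ring stored as
#' a two-column (lon, lat) matrix.
#'
#' @slot polygons list of two-column coordinate matrices.
#' @slot status character vector, one of "current"/"negotiated" per polygon.
#' @slot names polygon names.
#' @export
setClass("ProtectedAreaSet",
  representation(polygons = "list", status = "character", names = "character"))

setValidity("ProtectedAreaSet", function(object) {
  msg <- character()
  n <- length(object@polygons)
  if (length(object@status) != n || length(object@names) != n)
    msg <- c(msg, "polygons, status and names must have equal length")
  if (n && !all(object@status %in% c("current", "negotiated")))
    msg <- c(msg, "status must be 'current' or 'negotiated'")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      msg <- c(msg, "each polygon must be a >=3-row, 2-column matrix")
  }
  if (length(msg)) msg else TRUE
})
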