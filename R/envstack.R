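#' Bilinear regridding of a single field
#'
#' Interpolates a field from one rectilinear lon/lat grid to the cell
#' centers of another. Weights are the standard bilinear ones; where some of
#' the four surrounding source cells are masked (NA) the remaining weights
#' are renormalized, and a target cell whose four neighbours are all masked
#' becomes masked. Target centers outside the source center extent are
#' masked, never extrapolated.
#'
#' @param field matrix on \code{sourceGrid} (nLat x nLon, south-first rows).
#' @param sourceGrid,targetGrid [GridSpec-class] objects.
#' @return matrix on \code{targetGrid}.
#' @export
resampleBilinear <- function(field, sourceGrid, targetGrid) {
  sLat <- latCenters(sourceGrid); sLon <- lonCenters(sourceGrid)
  tLat <- latCenters(targetGrid); tLon <- lonCenters(targetGrid)
  nr <- length(tLat); nc <- length(tLon)
  out <- matrix(NA_real_, nr, nc)
  # fractional index of each target center in source-center coordinates
  fi <- (tLat - sLat[1]) / sourceGrid@cellSize + 1
  fj <- (tLon - sLon[1]) / sourceGrid@cellSize + 1
  for (i in seq_len(nr)) {
    if (fi[i] < 1 - 1e-9 || fi[i] > length(sLat) + 1e-9) next
    i0 <- clip(floor(fi[i]), 1, length(sLat) - 1)
    if (length(sLat) == 1) { i0 <- 1; wi <- 0 } else wi <- fi[i] - i0
    for (j in seq_len(nc)) {
      if (fj[j] < 1 - 1e-9 || fj[j] > length(sLon) + 1e-9) next
      j0 <- clip(floor(fj[j]), 1, length(sLon) - 1)
      if (length(sLon) == 1) { j0 <- 1; wj <- 0 } else wj <- fj[j] - j0
      v <- c(field[i0, j0], field[i0 + 1, j0], field[i0, j0 + 1],
             field[i0 + 1, j0 + 1])
      w <- c((1 - wi) * (1 - wj), wi * (1 - wj), (1 - wi) * wj, wi * wj)
      ok <- !is.na(v)
      if (!any(ok) || sum(w[ok]) <= 0) next
      out[i, j] <- sum(v[ok] * w[ok]) / sum(w[ok])
    }
  }
  out
}

#' Period climatology from annual fields
#'
#' Per-cell arithmetic mean over the years of a named period. The three
#' canonical periods are present 1956-2005, short_future 2006-2055 and
#' long_future 2050-2099. Errors if any period year is missing, listing
#' the missing years.
#'
#' @param annualFields named list of matrices; names are years.
#' @param period one of "present", "short_future", "long_future", or an
#'   integer vector of years.
#' @return matrix of per-cell means.
#' @export
periodClimatology <- function(annualFields, period) {
  years <- periodYears(period)
  have <- as.integer(names(annualFields))
  missing <- setdiff(years, have)
  if (length(missing))
    stopf("period not fully covered; missing years: %s",
          paste(missing, collapse = ", "))
  sel <- annualFields[as.character(years)]
  Reduce(`+`, sel) / length(sel)
}

#' @rdname periodClimatology
#' @export
periodYears <- function(period) {
  if (is.numeric(period)) return(as.integer(period))
  switch(period,
         present = 1956:2005,
         short_future = 2006:2055,
         long_future = 2050:2099,
         stopf("unknown period '%s'", period))
}

#' Extract model covariates at point locations
#'
#' Nearest-cell lookup of all seven variables for each point (points were
#' already rarefied to grid cells, so interpolation would add nothing).
#' Rows with any missing covariate — points on masked cells or outside the
#' grid — are dropped and counted.
#'
#' @param stack an [EnvStack-class].
#' @param points data.frame with columns longitude, latitude.
#' @param label optional 0/1 label attached as column \code{label}.
#' @return data.frame with the seven covariate columns (and \code{label} if
#'   given) plus attribute \code{dropped}, the number of removed rows.
#' @export
extractFeatures <- function(stack, points, label = NULL) {
  vars <- ENV_VARS
  if (nrow(points) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric()), length(vars)), vars))
    if (!is.null(label)) out$label <- integer()
    return(structure(out, dropped = 0L))
  }
  ci <- cellIndex(stack@grid, points$longitude, points$latitude)
  out <- as.data.frame(lapply(stats::setNames(vars, vars), function(v) {
    f <- stack@fields[[v]]
    val <- rep(NA_real_, nrow(points))
    ok <- !is.na(ci$row)
    val[ok] <- f[cbind(ci$row[ok], ci$col[ok])]
    val
  }))
  if (!is.null(label)) out$label <- rep_len(label, nrow(out))
  keep <- stats::complete.cases(out[vars])
  structure(out[keep, , drop = FALSE], dropped = sum(!keep))
}
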