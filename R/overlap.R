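#' Cellwise mean of habitat-suitability maps
#'
#' Unweighted mean over a set of species maps sharing a grid — the "mean
#' HSI" surface whose top-5% cells are the community's important areas.
#'
#' @param speciesMaps list of [HsiMap-class] on the same grid.
#' @return an [HsiMap-class] with species \code{"mean"}.
#' @export
meanHsi <- function(speciesMaps) {
  stopifnot(length(speciesMaps) >= 1)
  g <- speciesMaps[[1]]@grid
  for (m in speciesMaps) if (!identical(m@grid, g)) stopf("grid mismatch")
  vals <- Reduce(`+`, lapply(speciesMaps, function(m) m@values)) /
    length(speciesMaps)
  ref <- speciesMaps[[1]]
  new("HsiMap", grid = g, values = vals, species = "mean", esm = ref@esm,
      scenario = ref@scenario, period = ref@period)
}

#' Identify important areas (IAs)
#'
#' Applies the top-5% rule to a (mean) suitability map; the result carries
#' IA provenance. The krill pipeline uses the same rule on its single
#' species map.
#'
#' @param meanMap an [HsiMap-class].
#' @param fraction top fraction retained (default 0.05).
#' @return a [BinaryHabitat-class].
#' @export
identifyIas <- function(meanMap, fraction = 0.05) {
  b <- binarizeTop5(meanMap, fraction = fraction)
  b@provenance$role <- "IAs, top 5% HSI"
  b
}

#' Rasterize protected-area polygons to per-status masks
#'
#' A grid cell is covered when its center lies inside (or on the boundary
#' of) any polygon of that status; where current and negotiated polygons
#' overlap, the cell counts as current only.
#'
#' @param pas a [ProtectedAreaSet-class].
#' @param grid a [GridSpec-class].
#' @return list(current, negotiated): logical nLat x nLon matrices.
#' @export
rasterizePas <- function(pas, grid) {
  nr <- nLat(grid); nc <- nLon(grid)
  lat <- rep(latCenters(grid), nc)
  lon <- rep(lonCenters(grid), each = nr)
  masks <- list(current = matrix(FALSE, nr, nc),
                negotiated = matrix(FALSE, nr, nc))
  for (i in seq_along(pas@polygons)) {
    p <- pas@polygons[[i]]
    if (anyNA(p)) stopf("invalid geometry in polygon '%s'", pas@names[i])
    inside <- pracma::inpolygon(lon, lat, p[, 1], p[, 2], boundary = TRUE)
    masks[[pas@status[i]]] <- masks[[pas@status[i]]] |
      matrix(inside, nr, nc)
  }
  masks$negotiated <- masks$negotiated & !masks$current
  masks
}

#' Protected-area coverage of important areas
#'
#' Splits the IA area into the share under current protection, under
#' negotiated (proposed) protection, and outside any protected area;
#' percentages are area-weighted by spherical cell areas (pass a matrix of
#' ones for plain cell-count percentages) and always sum to 100.
#'
#' @param ia a [BinaryHabitat-class] of important areas.
#' @param masks per-status masks from [rasterizePas()].
#' @param areas cell-area matrix from [cellAreas()] (a matrix of ones gives
#'   cell-count percentages).
#' @return data.frame(category, area, pct) with categories current /
#'   negotiated / outside.
#' @export
overlapReport <- function(ia, masks, areas = cellAreas(ia@grid)) {
  sel <- !is.na(ia@suitable) & ia@suitable
  total <- sum(areas[sel])
  if (total <= 0) stopf("important-area set is empty")
  cur <- sum(areas[sel & masks$current])
  neg <- sum(areas[sel & masks$negotiated & !masks$current])
  out <- total - cur - neg
  data.frame(category = c("current", "negotiated", "outside"),
             area = c(cur, neg, out),
             pct = 100 * c(cur, neg, out) / total)
}

#' Intersection of two important-area sets
#'
#' Cellwise conjunction of, e.g., the meso-fish and krill IA maps, with the
#' spherical area of the shared cells.
#'
#' @param iaFish,iaKrill [BinaryHabitat-class] on the same grid.
#' @param areas cell-area matrix from [cellAreas()].
#' @return list(mask, area) — logical matrix and overlap area in km^2.
#' @export
iaIntersection <- function(iaFish, iaKrill, areas = cellAreas(iaFish@grid)) {
  if (!identical(iaFish@grid, iaKrill@grid)) stopf("grid mismatch")
  a <- !is.na(iaFish@suitable) & iaFish@suitable
  b <- !is.na(iaKrill@suitable) & iaKrill@suitable
  mask <- a & b
  list(mask = mask, area = sum(areas[mask]))
}
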