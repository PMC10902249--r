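#' Binarize a suitability map at the top-5% rule
#'
#' Ranks valid cells by HSI descending and marks the top ceiling(fraction*N)
#' cells suitable. The threshold tau is the minimum suitable HSI and every
#' cell tied with tau is included, so ties can push the count above
#' ceiling(fraction*N). A map with all-equal HSI is rejected as degenerate.
#' (The alternative fixed-value reading — suitable when HSI >= 0.95 — is
#' available via \code{rule = "fixed"}.)
#'
#' @param hsi an [HsiMap-class].
#' @param fraction fraction of valid cells kept (default 0.05).
#' @param rule "percentile" (default) or "fixed" (threshold =
#'   \code{fixedThreshold}).
#' @param fixedThreshold HSI cutoff used when \code{rule = "fixed"}.
#' @return a [BinaryHabitat-class].
#' @export
binarizeTop5 <- function(hsi, fraction = 0.05, rule = c("percentile", "fixed"),
                         fixedThreshold = 0.95) {
  rule <- match.arg(rule)
  v <- hsi@values
  valid <- which(!is.na(v))
  if (length(valid) == 0) stopf("map has no valid cells")
  vv <- v[valid]
  if (rule == "percentile") {
    if (max(vv) == min(vv)) stopf("degenerate suitability: all cells equal")
    k <- ceiling(fraction * length(valid))
    tau <- sort(vv, decreasing = TRUE)[k]
  } else tau <- fixedThreshold
  suit <- matrix(NA, nrow(v), ncol(v))
  suit[valid] <- vv >= tau
  new("BinaryHabitat", grid = hsi@grid, suitable = suit, threshold = tau,
      provenance = list(species = hsi@species, esm = hsi@esm,
                        scenario = hsi@scenario, period = hsi@period,
                        rule = rule, fraction = fraction))
}

#' Gain/loss/stability change map between two binary habitats
#'
#' Cellwise comparison of present and future suitable/unsuitable maps:
#' gain = newly suitable, loss = no longer suitable, stability = suitable in
#' both, never = suitable in neither. The four categories partition the
#' valid cells.
#'
#' @param present,future [BinaryHabitat-class] on the same grid.
#' @return matrix of factor-coded categories ("gain", "loss", "stability",
#'   "never"; NA on masked cells) with attribute \code{counts}.
#' @export
changeMap <- function(present, future) {
  if (!identical(present@grid, future@grid)) stopf("grid mismatch")
  p <- present@suitable; f <- future@suitable
  out <- matrix(NA_character_, nrow(p), ncol(p))
  valid <- !is.na(p) & !is.na(f)
  out[valid & !p & f] <- "gain"
  out[valid & p & !f] <- "loss"
  out[valid & p & f] <- "stability"
  out[valid & !p & !f] <- "never"
  structure(out, counts = c(gain = sum(out == "gain", na.rm = TRUE),
                            loss = sum(out == "loss", na.rm = TRUE),
                            stability = sum(out == "stability", na.rm = TRUE),
                            never = sum(out == "never", na.rm = TRUE)))
}

#' Regional habitat-area change report
#'
#' Suitable-habitat area (km^2, spherical cell areas) for present and
#' future maps and the percentage change, for the whole Southern Ocean and
#' its western ([-180, split)) and eastern ([split, 180)) halves. The
#' default split meridian 0 puts the Antarctic Peninsula in the west and
#' East Antarctica in the east. A region with zero present area gets
#' \code{NA} percentage and \code{undefined = TRUE}.
#'
#' @param present,future [BinaryHabitat-class] on the same grid.
#' @param areas cell-area matrix from [cellAreas()].
#' @param splitLon boundary meridian between western and eastern halves.
#' @return data.frame(region, presentArea, futureArea, pctChange, undefined).
#' @export
areaChange <- function(present, future, areas = cellAreas(present@grid),
                       splitLon = 0) {
  if (!identical(present@grid, future@grid)) stopf("grid mismatch")
  g <- present@grid
  lon <- matrix(lonCenters(g), nLat(g), nLon(g), byrow = TRUE)
  regions <- list(SO = lon >= g@lonMin,
                  western_SO = lon < splitLon,
                  eastern_SO = lon >= splitLon)
  rows <- lapply(names(regions), function(rg) {
    sel <- regions[[rg]]
    aP <- sum(areas[sel & !is.na(present@suitable) & present@suitable])
    aF <- sum(areas[sel & !is.na(future@suitable) & future@suitable])
    und <- aP == 0
    data.frame(region = rg, presentArea = aP, futureArea = aF,
               pctChange = if (und) NA_real_ else 100 * (aF - aP) / aP,
               undefined = und)
  })
  do.call(rbind, rows)
}

#' Area-weighted centroid latitude and its shift
#'
#' The suitable-habitat centroid latitude is the spherical-area-weighted
#' mean cell-center latitude over suitable cells; the shift is future minus
#' present, so a negative shift is poleward in the Southern Hemisphere.
#'
#' @param present,future [BinaryHabitat-class] on the same grid.
#' @param areas cell-area matrix from [cellAreas()].
#' @return list(presentCentroid, futureCentroid, shift, poleward).
#' @export
centroidShift <- function(present, future, areas = cellAreas(present@grid)) {
  if (!identical(present@grid, future@grid)) stopf("grid mismatch")
  cp <- centroidLatitude(present, areas)
  cf <- centroidLatitude(future, areas)
  list(presentCentroid = cp, futureCentroid = cf, shift = cf - cp,
       poleward = (cf - cp) < 0)
}

#' @rdname centroidShift
#' @param habitat a [BinaryHabitat-class].
#' @export
centroidLatitude <- function(habitat, areas = cellAreas(habitat@grid)) {
  g <- habitat@grid
  latM <- matrix(latCenters(g), nLat(g), nLon(g))
  sel <- !is.na(habitat@suitable) & habitat@suitable
  if (!any(sel)) stopf("habitat has no suitable cells")
  sum(areas[sel] * latM[sel]) / sum(areas[sel])
}
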