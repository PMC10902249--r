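#' Clean raw presence-only occurrence records
#'
#' Applies the record-quality rules used for Southern Ocean presence data:
#' drops records with missing or out-of-range coordinates, records before
#' 1955, records north of 35 degrees S, preserved specimens, and records
#' falling on land cells of the analysis bathymetry. Every dropped record is
#' attributed to exactly one reason (checked in the order listed) and the
#' per-reason counts are returned alongside the surviving records.
#'
#' @param raw data.frame with columns species, longitude, latitude, year,
#'   basis_flag.
#' @param stack an [EnvStack-class] supplying the grid and land mask.
#' @param minYear earliest admissible record year (default 1955).
#' @param maxLat northern latitude limit (default -35).
#' @return list with \code{records} (the cleaned data.frame) and \code{log}
#'   (named integer vector of drop counts: invalid_coords, pre_cutoff_year,
#'   north_of_limit, preserved_specimen, on_land, kept).
#' @export
filterRecords <- function(raw, stack, minYear = 1955, maxLat = -35) {
  need <- c("species", "longitude", "latitude", "year", "basis_flag")
  if (!all(need %in% names(raw)))
    stopf("raw records must have columns: %s", paste(need, collapse = ", "))
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  badCoord <- is.na(raw$longitude) | is.na(raw$latitude) |
    abs(raw$longitude) > 180 | abs(raw$latitude) > 90
  reason[badCoord] <- "invalid_coords"
  old <- is.na(reason) & (is.na(raw$year) | raw$year < minYear)
  reason[old] <- "pre_cutoff_year"
  north <- is.na(reason) & raw$latitude > maxLat
  reason[north] <- "north_of_limit"
  spec <- is.na(reason) & raw$basis_flag == "preserved_specimen"
  reason[spec] <- "preserved_specimen"
  idx <- which(is.na(reason))
  if (length(idx)) {
    ci <- cellIndex(stack@grid, raw$longitude[idx], raw$latitude[idx])
    ocean <- oceanMask(stack)
    outside <- is.na(ci$row)
    onLand <- !outside & !ocean[cbind(ci$row[!outside], ci$col[!outside])]
    landIdx <- idx[!outside][onLand]
    reason[idx[outside]] <- "invalid_coords"  # outside the analysis grid
    reason[landIdx] <- "on_land"
  }
  keep <- is.na(reason)
  log <- c(invalid_coords = sum(reason == "invalid_coords", na.rm = TRUE),
           pre_cutoff_year = sum(reason == "pre_cutoff_year", na.rm = TRUE),
           north_of_limit = sum(reason == "north_of_limit", na.rm = TRUE),
           preserved_specimen = sum(reason == "preserved_specimen", na.rm = TRUE),
           on_land = sum(reason == "on_land", na.rm = TRUE),
           kept = sum(keep))
  list(records = raw[keep, , drop = FALSE], log = log)
}

#' Deduplicate and spatially rarefy occurrences to one record per cell
#'
#' Removes exact duplicate rows, then collapses all records within each
#' 1-degree grid cell to a single record at the arithmetic mean coordinates
#' of the cell's records (longitudes averaged circularly so the dateline is
#' handled) with the rounded mean year. The output has at most one record
#' per grid cell.
#'
#' @param clean data.frame of filtered records.
#' @param grid a [GridSpec-class].
#' @return rarefied data.frame, row order by grid cell index.
#' @export
dedupeAndRarefy <- function(clean, grid) {
  if (nrow(clean) == 0) return(clean)
  clean <- unique(clean)
  ci <- cellIndex(grid, clean$longitude, clean$latitude)
  if (anyNA(ci$cell))
    stopf("%d record(s) outside grid bounds; filter first", sum(is.na(ci$cell)))
  parts <- split(seq_len(nrow(clean)), ci$cell)
  rows <- lapply(parts, function(ix) {
    r <- clean[ix, , drop = FALSE]
    data.frame(species = r$species[1],
               longitude = lonMean(r$longitude),
               latitude = mean(r$latitude),
               year = as.integer(round(mean(r$year))),
               basis_flag = r$basis_flag[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full occurrence preparation: filter then dedupe/rarefy
#'
#' @inheritParams filterRecords
#' @return list(records, log) as in [filterRecords()], with records rarefied
#'   to one per cell.
#' @export
prepOccurrences <- function(raw, stack, minYear = 1955, maxLat = -35) {
  f <- filterRecords(raw, stack, minYear = minYear, maxLat = maxLat)
  list(records = dedupeAndRarefy(f$records, stack@grid), log = f$log)
}
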