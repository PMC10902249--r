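#' Synthetic circumpolar environmental stack
#'
#' Builds a present-day (1956-2005) seven-variable stack on the analysis grid
#' with known, recoverable structure: SST declines linearly poleward with a
#' smooth zonal perturbation and seeded Gaussian noise; sea-ice fraction
#' rises poleward along a logistic front; temperature at 200 m tracks SST;
#' salinity fields carry weak latitudinal gradients; primary productivity
#' peaks in mid-latitudes. Bathymetry is a fixed synthetic bowl with a
#' continental shelf/slope ring around a pole-centred landmass whose edge
#' undulates with longitude, so shelf and open-ocean cells both exist.
#' Land cells (depth >= 0) are NA in all dynamic fields.
#'
#' @param grid a [GridSpec-class] (default: 1-degree grid south of 35 S).
#' @param seed integer seed for the noise fields.
#' @param sstNorth SST (deg C) at the northern grid edge.
#' @param sstSlope SST change per degree latitude moving north (deg C/deg;
#'   positive means colder poleward).
#' @param zonalAmp amplitude (deg C) of the smooth zonal SST perturbation.
#' @param noiseSd named numeric vector of Gaussian noise SDs per dynamic
#'   variable (defaults chosen to be small relative to each gradient).
#' @return an [EnvStack-class] with esm "truth", scenario "historical",
#'   period "present".
#' @export
makeEnvGrid <- function(grid = gridSpec(), seed = 1,
                        sstNorth = 12, sstSlope = 0.45, zonalAmp = 0.5,
                        noiseSd = c(sst = 0.3, t200 = 0.2, sea_ice = 2,
                                    sss = 0.05, s200 = 0.05, npp = 20)) {
  validObject(grid)
  if (nLat(grid) < 2 || nLon(grid) < 2)
    stopf("grid must have at least 2 cells in each direction")
  lat <- latCenters(grid); lon <- lonCenters(grid)
  nr <- nLat(grid); nc <- nLon(grid)
  latM <- matrix(lat, nr, nc)
  lonM <- matrix(lon, nr, nc, byrow = TRUE)
  lonR <- lonM * pi / 180

  depth <- syntheticBathymetry(latM, lonR)
  land <- depth >= 0

  set.seed(childSeed(seed, "env-noise"))
  noise <- function(v) matrix(stats::rnorm(nr * nc, 0, noiseSd[[v]]), nr, nc)

  sstBase <- sstNorth + sstSlope * (latM - grid@latMax) + zonalAmp * sin(2 * lonR)
  sst <- sstBase + noise("sst")
  ice <- clip(100 * stats::plogis(-(latM + 62) / 3) + noise("sea_ice"), 0, 100)
  t200 <- 0.7 * sstBase - 0.5 + noise("t200")
  sss <- 34 - 0.015 * (latM - grid@latMax) + 0.1 * cos(lonR) + noise("sss")
  s200 <- 34.6 + 0.004 * (latM - grid@latMax) + noise("s200")
  npp <- pmax(600 * exp(-((latM + 55) / 10)^2) + 50 + noise("npp"), 0)

  fields <- list(sea_ice = ice, sst = sst, sss = sss, t200 = t200,
                 s200 = s200, depth = depth, npp = npp)
  for (v in setdiff(names(fields), "depth")) fields[[v]][land] <- NA_real_
  new("EnvStack", grid = grid, fields = fields, esm = "truth",
      scenario = "historical", period = "present")
}

# Fixed synthetic bathymetry: continent edge undulating with longitude,
# shelf ring (-400 m), slope down to a -3800 m abyssal bowl.
syntheticBathymetry <- function(latM, lonR) {
  edge <- -74 + 3 * sin(3 * lonR)
  d <- -3800 - 200 * cos(2 * lonR)
  shelf <- latM > edge & latM <= edge + 3
  slope <- latM > edge + 3 & latM <= edge + 6
  d[shelf] <- -400
  frac <- (latM - (edge + 3)) / 3
  d[slope] <- (-400 - 3400 * frac)[slope]
  d[latM <= edge] <- 300
  d
}

#' Climate-scenario change fields
#'
#' A ScenarioDelta bundles additive per-variable change fields for one
#' (scenario, period) and the amplitude of per-ESM perturbations. The
#' built-in defaults follow CMIP5-scale Southern Ocean changes: modest
#' warming and ice loss under RCP4.5, roughly doubled under RCP8.5 by the
#' long-term future. A zero delta with zero ESM amplitude reproduces the
#' present stack bit for bit.
#'
#' @param scenario "RCP45" or "RCP85".
#' @param period "short_future" (2006-2055) or "long_future" (2050-2099).
#' @param deltas named numeric (or matrix) additive changes per dynamic
#'   variable; NULL uses the built-in defaults for (scenario, period).
#' @param esmAmplitude multiplier (>= 0) on the per-ESM perturbation SDs;
#'   0 makes all ESM variants identical.
#' @return list of class "ScenarioDelta".
#' @export
scenarioDelta <- function(scenario, period, deltas = NULL, esmAmplitude = 1) {
  if (!scenario %in% c("RCP45", "RCP85"))
    stopf("unknown scenario '%s' (expected RCP45 or RCP85)", scenario)
  if (!period %in% c("short_future", "long_future"))
    stopf("unknown period '%s' (expected short_future or long_future)", period)
  if (is.null(deltas)) {
    defaults <- list(
      RCP45 = list(
        short_future = c(sst = 0.6, t200 = 0.4, sea_ice = -4, sss = -0.05,
                         s200 = -0.02, npp = -15),
        long_future = c(sst = 1.2, t200 = 0.8, sea_ice = -8, sss = -0.1,
                        s200 = -0.05, npp = -30)),
      RCP85 = list(
        short_future = c(sst = 0.9, t200 = 0.6, sea_ice = -6, sss = -0.08,
                         s200 = -0.03, npp = -20),
        long_future = c(sst = 2.2, t200 = 1.5, sea_ice = -15, sss = -0.15,
                        s200 = -0.08, npp = -50)))
    deltas <- as.list(defaults[[scenario]][[period]])
  }
  bad <- setdiff(names(deltas), setdiff(ENV_VARS, "depth"))
  if (length(bad)) stopf("delta for unknown/static variable: %s",
                         paste(bad, collapse = ", "))
  structure(list(scenario = scenario, period = period, deltas = as.list(deltas),
                 esmAmplitude = esmAmplitude),
            class = "ScenarioDelta")
}

#' @rdname scenarioDelta
#' @export
zeroDelta <- function(scenario = "RCP45", period = "short_future")
  scenarioDelta(scenario, period,
                deltas = stats::setNames(as.list(rep(0, 6)),
                                         setdiff(ENV_VARS, "depth")),
                esmAmplitude = 0)

# Per-variable SDs (natural units) of the seeded ESM perturbation fields,
# scaled by delta$esmAmplitude.
ESM_PERTURB_SD <- c(sst = 0.15, t200 = 0.1, sea_ice = 2, sss = 0.02,
                    s200 = 0.02, npp = 10)

#' Project a present stack to a future scenario
#'
#' Adds the delta's change field to every dynamic variable, then a seeded
#' Gaussian perturbation specific to \code{esmId} (emulating spread between
#' Earth System Models), then clips sea ice to [0, 100]. Bathymetry is
#' static. Given the same seed, each esmId always produces the same
#' perturbation, and different esmIds produce distinct ones.
#'
#' @param present an [EnvStack-class] with period "present".
#' @param delta a [scenarioDelta()] object.
#' @param esmId label for the synthetic ESM variant (e.g. "BGC").
#' @param seed integer master seed for the perturbations.
#' @return a future [EnvStack-class] tagged (esmId, scenario, period).
#' @export
applyScenario <- function(present, delta, esmId = "BGC", seed = 1) {
  stopifnot(is(present, "EnvStack"), inherits(delta, "ScenarioDelta"))
  if (present@period != "present")
    stopf("applyScenario expects a present-period stack, got '%s'",
          present@period)
  nr <- nLat(present@grid); nc <- nLon(present@grid)
  land <- present@fields$depth >= 0
  set.seed(childSeed(seed, paste0("esm:", esmId, ":", delta$scenario, ":",
                                  delta$period)))
  fields <- present@fields
  for (v in setdiff(ENV_VARS, "depth")) {
    d <- delta$deltas[[v]]
    if (is.null(d)) d <- 0
    pert <- if (delta$esmAmplitude > 0)
      matrix(stats::rnorm(nr * nc, 0, delta$esmAmplitude * ESM_PERTURB_SD[[v]]),
             nr, nc)
    else 0
    f <- fields[[v]] + d + pert
    if (v == "sea_ice") f <- clip(f, 0, 100)
    f[land] <- NA_real_
    fields[[v]] <- f
  }
  new("EnvStack", grid = present@grid, fields = fields, esm = esmId,
      scenario = delta$scenario, period = delta$period)
}

#' Per-ESM present-day stack variants
#'
#' Emulates the spread between Earth System Models for the present period:
#' each esmId gets its own seeded additive Gaussian perturbation of every
#' dynamic field (SD = amplitude x the per-variable scale used by
#' [applyScenario()]), with sea ice clipped to [0, 100]. Amplitude 0
#' returns the input stack retagged only.
#'
#' @param present an [EnvStack-class] with period "present".
#' @param esmId label of the variant.
#' @param seed master integer seed.
#' @param amplitude perturbation scale multiplier (default 1).
#' @return an [EnvStack-class] tagged with \code{esmId}, period "present".
#' @export
esmVariant <- function(present, esmId, seed = 1, amplitude = 1) {
  stopifnot(is(present, "EnvStack"))
  if (present@period != "present")
    stopf("esmVariant expects a present-period stack")
  nr <- nLat(present@grid); nc <- nLon(present@grid)
  land <- present@fields$depth >= 0
  set.seed(childSeed(seed, paste0("esm-present:", esmId)))
  fields <- present@fields
  if (amplitude > 0) {
    for (v in setdiff(ENV_VARS, "depth")) {
      f <- fields[[v]] +
        matrix(stats::rnorm(nr * nc, 0, amplitude * ESM_PERTURB_SD[[v]]), nr, nc)
      if (v == "sea_ice") f <- clip(f, 0, 100)
      f[land] <- NA_real_
      fields[[v]] <- f
    }
  }
  new("EnvStack", grid = present@grid, fields = fields, esm = esmId,
      scenario = present@scenario, period = "present")
}

#' Gaussian niche specification and suitability
#'
#' A niche is a product of independent Gaussian responses: suitability
#' s(x) = exp(-sum_v w_v (x_v - mu_v)^2 / (2 sigma_v^2)), which is 1 at the
#' joint optimum and falls off with distance scaled by each tolerance.
#'
#' @param optima named numeric vector of per-variable optima (natural units).
#' @param tolerances named numeric vector of Gaussian SDs (same names).
#' @param weights named nonnegative weights (default 1 each).
#' @param detectionRate expected presences per unit summed suitability, used
#'   by [sampleOccurrences()] when \code{n} is not given.
#' @return list of class "NicheSpec".
#' @export
nicheSpec <- function(optima, tolerances, weights = NULL, detectionRate = 1) {
  vars <- names(optima)
  if (is.null(vars) || !all(vars %in% ENV_VARS))
    stopf("niche optima must be named with environmental variables")
  if (!identical(sort(vars), sort(names(tolerances))))
    stopf("optima and tolerances must share names")
  if (any(tolerances <= 0)) stopf("tolerances must be positive")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(vars)), vars)
  if (any(weights < 0)) stopf("weights must be nonnegative")
  structure(list(optima = optima, tolerances = tolerances[vars],
                 weights = weights[vars], detectionRate = detectionRate),
            class = "NicheSpec")
}

#' @rdname nicheSpec
#' @param stack an [EnvStack-class].
#' @param niche a [nicheSpec()].
#' @return for \code{nicheSuitability}: matrix of suitabilities in (0, 1]
#'   on ocean cells with complete covariates, NA elsewhere.
#' @export
nicheSuitability <- function(stack, niche) {
  stopifnot(inherits(niche, "NicheSpec"))
  q <- 0
  for (v in names(niche$optima)) {
    x <- envField(stack, v)
    q <- q + niche$weights[[v]] * (x - niche$optima[[v]])^2 /
      (2 * niche$tolerances[[v]]^2)
  }
  s <- exp(-q)
  s[!oceanMask(stack)] <- NA_real_
  s
}

#' Sample presence-only occurrences from a known niche
#'
#' Draws presence records from ocean cells with probability proportional to
#' the niche suitability, with uniform jitter inside the chosen cell and
#' record years uniform over 1955-2005 (the present-day window). The true
#' niche is attached as an attribute for recovery testing. Cells can repeat,
#' as in raw survey data; spatial rarefaction is downstream's job.
#'
#' @param stack an [EnvStack-class].
#' @param niche a [nicheSpec()].
#' @param n number of records; if NULL, drawn as
#'   Poisson(detectionRate * summed suitability).
#' @param seed integer seed.
#' @param species species name for the records.
#' @return data.frame(species, longitude, latitude, year, basis_flag) with
#'   attribute \code{niche}.
#' @export
sampleOccurrences <- function(stack, niche, n = NULL, seed = 1,
                              species = "synthetic_sp") {
  s <- nicheSuitability(stack, niche)
  ok <- which(!is.na(s) & s > 0)
  tot <- sum(s[ok])
  if (length(ok) == 0 || tot <= 0 || !is.finite(tot))
    stopf("degenerate niche: suitability is zero everywhere")
  set.seed(childSeed(seed, paste0("occ:", species)))
  if (is.null(n)) n <- stats::rpois(1, niche$detectionRate * tot)
  if (n < 0) stopf("n must be >= 0")
  emptyOcc <- data.frame(species = character(), longitude = numeric(),
                         latitude = numeric(), year = integer(),
                         basis_flag = character())
  if (n == 0) return(structure(emptyOcc, niche = niche))
  cells <- sample(ok, n, replace = TRUE, prob = s[ok])
  g <- stack@grid
  nr <- nLat(g)
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  lat <- g@latMin + (row - 1 + stats::runif(n)) * g@cellSize
  lon <- g@lonMin + (col - 1 + stats::runif(n)) * g@cellSize
  out <- data.frame(species = species, longitude = lon, latitude = lat,
                    year = sample(1955:2005, n, replace = TRUE),
                    basis_flag = "observation")
  structure(out, niche = niche)
}

#' Default synthetic species community
#'
#' Nine niche specifications emulating the structure of the Southern Ocean
#' mesopelagic community the pipeline targets: five lanternfish-like species
#' with temperature-led niches spanning the Polar Frontal Zone, and four
#' high-Antarctic species led by sea-ice fraction (one with a shelf depth
#' preference). The warm-edge species (K_anderssoni-like) is the canonical
#' subject for poleward-shift tests.
#'
#' @return named list of [nicheSpec()] objects.
#' @export
defaultSpeciesNiches <- function() {
  list(
    E_antarctica = nicheSpec(c(sst = 1.5, sea_ice = 40),
                             c(sst = 2.5, sea_ice = 35)),
    K_anderssoni = nicheSpec(c(sst = 3), c(sst = 1.8)),
    G_braueri = nicheSpec(c(sst = 2.5), c(sst = 2.0)),
    G_nicholsi = nicheSpec(c(sst = 4), c(sst = 1.8)),
    G_opisthopterus = nicheSpec(c(sst = 1.0, sea_ice = 50),
                                c(sst = 2.0, sea_ice = 30)),
    N_coatsi = nicheSpec(c(sea_ice = 80, sst = -0.5),
                         c(sea_ice = 25, sst = 2.0)),
    P_antarctica = nicheSpec(c(sea_ice = 90, depth = -400),
                             c(sea_ice = 20, depth = 600)),
    B_antarcticus = nicheSpec(c(sea_ice = 75), c(sea_ice = 25)),
    C_microdon = nicheSpec(c(sea_ice = 85, depth = -600),
                           c(sea_ice = 30, depth = 900)))
}

#' Synthetic protected-area polygons
#'
#' Generates rectangular lon/lat polygons tagged "current" or "negotiated",
#' disjoint across the two statuses, standing in for established and
#' proposed MPAs. Rectangles are placed at seeded random positions within
#' the configured latitude band.
#'
#' @param grid a [GridSpec-class].
#' @param config list with elements \code{current} and \code{negotiated},
#'   each a list(n, lonWidth, latHeight); widths/heights in degrees (may be
#'   length-2 ranges).
#' @param seed integer seed.
#' @param latBand latitude band polygons are placed in.
#' @return a [ProtectedAreaSet-class].
#' @export
makeMpaPolygons <- function(grid = gridSpec(),
                            config = list(current = list(n = 2, lonWidth = 25,
                                                         latHeight = 8),
                                          negotiated = list(n = 3, lonWidth = 30,
                                                            latHeight = 10)),
                            seed = 1, latBand = c(-78, -55)) {
  set.seed(childSeed(seed, "mpa"))
  polys <- list(); status <- character(); nms <- character()
  boxes <- list()  # lon0, lon1, lat0, lat1 for disjointness checks
  for (st in c("current", "negotiated")) {
    cf <- config[[st]]
    if (is.null(cf) || cf$n == 0) next
    for (i in seq_len(cf$n)) {
      w <- if (length(cf$lonWidth) == 2)
        stats::runif(1, cf$lonWidth[1], cf$lonWidth[2]) else cf$lonWidth
      h <- if (length(cf$latHeight) == 2)
        stats::runif(1, cf$latHeight[1], cf$latHeight[2]) else cf$latHeight
      if (w <= 0 || h <= 0) stopf("degenerate (zero-area) polygon requested")
      placed <- FALSE
      for (try in 1:200) {
        lon0 <- stats::runif(1, grid@lonMin, grid@lonMax - w)
        lat0 <- stats::runif(1, latBand[1], latBand[2] - h)
        cand <- c(lon0, lon0 + w, lat0, lat0 + h)
        overlap <- any(vapply(boxes, function(b)
          cand[1] < b[2] && cand[2] > b[1] && cand[3] < b[4] && cand[4] > b[3],
          logical(1)))
        if (!overlap) { placed <- TRUE; break }
      }
      if (!placed) stopf("could not place disjoint polygon %d (%s)", i, st)
      boxes[[length(boxes) + 1]] <- cand
      polys[[length(polys) + 1]] <- rectPolygon(cand[1], cand[2], cand[3], cand[4])
      status <- c(status, st)
      nms <- c(nms, sprintf("%s_%d", st, i))
    }
  }
  new("ProtectedAreaSet", polygons = polys, status = status, names = nms)
}

#' @rdname makeMpaPolygons
#' @param lon0,lon1,lat0,lat1 rectangle bounds in degrees.
#' @return for \code{rectPolygon}: a closed 5 x 2 (lon, lat) ring matrix.
#' @export
rectPolygon <- function(lon0, lon1, lat0, lat1) {
  if (lon1 <= lon0 || lat1 <= lat0) stopf("degenerate (zero-area) rectangle")
  cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
        lat = c(lat0, lat0, lat1, lat1, lat0))
}

#' @rdname makeMpaPolygons
#' @param polygons list of ring matrices.
#' @param status status per polygon.
#' @param names polygon names.
#' @export
protectedAreaSet <- function(polygons, status, names = NULL) {
  if (is.null(names)) names <- sprintf("%s_%d", status, seq_along(polygons))
  new("ProtectedAreaSet", polygons = polygons, status = status, names = names)
}
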