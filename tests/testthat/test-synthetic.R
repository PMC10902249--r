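test_that("present-day stack has the constructed gradients and ranges", {
  s <- defaultStack()
  expect_s4_class(s, "EnvStack")
  expect_equal(dim(envField(s, "sst")), c(55L, 360L))

  ice <- envField(s, "sea_ice")
  expect_true(all(ice[!is.na(ice)] >= 0 & ice[!is.na(ice)] <= 100))

  # noise-free stack: SST strictly decreasing poleward along every meridian
  s0 <- makeEnvGrid(seed = 1, noiseSd = c(sst = 0, t200 = 0, sea_ice = 0,
                                          sss = 0, s200 = 0, npp = 0))
  sst0 <- envField(s0, "sst")
  for (j in c(1, 90, 200, 360)) {
    col <- sst0[, j]
    col <- col[!is.na(col)]
    expect_true(all(diff(col) > 0))  # rows run south -> north
  }
  # sea ice increases poleward (noise-free zonal means)
  ice0 <- rowMeans(envField(s0, "sea_ice"), na.rm = TRUE)
  ice0 <- ice0[!is.nan(ice0)]
  expect_true(all(diff(ice0) <= 1e-9))
})

test_that("zonal-mean SST matches the analytic gradient within noise tolerance", {
  noiseSd <- 0.3
  s <- makeEnvGrid(seed = 5, sstNorth = 12, sstSlope = 0.3, zonalAmp = 0.5,
                   noiseSd = c(sst = noiseSd, t200 = 0.2, sea_ice = 2,
                               sss = 0.05, s200 = 0.05, npp = 20))
  lat <- -50.5  # fully ocean latitude
  i <- which(abs(latCenters(gridSpec()) - lat) < 1e-9)
  zonal <- mean(envField(s, "sst")[i, ])
  analytic <- 12 + 0.3 * (lat - (-35))  # zonal sine averages to ~0
  expect_lt(abs(zonal - analytic), 3 * noiseSd / sqrt(360))
})

test_that("stack generation is deterministic in the seed", {
  a <- makeEnvGrid(seed = 42)
  b <- makeEnvGrid(seed = 42)
  c <- makeEnvGrid(seed = 43)
  expect_identical(a@fields, b@fields)
  expect_false(identical(a@fields$sst, c@fields$sst))
})

test_that("scenario application: identity, exact additivity, clipping, monotonicity", {
  s <- defaultStack()
  # all-zero delta reproduces the stack bit for bit
  z <- applyScenario(s, zeroDelta(), esmId = "BGC", seed = 1)
  expect_identical(z@fields, s@fields)
  expect_equal(z@scenario, "RCP45")

  # uniform +2 C on SST only, no ESM noise: exact cellwise +2
  d2 <- scenarioDelta("RCP85", "long_future", deltas = c(sst = 2),
                      esmAmplitude = 0)
  f2 <- applyScenario(s, d2, esmId = "BGC", seed = 1)
  dd <- f2@fields$sst - s@fields$sst
  expect_equal(max(abs(dd[!is.na(dd)] - 2)), 0)

  # massive negative ice delta clips at zero, never negative
  dIce <- scenarioDelta("RCP85", "long_future", deltas = c(sea_ice = -200),
                        esmAmplitude = 0)
  fI <- applyScenario(s, dIce, esmId = "BGC", seed = 1)
  ice <- fI@fields$sea_ice
  expect_true(all(ice[!is.na(ice)] == 0))

  # larger SST delta dominates pointwise (same seed, same perturbation)
  dA <- scenarioDelta("RCP45", "long_future", deltas = c(sst = 1),
                      esmAmplitude = 1)
  dB <- scenarioDelta("RCP45", "long_future", deltas = c(sst = 3),
                      esmAmplitude = 1)
  fA <- applyScenario(s, dA, esmId = "E2G", seed = 7)
  fB <- applyScenario(s, dB, esmId = "E2G", seed = 7)
  diffs <- fB@fields$sst - fA@fields$sst
  expect_true(all(abs(diffs[!is.na(diffs)] - 2) < 1e-12))

  # four ESM ids give four distinct perturbations
  d <- scenarioDelta("RCP45", "short_future")
  futs <- lapply(c("BGC", "E2G", "E2M", "ES"), function(e)
    applyScenario(s, d, esmId = e, seed = 1))
  ssts <- lapply(futs, function(f) f@fields$sst)
  expect_equal(length(unique(lapply(ssts, digest::digest))), 4L)

  expect_error(scenarioDelta("RCP60", "long_future"), "unknown scenario")
  expect_error(scenarioDelta("RCP45", "mid_future"), "unknown period")
})

test_that("occurrence sampling respects the niche and the ocean mask", {
  s <- defaultStack()
  niche <- nicheSpec(c(sst = -1), c(sst = 1.5))
  occ <- sampleOccurrences(s, niche, n = 500, seed = 3, species = "sp1")
  expect_equal(nrow(occ), 500L)
  # all records on ocean cells inside the grid
  ci <- cellIndex(s@grid, occ$longitude, occ$latitude)
  expect_false(anyNA(ci$row))
  expect_true(all(oceanMask(s)[cbind(ci$row, ci$col)]))
  expect_true(all(occ$year >= 1955 & occ$year <= 2005))

  # mean sampled SST matches the suitability-weighted expectation (oracle:
  # brute-force expectation over all grid cells)
  sst <- envField(s, "sst")
  suit <- nicheSuitability(s, niche)
  ok <- !is.na(suit) & !is.na(sst)
  mu <- sum(suit[ok] * sst[ok]) / sum(suit[ok])
  sd2 <- sum(suit[ok] * (sst[ok] - mu)^2) / sum(suit[ok])
  sampled <- sst[cbind(ci$row, ci$col)]
  expect_lt(abs(mean(sampled) - mu), 3 * sqrt(sd2 / 500) + 0.3)  # + jitter slack

  # n = 0 gives an empty set; zero suitability errors
  expect_equal(nrow(sampleOccurrences(s, niche, n = 0)), 0L)
  farNiche <- nicheSpec(c(sst = 1e6), c(sst = 0.1))
  expect_error(sampleOccurrences(s, farNiche, n = 10), "degenerate niche")

  # determinism
  occ2 <- sampleOccurrences(s, niche, n = 500, seed = 3, species = "sp1")
  expect_identical(occ, occ2)
})

test_that("synthetic MPA polygons are disjoint across statuses and seedable", {
  g <- gridSpec()
  pas <- makeMpaPolygons(g, seed = 9)
  expect_s4_class(pas, "ProtectedAreaSet")
  expect_equal(sum(pas@status == "current"), 2L)
  expect_equal(sum(pas@status == "negotiated"), 3L)
  masks <- rasterizePas(pas, g)
  expect_equal(sum(masks$current & masks$negotiated), 0L)

  pas2 <- makeMpaPolygons(g, seed = 9)
  expect_identical(pas@polygons, pas2@polygons)

  # zero polygons -> empty set; zero-area request errors
  none <- makeMpaPolygons(g, config = list(current = list(n = 0),
                                           negotiated = list(n = 0)))
  expect_length(none@polygons, 0)
  expect_error(rectPolygon(0, 0, -70, -65), "degenerate")

  # grid-aligned 10 x 5 degree rectangle covers exactly 50 cells
  rect <- protectedAreaSet(list(rectPolygon(0, 10, -70, -65)), "current")
  m <- rasterizePas(rect, g)
  expect_equal(sum(m$current), 50L)

  # rasterized area of the grid-aligned rectangle equals the spherical
  # patch closed form
  a <- cellAreas(g)
  patch <- 10 * (pi / 180) * 6371^2 *
    (sin(-65 * pi / 180) - sin(-70 * pi / 180))
  expect_lt(abs(sum(a[m$current]) - patch) / patch, 1e-9)
})
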