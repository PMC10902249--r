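test_that("top-5% binarization: counts, threshold, ties, degenerate input", {
  # 100 distinct values 0.01..1.00 -> 5 suitable, threshold 0.96
  m <- hsiFromMatrix(matrix(seq(0.01, 1, by = 0.01), 10, 10))
  b <- binarizeTop5(m)
  expect_equal(sum(b@suitable), 5L)
  expect_equal(b@threshold, 0.96)
  expect_true(all(m@values[b@suitable] >= 0.96))

  # exact ceil(0.05 N) on distinct maps of several sizes
  for (N in c(20, 100, 400)) {
    mm <- hsiFromMatrix(matrix(seq_len(N) / N, nrow = 4, ncol = N / 4))
    expect_equal(sum(binarizeTop5(mm)@suitable), ceiling(0.05 * N))
  }

  # ties at the cutoff are all included (20 cells, top 3 tied)
  v <- c(seq(0.05, 0.85, length.out = 17), 0.9, 0.9, 0.9)
  mt <- hsiFromMatrix(matrix(v, 4, 5))
  bt <- binarizeTop5(mt)
  expect_equal(sum(bt@suitable), 3L)  # ceil(1) = 1 but all ties included
  expect_equal(bt@threshold, 0.9)

  expect_error(binarizeTop5(hsiFromMatrix(matrix(0.4, 5, 4))), "degenerate")

  # masked cells stay NA and are excluded from the ranking
  vm <- matrix(seq(0.01, 1, by = 0.01), 10, 10)
  vm[1:50] <- NA
  bm <- binarizeTop5(hsiFromMatrix(vm))
  expect_equal(sum(bm@suitable, na.rm = TRUE), ceiling(0.05 * 50))
  expect_true(all(is.na(bm@suitable[1:50])))

  # fixed-rule alternative
  bf <- binarizeTop5(m, rule = "fixed", fixedThreshold = 0.95)
  expect_equal(sum(bf@suitable), 6L)  # 0.95..1.00
})

test_that("change maps partition valid cells with the set identities", {
  g <- gridSpec(-80, -70, 0, 10, 1)
  p <- habitatFromMatrix(matrix(c(rep(TRUE, 30), rep(FALSE, 70)), 10, 10), g)
  # future = present: stability only
  cm <- changeMap(p, p)
  cnt <- attr(cm, "counts")
  expect_equal(unname(cnt["gain"]), 0L)
  expect_equal(unname(cnt["loss"]), 0L)
  expect_equal(unname(cnt["stability"]), 30L)
  # future = complement: no stability
  q <- habitatFromMatrix(!p@suitable, g)
  cnt2 <- attr(changeMap(p, q), "counts")
  expect_equal(unname(cnt2["stability"]), 0L)
  expect_equal(unname(cnt2["gain"]), 70L)
  expect_equal(unname(cnt2["loss"]), 30L)

  # random pairs: partition + Fig-style identities
  set.seed(41)
  for (r in 1:50) {
    a <- habitatFromMatrix(matrix(sample(c(TRUE, FALSE, NA), 100, TRUE,
                                         prob = c(.4, .4, .2)), 10, 10), g)
    b <- habitatFromMatrix(matrix(sample(c(TRUE, FALSE, NA), 100, TRUE,
                                         prob = c(.4, .4, .2)), 10, 10), g)
    cm <- changeMap(a, b)
    cnt <- attr(cm, "counts")
    valid <- !is.na(a@suitable) & !is.na(b@suitable)
    expect_equal(sum(cnt), sum(valid))
    # stability + loss = present suitable; stability + gain = future suitable
    expect_equal(unname(cnt["stability"] + cnt["loss"]),
                 sum(a@suitable & valid, na.rm = TRUE))
    expect_equal(unname(cnt["stability"] + cnt["gain"]),
                 sum(b@suitable & valid, na.rm = TRUE))
  }
  expect_error(changeMap(p, habitatFromMatrix(matrix(TRUE, 5, 5))),
               "grid mismatch")
})

test_that("regional area change matches hand computation and the identity", {
  g <- gridSpec(-80, -70, -10, 10, 1)
  areas <- cellAreas(g)
  base <- matrix(FALSE, 10, 20)
  base[5, 3:6] <- TRUE    # western cells (lon < 0)
  base[5, 15:16] <- TRUE  # eastern cells
  p <- habitatFromMatrix(base, g)
  # identical maps: 0% everywhere
  acSame <- areaChange(p, p, areas)
  expect_true(all(acSame$pctChange == 0))

  # one extra cell of known area
  plus <- base; plus[7, 10] <- TRUE
  f <- habitatFromMatrix(plus, g)
  ac <- areaChange(p, f, areas)
  aCell <- areas[7, 10]
  aPres <- sum(areas[base])
  expect_equal(ac$pctChange[ac$region == "SO"], 100 * aCell / aPres)

  # SO area = west + east exactly; SO change is their area-weighted blend
  expect_equal(ac$presentArea[ac$region == "SO"],
               sum(ac$presentArea[ac$region != "SO"]))
  w <- ac[ac$region == "western_SO", ]; e <- ac[ac$region == "eastern_SO", ]
  blend <- (w$pctChange * w$presentArea + e$pctChange * e$presentArea) /
    (w$presentArea + e$presentArea)
  expect_equal(ac$pctChange[ac$region == "SO"], blend)

  # empty region flagged undefined, not a division error
  westOnly <- matrix(FALSE, 10, 20); westOnly[4, 2] <- TRUE
  ac2 <- areaChange(habitatFromMatrix(westOnly, g),
                    habitatFromMatrix(westOnly, g), areas)
  expect_true(ac2$undefined[ac2$region == "eastern_SO"])
  expect_true(is.na(ac2$pctChange[ac2$region == "eastern_SO"]))
})

test_that("area-weighted centroids match closed-form band centroids", {
  g <- gridSpec()
  areas <- cellAreas(g)
  # single suitable cell at lat -60.5
  single <- matrix(FALSE, 55, 360)
  single[cellIndex(g, 0.5, -60.5)$row, cellIndex(g, 0.5, -60.5)$col] <- TRUE
  expect_equal(centroidLatitude(habitatFromMatrix(single, g), areas), -60.5)

  # full band 60-62 S vs band 64-66 S: shift equals difference of the
  # analytic area-weighted band centroids (cell-center discretization)
  bandRows <- function(lat0, lat1)
    which(latCenters(g) > lat0 & latCenters(g) < lat1)
  mk <- function(rows) {
    m <- matrix(FALSE, 55, 360); m[rows, ] <- TRUE
    habitatFromMatrix(m, g)
  }
  p <- mk(bandRows(-62, -60)); f <- mk(bandRows(-66, -64))
  bandCentroid <- function(lats) {
    wts <- cos(lats * pi / 180)  # cell area proportional to cos(latitude)
    sum(wts * lats) / sum(wts)
  }
  want <- bandCentroid(latCenters(g)[bandRows(-66, -64)]) -
    bandCentroid(latCenters(g)[bandRows(-62, -60)])
  cs <- centroidShift(p, f, areas)
  expect_equal(cs$shift, want, tolerance = 1e-4)
  expect_true(cs$poleward)

  # future = present: zero shift
  expect_equal(centroidShift(p, p, areas)$shift, 0)
  empty <- habitatFromMatrix(matrix(FALSE, 55, 360), g)
  expect_error(centroidShift(empty, p, areas), "no suitable cells")
})
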