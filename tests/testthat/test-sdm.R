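test_that("background sampling is uniform over ocean cells and seeded", {
  s <- defaultStack()
  g <- s@grid
  bg <- sampleBackground(s, 50, seed = 2)
  ci <- cellIndex(g, bg$longitude, bg$latitude)
  expect_true(all(oceanMask(s)[cbind(ci$row, ci$col)]))
  expect_identical(bg, sampleBackground(s, 50, seed = 2))

  # presence cells excluded
  pres <- data.frame(longitude = bg$longitude[1], latitude = bg$latitude[1])
  bg2 <- sampleBackground(s, 5000, seed = 3, presences = pres)
  ci2 <- cellIndex(g, bg2$longitude, bg2$latitude)
  ciP <- cellIndex(g, pres$longitude, pres$latitude)
  expect_false(ciP$cell %in% ci2$cell)

  # latitude histogram of a large draw matches ocean-cell availability
  big <- sampleBackground(s, 10000, seed = 4)
  ciB <- cellIndex(g, big$longitude, big$latitude)
  avail <- table(factor(which(oceanMask(s), arr.ind = TRUE)[, 1],
                        levels = seq_len(nLat(g))))
  got <- table(factor(ciB$row, levels = seq_len(nLat(g))))
  keep <- avail > 0
  p <- suppressWarnings(stats::chisq.test(
    got[keep], p = as.numeric(avail[keep]) / sum(avail[keep])))$p.value
  expect_gt(p, 1e-3)
})

test_that("cross-validation splits are stratified 70/30 partitions", {
  folds <- cvSplit(10, 40, reps = 10, seed = 5)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$trainPres, 7)
    expect_length(f$testPres, 3)
    expect_setequal(c(f$trainPres, f$testPres), 1:10)
    expect_setequal(c(f$trainBack, f$testBack), 1:40)
    expect_length(intersect(f$trainBack, f$testBack), 0)
  }
  expect_identical(folds, cvSplit(10, 40, reps = 10, seed = 5))
  expect_error(cvSplit(1, 40), "at least 2")
})

test_that("the three models separate an easy signal and stay in [0,1]", {
  set.seed(31)
  df <- separableFeatures(60)
  models <- fitSdmModels(df, seed = 1)
  expect_named(models, c("RF", "BRT", "MAXENT"))
  for (m in models) {
    sc <- predict(m, df)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(aucScore(sc, df$label), 1.0)
  }
  expect_error(fitSdmModels(transform(df, label = 1)), "both classes")

  # determinism of fit + predict
  models2 <- fitSdmModels(df, seed = 1)
  for (a in names(models))
    expect_equal(predict(models[[a]], df), predict(models2[[a]], df))
})

test_that("randomly permuted labels give chance-level test AUC", {
  set.seed(32)
  df <- separableFeatures(60)
  df$label <- sample(df$label)
  tr <- sort(sample.int(nrow(df), 84))
  te <- setdiff(seq_len(nrow(df)), tr)
  if (length(unique(df$label[tr])) < 2 || length(unique(df$label[te])) < 2) {
    tr <- c(which(df$label == 0)[1:42], which(df$label == 1)[1:42])
    te <- setdiff(seq_len(nrow(df)), tr)
  }
  models <- fitSdmModels(df[tr, ], seed = 2)
  aucs <- vapply(models, function(m)
    aucScore(predict(m, df[te, ]), df$label[te]), numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("the maxent-style response is unimodal for a Gaussian niche", {
  set.seed(33)
  n <- 300
  vars <- c("sea_ice", "sst", "sss", "t200", "s200", "depth", "npp")
  mk <- function(sst) {
    df <- as.data.frame(setNames(lapply(vars, function(v)
      rep(0, length(sst))), vars))
    df$sst <- sst
    df
  }
  # presences from a niche at sst = -1, background uniform
  pres <- mk(rnorm(n, -1, 1.5))
  back <- mk(runif(3 * n, -10, 12))
  train <- rbind(cbind(pres, label = 1), cbind(back, label = 0))
  m <- fitSdmModels(train, seed = 3)$MAXENT
  curve <- predict(m, mk(seq(-10, 12, by = 0.25)))
  peak <- which.max(curve)
  expect_true(all(diff(curve[seq_len(peak)]) >= -1e-9))
  expect_true(all(diff(curve[peak:length(curve)]) <= 1e-9))
})

test_that("permutation importance zeroes constant columns and finds the driver", {
  set.seed(34)
  df <- separableFeatures(80)
  te <- separableFeatures(40)
  m <- fitSdmModels(df, seed = 4)$RF
  imp <- variableImportance(m, te, reps = 5, seed = 1)
  expect_equal(sum(imp), 1)
  expect_equal(unname(imp["sss"]), 0)  # constant column
  expect_equal(names(which.max(imp)), "sst")
})

test_that("ensemble maps are convex TSS-weighted combinations", {
  g <- gridSpec(-80, -75, 0, 5, 1)
  mk <- function(v) hsiFromMatrix(matrix(v, nLat(g), nLon(g)), g)
  maps <- list(RF = mk(1.0), BRT = mk(0.5), MAXENT = mk(0.0))
  w <- c(RF = 0.6, BRT = 0.3, MAXENT = 0.1)
  ens <- ensembleHsi(maps, w)
  expect_true(all(ens@values == 0.75))

  # equal weights -> arithmetic mean; single weight 1 -> that member
  wEq <- c(RF = 1, BRT = 1, MAXENT = 1) / 3
  expect_true(all(abs(ensembleHsi(maps, wEq)@values - 0.5) < 1e-12))
  w1 <- c(RF = 1, BRT = 0, MAXENT = 0)
  expect_equal(ensembleHsi(maps, w1)@values, maps$RF@values)

  # convexity on random members
  set.seed(35)
  rnd <- list(RF = mk(0), BRT = mk(0), MAXENT = mk(0))
  for (a in names(rnd))
    rnd[[a]]@values <- matrix(runif(nLat(g) * nLon(g)), nLat(g), nLon(g))
  e2 <- ensembleHsi(rnd, w)
  lo <- pmin(rnd$RF@values, rnd$BRT@values, rnd$MAXENT@values)
  hi <- pmax(rnd$RF@values, rnd$BRT@values, rnd$MAXENT@values)
  expect_true(all(e2@values >= lo - 1e-12 & e2@values <= hi + 1e-12))

  expect_error(ensembleHsi(maps, c(RF = 0.5, BRT = 0.2, MAXENT = 0.1)),
               "sum to 1")
})

test_that("ensemble weights come from positive mean TSS", {
  ev <- list(meanTss = c(RF = 0.6, BRT = 0.3, MAXENT = -0.2))
  w <- ensembleWeights(ev)
  expect_equal(unname(w), c(0.6, 0.3, 0) / 0.9)
  expect_error(ensembleWeights(list(meanTss = c(RF = -1, BRT = 0,
                                                MAXENT = -0.5))),
               "no skilled model")
})

test_that("cross-ESM projection averages member maps cellwise", {
  s <- defaultStack()
  niche <- nicheSpec(c(sst = 2), c(sst = 2))
  occ <- sampleOccurrences(s, niche, n = 60, seed = 6)
  bg <- sampleBackground(s, 300, seed = 6, presences = occ)
  feats <- rbind(cbind(extractFeatures(s, occ), label = 1),
                 cbind(extractFeatures(s, bg), label = 0))
  models <- fitSdmModels(feats, seed = 7)
  w <- c(RF = 0.5, BRT = 0.3, MAXENT = 0.2)

  stacks <- list(BGC = esmVariant(s, "BGC", seed = 1),
                 E2G = esmVariant(s, "E2G", seed = 1))
  pr <- projectAndAverage(models, w, stacks, species = "sp")
  expect_named(pr$perEsm, c("BGC", "E2G"))
  # cellwise mean equals loop-computed oracle
  oracle <- (pr$perEsm$BGC@values + pr$perEsm$E2G@values) / 2
  expect_equal(pr$ensemble@values, oracle)
  # identical stacks -> mean equals the member
  same <- projectAndAverage(models, w, list(A = stacks$BGC, B = stacks$BGC))
  expect_equal(same$ensemble@values, same$perEsm$A@values)
  expect_error(projectAndAverage(models, w, stacks,
                                 esmIds = c("BGC", "E2G", "E2M")),
               "E2M")
})
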