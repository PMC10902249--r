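#' Sample background (pseudo-absence) points
#'
#' Draws n ocean cells uniformly at random, excluding cells holding
#' presences, and returns their cell-center coordinates. Sampling is without
#' replacement unless n exceeds the number of available cells, in which case
#' it switches to with-replacement. The default background size used by the
#' pipeline is 10 x the presence count, a standard presence-background
#' ratio.
#'
#' @param stack an [EnvStack-class].
#' @param n number of background points.
#' @param seed integer seed.
#' @param presences optional data.frame(longitude, latitude) whose cells are
#'   excluded.
#' @return data.frame(longitude, latitude) of cell centers.
#' @export
sampleBackground <- function(stack, n, seed = 1, presences = NULL) {
  stopifnot(n >= 1)
  g <- stack@grid
  ocean <- which(oceanMask(stack))
  if (length(ocean) == 0) stopf("no ocean cells to sample background from")
  if (!is.null(presences) && nrow(presences)) {
    ci <- cellIndex(g, presences$longitude, presences$latitude)
    ocean <- setdiff(ocean, ci$cell[!is.na(ci$cell)])
    if (length(ocean) == 0) stopf("no non-presence ocean cells left")
  }
  set.seed(childSeed(seed, "background"))
  cells <- if (n > length(ocean)) sample(ocean, n, replace = TRUE)
  else sample(ocean, n)
  nr <- nLat(g)
  row <- ((cells - 1) %% nr) + 1
  col <- ((cells - 1) %/% nr) + 1
  data.frame(longitude = g@lonMin + (col - 0.5) * g@cellSize,
             latitude = g@latMin + (row - 0.5) * g@cellSize)
}

#' Repeated stratified 70/30 cross-validation splits
#'
#' Ten (by default) independent random splits in which presences and
#' background points are each divided 70% training / 30% testing;
#' train and test are disjoint and exhaustive within a repetition.
#'
#' @param nPres,nBack class sizes.
#' @param trainFrac training fraction (default 0.7).
#' @param reps number of repetitions (default 10).
#' @param seed integer seed.
#' @return list of length \code{reps}; each element has integer index
#'   vectors trainPres, testPres, trainBack, testBack (presence indices in
#'   1..nPres, background in 1..nBack).
#' @export
cvSplit <- function(nPres, nBack, trainFrac = 0.7, reps = 10, seed = 1) {
  if (nPres < 2 || nBack < 2)
    stopf("each class needs at least 2 members to split")
  set.seed(childSeed(seed, "cv"))
  splitOne <- function(n) {
    k <- clip(round(trainFrac * n), 1, n - 1)
    tr <- sort(sample.int(n, k))
    list(train = tr, test = setdiff(seq_len(n), tr))
  }
  lapply(seq_len(reps), function(r) {
    p <- splitOne(nPres); b <- splitOne(nBack)
    list(trainPres = p$train, testPres = p$test,
         trainBack = b$train, testBack = b$test)
  })
}

SDM_ALGOS <- c("RF", "BRT", "MAXENT")

# linear + quadratic design matrix for the maximum-entropy-style model
maxentFeatures <- function(df) {
  vars <- intersect(ENV_VARS, names(df))
  X <- as.matrix(df[vars])
  cbind(X, `colnames<-`(X^2, paste0(vars, "_sq")))
}

#' Fit the three presence-background models
#'
#' Fits, on a labelled feature table: a probability random forest (500
#' trees), a stagewise boosted shallow-tree model (learning rate 0.01,
#' depth 3, early stopping on held-out log-loss), and a
#' maximum-entropy-style lasso-regularized logistic model on linear +
#' quadratic features (penalty chosen by internal cross-validation). All
#' three expose the same contract: \code{predict(model, newdata)} returns
#' scores in [0, 1], deterministically given the fitted state.
#'
#' @param train data.frame with the seven covariate columns and a 0/1
#'   \code{label} column, no missing values.
#' @param seed integer seed for the stochastic fitting steps.
#' @return named list of \code{sdmFit} objects (RF, BRT, MAXENT).
#' @export
fitSdmModels <- function(train, seed = 1) {
  if (length(unique(train$label)) < 2)
    stopf("training data must contain both classes")
  vars <- intersect(ENV_VARS, names(train))
  y <- as.integer(train$label)

  rf <- ranger::ranger(x = train[vars], y = factor(y, levels = c(0, 1)),
                       num.trees = 500, probability = TRUE,
                       seed = childSeed(seed, "rf"), num.threads = 1)

  # internal 85/15 split for boosting early stopping
  set.seed(childSeed(seed, "brt-split"))
  n <- nrow(train)
  hold <- sort(sample.int(n, max(2, round(0.15 * n))))
  if (length(unique(y[hold])) < 2 || length(unique(y[-hold])) < 2)
    hold <- c(which(y == 0)[1], which(y == 1)[1])
  X <- as.matrix(train[vars])
  dtrain <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE], label = y[-hold])
  dhold <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold])
  set.seed(childSeed(seed, "brt"))
  brt <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.01, max_depth = 3,
                  nthread = 1, eval_metric = "logloss"),
    data = dtrain, nrounds = 1200,
    evals = list(holdout = dhold),
    early_stopping_rounds = 30, verbose = 0)
  brtBest <- as.integer(xgboost::xgb.attributes(brt)$best_iteration)
  if (length(brtBest) == 0) brtBest <- xgboost::xgb.get.num.boosted.rounds(brt) - 1L

  set.seed(childSeed(seed, "maxent"))
  Xq <- maxentFeatures(train)
  mx <- glmnet::cv.glmnet(Xq, y, family = "binomial", alpha = 1, nfolds = 5)

  list(RF = structure(list(algorithm = "RF", fit = rf, vars = vars),
                      class = "sdmFit"),
       BRT = structure(list(algorithm = "BRT", fit = brt, vars = vars,
                            bestIter = brtBest),
                       class = "sdmFit"),
       MAXENT = structure(list(algorithm = "MAXENT", fit = mx, vars = vars),
                          class = "sdmFit"))
}

#' @rdname fitSdmModels
#' @param object an \code{sdmFit}.
#' @param newdata data.frame with the covariate columns.
#' @param ... unused.
#' @export
predict.sdmFit <- function(object, newdata, ...) {
  switch(object$algorithm,
    RF = {
      p <- predict(object$fit, data = newdata[object$vars],
                   num.threads = 1)$predictions
      p[, "1"]
    },
    BRT = as.numeric(predict(object$fit,
                             xgboost::xgb.DMatrix(as.matrix(newdata[object$vars])),
                             # bestIter is 0-based; the range end is 1-based
                             iterationrange = c(1L, object$bestIter + 1L))),
    MAXENT = as.numeric(predict(object$fit, newx = maxentFeatures(newdata),
                                s = "lambda.min", type = "response")),
    stopf("unknown algorithm '%s'", object$algorithm))
}

#' Permutation variable importance
#'
#' Importance of each covariate as the mean drop in test AUC when that
#' column is permuted (reps seeded permutations), floored at zero and
#' normalized to sum one. A constant column scores exactly zero before
#' normalization.
#'
#' @param model an \code{sdmFit}.
#' @param test labelled feature table with both classes.
#' @param reps permutations per variable (default 5).
#' @param seed integer seed.
#' @return named numeric vector over the covariates summing to 1 (all zero
#'   if no variable matters).
#' @export
variableImportance <- function(model, test, reps = 5, seed = 1) {
  vars <- model$vars
  base <- aucScore(predict(model, test), test$label)
  set.seed(childSeed(seed, "importance"))
  raw <- vapply(vars, function(v) {
    drops <- vapply(seq_len(reps), function(r) {
      perm <- test
      perm[[v]] <- sample(perm[[v]])
      base - aucScore(predict(model, perm), perm$label)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  raw <- pmax(raw, 0)
  if (sum(raw) > 0) raw / sum(raw) else raw
}

#' Cross-validated evaluation of the three models
#'
#' Runs the repeated 70/30 evaluation: per repetition, fits all three
#' models on the training split and computes test AUC and maximum TSS (with
#' its threshold, sensitivity and specificity), plus permutation variable
#' importance on the test split. Per-algorithm means are over the
#' repetitions.
#'
#' @param presFeat,backFeat feature tables for presences and background
#'   (seven covariate columns, no label).
#' @param reps repetitions (default 10).
#' @param trainFrac training fraction (default 0.7).
#' @param seed integer seed.
#' @param importanceReps permutations per variable for importance.
#' @return object of class \code{sdmEval}: list(metrics = long data.frame
#'   (with an extra "ENSEMBLE" row per repetition: the within-repetition
#'   TSS-weighted score combination), importance = array
#'   rep x algorithm x variable, meanTss, meanAuc — means over the three
#'   base algorithms).
#' @export
evaluateSdm <- function(presFeat, backFeat, reps = 10, trainFrac = 0.7,
                        seed = 1, importanceReps = 5) {
  folds <- cvSplit(nrow(presFeat), nrow(backFeat), trainFrac, reps, seed)
  vars <- intersect(ENV_VARS, names(presFeat))
  metrics <- list()
  imp <- array(NA_real_, c(reps, length(SDM_ALGOS), length(vars)),
               dimnames = list(NULL, SDM_ALGOS, vars))
  for (r in seq_len(reps)) {
    f <- folds[[r]]
    train <- rbind(cbind(presFeat[f$trainPres, vars, drop = FALSE], label = 1),
                   cbind(backFeat[f$trainBack, vars, drop = FALSE], label = 0))
    test <- rbind(cbind(presFeat[f$testPres, vars, drop = FALSE], label = 1),
                  cbind(backFeat[f$testBack, vars, drop = FALSE], label = 0))
    models <- fitSdmModels(train, seed = childSeed(seed, paste0("rep", r)))
    scores <- list()
    for (a in SDM_ALGOS) {
      sc <- predict(models[[a]], test)
      scores[[a]] <- sc
      mt <- maxTss(sc, test$label)
      metrics[[length(metrics) + 1]] <- data.frame(
        rep = r, algorithm = a, auc = aucScore(sc, test$label), tss = mt$tss,
        threshold = mt$threshold, sensitivity = mt$sensitivity,
        specificity = mt$specificity)
      imp[r, a, ] <- variableImportance(models[[a]], test,
                                        reps = importanceReps,
                                        seed = childSeed(seed,
                                                         paste0("imp", r, a)))
    }
    # within-repetition TSS-weighted ensemble of the three score vectors
    repTss <- vapply(SDM_ALGOS, function(a)
      maxTss(scores[[a]], test$label)$tss, numeric(1))
    wr <- pmax(repTss, 0)
    wr <- if (sum(wr) > 0) wr / sum(wr) else rep(1 / length(wr), length(wr))
    ens <- Reduce(`+`, Map(`*`, scores, wr))
    mtE <- maxTss(ens, test$label)
    metrics[[length(metrics) + 1]] <- data.frame(
      rep = r, algorithm = "ENSEMBLE", auc = aucScore(ens, test$label),
      tss = mtE$tss, threshold = mtE$threshold,
      sensitivity = mtE$sensitivity, specificity = mtE$specificity)
  }
  metrics <- do.call(rbind, metrics)
  agg <- function(col) vapply(SDM_ALGOS, function(a)
    mean(metrics[[col]][metrics$algorithm == a]), numeric(1))
  structure(list(metrics = metrics, importance = imp,
                 meanAuc = agg("auc"), meanTss = agg("tss")),
            class = "sdmEval")
}

#' @rdname evaluateSdm
#' @param eval an \code{sdmEval}.
#' @return for \code{ensembleWeights}: per-algorithm weights proportional to
#'   max(mean TSS, 0), summing to 1.
#' @export
ensembleWeights <- function(eval) {
  w <- pmax(eval$meanTss, 0)
  if (sum(w) <= 0) stopf("no skilled model: all mean TSS <= 0")
  w / sum(w)
}

#' @rdname evaluateSdm
#' @return for \code{importanceSummary}: variable importance averaged over
#'   repetitions and algorithms, renormalized to sum 1.
#' @export
importanceSummary <- function(eval) {
  m <- apply(eval$importance, 3, mean, na.rm = TRUE)
  if (sum(m) > 0) m / sum(m) else m
}

#' Project fitted models to a stack and ensemble them
#'
#' \code{predictHsi} maps each model over the ocean cells of a stack;
#' \code{ensembleHsi} combines member maps as the TSS-weighted convex
#' combination; \code{projectAndAverage} does both per ESM and then takes
#' the unweighted cellwise mean over ESMs (the "ensemble" map).
#'
#' @param models list of \code{sdmFit} objects from [fitSdmModels()].
#' @param stack an [EnvStack-class].
#' @param weights named nonnegative per-algorithm weights summing to 1
#'   (from [ensembleWeights()]).
#' @param species species name recorded in the map provenance.
#' @return an [HsiMap-class].
#' @export
predictHsi <- function(models, stack, weights, species = "species") {
  g <- stack@grid
  ocean <- which(oceanMask(stack))
  df <- as.data.frame(lapply(stats::setNames(ENV_VARS, ENV_VARS),
                             function(v) stack@fields[[v]][ocean]))
  ok <- stats::complete.cases(df)
  vals <- matrix(NA_real_, nLat(g), nLon(g))
  if (any(ok)) {
    scores <- vapply(names(models),
                     function(a) predict(models[[a]], df[ok, , drop = FALSE]),
                     numeric(sum(ok)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    vals[ocean[ok]] <- as.numeric(scores %*% weights[names(models)])
  }
  new("HsiMap", grid = g, values = clip(vals, 0, 1), species = species,
      esm = stack@esm, scenario = stack@scenario, period = stack@period)
}

#' @rdname predictHsi
#' @param memberMaps named list of [HsiMap-class] maps (one per algorithm).
#' @export
ensembleHsi <- function(memberMaps, weights) {
  stopifnot(length(memberMaps) >= 1)
  g <- memberMaps[[1]]@grid
  for (m in memberMaps) if (!identical(m@grid, g)) stopf("grid mismatch")
  w <- weights[names(memberMaps)]
  if (any(is.na(w)) || any(w < 0)) stopf("invalid ensemble weights")
  if (abs(sum(w) - 1) > 1e-9) stopf("weights must sum to 1")
  vals <- Reduce(`+`, Map(function(m, wi) m@values * wi, memberMaps, w))
  p <- memberMaps[[1]]
  new("HsiMap", grid = g, values = vals, species = p@species, esm = p@esm,
      scenario = p@scenario, period = p@period)
}

#' @rdname predictHsi
#' @param stacksByEsm named list of [EnvStack-class], one per ESM, all for
#'   the same (scenario, period).
#' @param esmIds the ESM ids that must be present (default: the list names).
#' @return for \code{projectAndAverage}: list(perEsm = named list of
#'   [HsiMap-class], ensemble = cross-ESM mean [HsiMap-class]).
#' @export
projectAndAverage <- function(models, weights, stacksByEsm,
                              esmIds = names(stacksByEsm),
                              species = "species") {
  missing <- setdiff(esmIds, names(stacksByEsm))
  if (length(missing))
    stopf("missing ESM stack(s): %s", paste(missing, collapse = ", "))
  perEsm <- lapply(stacksByEsm[esmIds], function(s)
    predictHsi(models, s, weights, species = species))
  vals <- Reduce(`+`, lapply(perEsm, function(m) m@values)) / length(perEsm)
  ref <- perEsm[[1]]
  ens <- new("HsiMap", grid = ref@grid, values = vals, species = species,
             esm = "ensemble", scenario = ref@scenario, period = ref@period)
  list(perEsm = perEsm, ensemble = ens)
}
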