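#' Default pipeline configuration
#'
#' Returns the configuration driving [runPipeline()]: the 1-degree
#' circumpolar grid, four synthetic ESM variants, both emission scenarios
#' and future periods, the nine-species synthetic community plus a
#' krill-like ice-edge species, 300 presences per species with a 10x
#' background, 10 x 70/30 cross-validation, and the joint-model chain
#' settings (q = 2, 5000 iterations, 1000 burn-in, 1000 subsampled sites).
#' The list round-trips through YAML unchanged, so a config file can be
#' edited and passed back.
#'
#' @param seed master integer seed; every stage derives its own seed from it.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1) {
  # niche fields are stored as named lists (not named vectors) so that the
  # names survive YAML serialization even for single-variable niches
  asConfigNiche <- function(n) list(optima = as.list(n$optima),
                                    tolerances = as.list(n$tolerances),
                                    weights = as.list(n$weights),
                                    detectionRate = n$detectionRate)
  niches <- lapply(defaultSpeciesNiches(), asConfigNiche)
  list(
    seed = seed,
    grid = list(latMin = -90, latMax = -35, lonMin = -180, lonMax = 180,
                cellSize = 1),
    esmIds = c("BGC", "E2G", "E2M", "ES"),
    esmAmplitude = 1,
    scenarios = c("RCP45", "RCP85"),
    periods = c("short_future", "long_future"),
    species = niches,
    krill = asConfigNiche(nicheSpec(c(sea_ice = 55, sst = 0.5),
                                    c(sea_ice = 30, sst = 2.5))),
    nPresence = 300,
    backgroundFactor = 10,
    cv = list(reps = 10, trainFrac = 0.7),
    importanceReps = 5,
    jsdm = list(q = 2, nIter = 5000, burn = 1000, thin = 5, subsample = 1000),
    mpa = list(current = list(n = 2, lonWidth = 25, latHeight = 8),
               negotiated = list(n = 3, lonWidth = 30, latHeight = 10)),
    topFraction = 0.05)
}

#' @rdname defaultRunConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname defaultRunConfig
#' @param config a configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

configGrid <- function(config) do.call(gridSpec, config$grid)

configNiche <- function(spec) {
  nicheSpec(unlist(spec$optima), unlist(spec$tolerances),
            if (!is.null(spec$weights)) unlist(spec$weights),
            detectionRate = if (is.null(spec$detectionRate)) 1
            else spec$detectionRate)
}

PIPELINE_STAGES <- c("simulate", "prep", "fit", "project", "change",
                     "associate", "overlap")

needFile <- function(path, producer) {
  if (!file.exists(path))
    stopf("missing upstream output '%s'; run stage '%s' first",
          basename(path), producer)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, prep, fit, project, change, associate, overlap). Stages
#' communicate only through files under \code{outdir} (CSV, JSON, GeoJSON),
#' so any subset can be re-run against existing upstream outputs. A
#' manifest (JSON) with per-stage parameters, wall-clock seconds and MD5
#' hashes of every text output is written at the end; identical configs
#' produce identical hashes.
#'
#' @param config configuration list from [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param outdir output directory (created if absent).
#' @param stages character vector of stages, or "all".
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outdir, stages = "all") {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list())
  timing <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- switch(st,
      simulate = stageSimulate(config, outdir),
      prep = stagePrep(config, outdir),
      fit = stageFit(config, outdir),
      project = stageProject(config, outdir),
      change = stageChange(config, outdir),
      associate = stageAssociate(config, outdir),
      overlap = stageOverlap(config, outdir))
    timing[[st]] <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$stages[[st]] <- list(
      files = vapply(sort(files), function(f)
        digest::digest(file = file.path(outdir, f), algo = "md5"),
        character(1)))
  }
  # wall-clock goes to a sidecar so the manifest itself is reproducible
  jsonlite::write_json(timing, file.path(outdir, "timing.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

allSpeciesNiches <- function(config) {
  n <- lapply(config$species, configNiche)
  n$krill <- configNiche(config$krill)
  n
}

futureName <- function(esm, scn, per) sprintf("future_%s_%s_%s.csv", esm, scn, per)

stageSimulate <- function(config, outdir) {
  g <- configGrid(config)
  present <- makeEnvGrid(g, seed = config$seed)
  files <- c("present_truth.csv", "present_truth.json")
  writeEnvStack(present, file.path(outdir, "present_truth.csv"))
  for (esm in config$esmIds) {
    v <- esmVariant(present, esm, seed = config$seed,
                    amplitude = config$esmAmplitude)
    f <- sprintf("present_%s.csv", esm)
    writeEnvStack(v, file.path(outdir, f))
    files <- c(files, f, sub("csv$", "json", f))
    for (scn in config$scenarios) for (per in config$periods) {
      fut <- applyScenario(v, scenarioDelta(scn, per,
                                            esmAmplitude = config$esmAmplitude),
                           esmId = esm, seed = config$seed)
      ff <- futureName(esm, scn, per)
      writeEnvStack(fut, file.path(outdir, ff))
      files <- c(files, ff, sub("csv$", "json", ff))
    }
  }
  for (sp in names(allSpeciesNiches(config))) {
    occ <- sampleOccurrences(present, allSpeciesNiches(config)[[sp]],
                             n = config$nPresence,
                             seed = childSeed(config$seed, sp), species = sp)
    f <- sprintf("occ_raw_%s.csv", sp)
    writeOccurrences(occ, file.path(outdir, f))
    files <- c(files, f)
  }
  pas <- makeMpaPolygons(g, config$mpa, seed = config$seed)
  writeGeoJson(pas, file.path(outdir, "mpas.geojson"))
  c(files, "mpas.geojson")
}

stagePrep <- function(config, outdir) {
  present <- readEnvStack(needFile(file.path(outdir, "present_truth.csv"),
                                   "simulate"))
  files <- character(); logs <- list()
  for (sp in names(allSpeciesNiches(config))) {
    raw <- readOccurrences(needFile(file.path(outdir,
                                              sprintf("occ_raw_%s.csv", sp)),
                                    "simulate"))
    res <- prepOccurrences(raw, present)
    f <- sprintf("occ_clean_%s.csv", sp)
    writeOccurrences(res$records, file.path(outdir, f))
    files <- c(files, f)
    logs[[sp]] <- data.frame(species = sp, reason = names(res$log),
                             count = as.integer(res$log))
  }
  utils::write.csv(do.call(rbind, logs), file.path(outdir, "prep_log.csv"),
                   row.names = FALSE)
  c(files, "prep_log.csv")
}

stageFit <- function(config, outdir) {
  files <- character()
  for (sp in names(allSpeciesNiches(config))) {
    occ <- readOccurrences(needFile(file.path(outdir,
                                              sprintf("occ_clean_%s.csv", sp)),
                                    "prep"))
    impAcc <- list()
    for (esm in config$esmIds) {
      stack <- readEnvStack(needFile(file.path(outdir,
                                               sprintf("present_%s.csv", esm)),
                                     "simulate"))
      bg <- sampleBackground(stack,
                             n = min(config$backgroundFactor * nrow(occ),
                                     sum(oceanMask(stack))),
                             seed = childSeed(config$seed,
                                              paste0("bg:", sp, esm)),
                             presences = occ)
      presFeat <- extractFeatures(stack, occ)
      backFeat <- extractFeatures(stack, bg)
      ev <- evaluateSdm(presFeat, backFeat, reps = config$cv$reps,
                        trainFrac = config$cv$trainFrac,
                        seed = childSeed(config$seed, paste0("cv:", sp, esm)),
                        importanceReps = config$importanceReps)
      f <- sprintf("eval_%s_%s.csv", sp, esm)
      utils::write.csv(ev$metrics, file.path(outdir, f), row.names = FALSE)
      w <- ensembleWeights(ev)
      fw <- sprintf("weights_%s_%s.csv", sp, esm)
      utils::write.csv(data.frame(algorithm = names(w), weight = as.numeric(w)),
                       file.path(outdir, fw), row.names = FALSE)
      impAcc[[esm]] <- importanceSummary(ev)
      files <- c(files, f, fw)
      all <- rbind(cbind(presFeat[intersect(ENV_VARS, names(presFeat))],
                         label = 1),
                   cbind(backFeat[intersect(ENV_VARS, names(backFeat))],
                         label = 0))
      models <- fitSdmModels(all, seed = childSeed(config$seed,
                                                   paste0("fit:", sp, esm)))
      saveRDS(list(models = models, weights = w),
              file.path(outdir, sprintf("models_%s_%s.rds", sp, esm)))
    }
    imp <- Reduce(`+`, impAcc) / length(impAcc)
    fi <- sprintf("importance_%s.csv", sp)
    utils::write.csv(data.frame(variable = names(imp),
                                importance = as.numeric(imp)),
                     file.path(outdir, fi), row.names = FALSE)
    files <- c(files, fi)
  }
  files
}

stageProject <- function(config, outdir) {
  files <- character()
  combos <- c(list(list(scn = "historical", per = "present")),
              unlist(lapply(config$scenarios, function(scn)
                lapply(config$periods, function(per)
                  list(scn = scn, per = per))), recursive = FALSE))
  for (sp in names(allSpeciesNiches(config))) {
    for (cb in combos) {
      perEsm <- list()
      for (esm in config$esmIds) {
        mw <- readRDS(needFile(file.path(outdir,
                                         sprintf("models_%s_%s.rds", sp, esm)),
                               "fit"))
        stackFile <- if (cb$per == "present") sprintf("present_%s.csv", esm)
        else futureName(esm, cb$scn, cb$per)
        stack <- readEnvStack(needFile(file.path(outdir, stackFile),
                                       "simulate"))
        m <- predictHsi(mw$models, stack, mw$weights, species = sp)
        perEsm[[esm]] <- m
        f <- sprintf("hsi_%s_%s_%s_%s.csv", sp, cb$scn, cb$per, esm)
        writeHsiMap(m, file.path(outdir, f))
        files <- c(files, f, sub("csv$", "json", f))
      }
      vals <- Reduce(`+`, lapply(perEsm, function(m) m@values)) /
        length(perEsm)
      ens <- new("HsiMap", grid = perEsm[[1]]@grid, values = vals,
                 species = sp, esm = "ensemble", scenario = cb$scn,
                 period = cb$per)
      f <- sprintf("hsi_%s_%s_%s_ensemble.csv", sp, cb$scn, cb$per)
      writeHsiMap(ens, file.path(outdir, f))
      files <- c(files, f, sub("csv$", "json", f))
    }
  }
  files
}

ensembleMapPath <- function(outdir, sp, scn, per)
  file.path(outdir, sprintf("hsi_%s_%s_%s_ensemble.csv", sp, scn, per))

stageChange <- function(config, outdir) {
  g <- configGrid(config)
  areas <- cellAreas(g)
  cent <- list(); area <- list(); cnts <- list()
  for (sp in names(allSpeciesNiches(config))) {
    pres <- binarizeTop5(readHsiMap(needFile(
      ensembleMapPath(outdir, sp, "historical", "present"), "project")),
      fraction = config$topFraction)
    for (scn in config$scenarios) for (per in config$periods) {
      fut <- binarizeTop5(readHsiMap(needFile(
        ensembleMapPath(outdir, sp, scn, per), "project")),
        fraction = config$topFraction)
      cs <- centroidShift(pres, fut, areas)
      cent[[length(cent) + 1]] <- data.frame(
        species = sp, scenario = scn, period = per,
        presentCentroid = cs$presentCentroid,
        futureCentroid = cs$futureCentroid, shift = cs$shift)
      ac <- areaChange(pres, fut, areas)
      ac$species <- sp; ac$scenario <- scn; ac$period <- per
      area[[length(area) + 1]] <- ac
      cm <- attr(changeMap(pres, fut), "counts")
      cnts[[length(cnts) + 1]] <- data.frame(
        species = sp, scenario = scn, period = per,
        category = names(cm), cells = as.integer(cm))
    }
  }
  utils::write.csv(do.call(rbind, cent),
                   file.path(outdir, "centroid_shifts.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, area),
                   file.path(outdir, "area_change.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, cnts),
                   file.path(outdir, "change_counts.csv"), row.names = FALSE)
  c("centroid_shifts.csv", "area_change.csv", "change_counts.csv")
}

stageAssociate <- function(config, outdir) {
  fish <- names(config$species)
  perEsm <- list(); files <- character()
  for (esm in config$esmIds) {
    stack <- readEnvStack(needFile(file.path(outdir,
                                             sprintf("present_%s.csv", esm)),
                                   "simulate"))
    habs <- lapply(stats::setNames(fish, fish), function(sp)
      binarizeTop5(readHsiMap(needFile(
        file.path(outdir,
                  sprintf("hsi_%s_historical_present_%s.csv", sp, esm)),
        "project")), fraction = config$topFraction))
    m <- buildSiteMatrix(habs, stack, subsample = config$jsdm$subsample,
                         seed = childSeed(config$seed, paste0("sites:", esm)))
    post <- fitJsdm(m, q = config$jsdm$q, nIter = config$jsdm$nIter,
                    burn = config$jsdm$burn, thin = config$jsdm$thin,
                    seed = childSeed(config$seed, paste0("jsdm:", esm)))
    assoc <- residualCorrelation(post)
    perEsm[[esm]] <- assoc
    f <- sprintf("association_%s.csv", esm)
    writeAssociation(assoc, file.path(outdir, f))
    files <- c(files, f, sub("\\.csv$", "_significant.csv", f))
  }
  avg <- averageAssociations(perEsm)
  writeAssociation(avg, file.path(outdir, "association.csv"))
  c(files, "association.csv", "association_significant.csv")
}

stageOverlap <- function(config, outdir) {
  g <- configGrid(config)
  areas <- cellAreas(g)
  pas <- readGeoJson(needFile(file.path(outdir, "mpas.geojson"), "simulate"))
  masks <- rasterizePas(pas, g)
  fish <- names(config$species)
  combos <- c(list(list(scn = "historical", per = "present")),
              unlist(lapply(config$scenarios, function(scn)
                lapply(config$periods, function(per)
                  list(scn = scn, per = per))), recursive = FALSE))
  reports <- list(); inter <- list()
  for (cb in combos) {
    fishMaps <- lapply(fish, function(sp)
      readHsiMap(needFile(ensembleMapPath(outdir, sp, cb$scn, cb$per),
                          "project")))
    iaFish <- identifyIas(meanHsi(fishMaps), fraction = config$topFraction)
    iaKrill <- identifyIas(readHsiMap(needFile(
      ensembleMapPath(outdir, "krill", cb$scn, cb$per), "project")),
      fraction = config$topFraction)
    for (tx in c("meso_fish", "krill")) {
      ia <- if (tx == "meso_fish") iaFish else iaKrill
      rep <- overlapReport(ia, masks, areas)
      rep$taxon <- tx; rep$scenario <- cb$scn; rep$period <- cb$per
      reports[[length(reports) + 1]] <- rep
    }
    ov <- iaIntersection(iaFish, iaKrill, areas)
    inter[[length(inter) + 1]] <- data.frame(
      scenario = cb$scn, period = cb$per, overlapArea = ov$area)
  }
  utils::write.csv(do.call(rbind, reports),
                   file.path(outdir, "overlap_report.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, inter),
                   file.path(outdir, "ia_intersection.csv"), row.names = FALSE)
  c("overlap_report.csv", "ia_intersection.csv")
}
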