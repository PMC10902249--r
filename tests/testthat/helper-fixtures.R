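# Shared fixtures, all built in code.

# Small circumpolar-like grid for fast tests: 2-degree cells, 10 x 18.
smallGrid <- function() gridSpec(latMin = -80, latMax = -60, lonMin = -90,
                                 lonMax = -54, cellSize = 2)

# Full-domain default stack, cached per session (generation is cheap).
defaultStack <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache)) cache <<- makeEnvGrid(seed = seed)
    cache
  }
})

# HsiMap from a plain matrix on an arbitrary grid
hsiFromMatrix <- function(values, grid = NULL) {
  if (is.null(grid))
    grid <- gridSpec(latMin = -80, latMax = -80 + nrow(values),
                     lonMin = 0, lonMax = ncol(values), cellSize = 1)
  new("HsiMap", grid = grid, values = values, species = "test",
      esm = "truth", scenario = "historical", period = "present")
}

# BinaryHabitat from a logical matrix
habitatFromMatrix <- function(suitable, grid = NULL, threshold = 0.5) {
  if (is.null(grid))
    grid <- gridSpec(latMin = -80, latMax = -80 + nrow(suitable),
                     lonMin = 0, lonMax = ncol(suitable), cellSize = 1)
  new("BinaryHabitat", grid = grid, suitable = suitable,
      threshold = threshold, provenance = list())
}

# labelled two-class feature table with an informative sst column
separableFeatures <- function(n = 40) {
  vars <- c("sea_ice", "sst", "sss", "t200", "s200", "depth", "npp")
  df <- as.data.frame(setNames(lapply(vars, function(v) rep(0, 2 * n)), vars))
  df$sst <- c(rnorm(n, -2, 0.3), rnorm(n, 2, 0.3))
  df$label <- rep(c(0, 1), each = n)
  df
}
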