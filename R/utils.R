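# Internal helpers shared across modules.

# Deterministic child seed from a master seed and a tag, kept inside the
# 32-bit integer range so set.seed() accepts it.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483587L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap longitudes into [-180, 180); identity (bit-exact) when already inside.
wrapLon <- function(lon) {
  out <- lon
  off <- !is.na(lon) & (lon < -180 | lon >= 180)
  out[off] <- ((lon[off] + 180) %% 360) - 180
  out
}

# Mean of longitudes in degrees, result in [-180, 180). Arithmetic when the
# values span less than a half-circle (exact, the common case for records
# inside one grid cell); circular otherwise so the dateline is handled.
lonMean <- function(lon) {
  if (max(lon) - min(lon) <= 180) return(wrapLon(mean(lon)))
  r <- lon * pi / 180
  wrapLon(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
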