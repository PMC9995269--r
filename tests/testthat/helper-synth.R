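# Small, fast configurations and independent brute-force oracles shared
# across the test files. Fixtures are generated in code; nothing is stored.

small_config <- function(...) {
  defaults <- list(nlat = 48L, nlon = 48L, agg_factor = 2L, years = 2003:2012,
                   n_clusters = 12L, sigma = 5)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_windows <- list(start = 2003:2007, end = 2008:2012)

# brute-force cos-latitude block mean (independent of block_apply_sum)
bf_block_mean <- function(x, lat, f) {
  nbr <- nrow(x) %/% f; nbc <- ncol(x) %/% f
  out <- matrix(NA_real_, nbr, nbc)
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    rows <- ((bi - 1) * f + 1):(bi * f)
    cols <- ((bj - 1) * f + 1):(bj * f)
    vals <- x[rows, cols]
    w <- matrix(cos(lat[rows] * pi / 180), f, f)
    ok <- !is.na(vals)
    if (sum(ok) >= f^2 / 2)
      out[bi, bj] <- sum(w[ok] * vals[ok]) / sum(w[ok])
  }
  out
}

# plain block sum (no weighting) -- used to total cell areas over blocks
bf_block_sum <- function(x, f) {
  nbr <- nrow(x) %/% f; nbc <- ncol(x) %/% f
  out <- matrix(0, nbr, nbc)
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc))
    out[bi, bj] <- sum(x[((bi - 1) * f + 1):(bi * f), ((bj - 1) * f + 1):(bj * f)])
  out
}

# brute-force bilinear interpolation at one point set
bf_bilinear <- function(z, lat, lon, tlat, tlon) {
  out <- matrix(NA_real_, length(tlat), length(tlon))
  for (i in seq_along(tlat)) for (j in seq_along(tlon)) {
    y <- tlat[i]; x <- tlon[j]
    iy <- max(1L, min(length(lat) - 1L, findInterval(y, lat)))
    ix <- max(1L, min(length(lon) - 1L, findInterval(x, lon)))
    ty <- (y - lat[iy]) / (lat[iy + 1] - lat[iy])
    tx <- (x - lon[ix]) / (lon[ix + 1] - lon[ix])
    out[i, j] <- (1 - ty) * ((1 - tx) * z[iy, ix] + tx * z[iy, ix + 1]) +
      ty * ((1 - tx) * z[iy + 1, ix] + tx * z[iy + 1, ix + 1])
  }
  out
}

set_grid_attrs_for_test <- function(x, lat, lon) {
  attr(x, "lat") <- lat
  attr(x, "lon") <- lon
  x
}

# a deterministic tiny cube built by hand: one value per (pixel, month, year)
toy_cube <- function(values, lat, lon, years, category = "satellite") {
  precip_cube(values, lat, lon, years, category)
}
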