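# Seeded synthetic generator: forest-cover histories with patch-style clearing,
# a biome mask, monthly precipitation with a known injected response to local
# forest loss, and future loss scenarios. Ground truth travels with the bundle
# so every downstream stage can be checked by parameter recovery.

#' Configuration for the synthetic gridded-data generator
#'
#' The defaults describe an evergreen-tropics-like domain: a 256 x 256 fine
#' grid aggregated by a factor of 4 to a 64 x 64 analysis grid, mean
#' precipitation 165 mm/month (about 2,000 mm/yr) with a per-pixel seasonal
#' cycle, interannual noise of 10 mm/month, and patch-style deforestation
#' clusters with sharp frontiers reaching 50 percentage points of canopy
#' loss at the fine scale, ramped linearly over the analysis years. Forest
#' loss is generated at the fine scale and area-aggregated; precipitation is
#' generated on the analysis grid, responding to the aggregated (area-mean)
#' loss of each analysis pixel.
#'
#' @param nlat,nlon fine grid shape (pixels)
#' @param res fine grid resolution in degrees
#' @param agg_factor linear fine-to-coarse aggregation factor defining the
#'   analysis grid (1 = analyse at the fine grid)
#' @param lat0,lon0 cell-centre coordinates of the first (south-west) pixel
#' @param years consecutive years covered by cover and precipitation
#' @param mu_p baseline mean precipitation (mm/month)
#' @param seasonal_amp amplitude of the per-pixel seasonal cycle (mm/month)
#' @param sigma interannual noise standard deviation (mm/month)
#' @param noise `"monthly"` (default) draws an independent deviate per
#'   pixel-month; `"annual"` draws one deviate per pixel-year added to all
#'   12 months (keeps each pixel's seasonal ranking exactly stable)
#' @param n_clusters number of deforestation patches
#' @param max_loss maximum total canopy loss at a patch core (pp, in \[0,100\])
#' @param radius_range range of patch radii (fine pixels); each patch draws
#'   its radius uniformly from this interval
#' @param loss_duration years over which a patch is cleared; each patch
#'   draws a uniform start year such that its linear clearing ramp completes
#'   within the series (clearing events are fast relative to the record;
#'   set to `length(years) - 1` to ramp every patch over the whole span)
#' @param edge_width logistic scale of the patch frontier (pixels); the
#'   10-90% transition spans about `4.4 * edge_width`, so the default 0.4
#'   resolves the cleared-to-intact boundary within one or two pixels, as in
#'   gridded forest-loss maps at these scales
#' @param beta injected sensitivity: precipitation change per percentage point
#'   of canopy loss (mm/month per pp; negative for drying)
#' @param response `"linear"` or `"saturating"`; the saturating form is
#'   `beta * H * L / (H + L)` whose initial slope equals `beta`
#' @param half_sat half-saturation constant `H` (pp) for the saturating form
#' @param elnino_years years receiving a basin-wide additive anomaly
#' @param elnino_anom additive precipitation anomaly in those years (mm/month,
#'   negative for drought)
#' @param elnino_beta_mult multiplier on `beta` during El Nino years (1 = none)
#' @param mask_fraction fraction of the domain covered by the biome mask
#'   (a centred square block)
#' @param seed integer random seed; identical seed and config give
#'   bit-identical output
#' @return a `synth_config` list, validated
#' @export
synth_config <- function(nlat = 256L, nlon = 256L, res = 0.05,
                         lat0 = -1.6, lon0 = 20, agg_factor = 4L,
                         years = 2003:2017,
                         mu_p = 165, seasonal_amp = 80, sigma = 10,
                         noise = c("monthly", "annual"),
                         n_clusters = 180L, max_loss = 50,
                         radius_range = c(2, 5), edge_width = 0.4,
                         loss_duration = 3L,
                         beta = -0.25,
                         response = c("linear", "saturating"), half_sat = 30,
                         elnino_years = integer(0), elnino_anom = 0,
                         elnino_beta_mult = 1,
                         mask_fraction = 0.9, seed = 1L) {
  noise <- match.arg(noise)
  response <- match.arg(response)
  cfg <- list(nlat = as.integer(nlat), nlon = as.integer(nlon), res = res,
              lat0 = lat0, lon0 = lon0, agg_factor = as.integer(agg_factor),
              years = as.integer(years),
              mu_p = mu_p, seasonal_amp = seasonal_amp, sigma = sigma,
              noise = noise, n_clusters = as.integer(n_clusters),
              max_loss = max_loss, radius_range = radius_range,
              edge_width = edge_width, loss_duration = as.integer(loss_duration),
              beta = beta, response = response,
              half_sat = half_sat, elnino_years = as.integer(elnino_years),
              elnino_anom = elnino_anom, elnino_beta_mult = elnino_beta_mult,
              mask_fraction = mask_fraction, seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$nlat < 1L || cfg$nlon < 1L)
    stop("grid shape must be positive", call. = FALSE)
  if (cfg$agg_factor < 1L || cfg$nlat %/% cfg$agg_factor < 1L ||
      cfg$nlon %/% cfg$agg_factor < 1L)
    stop("agg_factor must be >= 1 and not larger than the grid", call. = FALSE)
  if (cfg$max_loss < 0 || cfg$max_loss > 100)
    stop("max_loss must lie in [0, 100] percentage points", call. = FALSE)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(cfg$years) < 6L)
    stop("need at least 6 years (two 3-yr windows must fit)", call. = FALSE)
  if (any(diff(cfg$years) != 1L)) stop("years must be consecutive", call. = FALSE)
  if (cfg$mask_fraction <= 0 || cfg$mask_fraction > 1)
    stop("mask_fraction must be in (0, 1]", call. = FALSE)
  if (cfg$half_sat <= 0) stop("half_sat must be positive", call. = FALSE)
  if (cfg$mu_p <= 0) stop("mu_p must be positive", call. = FALSE)
  if (cfg$loss_duration < 1L || cfg$loss_duration > length(cfg$years) - 1L)
    stop("loss_duration must be in [1, length(years) - 1]", call. = FALSE)
  invisible(cfg)
}

synth_coords <- function(cfg) {
  list(lat = cfg$lat0 + cfg$res * (seq_len(cfg$nlat) - 1L),
       lon = cfg$lon0 + cfg$res * (seq_len(cfg$nlon) - 1L))
}

# Sample patch-style clusters: a sigmoid-frontier loss profile (normalised
# so each patch core realises max_loss exactly) in a local bounding box,
# plus a clearing period of loss_duration years starting at a uniformly
# drawn year. Where patches overlap, the pixelwise maximum of their
# cumulative contributions applies.
sample_clusters <- function(cfg) {
  if (cfg$n_clusters == 0L || cfg$max_loss == 0) return(list())
  ny <- length(cfg$years)
  lapply(seq_len(cfg$n_clusters), function(k) {
    # seeds snap to pixel centres so a patch core realises max_loss exactly
    cy <- sample.int(cfg$nlat, 1L)
    cx <- sample.int(cfg$nlon, 1L)
    r0 <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
    start <- sample.int(ny - cfg$loss_duration, 1L)  # ramp completes in-span
    ext <- ceiling(r0 + 10 * cfg$edge_width)  # logistic tail negligible beyond
    rr <- max(1L, cy - ext):min(cfg$nlat, cy + ext)
    cc <- max(1L, cx - ext):min(cfg$nlon, cx + ext)
    d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, `+`))
    prof <- stats::plogis((r0 - d) / cfg$edge_width)
    prof <- prof / stats::plogis(r0 / cfg$edge_width)  # core == 1 at d = 0
    # fraction of the patch's total loss realised by each year of the series
    ramp <- pmin(pmax((seq_len(ny) - start) / cfg$loss_duration, 0), 1)
    list(rows = rr, cols = cc, field = cfg$max_loss * pmin(prof, 1), ramp = ramp)
  })
}

# Cumulative loss field at one time step (ramp fraction per cluster).
compose_loss <- function(cfg, clusters, step) {
  loss <- matrix(0, cfg$nlat, cfg$nlon)
  for (cl in clusters) {
    r <- cl$ramp[step]
    if (r <= 0) next
    loss[cl$rows, cl$cols] <- pmax(loss[cl$rows, cl$cols], r * cl$field)
  }
  loss
}

# Final-state loss field (used for future scenarios).
total_loss_field <- function(cfg) {
  clusters <- sample_clusters(cfg)
  if (!length(clusters)) return(matrix(0, cfg$nlat, cfg$nlon))
  loss <- matrix(0, cfg$nlat, cfg$nlon)
  for (cl in clusters)
    loss[cl$rows, cl$cols] <- pmax(loss[cl$rows, cl$cols], cl$field)
  loss
}

#' Generate a synthetic forest-cover history and biome mask
#'
#' Baseline cover is high (80-90%) with mild spatial texture. Each patch is
#' cleared by a linear ramp over its own `loss_duration`-year clearing
#' period, so cover is non-increasing per pixel and the final-minus-first
#' difference equals the composite patch loss field.
#'
#' @param config a [synth_config()]
#' @return list with `cover` (a [cover_series()]), `mask` (logical matrix),
#'   and `loss_total` (numeric matrix, pp, the realised total loss)
#' @export
generate_cover_history <- function(config) {
  validate_synth_config(config)
  co <- synth_coords(config)
  set.seed(config$seed + 11L)
  baseline <- matrix(80 + 10 * stats::runif(config$nlat * config$nlon),
                     config$nlat, config$nlon)
  clusters <- sample_clusters(config)
  ny <- length(config$years)
  values <- array(0, c(config$nlat, config$nlon, ny))
  for (t in seq_len(ny)) {
    # realised loss is capped by available cover (never drives cover negative)
    values[, , t] <- baseline - pmin(compose_loss(config, clusters, t), baseline)
  }
  loss_total <- baseline - values[, , ny]
  cover <- cover_series(values, co$lat, co$lon, config$years)
  # centred square biome mask covering ~mask_fraction of the domain
  side_r <- max(1L, round(config$nlat * sqrt(config$mask_fraction)))
  side_c <- max(1L, round(config$nlon * sqrt(config$mask_fraction)))
  r0 <- (config$nlat - side_r) %/% 2L
  c0 <- (config$nlon - side_c) %/% 2L
  mask <- matrix(FALSE, config$nlat, config$nlon)
  mask[r0 + seq_len(side_r), c0 + seq_len(side_c)] <- TRUE
  list(cover = cover, mask = mask, loss_total = loss_total)
}

injected_response <- function(cfg, loss_pp) {
  if (cfg$response == "linear") cfg$beta * loss_pp
  else cfg$beta * cfg$half_sat * loss_pp / (cfg$half_sat + loss_pp)
}

#' Generate a synthetic monthly precipitation cube
#'
#' Per pixel and month: seasonal climatology + interannual noise + El Nino
#' anomaly (additive, spatially uniform, in configured years) + the injected
#' response to the pixel's cumulative canopy loss up to that year. During El
#' Nino years the response term is multiplied by `elnino_beta_mult`.
#' Precipitation is floored at zero.
#'
#' The precipitation cube is generated on the grid of the cover series it is
#' given: passing the fine cover injects the response at the fine scale,
#' passing an [aggregate_cover()]-coarsened series injects a response to the
#' area-mean loss of each analysis pixel (the default in
#' [simulate_bundle()]).
#'
#' @param config a [synth_config()]
#' @param cover a [cover_series()] from [generate_cover_history()] (possibly
#'   aggregated); its years must match the config's
#' @return a [precip_cube()] (category `"satellite"`) on the cover's grid
#' @export
generate_precip <- function(config, cover) {
  validate_synth_config(config)
  if (!inherits(cover, "cover_series") ||
      !identical(attr(cover, "years"), config$years))
    stop("cover series is misaligned with the configuration", call. = FALSE)
  co <- list(lat = grid_lat(cover), lon = grid_lon(cover))
  nlat <- dim(cover)[1]; nlon <- dim(cover)[2]
  ny <- length(config$years); nt <- 12L * ny
  set.seed(config$seed + 202L)
  peak <- matrix(sample.int(12L, nlat * nlon, replace = TRUE), nlat, nlon)
  values <- array(0, c(nlat, nlon, nt))
  # interannual noise
  if (config$noise == "annual") {
    eps <- array(stats::rnorm(nlat * nlon * ny, 0, config$sigma),
                 c(nlat, nlon, ny))
  } else {
    eps <- array(stats::rnorm(nlat * nlon * nt, 0, config$sigma),
                 c(nlat, nlon, nt))
  }
  baseline_cover <- cover[, , 1L]
  for (y in seq_len(ny)) {
    yr <- config$years[y]
    is_nino <- yr %in% config$elnino_years
    loss_cum <- baseline_cover - cover[, , y]
    resp <- injected_response(config, loss_cum)
    if (is_nino) resp <- resp * config$elnino_beta_mult
    anom <- if (is_nino) config$elnino_anom else 0
    for (m in 1:12) {
      clim <- config$mu_p +
        config$seasonal_amp * cos(2 * pi * (m - peak) / 12)
      e <- if (config$noise == "annual") eps[, , y] else eps[, , (y - 1L) * 12L + m]
      values[, , (y - 1L) * 12L + m] <- pmax(0, clim + e + anom + resp)
    }
  }
  precip_cube(values, co$lat, co$lon, config$years, category = "satellite")
}

#' Generate a future forest-loss scenario
#'
#' @param config a [synth_config()]
#' @param pattern `"clustered"` draws a fresh set of patches (independent of
#'   the historical ones) with core loss `max_loss`; `"uniform"` assigns
#'   `uniform_loss` everywhere
#' @param max_loss core loss of future patches (pp); the default 60 spans
#'   both sides of the 30-pp projection cap
#' @param uniform_loss loss used by the uniform pattern (pp)
#' @return a [loss_grid()] of projected pp loss versus the scenario baseline
#' @export
generate_future_loss <- function(config, pattern = c("clustered", "uniform"),
                                 max_loss = 60, uniform_loss = 40) {
  validate_synth_config(config)
  pattern <- match.arg(pattern)
  if (max_loss < 0 || max_loss > 100 || uniform_loss < 0 || uniform_loss > 100)
    stop("future loss must lie in [0, 100] percentage points", call. = FALSE)
  co <- synth_coords(config)
  if (pattern == "uniform") {
    v <- matrix(uniform_loss, config$nlat, config$nlon)
  } else {
    cfg2 <- config
    cfg2$max_loss <- max_loss
    set.seed(config$seed + 303L)
    v <- total_loss_field(cfg2)
  }
  loss_grid(v, co$lat, co$lon, period = "future")
}

#' Generate a full synthetic bundle
#'
#' Cover history, biome mask, precipitation cube, a clustered future-loss
#' scenario and the ground-truth record, all from one seeded configuration.
#' Fine-scale cover, mask and future loss are aggregated by
#' `config$agg_factor` to the analysis grid; precipitation is generated on
#' the analysis grid, responding to each analysis pixel's area-mean
#' cumulative loss. All elements except `cover_fine` live on the analysis
#' grid.
#'
#' @param config a [synth_config()]
#' @param future_max_loss core loss (pp) of the future scenario patches at
#'   the fine scale
#' @return list with elements `cover` (analysis scale), `cover_fine`,
#'   `mask`, `precip`, `future`, `truth` (injected `beta`, response form,
#'   El Nino multiplier, and the realised analysis-scale total loss)
#' @export
simulate_bundle <- function(config, future_max_loss = 60) {
  ch <- generate_cover_history(config)
  f <- config$agg_factor
  if (f > 1L) {
    cover <- aggregate_cover(ch$cover, f)
    mask <- aggregate_mask(ch$mask, f)
    future <- aggregate_loss(
      generate_future_loss(config, "clustered", max_loss = future_max_loss), f)
  } else {
    cover <- ch$cover
    mask <- ch$mask
    future <- generate_future_loss(config, "clustered", max_loss = future_max_loss)
  }
  precip <- generate_precip(config, cover)
  ny <- dim(cover)[3]
  list(cover = cover, cover_fine = ch$cover, mask = mask, precip = precip,
       future = future,
       truth = list(beta = config$beta, response = config$response,
                    half_sat = config$half_sat,
                    elnino_beta_mult = config$elnino_beta_mult,
                    loss_total = cover[, , 1L] - cover[, , ny]))
}

#' Draw null pair records with independent deforested and control changes
#'
#' Generates `n` pair records whose deforested-pixel and control precipitation
#' changes are independent draws from the same zero-mean normal distribution
#' (the distribution of a difference of two window means under i.i.d.
#' per-month noise: variance `2 sigma^2 / (12 window_years)`, or
#' `2 sigma^2 / window_years` for per-year noise). Used to calibrate the
#' significance machinery under the null of no deforestation effect.
#'
#' @param n number of pairs
#' @param sigma interannual noise standard deviation (mm/month)
#' @param window_years number of years averaged in each period window
#' @param noise `"monthly"` or `"annual"`, as in [synth_config()]
#' @param seed integer seed
#' @return a tibble of pair records compatible with [significance()] and
#'   [estimate_sensitivity()]
#' @export
simulate_null_pairs <- function(n, sigma = 10, window_years = 5L,
                                noise = c("monthly", "annual"), seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  sd_chg <- if (noise == "monthly") sigma * sqrt(2 / (12 * window_years))
            else sigma * sqrt(2 / window_years)
  dp_def <- stats::rnorm(n, 0, sd_chg)
  dp_ctl <- stats::rnorm(n, 0, sd_chg)
  d_f <- stats::runif(n, 0.1, 30)
  dp <- dp_def - dp_ctl
  tibble::tibble(row = NA_integer_, col = NA_integer_,
                 d_f = d_f, n_ctl = 1L,
                 dp_def = dp_def, dp_ctl = dp_ctl, dp = dp,
                 p_start_def = 165, p_start_ctl = 165,
                 dp_rel = 100 * dp / 165,
                 sens = dp / d_f, sens_rel = (100 * dp / 165) / d_f)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %dx%d @ %.3f deg, years %d-%d, beta=%g (%s), sigma=%g\n",
              x$nlat, x$nlon, x$res, min(x$years), max(x$years),
              x$beta, x$response, x$sigma))
  invisible(x)
}
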