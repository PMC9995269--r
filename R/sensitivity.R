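# Sensitivity estimation: median per-pair sensitivities with mean-based
# standard errors, two-sample significance tests, per-pixel season
# classification, seasonal and loss-binned estimates, and comparison of
# alternative analysis windows.

#' Median precipitation sensitivity to forest loss
#'
#' Point estimate: median over the per-pair sensitivities `dp/d_f`
#' (mm/month per percentage point) and their relative counterparts
#' (% per percentage point). The reported standard error is the mean-based
#' one, `sd(sens)/sqrt(n)`; a seeded bootstrap standard error of the median
#' is stored alongside for diagnostic use. With a single pair the standard
#' errors are undefined and reported as missing.
#'
#' @param records pair records from [pair_delta_p()]
#' @param boot number of bootstrap resamples for the median SE (0 disables)
#' @param boot_seed seed for the bootstrap resampling
#' @return one-row tibble: `n`, `median_sens`, `median_sens_rel`, `mean_sens`,
#'   `se`, `se_rel`, `boot_se_median`, `p_t`, `p_mw`
#' @export
estimate_sensitivity <- function(records, boot = 0L, boot_seed = 1L) {
  n <- nrow(records)
  if (n < 1L) stop("no pairs to estimate from", call. = FALSE)
  s <- records$sens
  se <- if (n >= 2L) stats::sd(s) / sqrt(n) else NA_real_
  se_rel <- if (n >= 2L) stats::sd(records$sens_rel) / sqrt(n) else NA_real_
  bse <- NA_real_
  if (boot > 0L && n >= 2L) {
    set.seed(boot_seed)
    meds <- replicate(boot, stats::median(s[sample.int(n, n, replace = TRUE)]))
    bse <- stats::sd(meds)
  }
  pv <- significance(records)
  tibble::tibble(n = n,
                 median_sens = stats::median(s),
                 median_sens_rel = stats::median(records$sens_rel),
                 mean_sens = mean(s),
                 se = se, se_rel = se_rel, boot_se_median = bse,
                 p_t = pv$p_t, p_mw = pv$p_mw)
}

#' Two-sample tests of deforested versus control precipitation change
#'
#' Pools the deforested-pixel changes and the control changes (the two
#' components of each pair) and compares them with a two-sided Welch t-test
#' (difference in means) and a Mann-Whitney test (difference in medians).
#' Degenerate inputs (fewer than two pairs, or zero variance in both groups)
#' yield missing p-values with a warning.
#'
#' @param records pair records
#' @return list with elements `p_t` and `p_mw`
#' @export
significance <- function(records) {
  a <- records$dp_def; b <- records$dp_ctl
  if (length(a) < 2L) {
    warning("fewer than 2 pairs; p-values undefined")
    return(list(p_t = NA_real_, p_mw = NA_real_))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("zero-variance groups; p-values undefined")
    return(list(p_t = NA_real_, p_mw = NA_real_))
  }
  p_t <- stats::t.test(a, b, var.equal = FALSE)$p.value
  p_mw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  list(p_t = p_t, p_mw = p_mw)
}

#' Classify each pixel's wet, dry and transition months
#'
#' Builds the monthly climatology over the cube's full span and labels, per
#' pixel, its 3 climatologically wettest months (wet season), 3 driest
#' months (dry season) and the remaining 6 (transition season). Contiguity
#' is not required; ties are broken by ascending month index. Pixels with a
#' missing climatology month are dropped (all-NA labels).
#'
#' @param cube a [precip_cube()]
#' @return a `season_map`: integer array `lat x lon x 12` with codes
#'   1 = dry, 2 = transition, 3 = wet
#' @export
season_map <- function(cube) {
  years <- attr(cube, "years")
  nlat <- dim(cube)[1]; nlon <- dim(cube)[2]
  clim <- array(0, c(nlat, nlon, 12))
  for (m in 1:12) clim[, , m] <- period_mean(cube, years, months = m)
  out <- array(NA_integer_, c(nlat, nlon, 12))
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    v <- clim[i, j, ]
    if (anyNA(v)) next
    ord <- order(v)  # ascending; ties broken by month index
    codes <- rep.int(2L, 12)
    codes[ord[1:3]] <- 1L
    codes[ord[10:12]] <- 3L
    out[i, j, ] <- codes
  }
  out <- set_grid_attrs(out, grid_lat(cube), grid_lon(cube))
  class(out) <- c("season_map", "array")
  out
}

#' Seasonal sensitivity estimates
#'
#' Recomputes the period means using only each pixel's own wet, dry or
#' transition months (from [season_map()]) and re-runs the pair arithmetic
#' and estimation per season. Intended for satellite-category cubes, with
#' the season map derived from the same dataset.
#'
#' @param ps a `pair_set` from [find_pairs()]
#' @param cube a [precip_cube()] on the pairing grid
#' @param smap a `season_map` from the same cube
#' @param start_years,end_years the analysis windows
#' @param seasons seasons to estimate (default all three)
#' @return tibble with one estimate row per season (column `season` first)
#' @export
seasonal_estimate <- function(ps, cube, smap, start_years, end_years,
                              seasons = c("wet", "dry", "transition")) {
  out <- lapply(seasons, function(se) {
    p_s <- period_mean_seasonal(cube, start_years, smap, se)
    p_e <- period_mean_seasonal(cube, end_years, smap, se)
    rec <- pair_records_from_maps(ps, p_s, p_e)
    dplyr::bind_cols(tibble::tibble(season = se), estimate_sensitivity(rec))
  })
  dplyr::bind_rows(out)
}

#' Median sensitivity within forest-loss bins
#'
#' Pairs are assigned to bins by their excess loss `d_f` (left-closed,
#' right-open); pairs below the lowest edge are excluded. Empty bins are
#' reported with `n = 0` and missing statistics, never zero.
#'
#' @param records pair records
#' @param edges strictly increasing bin edges in pp; the default
#'   `c(0.1, 5, 10, 20, 30, Inf)` gives bins 0.1-5, 5-10, 10-20, 20-30, >=30
#' @return a `binned_response` tibble: `bin_lo`, `bin_hi`, `n`,
#'   `median_sens`, `se`
#' @export
binned_response <- function(records, edges = c(0.1, 5, 10, 20, 30, Inf)) {
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least two values", call. = FALSE)
  bin <- findInterval(records$d_f, edges, rightmost.closed = FALSE)
  bin[bin == length(edges)] <- length(edges) - 1L  # d_f == top finite edge
  nb <- length(edges) - 1L
  rows <- lapply(seq_len(nb), function(b) {
    s <- records$sens[bin == b]
    tibble::tibble(bin_lo = edges[b], bin_hi = edges[b + 1L],
                   n = length(s),
                   median_sens = if (length(s)) stats::median(s) else NA_real_,
                   se = if (length(s) >= 2L) stats::sd(s) / sqrt(length(s)) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$n == 0L)) stop("no pairs fall in any bin", call. = FALSE)
  if (any(out$n == 0L))
    message(sprintf("%d empty loss bins reported as missing", sum(out$n == 0L)))
  attr(out, "edges") <- edges
  class(out) <- c("binned_response", class(out))
  out
}

#' Sensitivity under alternative analysis windows
#'
#' Re-runs loss computation, pairing and estimation for each labelled
#' (start, end) window configuration, without pooling across configurations.
#' Comparing a window that contains El Nino years with one that excludes
#' them isolates any El Nino modulation of the deforestation response.
#'
#' @param cover a [cover_series()]
#' @param mask logical biome/region mask on the cover grid
#' @param cube a [precip_cube()] on the cover grid
#' @param windows named list; each element a list with `start` and `end`
#'   year vectors
#' @param window_size moving-window size for [find_pairs()]
#' @param min_excess minimum excess loss (pp)
#' @param similarity optional climate-similarity threshold in percent
#'   (`NULL` disables the filter)
#' @return tibble with one estimate row per window configuration (column
#'   `window` first)
#' @export
stratify_windows <- function(cover, mask, cube, windows,
                             window_size = 3L, min_excess = 0.1,
                             similarity = NULL) {
  if (is.null(names(windows)) || any(names(windows) == ""))
    stop("windows must be a named list", call. = FALSE)
  out <- lapply(names(windows), function(w) {
    ws <- windows[[w]]
    loss <- loss_between(cover, ws$start, ws$end)
    ps <- find_pairs(loss, mask, window = window_size, min_excess = min_excess)
    rec <- pair_delta_p(ps, cube, ws$start, ws$end)
    if (!is.null(similarity)) rec <- climate_similarity_filter(rec, similarity)
    dplyr::bind_cols(tibble::tibble(window = w), estimate_sensitivity(rec))
  })
  dplyr::bind_rows(out)
}
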