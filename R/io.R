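# Plain-text readers/writers (long-format CSV for grids and cubes, JSON for
# summaries) and the end-to-end pipeline driver with a run manifest.

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2 & leap] <- 29
  d
}

#' Write a precipitation cube to long-format CSV
#'
#' Columns: `year`, `month`, `lat`, `lon`, `value`, `units` (constant
#' `"mm/month"`), `category` (constant). Values round-trip through
#' [read_precip_csv()] to full double precision.
#'
#' @param cube a [precip_cube()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_precip_csv <- function(cube, path) {
  tt <- cube_time(cube)
  lat <- grid_lat(cube); lon <- grid_lon(cube)
  nt <- nrow(tt)
  df <- data.frame(
    year = rep(tt$year, each = length(lat) * length(lon)),
    month = rep(tt$month, each = length(lat) * length(lon)),
    lat = rep(rep(lat, length(lon)), nt),
    lon = rep(rep(lon, each = length(lat)), nt),
    value = as.vector(cube),
    units = "mm/month",
    category = attr(cube, "category"))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a precipitation cube from long-format CSV
#'
#' Accepts `mm/month` directly or `mm/day`, which is converted by the number
#' of days in each calendar month (Gregorian; a `calendar = "360_day"`
#' argument converts by a nominal 30-day month with a warning). Unknown
#' units are a hard error. The time axis must be complete (every month of
#' every year present).
#'
#' @param path CSV path as written by [write_precip_csv()] (a `units` column
#'   is required; `category` optional, default `"satellite"`)
#' @param calendar `"standard"` or `"360_day"`
#' @return a [precip_cube()]
#' @export
read_precip_csv <- function(path, calendar = c("standard", "360_day")) {
  calendar <- match.arg(calendar)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "month", "lat", "lon", "value", "units")
  if (!all(need %in% names(df)))
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  units <- unique(df$units)
  if (length(units) != 1L || !units %in% c("mm/month", "mm/day"))
    stop("unrecognised units attribute: ", paste(units, collapse = ", "), call. = FALSE)
  if (units == "mm/day") {
    if (calendar == "360_day") {
      warning("360-day calendar: converting mm/day by nominal 30-day months")
      df$value <- df$value * 30
    } else {
      df$value <- df$value * days_in_month(df$year, df$month)
    }
  }
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  years <- sort(unique(df$year))
  nt <- 12L * length(years)
  if (nrow(df) != length(lat) * length(lon) * nt)
    stop("incomplete cube: expected every month of every year for every pixel",
         call. = FALSE)
  idx_t <- (match(df$year, years) - 1L) * 12L + df$month
  arr <- array(NA_real_, c(length(lat), length(lon), nt))
  arr[cbind(match(df$lat, lat), match(df$lon, lon), idx_t)] <- df$value
  category <- if ("category" %in% names(df)) unique(df$category)[1] else "satellite"
  precip_cube(arr, lat, lon, years, category = category)
}

#' Write a single grid layer (loss, mask or map) to CSV
#'
#' Columns: `lat`, `lon`, `value`.
#'
#' @param grid matrix with grid attributes (e.g. a [loss_grid()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_grid_csv <- function(grid, path) {
  lat <- grid_lat(grid); lon <- grid_lon(grid)
  df <- data.frame(lat = rep(lat, length(lon)),
                   lon = rep(lon, each = length(lat)),
                   value = as.vector(unclass(grid)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grid layer written by [write_grid_csv()]
#'
#' @param path CSV path
#' @param as_loss return a [loss_grid()] (validates the \[0,100\] range)
#' @return matrix with grid attributes, or a [loss_grid()]
#' @export
read_grid_csv <- function(path, as_loss = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  if (as_loss) loss_grid(m, lat, lon) else set_grid_attrs(m, lat, lon)
}

#' Write estimates to CSV and JSON
#'
#' @param estimates a tibble of estimate rows
#' @param csv_path,json_path output paths (either may be `NULL` to skip)
#' @return invisibly, the estimates
#' @export
write_estimates <- function(estimates, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(estimates, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(estimates, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(estimates)
}

#' Pipeline configuration
#'
#' Bundles a synthetic-data configuration (or pre-loaded inputs) with the
#' analysis choices: aggregation factors (analysis scales), moving-window
#' size, minimum excess loss, analysis windows, optional climate-similarity
#' threshold, seasonal switch, loss-bin edges and projection settings.
#'
#' @param synth a [synth_config()] describing the synthetic inputs
#' @param factors integer vector of linear coarsening factors (1 = the
#'   generation grid); must be non-empty, positive, sorted ascending
#' @param window moving-window size (odd, >= 3)
#' @param min_excess minimum excess loss (pp)
#' @param start_years,end_years the analysis windows
#' @param similarity optional climate-similarity threshold (%); `NULL` skips
#'   the filter
#' @param seasonal also compute per-season estimates?
#' @param edges loss-bin edges for the binned response
#' @param cap projection loss cap (pp)
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(synth = synth_config(),
                            factors = 1L,
                            window = 3L, min_excess = 0.1,
                            start_years = NULL, end_years = NULL,
                            similarity = NULL, seasonal = FALSE,
                            edges = c(0.1, 5, 10, 20, 30, Inf),
                            cap = 30) {
  yrs <- synth$years
  if (is.null(start_years)) start_years <- yrs[1:5]
  if (is.null(end_years)) end_years <- yrs[(length(yrs) - 4):length(yrs)]
  cfg <- list(synth = synth, factors = as.integer(factors), window = as.integer(window),
              min_excess = min_excess, start_years = as.integer(start_years),
              end_years = as.integer(end_years), similarity = similarity,
              seasonal = seasonal, edges = edges, cap = cap)
  if (!length(cfg$factors)) stop("no analysis scales (factors) configured", call. = FALSE)
  if (any(cfg$factors < 1L)) stop("factors must be >= 1", call. = FALSE)
  if (is.unsorted(cfg$factors)) stop("factors must be sorted ascending", call. = FALSE)
  if (!all(c(cfg$start_years, cfg$end_years) %in% yrs))
    stop("analysis windows outside the configured years", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-attribution pipeline
#'
#' Generates (or accepts) a synthetic bundle, then per analysis scale:
#' aggregates loss and mask, conservatively regrids precipitation, finds
#' pairs, computes pair records (optionally similarity-filtered), estimates
#' annual (and optionally seasonal) sensitivities and the binned response,
#' and projects the bundle's future-loss scenario under linear, capped and
#' nonlinear assumptions. Writes pair CSVs, estimate CSV/JSON, projection
#' summaries and a machine-readable manifest to `out_dir`; returns the
#' results invisibly.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed); `NULL` skips writing
#' @param bundle optional pre-generated bundle from [simulate_bundle()]
#'   (must match `config$synth`)
#' @return invisible list: `estimates`, `binned`, `projection_summary`,
#'   `pair_counts`, `manifest`
#' @export
run_pipeline <- function(config, out_dir = NULL, bundle = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  if (is.null(bundle)) bundle <- simulate_bundle(config$synth)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  est_rows <- list(); binned_out <- list(); proj_rows <- list()
  pair_counts <- integer(0)
  for (f in config$factors) {
    loss <- loss_between(bundle$cover, config$start_years, config$end_years)
    mask <- bundle$mask
    cube <- bundle$precip
    future <- bundle$future
    if (f > 1L) {
      loss <- aggregate_loss(loss, f)
      mask <- aggregate_mask(mask, f)
      cube <- regrid_precip(cube, grid_lat(loss), grid_lon(loss),
                            method = "conservative")
      future <- loss_grid(unclass(regrid_precip(future, grid_lat(loss),
                                                grid_lon(loss),
                                                method = "conservative")),
                          grid_lat(loss), grid_lon(loss),
                          period = attr(bundle$future, "period"))
    }
    ps <- find_pairs(loss, mask, window = config$window,
                     min_excess = config$min_excess)
    rec <- pair_delta_p(ps, cube, config$start_years, config$end_years)
    if (!is.null(config$similarity))
      rec <- climate_similarity_filter(rec, config$similarity)
    pair_counts[as.character(f)] <- nrow(rec)
    lbl <- tibble::tibble(factor = f, season = "annual")
    est_rows[[length(est_rows) + 1L]] <-
      dplyr::bind_cols(lbl, estimate_sensitivity(rec))
    if (config$seasonal) {
      smap <- season_map(cube)
      se <- seasonal_estimate(ps, cube, smap, config$start_years, config$end_years)
      est_rows[[length(est_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(factor = f), se)
    }
    br <- binned_response(rec, config$edges)
    binned_out[[as.character(f)]] <- br
    sens <- estimate_sensitivity(rec)
    masks <- list(domain = mask)
    baseline <- period_mean(cube, config$start_years)
    for (mode in c("linear", "capped", "nonlinear")) {
      field <- switch(mode,
                      linear = project_linear(future, sens),
                      capped = project_capped(future, sens, cap = config$cap),
                      nonlinear = project_nonlinear(future, br))
      rs <- regional_summary(field, masks, baseline = baseline)
      proj_rows[[length(proj_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(factor = f, mode = mode), rs)
    }
    if (!is.null(out_dir))
      utils::write.csv(rec, file.path(out_dir, sprintf("pairs_f%d.csv", f)),
                       row.names = FALSE)
  }
  estimates <- dplyr::bind_rows(est_rows)
  projection_summary <- dplyr::bind_rows(proj_rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("defoprecip")),
    config_hash = rlang::hash(config),
    seed = config$synth$seed,
    pair_counts = as.list(pair_counts),
    results_hash = rlang::hash(list(estimates, projection_summary)))
  if (!is.null(out_dir)) {
    write_estimates(estimates, file.path(out_dir, "estimates.csv"),
                    file.path(out_dir, "estimates.json"))
    utils::write.csv(projection_summary,
                     file.path(out_dir, "projection_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(estimates = estimates, binned = binned_out,
                 projection_summary = projection_summary,
                 pair_counts = pair_counts, manifest = manifest))
}
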