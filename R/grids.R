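# Regular lat/lon grid containers. Values are matrices (rows = latitude,
# cols = longitude) or arrays with a trailing time dimension; coordinates are
# cell-centre degrees, strictly monotone increasing.

assert_coords <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || length(lat) < 1L || length(lon) < 1L)
    stop("lat/lon must be non-empty numeric vectors", call. = FALSE)
  if (length(lat) > 1L && any(diff(lat) <= 0))
    stop("lat must be strictly increasing", call. = FALSE)
  if (length(lon) > 1L && any(diff(lon) <= 0))
    stop("lon must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

set_grid_attrs <- function(x, lat, lon) {
  attr(x, "lat") <- as.numeric(lat)
  attr(x, "lon") <- as.numeric(lon)
  x
}

#' Latitude coordinates of a grid object
#' @param x a grid object (loss grid, cover series or precipitation cube)
#' @return numeric vector of cell-centre latitudes (degrees)
#' @export
grid_lat <- function(x) attr(x, "lat")

#' Longitude coordinates of a grid object
#' @param x a grid object
#' @return numeric vector of cell-centre longitudes (degrees)
#' @export
grid_lon <- function(x) attr(x, "lon")

#' Test whether two grid objects share the same spatial reference
#' @param a,b grid objects
#' @param tol coordinate tolerance in degrees
#' @return logical scalar
#' @export
same_grid <- function(a, b, tol = 1e-8) {
  la <- grid_lat(a); lb <- grid_lat(b)
  oa <- grid_lon(a); ob <- grid_lon(b)
  length(la) == length(lb) && length(oa) == length(ob) &&
    all(abs(la - lb) < tol) && all(abs(oa - ob) < tol)
}

#' Construct a forest-loss grid
#'
#' Per-pixel forest-cover loss in percentage points over a stated period.
#'
#' @param values numeric matrix, rows = lat, cols = lon; values in \[0, 100\]
#'   or `NA`
#' @param lat,lon cell-centre coordinates (degrees, strictly increasing)
#' @param period optional character label, e.g. `"2003-2017"`
#' @return a `loss_grid` object (matrix with coordinate attributes)
#' @export
loss_grid <- function(values, lat, lon, period = NULL) {
  values <- as.matrix(values)
  assert_coords(lat, lon)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("loss values must be length(lat) x length(lon)", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 100 + 1e-9))
    stop("loss values must lie in [0, 100] percentage points", call. = FALSE)
  out <- set_grid_attrs(values, lat, lon)
  attr(out, "period") <- period
  class(out) <- c("loss_grid", "matrix", "array")
  out
}

#' Construct a forest-cover time series
#'
#' Fractional canopy cover (%) on a fixed grid for a sequence of years.
#' Cover must be non-increasing through time (a loss-only process).
#'
#' @param values numeric array `lat x lon x year`, values in \[0, 100\] or `NA`
#' @param lat,lon cell-centre coordinates (degrees)
#' @param years integer vector, one per slice
#' @return a `cover_series` object
#' @export
cover_series <- function(values, lat, lon, years) {
  if (length(dim(values)) != 3L) stop("cover values must be a 3-d array", call. = FALSE)
  assert_coords(lat, lon)
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon) ||
      dim(values)[3] != length(years))
    stop("cover dimensions must be lat x lon x years", call. = FALSE)
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 100 + 1e-9))
    stop("cover must lie in [0, 100] percent", call. = FALSE)
  if (length(years) > 1L) {
    d <- values[, , -1L, drop = FALSE] - values[, , -length(years), drop = FALSE]
    if (any(d > 1e-9, na.rm = TRUE))
      stop("cover must be non-increasing over time", call. = FALSE)
  }
  out <- set_grid_attrs(values, lat, lon)
  attr(out, "years") <- as.integer(years)
  class(out) <- c("cover_series", "array")
  out
}

#' Construct a monthly precipitation cube
#'
#' @param values numeric array `lat x lon x time` (mm/month, non-negative or
#'   `NA`); time runs January..December within each year, years consecutive
#' @param lat,lon cell-centre coordinates (degrees)
#' @param years integer vector of years; the time dimension must equal
#'   `12 * length(years)`
#' @param category dataset category, one of `"satellite"`, `"station"`,
#'   `"reanalysis"`
#' @return a `precip_cube` object
#' @export
precip_cube <- function(values, lat, lon, years,
                        category = c("satellite", "station", "reanalysis")) {
  category <- match.arg(category)
  if (length(dim(values)) != 3L) stop("precip values must be a 3-d array", call. = FALSE)
  assert_coords(lat, lon)
  if (dim(values)[3] != 12L * length(years))
    stop("time dimension must be 12 * length(years)", call. = FALSE)
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon))
    stop("precip dimensions must be lat x lon x time", call. = FALSE)
  if (any(values < -1e-9, na.rm = TRUE))
    stop("precipitation must be non-negative", call. = FALSE)
  out <- set_grid_attrs(values, lat, lon)
  attr(out, "years") <- as.integer(years)
  attr(out, "category") <- category
  class(out) <- c("precip_cube", "array")
  out
}

#' Year and month of every time slice of a cube
#' @param cube a `precip_cube`
#' @return data.frame with integer columns `year` and `month`
#' @export
cube_time <- function(cube) {
  years <- attr(cube, "years")
  data.frame(year = rep(years, each = 12L), month = rep.int(1:12, length(years)))
}

#' Cosine-latitude area weights
#'
#' Relative cell areas on a regular lat/lon grid, proportional to the cosine
#' of the cell-centre latitude.
#'
#' @param lat cell-centre latitudes in degrees
#' @return numeric vector of weights, one per latitude row
#' @export
coslat_weights <- function(lat) cos(lat * pi / 180)

#' @export
print.loss_grid <- function(x, ...) {
  cat(sprintf("<loss_grid> %d x %d pixels", nrow(x), ncol(x)))
  if (!is.null(attr(x, "period"))) cat(", period", attr(x, "period"))
  cat(sprintf("\n  loss: %.2f-%.2f pp, %d missing\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))))
  invisible(x)
}

#' @export
print.precip_cube <- function(x, ...) {
  yrs <- attr(x, "years")
  cat(sprintf("<precip_cube> %d x %d pixels, %d months (%d-%d), category %s\n",
              dim(x)[1], dim(x)[2], dim(x)[3], min(yrs), max(yrs),
              attr(x, "category")))
  invisible(x)
}

#' @export
print.cover_series <- function(x, ...) {
  yrs <- attr(x, "years")
  cat(sprintf("<cover_series> %d x %d pixels, years %d-%d\n",
              dim(x)[1], dim(x)[2], min(yrs), max(yrs)))
  invisible(x)
}
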