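# Multi-scale grid operations: block aggregation of fractional loss,
# bilinear regridding of precipitation cubes, and period means.

block_apply_sum <- function(x, f) {
  nbr <- nrow(x) %/% f; nbc <- ncol(x) %/% f
  dim(x) <- NULL
  a <- array(x, c(f, nbr, f, nbc))
  apply(a, c(2L, 4L), sum)
}

#' Aggregate a forest-loss grid to a coarser resolution
#'
#' Coarse cell value is the area-weighted (cosine-latitude) mean of the fine
#' fractional losses inside each `factor x factor` block -- i.e. total lost
#' forest area divided by block area, expressed in percent. Missing fine cells
#' are excluded from the weight; a coarse cell is missing when more than half
#' of its fine cells are missing. Blocks that do not fully fit at the grid
#' edge are dropped with a warning.
#'
#' @param fine a [loss_grid()]
#' @param factor integer >= 1, the linear coarsening factor
#' @return a [loss_grid()] on the coarse grid
#' @export
aggregate_loss <- function(fine, factor) {
  if (!inherits(fine, "loss_grid")) stop("fine must be a loss_grid", call. = FALSE)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(fine)
  lat <- grid_lat(fine); lon <- grid_lon(fine)
  nbr <- nrow(fine) %/% factor; nbc <- ncol(fine) %/% factor
  if (nbr < 1L || nbc < 1L) stop("factor larger than the grid", call. = FALSE)
  if (nbr * factor < nrow(fine) || nbc * factor < ncol(fine))
    warning("grid shape not divisible by factor; trailing cells dropped")
  x <- unclass(fine)[seq_len(nbr * factor), seq_len(nbc * factor), drop = FALSE]
  w <- matrix(coslat_weights(lat[seq_len(nbr * factor)]), nrow(x), ncol(x))
  ok <- !is.na(x)
  num <- block_apply_sum(ifelse(ok, w * x, 0), factor)
  den <- block_apply_sum(ifelse(ok, w, 0), factor)
  n_ok <- block_apply_sum(ok + 0, factor)
  out <- num / den
  out[n_ok < factor^2 / 2] <- NA_real_  # >50% of fine cells missing
  clat <- colMeans(matrix(lat[seq_len(nbr * factor)], factor))
  clon <- colMeans(matrix(lon[seq_len(nbc * factor)], factor))
  loss_grid(out, clat, clon, period = attr(fine, "period"))
}

#' Aggregate a forest-cover series to a coarser resolution
#'
#' Applies the same area-weighted block mean as [aggregate_loss()] to every
#' yearly slice.
#'
#' @param cover a [cover_series()]
#' @param factor integer coarsening factor
#' @return a [cover_series()] on the coarse grid
#' @export
aggregate_cover <- function(cover, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(cover)
  lat <- grid_lat(cover); lon <- grid_lon(cover)
  nbr <- dim(cover)[1] %/% factor; nbc <- dim(cover)[2] %/% factor
  if (nbr < 1L || nbc < 1L) stop("factor larger than the grid", call. = FALSE)
  w <- matrix(coslat_weights(lat[seq_len(nbr * factor)]),
              nbr * factor, nbc * factor)
  wsum <- block_apply_sum(w, factor)
  ny <- dim(cover)[3]
  out <- array(0, c(nbr, nbc, ny))
  for (t in seq_len(ny)) {
    z <- cover[seq_len(nbr * factor), seq_len(nbc * factor), t]
    out[, , t] <- block_apply_sum(w * z, factor) / wsum
  }
  clat <- colMeans(matrix(lat[seq_len(nbr * factor)], factor))
  clon <- colMeans(matrix(lon[seq_len(nbc * factor)], factor))
  cover_series(out, clat, clon, attr(cover, "years"))
}

#' Aggregate a boolean mask to a coarser resolution
#'
#' A coarse cell is in the mask when at least half of its fine cells are.
#'
#' @param mask logical matrix
#' @param factor integer coarsening factor
#' @return logical matrix on the coarse grid
#' @export
aggregate_mask <- function(mask, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(mask)
  nbr <- nrow(mask) %/% factor; nbc <- ncol(mask) %/% factor
  m <- mask[seq_len(nbr * factor), seq_len(nbc * factor), drop = FALSE]
  block_apply_sum(m + 0, factor) >= factor^2 / 2
}

bilinear_slice <- function(z, lat, lon, tlat, tlon) {
  # pracma::interp2 takes Z with rows = y (lat) and cols = x (lon)
  pts <- expand.grid(lat = tlat, lon = tlon)
  v <- pracma::interp2(x = lon, y = lat, Z = z,
                       xp = pts$lon, yp = pts$lat, method = "linear")
  matrix(v, length(tlat), length(tlon))
}

#' Regrid a precipitation cube onto a target grid
#'
#' Months are treated independently. The default scheme interpolates
#' cell-centre values bilinearly onto the target cell centres; the
#' `"conservative"` scheme takes area-weighted block means and requires the
#' target to be an exact integer coarsening of the source grid.
#'
#' @param cube a [precip_cube()] (or a plain matrix with grid attributes)
#' @param target_lat,target_lon target cell-centre coordinates; must lie
#'   inside the source domain
#' @param method `"bilinear"` (default) or `"conservative"`
#' @return a [precip_cube()] (or matrix) on the target grid
#' @export
regrid_precip <- function(cube, target_lat, target_lon,
                          method = c("bilinear", "conservative")) {
  method <- match.arg(method)
  assert_coords(target_lat, target_lon)
  lat <- grid_lat(cube); lon <- grid_lon(cube)
  if (min(target_lat) < min(lat) - 1e-9 || max(target_lat) > max(lat) + 1e-9 ||
      min(target_lon) < min(lon) - 1e-9 || max(target_lon) > max(lon) + 1e-9)
    stop("target grid does not overlap the source domain", call. = FALSE)
  if (method == "conservative")
    return(regrid_conservative(cube, target_lat, target_lon))
  if (is.matrix(cube))
    return(set_grid_attrs(bilinear_slice(unclass(cube), lat, lon,
                                         target_lat, target_lon),
                          target_lat, target_lon))
  nt <- dim(cube)[3]
  out <- array(0, c(length(target_lat), length(target_lon), nt))
  for (t in seq_len(nt))
    out[, , t] <- bilinear_slice(cube[, , t], lat, lon, target_lat, target_lon)
  precip_cube(out, target_lat, target_lon, attr(cube, "years"),
              category = attr(cube, "category"))
}

regrid_conservative <- function(cube, target_lat, target_lon) {
  lat <- grid_lat(cube)
  f <- length(lat) %/% length(target_lat)
  if (f < 1L || length(lat) != f * length(target_lat) ||
      length(grid_lon(cube)) != f * length(target_lon))
    stop("conservative regridding needs an exact integer coarsening", call. = FALSE)
  w <- matrix(coslat_weights(lat), dim(cube)[1], dim(cube)[2])
  wsum <- block_apply_sum(w, f)
  agg1 <- function(z) block_apply_sum(w * z, f) / wsum
  if (is.matrix(cube))
    return(set_grid_attrs(agg1(unclass(cube)), target_lat, target_lon))
  nt <- dim(cube)[3]
  out <- array(0, c(length(target_lat), length(target_lon), nt))
  for (t in seq_len(nt)) out[, , t] <- agg1(cube[, , t])
  precip_cube(out, target_lat, target_lon, attr(cube, "years"),
              category = attr(cube, "category"))
}

#' Multi-year period mean of a precipitation cube
#'
#' Mean over all months of the listed years (optionally restricted to a fixed
#' subset of calendar months). A pixel is missing when any contributing month
#' is missing, which avoids seasonally biased means.
#'
#' @param cube a [precip_cube()]
#' @param years years to average over; all must be present in the cube
#' @param months calendar months to include (default all 12)
#' @return numeric matrix (mm/month) with grid attributes
#' @export
period_mean <- function(cube, years, months = 1:12) {
  tt <- cube_time(cube)
  if (!all(years %in% attr(cube, "years")))
    stop("requested years outside the cube's span", call. = FALSE)
  idx <- which(tt$year %in% years & tt$month %in% months)
  m <- apply(cube[, , idx, drop = FALSE], c(1L, 2L), mean)  # NA if any month NA
  set_grid_attrs(m, grid_lat(cube), grid_lon(cube))
}

# Period mean with per-pixel month sets taken from a season map.
period_mean_seasonal <- function(cube, years, smap, season) {
  code <- c(dry = 1L, transition = 2L, wet = 3L)[[season]]
  lat <- grid_lat(cube); lon <- grid_lon(cube)
  acc <- matrix(0, length(lat), length(lon))
  cnt <- matrix(0L, length(lat), length(lon))
  for (m in 1:12) {
    mm <- period_mean(cube, years, months = m)
    sel <- smap[, , m] == code
    sel[is.na(sel)] <- FALSE
    acc[sel] <- acc[sel] + mm[sel]
    acc[sel & is.na(mm)] <- NA_real_
    cnt[sel] <- cnt[sel] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  set_grid_attrs(out, lat, lon)
}

#' Forest loss between two analysis windows
#'
#' Computes the pp loss grid that enters the pairing stage. The default
#' `"window_mean"` method takes the difference between the mean cover over
#' the start-window years and the mean cover over the end-window years,
#' mirroring the multi-year averaging applied to precipitation, so that loss
#' and precipitation change refer to the same periods. `"endpoints"` takes
#' the total first-to-last-year loss instead.
#'
#' @param cover a [cover_series()]
#' @param start_years,end_years the two analysis windows
#' @param method `"window_mean"` or `"endpoints"`
#' @return a [loss_grid()] labelled with the window span
#' @export
loss_between <- function(cover, start_years, end_years,
                         method = c("window_mean", "endpoints")) {
  method <- match.arg(method)
  years <- attr(cover, "years")
  if (!all(c(start_years, end_years) %in% years))
    stop("window years outside the cover series", call. = FALSE)
  if (method == "window_mean") {
    cs <- apply(cover[, , match(start_years, years), drop = FALSE], c(1, 2), mean)
    ce <- apply(cover[, , match(end_years, years), drop = FALSE], c(1, 2), mean)
    v <- cs - ce
  } else {
    v <- cover[, , match(min(start_years), years)] -
      cover[, , match(max(end_years), years)]
  }
  v <- pmax(v, 0)
  loss_grid(v, grid_lat(cover), grid_lon(cover),
            period = paste0(min(start_years), "-", max(end_years)))
}
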