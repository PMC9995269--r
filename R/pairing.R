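# Moving-window nearest-neighbour pairing: each in-mask pixel is compared
# with the strictly-less-deforested pixels of its surrounding window; the
# unweighted mean of those neighbours is the local control.

#' Find deforested-pixel / control pairs
#'
#' For every in-mask, non-missing pixel, the eligible neighbours are the
#' in-mask, non-missing cells of the surrounding `window x window`
#' neighbourhood (centre excluded) with strictly less forest loss than the
#' centre; ties carry no treatment contrast and are excluded. The control
#' loss is the composite over eligible neighbours, by default their
#' unweighted mean (`"mean"`), alternatively the single least-deforested
#' neighbour (`"min"`) or the single most similar lower-loss neighbour
#' (`"nearest"`). The pixel becomes a deforested pixel when its excess loss
#' over the control is at least `min_excess`. Windows truncate at domain
#' edges; every pixel is evaluated independently, so a deforested pixel may
#' also serve inside another pixel's control.
#'
#' @param loss a [loss_grid()]
#' @param mask logical matrix on the same grid
#' @param window odd window size >= 3 (the paper-style defaults are 3 and 5)
#' @param min_excess minimum excess loss in percentage points (default 0.1)
#' @param composite control-compositing rule: `"mean"`, `"min"` or
#'   `"nearest"`
#' @return a `pair_set`: list with `pairs` (tibble: `row`, `col`, `loss_def`,
#'   `ctl_loss`, `d_f`, `n_ctl`) and `neighbours` (list of linear pixel
#'   indices used as each pair's control)
#' @export
find_pairs <- function(loss, mask, window = 3L, min_excess = 0.1,
                       composite = c("mean", "min", "nearest")) {
  composite <- match.arg(composite)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  nr <- nrow(loss); nc <- ncol(loss)
  if (window > nr || window > nc)
    stop("window larger than the grid", call. = FALSE)
  if (!is.logical(mask) || nrow(mask) != nr || ncol(mask) != nc)
    stop("mask must be a logical matrix on the loss grid", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (min_excess < 0) stop("min_excess must be >= 0", call. = FALSE)
  h <- window %/% 2L
  x <- unclass(loss)
  ok <- mask & !is.na(x)
  rows <- integer(0); cols <- integer(0)
  loss_def <- numeric(0); ctl <- numeric(0); nct <- integer(0)
  nbrs <- list()
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!ok[i, j]) next
      r1 <- max(1L, i - h); r2 <- min(nr, i + h)
      c1 <- max(1L, j - h); c2 <- min(nc, j + h)
      centre <- x[i, j]
      rr <- rep.int(r1:r2, c2 - c1 + 1L)
      cc <- rep(c1:c2, each = r2 - r1 + 1L)
      lin <- rr + (cc - 1L) * nr
      lin <- lin[lin != i + (j - 1L) * nr]
      lin <- lin[ok[lin] & x[lin] < centre]
      if (!length(lin)) next
      if (composite == "min") {
        lin <- lin[which.min(x[lin])]
      } else if (composite == "nearest") {
        lin <- lin[which.max(x[lin])]
      }
      cl <- mean(x[lin])
      df <- centre - cl
      if (df < min_excess) next
      k <- k + 1L
      rows[k] <- i; cols[k] <- j
      loss_def[k] <- centre; ctl[k] <- cl; nct[k] <- length(lin)
      nbrs[[k]] <- lin
    }
  }
  out <- list(pairs = tibble::tibble(row = rows, col = cols,
                                     loss_def = loss_def, ctl_loss = ctl,
                                     d_f = loss_def - ctl, n_ctl = nct),
              neighbours = nbrs,
              lat = grid_lat(loss), lon = grid_lon(loss),
              window = window, min_excess = min_excess, composite = composite)
  class(out) <- "pair_set"
  out
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d deforested pixels (window %dx%d, min excess %.2f pp, %s control)\n",
              nrow(x$pairs), x$window, x$window, x$min_excess, x$composite))
  invisible(x)
}

pair_records_from_maps <- function(ps, p_start, p_end) {
  chg <- p_end - p_start
  nr <- nrow(chg)
  n <- nrow(ps$pairs)
  keep <- logical(n)
  dp_def <- dp_ctl <- psd <- psc <- numeric(n)
  for (k in seq_len(n)) {
    i <- ps$pairs$row[k]; j <- ps$pairs$col[k]
    lin0 <- i + (j - 1L) * nr
    if (is.na(chg[lin0]) || is.na(p_start[lin0])) next
    nb <- ps$neighbours[[k]]
    nb <- nb[!is.na(chg[nb]) & !is.na(p_start[nb])]
    if (!length(nb)) next
    keep[k] <- TRUE
    dp_def[k] <- chg[lin0]
    dp_ctl[k] <- mean(chg[nb])
    psd[k] <- p_start[lin0]
    psc[k] <- mean(p_start[nb])
  }
  pr <- ps$pairs[keep, ]
  dp <- dp_def[keep] - dp_ctl[keep]
  psd <- psd[keep]
  rec <- tibble::tibble(
    row = pr$row, col = pr$col,
    lat = ps$lat[pr$row], lon = ps$lon[pr$col],
    d_f = pr$d_f, n_ctl = pr$n_ctl,
    dp_def = dp_def[keep], dp_ctl = dp_ctl[keep], dp = dp,
    p_start_def = psd, p_start_ctl = psc[keep],
    dp_rel = 100 * dp / psd,
    sens = dp / pr$d_f, sens_rel = (100 * dp / psd) / pr$d_f)
  if (nrow(rec) < n)
    message(sprintf("%d pairs dropped (missing precipitation in centre or all controls)",
                    n - nrow(rec)))
  rec
}

#' Precipitation change of each pair
#'
#' Computes, for each pair, the deforested pixel's precipitation change
#' (end-window mean minus start-window mean) minus the control change (mean
#' change over the pair's eligible neighbours, excluding any with missing
#' precipitation; the pair is dropped when none survive). Records the
#' absolute change `dp` (mm/month), the relative change `dp_rel` (%, with the
#' deforested pixel's start-period mean as denominator) and the per-pair
#' sensitivities `sens = dp/d_f` and `sens_rel = dp_rel/d_f`.
#'
#' @param ps a `pair_set` from [find_pairs()]
#' @param cube a [precip_cube()] on the pairing grid
#' @param start_years,end_years the two analysis windows (e.g. 2003:2007 and
#'   2013:2017)
#' @param months calendar months entering the period means (default all 12)
#' @return a tibble of pair records
#' @export
pair_delta_p <- function(ps, cube, start_years, end_years, months = 1:12) {
  if (!inherits(ps, "pair_set")) stop("ps must be a pair_set", call. = FALSE)
  if (length(grid_lat(cube)) != length(ps$lat) ||
      length(grid_lon(cube)) != length(ps$lon) ||
      any(abs(grid_lat(cube) - ps$lat) > 1e-8) ||
      any(abs(grid_lon(cube) - ps$lon) > 1e-8))
    stop("cube must be on the pairing grid (regrid first)", call. = FALSE)
  p_start <- period_mean(cube, start_years, months)
  p_end <- period_mean(cube, end_years, months)
  pair_records_from_maps(ps, p_start, p_end)
}

#' Filter pairs by pre-deforestation climate similarity
#'
#' Retains pairs whose start-period mean precipitation differs between the
#' deforested pixel and its control by less than `threshold` percent of the
#' deforested pixel's mean. Pairs with a zero start-period mean cannot be
#' assessed and are dropped with a message.
#'
#' @param records pair records from [pair_delta_p()]
#' @param threshold relative difference threshold in percent (default 10;
#'   100 makes the filter a no-op for any physically sensible pair)
#' @return the filtered pair records
#' @export
climate_similarity_filter <- function(records, threshold = 10) {
  zero <- records$p_start_def == 0
  if (any(zero)) {
    message(sprintf("%d pairs dropped (zero start-period mean)", sum(zero)))
    records <- records[!zero, ]
  }
  rel <- 100 * abs(records$p_start_def - records$p_start_ctl) / records$p_start_def
  records[rel < threshold, ]
}
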