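# Projection of future precipitation change from forest-loss scenarios under
# linear, capped and binned (piecewise) sensitivity assumptions, with +/-1
# standard-error uncertainty bands, plus cos-latitude regional aggregation.

as_sens <- function(sensitivity) {
  if (is.data.frame(sensitivity))
    return(list(median = sensitivity$median_sens[1], se = sensitivity$se[1]))
  if (is.list(sensitivity) && !is.null(sensitivity$median))
    return(list(median = sensitivity$median,
                se = if (is.null(sensitivity$se)) NA_real_ else sensitivity$se))
  stop("sensitivity must be an estimate row or list(median =, se =)", call. = FALSE)
}

projection_field <- function(dp, lower, upper, loss, mode) {
  out <- list(dp = set_grid_attrs(dp, grid_lat(loss), grid_lon(loss)),
              lower = set_grid_attrs(lower, grid_lat(loss), grid_lon(loss)),
              upper = set_grid_attrs(upper, grid_lat(loss), grid_lon(loss)),
              mode = mode)
  class(out) <- "projection_field"
  out
}

#' Linear projection of precipitation change from projected forest loss
#'
#' Multiplies each pixel's projected pp loss by the median sensitivity
#' (mm/month per pp). The uncertainty band scales the loss by the median
#' plus/minus one standard error; `lower` is the pixelwise smaller (more
#' negative, for a drying response) of the two.
#'
#' @param loss a [loss_grid()] of projected pp loss, on the analysis scale
#' @param sensitivity an [estimate_sensitivity()] row, or
#'   `list(median =, se =)`
#' @return a `projection_field` with elements `dp`, `lower`, `upper` (all
#'   mm/month matrices with grid attributes) and `mode`
#' @export
project_linear <- function(loss, sensitivity) {
  s <- as_sens(sensitivity)
  if (is.na(s$median)) stop("missing sensitivity", call. = FALSE)
  v <- unclass(loss)
  dp <- v * s$median
  if (is.na(s$se)) {
    lo <- up <- dp
  } else {
    a <- v * (s$median - s$se); b <- v * (s$median + s$se)
    lo <- pmin(a, b); up <- pmax(a, b)
  }
  projection_field(dp, lo, up, loss, "linear")
}

#' Capped projection of precipitation change
#'
#' As [project_linear()], with each pixel's loss truncated at `cap`
#' percentage points -- the default 30 pp marks the upper range of forest
#' loss that is well sampled observationally.
#'
#' @inheritParams project_linear
#' @param cap loss cap in pp (default 30)
#' @return a `projection_field` with `mode = "capped"`
#' @export
project_capped <- function(loss, sensitivity, cap = 30) {
  capped <- loss_grid(pmin(unclass(loss), cap), grid_lat(loss), grid_lon(loss),
                      period = attr(loss, "period"))
  out <- project_linear(capped, sensitivity)
  out$mode <- "capped"
  out
}

#' Binned (piecewise) nonlinear projection of precipitation change
#'
#' Applies a piecewise-constant sensitivity: each pixel's total projected
#' loss is multiplied by the median sensitivity of the loss bin that
#' contains it. Losses above the top bin use the top bin's sensitivity;
#' losses below the lowest edge are treated as zero change; bins with no
#' pairs fall back to the nearest populated lower bin. Bands use each bin's
#' standard error where available.
#'
#' @param loss a [loss_grid()] of projected pp loss
#' @param binned a [binned_response()]
#' @return a `projection_field` with `mode = "nonlinear"`
#' @export
project_nonlinear <- function(loss, binned) {
  if (!inherits(binned, "binned_response"))
    stop("binned must be a binned_response", call. = FALSE)
  edges <- attr(binned, "edges")
  med <- binned$median_sens; se <- binned$se
  # fall back to nearest populated lower (then upper) bin
  for (b in seq_along(med)) {
    if (!is.na(med[b])) next
    lower <- which(!is.na(med[seq_len(b - 1L)]))
    upper <- which(!is.na(med)); upper <- upper[upper > b]
    src <- if (length(lower)) max(lower) else if (length(upper)) min(upper) else NA_integer_
    if (is.na(src)) stop("binned response has no populated bin", call. = FALSE)
    med[b] <- med[src]; se[b] <- se[src]
  }
  v <- unclass(loss)
  bin <- findInterval(v, edges, rightmost.closed = FALSE)
  bin[bin >= length(edges)] <- length(edges) - 1L  # above top edge: top bin
  s_px <- ifelse(bin == 0L, 0, med[pmax(bin, 1L)])
  se_px <- ifelse(bin == 0L, 0, se[pmax(bin, 1L)])
  se_px[is.na(se_px)] <- 0
  dp <- v * s_px
  a <- v * (s_px - se_px); b2 <- v * (s_px + se_px)
  dim(dp) <- dim(a) <- dim(b2) <- dim(v)
  projection_field(dp, pmin(a, b2), pmax(a, b2), loss, "nonlinear")
}

#' Regional aggregates of a projection field
#'
#' Cosine-latitude area-weighted regional means of the projected change and,
#' given a baseline precipitation map, of the relative change
#' (100 * mean change / mean baseline, %).
#'
#' @param field a `projection_field`
#' @param masks a named list of logical region masks on the field's grid
#'   (a single matrix is treated as one region named `"region"`)
#' @param baseline optional baseline precipitation map (mm/month) for
#'   relative changes
#' @return tibble: `region`, `dp`, `dp_lower`, `dp_upper`, `dp_rel` (% or
#'   `NA`), `n_pixels`
#' @export
regional_summary <- function(field, masks, baseline = NULL) {
  if (is.matrix(masks)) masks <- list(region = masks)
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be named", call. = FALSE)
  lat <- grid_lat(field$dp)
  w_full <- matrix(coslat_weights(lat), nrow(field$dp), ncol(field$dp))
  rows <- lapply(names(masks), function(rg) {
    m <- masks[[rg]]
    sel <- m & !is.na(field$dp)
    if (!any(sel)) stop(sprintf("region mask '%s' is empty", rg), call. = FALSE)
    w <- w_full[sel]
    wm <- function(x) sum(w * x[sel]) / sum(w)
    rel <- NA_real_
    if (!is.null(baseline)) rel <- 100 * wm(field$dp) / wm(baseline)
    tibble::tibble(region = rg, dp = wm(field$dp),
                   dp_lower = wm(field$lower), dp_upper = wm(field$upper),
                   dp_rel = rel, n_pixels = sum(sel))
  })
  dplyr::bind_rows(rows)
}

#' Projected forest loss from a multi-category cover scenario
#'
#' Sums cover across forest categories per year and differences against a
#' baseline year, yielding pp loss (negative changes, i.e. gains, floor at
#' zero).
#'
#' @param cover_by_category list of [cover_series()], one per forest
#'   category, on a shared grid and year axis
#' @param baseline_year,target_year years present in the series
#' @return a [loss_grid()]
#' @export
scenario_loss <- function(cover_by_category, baseline_year, target_year) {
  if (!length(cover_by_category)) stop("no cover categories", call. = FALSE)
  years <- attr(cover_by_category[[1]], "years")
  for (cv in cover_by_category)
    if (!identical(attr(cv, "years"), years) ||
        !same_grid(cv, cover_by_category[[1]]))
      stop("cover categories must share grid and years", call. = FALSE)
  if (!all(c(baseline_year, target_year) %in% years))
    stop("baseline/target year outside the series", call. = FALSE)
  ib <- match(baseline_year, years); it <- match(target_year, years)
  tot_b <- Reduce(`+`, lapply(cover_by_category, function(cv) cv[, , ib]))
  tot_t <- Reduce(`+`, lapply(cover_by_category, function(cv) cv[, , it]))
  v <- pmax(pmin(tot_b - tot_t, 100), 0)
  loss_grid(v, grid_lat(cover_by_category[[1]]), grid_lon(cover_by_category[[1]]),
            period = paste0(baseline_year, "-", target_year))
}

#' Crop-yield impact of forest loss via the precipitation pathway
#'
#' Chains a relative precipitation sensitivity (% precipitation per pp of
#' forest loss) with a crop-yield elasticity to precipitation (% yield per
#' 1% precipitation): a 10-pp loss at 0.25 %/pp sensitivity and 0.5
#' elasticity gives a 1.25% yield decline.
#'
#' @param loss_pp forest loss in percentage points
#' @param rel_sensitivity relative precipitation decline per pp loss
#'   (positive number, % per pp)
#' @param yield_elasticity yield decline per 1% precipitation decline
#'   (default 0.5)
#' @return yield decline in percent (positive = decline)
#' @export
crop_yield_impact <- function(loss_pp, rel_sensitivity, yield_elasticity = 0.5) {
  loss_pp * rel_sensitivity * yield_elasticity
}

#' @export
print.projection_field <- function(x, ...) {
  cat(sprintf("<projection_field> mode %s, %d x %d pixels, mean dP %.2f mm/month\n",
              x$mode, nrow(x$dp), ncol(x$dp), mean(x$dp, na.rm = TRUE)))
  invisible(x)
}
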