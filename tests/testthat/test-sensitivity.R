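mk_records <- function(sens, dp_def = sens, dp_ctl = 0 * sens) {
  tibble::tibble(d_f = rep(1, length(sens)), n_ctl = 1L,
                 dp_def = dp_def, dp_ctl = dp_ctl, dp = dp_def - dp_ctl,
                 p_start_def = 165, p_start_ctl = 165,
                 dp_rel = 100 * (dp_def - dp_ctl) / 165,
                 sens = sens, sens_rel = 100 * (dp_def - dp_ctl) / 165)
}

test_that("the estimate reports the median sensitivity with a mean-based SE", {
  rec <- mk_records(c(-0.2, -0.3, -0.25))
  est <- estimate_sensitivity(rec)
  expect_equal(est$median_sens, -0.25)
  expect_equal(est$se, sd(c(-0.2, -0.3, -0.25)) / sqrt(3))
  expect_equal(est$n, 3L)
})

test_that("a single pair yields its own value with an undefined SE", {
  est <- suppressWarnings(estimate_sensitivity(mk_records(-0.4)))
  expect_equal(est$median_sens, -0.4)
  expect_true(is.na(est$se))
  expect_error(estimate_sensitivity(mk_records(numeric(0))), "no pairs")
})

test_that("bootstrap SE of the median is seeded and reproducible", {
  rec <- mk_records(rnorm(50, -0.25, 0.1))
  e1 <- estimate_sensitivity(rec, boot = 200L, boot_seed = 4L)
  e2 <- estimate_sensitivity(rec, boot = 200L, boot_seed = 4L)
  expect_equal(e1$boot_se_median, e2$boot_se_median)
  expect_gt(e1$boot_se_median, 0)
})

test_that("degenerate groups give missing p-values with a warning", {
  rec <- mk_records(c(1, 1), dp_def = c(2, 2), dp_ctl = c(2, 2))
  expect_warning(pv <- significance(rec), "zero-variance")
  expect_true(is.na(pv$p_t) && is.na(pv$p_mw))
  expect_warning(pv1 <- significance(mk_records(1)), "fewer than 2")
  expect_true(is.na(pv1$p_t))
})

test_that("an injected drying signal is detected by both tests", {
  cfg <- small_config(sigma = 5, beta = -0.4, seed = 21L)
  b <- simulate_bundle(cfg)
  loss <- loss_between(b$cover, small_windows$start, small_windows$end)
  ps <- find_pairs(loss, b$mask)
  rec <- pair_delta_p(ps, b$precip, small_windows$start, small_windows$end)
  pv <- significance(rec)
  expect_lt(pv$p_t, 0.01)
  expect_lt(pv$p_mw, 0.01)
})

test_that("season classification finds each pixel's wettest and driest months", {
  lat <- c(0, 0.05); lon <- c(10, 10.05)
  years <- 2003:2004
  vals <- array(0, c(2, 2, 24))
  for (m in 1:12) {
    clim <- 150 + 60 * cos(2 * pi * (m - 2) / 12)  # peak in February
    vals[, , m] <- clim; vals[, , 12 + m] <- clim
  }
  smap <- season_map(precip_cube(vals, lat, lon, years))
  expect_equal(which(smap[1, 1, ] == 3L), c(1L, 2L, 3L))   # wet: Jan-Mar
  expect_equal(which(smap[1, 1, ] == 1L), c(7L, 8L, 9L))   # dry: Jul-Sep
})

test_that("season ties are broken by ascending month index", {
  vals <- array(100, c(1, 1, 24))
  smap <- season_map(precip_cube(vals, 0, 0, 2003:2004))
  expect_equal(which(smap[1, 1, ] == 1L), 1:3)
  expect_equal(which(smap[1, 1, ] == 3L), 10:12)
})

test_that("season sets match a brute-force sort and partition the year", {
  set.seed(31)
  lat <- 0.05 * (1:4); lon <- 0.05 * (1:4)
  vals <- array(runif(4 * 4 * 24, 0, 300), c(4, 4, 24))
  cube <- precip_cube(vals, lat, lon, 2003:2004)
  smap <- season_map(cube)
  for (i in 1:4) for (j in 1:4) {
    clim <- sapply(1:12, function(m) mean(vals[i, j, c(m, 12 + m)]))
    ord <- order(clim)
    expect_equal(sort(which(smap[i, j, ] == 1L)), sort(ord[1:3]))
    expect_equal(sort(which(smap[i, j, ] == 3L)), sort(ord[10:12]))
    expect_equal(table(factor(smap[i, j, ], levels = 1:3)),
                 table(factor(c(rep(1, 3), rep(2, 6), rep(3, 3)), levels = 1:3)),
                 ignore_attr = TRUE)
  }
})

test_that("pixels with missing climatology are dropped from the season map", {
  vals <- array(100 + rnorm(24), c(1, 1, 24))
  vals[1, 1, 3] <- NA
  smap <- season_map(precip_cube(vals, 0, 0, 2003:2004))
  expect_true(all(is.na(smap[1, 1, ])))
})

test_that("a uniform injected effect appears equally in every season", {
  cfg <- small_config(sigma = 0, beta = -0.25, seed = 13L)
  b <- simulate_bundle(cfg)
  loss <- loss_between(b$cover, small_windows$start, small_windows$end)
  ps <- find_pairs(loss, b$mask)
  smap <- season_map(b$precip)
  se <- seasonal_estimate(ps, b$precip, smap,
                          small_windows$start, small_windows$end)
  expect_equal(se$season, c("wet", "dry", "transition"))
  expect_equal(se$median_sens, rep(-0.25, 3), tolerance = 1e-6)
})

test_that("loss bins collect pairs left-closed and report empty bins as missing", {
  rec <- mk_records(c(-0.1, -0.2, -0.3))
  rec$d_f <- c(0.5, 5, 12)
  expect_message(br <- binned_response(rec), "empty")
  expect_equal(br$n, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(br$median_sens[1:3], c(-0.1, -0.2, -0.3))
  expect_true(all(is.na(br$median_sens[4:5])))
  one <- binned_response(rec, edges = c(0.1, Inf))
  expect_equal(one$median_sens, median(rec$sens))
  expect_error(binned_response(rec, edges = c(5, 5)), "increasing")
  rec_out <- mk_records(-0.1); rec_out$d_f <- 0.05
  expect_error(suppressMessages(binned_response(rec_out)), "no pairs")
})

test_that("an additive basin-wide anomaly leaves window comparisons unchanged", {
  cfg <- small_config(sigma = 0, beta = -0.25, seed = 17L,
                      elnino_years = 2008:2009, elnino_anom = -15)
  b <- simulate_bundle(cfg)
  est <- stratify_windows(b$cover, b$mask, b$precip,
                          windows = list(incl = list(start = 2003:2005,
                                                     end = 2007:2009),
                                         excl = list(start = 2003:2005,
                                                     end = 2010:2012)))
  expect_equal(est$median_sens, rep(-0.25, 2), tolerance = 1e-9)
})

test_that("window stratification requires labelled configurations", {
  cfg <- small_config()
  b <- simulate_bundle(cfg)
  expect_error(stratify_windows(b$cover, b$mask, b$precip,
                                windows = list(list(start = 2003:2005,
                                                    end = 2010:2012))),
               "named")
})
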