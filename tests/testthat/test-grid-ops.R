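test_that("block aggregation averages fractional loss area-weighted", {
  # symmetric latitudes about the equator make the 2x2 block weights equal
  g <- loss_grid(matrix(c(0, 100, 0, 100), 2, 2), c(-0.025, 0.025), c(10, 10.05))
  a <- aggregate_loss(g, 2L)
  expect_equal(as.numeric(a), 50)

  m <- matrix(c(NA, NA, NA, NA), 2, 2)
  expect_true(is.na(as.numeric(aggregate_loss(
    loss_grid(m, c(-0.025, 0.025), c(10, 10.05)), 2L))))
})

test_that("aggregation matches a brute-force weighted block mean", {
  set.seed(42)
  lat <- 5 + 0.05 * (0:7); lon <- 20 + 0.05 * (0:7)
  x <- matrix(runif(64, 0, 100), 8, 8)
  x[sample(64, 6)] <- NA
  g <- loss_grid(x, lat, lon)
  a <- aggregate_loss(g, 4L)
  expect_equal(unclass(a), bf_block_mean(x, lat, 4L),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a coarse cell is missing when over half its fine cells are", {
  lat <- 0.05 * (1:2); lon <- 0.05 * (1:2)
  m <- matrix(c(10, NA, NA, NA), 2, 2)
  expect_true(is.na(as.numeric(aggregate_loss(loss_grid(m, lat, lon), 2L))))
  m2 <- matrix(c(10, 20, NA, NA), 2, 2)  # exactly half present
  expect_false(is.na(as.numeric(aggregate_loss(loss_grid(m2, lat, lon), 2L))))
})

test_that("partial edge blocks are dropped with a warning", {
  g <- loss_grid(matrix(1, 5, 5), 0.05 * (1:5), 0.05 * (1:5))
  expect_warning(a <- aggregate_loss(g, 2L), "dropped")
  expect_equal(dim(a), c(2L, 2L))
  expect_error(aggregate_loss(g, 0L), "factor")
  expect_error(aggregate_loss(g, 9L), "larger than the grid")
})

test_that("aggregation conserves total lost forest area", {
  set.seed(7)
  lat <- -3 + 0.05 * (0:31); lon <- 20 + 0.05 * (0:31)
  x <- matrix(runif(1024, 0, 60), 32, 32)
  g <- loss_grid(x, lat, lon)
  w_fine <- matrix(coslat_weights(lat), 32, 32)
  total_fine <- sum(w_fine * x)
  for (f in c(2L, 4L, 8L)) {
    a <- aggregate_loss(g, f)
    # block area = sum of fine-cell areas within the block
    w_block <- bf_block_sum(w_fine, f)
    expect_equal(sum(unclass(a) * w_block), total_fine, tolerance = 1e-9)
  }
})

test_that("aggregating cover then differencing equals differencing then aggregating", {
  cfg <- small_config(seed = 9L)
  ch <- generate_cover_history(cfg)
  l_fine <- loss_between(ch$cover, small_windows$start, small_windows$end)
  a1 <- aggregate_loss(l_fine, 2L)
  a2 <- loss_between(aggregate_cover(ch$cover, 2L),
                     small_windows$start, small_windows$end)
  expect_equal(unclass(a1), unclass(a2), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("bilinear regridding preserves constants and planes exactly", {
  lat <- seq(-2, 2, by = 0.25); lon <- seq(10, 14, by = 0.25)
  tlat <- seq(-1.7, 1.7, by = 0.4); tlon <- seq(10.3, 13.7, by = 0.4)
  const <- set_grid_attrs_for_test(matrix(7, length(lat), length(lon)), lat, lon)
  rc <- regrid_precip(const, tlat, tlon)
  expect_equal(as.vector(rc), rep(7, length(tlat) * length(tlon)))
  plane <- outer(lat, lon, function(a, b) 3.2 * a - 1.4 * b + 100)
  rp <- regrid_precip(set_grid_attrs_for_test(plane, lat, lon), tlat, tlon)
  expect_equal(unclass(rp), outer(tlat, tlon, function(a, b) 3.2 * a - 1.4 * b + 100),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("bilinear regridding matches an independent implementation", {
  set.seed(3)
  lat <- seq(0, 3, by = 0.25); lon <- seq(20, 23, by = 0.25)
  z <- matrix(runif(length(lat) * length(lon), 50, 300), length(lat))
  tlat <- sort(runif(9, 0.1, 2.9)); tlon <- sort(runif(9, 20.1, 22.9))
  r <- regrid_precip(set_grid_attrs_for_test(z, lat, lon), tlat, tlon)
  expect_equal(unclass(r), bf_bilinear(z, lat, lon, tlat, tlon),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("regridding rejects non-overlapping domains", {
  lat <- 0:3; lon <- 20:23
  z <- set_grid_attrs_for_test(matrix(1, 4, 4), lat, lon)
  expect_error(regrid_precip(z, 10:12, 20:22), "overlap")
})

test_that("conservative regridding equals the area-weighted block mean", {
  set.seed(8)
  lat <- -1 + 0.05 * (0:7); lon <- 30 + 0.05 * (0:7)
  vals <- array(runif(8 * 8 * 12, 0, 200), c(8, 8, 12))
  cube <- precip_cube(vals, lat, lon, 2003L)
  clat <- colMeans(matrix(lat, 2)); clon <- colMeans(matrix(lon, 2))
  r <- regrid_precip(cube, clat, clon, method = "conservative")
  for (t in c(1L, 7L))
    expect_equal(r[, , t], bf_block_mean(vals[, , t], lat, 2L), tolerance = 1e-12)
})

test_that("period means average the requested months and propagate gaps", {
  lat <- c(0, 0.05); lon <- c(10, 10.05)
  years <- 2003:2012
  nt <- 12L * length(years)
  # linear trend of -1.2 mm/month per year on a 100 mm/month base
  trend <- rep(100 - 1.2 * (seq_along(years) - 1), each = 12L)
  vals <- array(rep(trend, each = 4L), c(2, 2, nt))
  cube <- precip_cube(vals, lat, lon, years)
  m1 <- period_mean(cube, 2003:2007)
  m2 <- period_mean(cube, 2008:2012)
  expect_equal(as.vector(m2 - m1), rep(-6, 4), tolerance = 1e-12)

  vals2 <- vals; vals2[1, 1, 5] <- NA
  cube2 <- precip_cube(vals2, lat, lon, years)
  expect_true(is.na(period_mean(cube2, 2003:2007)[1, 1]))
  expect_false(is.na(period_mean(cube2, 2003:2007)[2, 2]))
  expect_error(period_mean(cube, 1999), "span")
})

test_that("period means match a brute-force month loop and are linear", {
  set.seed(12)
  lat <- c(0, 0.05); lon <- c(10, 10.05)
  years <- 2003:2008
  a <- array(runif(4 * 72, 0, 300), c(2, 2, 72))
  b <- array(runif(4 * 72, 0, 300), c(2, 2, 72))
  ca <- precip_cube(a, lat, lon, years)
  cb <- precip_cube(b, lat, lon, years)
  tt <- data.frame(year = rep(years, each = 12), month = rep(1:12, 6))
  idx <- which(tt$year %in% 2004:2006)
  bf <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) bf[i, j] <- mean(a[i, j, idx])
  expect_equal(unclass(period_mean(ca, 2004:2006)), bf,
               ignore_attr = TRUE, tolerance = 1e-12)
  lin <- precip_cube(2 * a + 3 * b, lat, lon, years)
  expect_equal(unclass(period_mean(lin, 2004:2006)),
               unclass(2 * period_mean(ca, 2004:2006) +
                         3 * period_mean(cb, 2004:2006)),
               tolerance = 1e-10)
})

test_that("window-mean and endpoint loss definitions behave as documented", {
  lat <- c(0, 0.05); lon <- c(10, 10.05)
  years <- 2003:2008
  cov <- array(0, c(2, 2, 6))
  for (t in 1:6) cov[, , t] <- 80 - 2 * (t - 1)  # 2 pp lost per year
  cs <- cover_series(cov, lat, lon, years)
  wm <- loss_between(cs, 2003:2004, 2007:2008)
  expect_equal(as.vector(wm), rep(8, 4))  # mean cover 79 vs 71
  ep <- loss_between(cs, 2003:2004, 2007:2008, method = "endpoints")
  expect_equal(as.vector(ep), rep(10, 4))  # 80 vs 70
  expect_error(loss_between(cs, 1999, 2008), "outside")
})
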