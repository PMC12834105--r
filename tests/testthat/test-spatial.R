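test_that("ASCII raster round-trips through write/read, including nodata", {
  vals <- matrix(c(1, 0, NA, 0.5, -2, 3), 2, 3)
  r <- raster_grid(vals, lon0 = 90, lat0 = 35, cell_deg = 0.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(r, path)
  r2 <- read_ascii_raster(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$lon0, r$lon0)
  expect_equal(r2$lat0, r$lat0)
  expect_equal(r2$cell_deg, r$cell_deg)
})

test_that("empirical variogram: constant field is zero, two points give one bin", {
  lon <- runif(10, 90, 95); lat <- runif(10, 30, 34)
  expect_message(ev <- empirical_variogram(lon, lat, rep(3, 10), max_dist = 1e4),
                 "constant")
  expect_true(all(ev$gamma == 0))

  ev2 <- empirical_variogram(c(90, 91), c(30, 30), c(0, 2),
                             n_lags = 1, max_dist = 1e3)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$gamma, 2)  # (1/2) * (2 - 0)^2
  expect_equal(ev2$n_pairs, 1L)
})

test_that("fit_variogram recovers its own theoretical curve to 1e-6", {
  for (fam in c("exponential", "gaussian", "spherical")) {
    truth <- structure(list(family = fam, nugget = 0.3, partial_sill = 1.2,
                            range_km = 150), class = "variogram_model")
    h <- seq(20, 600, length.out = 15)
    ev <- data.frame(h = h, gamma = variogram_gamma(truth, h),
                     n_pairs = rep(50L, 15))
    fit <- fit_variogram(ev, family = fam)
    expect_equal(fit$nugget, truth$nugget, tolerance = 1e-6)
    expect_equal(fit$partial_sill, truth$partial_sill, tolerance = 1e-6)
    expect_equal(fit$range_km, truth$range_km, tolerance = 1e-6)
  }
})

test_that("fit_variogram on a constant field returns a degenerate model", {
  ev <- data.frame(h = c(10, 20, 30), gamma = 0, n_pairs = 5L)
  fit <- fit_variogram(ev)
  expect_equal(fit$nugget, 0)
  expect_equal(fit$partial_sill, 0)
})

test_that("ordinary kriging is exact at data points when nugget is zero", {
  set.seed(6)
  lon <- runif(25, 90, 95); lat <- runif(25, 28, 33)
  z <- sin(lon) + cos(lat) + rnorm(25, 0, 0.1)
  model <- structure(list(family = "exponential", nugget = 0,
                          partial_sill = 1, range_km = 120),
                     class = "variogram_model")
  kp <- refugia:::krige_points(lon, lat, z, model, lon, lat)
  expect_equal(kp$prediction, z, tolerance = 1e-6)
})

test_that("kriging weights sum to one and constant fields stay constant", {
  set.seed(61)
  lon <- runif(20, 90, 95); lat <- runif(20, 28, 33)
  z <- rnorm(20)
  model <- structure(list(family = "spherical", nugget = 0.2,
                          partial_sill = 0.8, range_km = 200),
                     class = "variogram_model")
  plon <- runif(40, 89, 96); plat <- runif(40, 27, 34)
  kp <- refugia:::krige_points(lon, lat, z, model, plon, plat)
  expect_equal(unname(colSums(kp$weights)), rep(1, 40), tolerance = 1e-8)

  kc <- refugia:::krige_points(lon, lat, rep(4.2, 20), model, plon, plat)
  expect_equal(kc$prediction, rep(4.2, 40), tolerance = 1e-8)
})

test_that("ordinary_krige fills a padded default grid", {
  set.seed(62)
  lon <- runif(15, 90, 95); lat <- runif(15, 28, 33)
  z <- rnorm(15)
  model <- fit_variogram(empirical_variogram(lon, lat, z, n_lags = 6,
                                             max_dist = 500))
  out <- ordinary_krige(lon, lat, z, model, n_cells = c(20, 20))
  expect_s3_class(out$prediction, "raster_grid")
  expect_equal(dim(out$prediction$values), c(20, 20))
  expect_true(all(is.finite(out$prediction$values)))
})

test_that("refuge_center averages presence cell centres", {
  vals <- matrix(0, 2, 2)
  vals[1, 2] <- 1  # centre (92, 32)
  vals[2, 1] <- 1  # centre (90, 30)
  r <- raster_grid(vals, lon0 = 90, lat0 = 32, cell_deg = 2)
  expect_equal(refuge_center(r), c(lon = 91, lat = 31))

  r1 <- raster_grid(matrix(1, 1, 1), lon0 = 95, lat0 = 20, cell_deg = 1)
  expect_equal(refuge_center(r1), c(lon = 95, lat = 20))

  full <- raster_grid(matrix(1, 5, 5), lon0 = 100, lat0 = 40, cell_deg = 1)
  expect_equal(refuge_center(full), c(lon = 102, lat = 38))

  shifted <- raster_grid(vals, lon0 = 90 + 3, lat0 = 32 - 2, cell_deg = 2)
  expect_equal(refuge_center(shifted),
               refuge_center(r) + c(lon = 3, lat = -2))

  expect_error(refuge_center(raster_grid(matrix(0, 2, 2), 0, 0, 1)),
               "no presence")
})

test_that("gradient_test recovers exact linear relations and rejects constants", {
  set.seed(13)
  lon <- runif(15, 90, 100); lat <- runif(15, 25, 35)
  center <- c(lon = 95, lat = 30)
  d <- geo_distance_km(lon, lat, center[["lon"]], center[["lat"]])
  up <- gradient_test(2 * d + 5, lon, lat, center, "up")
  expect_equal(up$r, 1, tolerance = 1e-12)
  expect_lt(up$p, 1e-6)
  down <- gradient_test(-0.5 * d, lon, lat, center, "down")
  expect_equal(down$r, -1, tolerance = 1e-12)
  expect_error(gradient_test(rep(1, 15), lon, lat, center), "zero variance")
})

test_that("fdr_adjust performs Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(14)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(q, bh_brute(p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "lie in")
})

test_that("gradient_table applies one FDR family across statistics", {
  set.seed(15)
  lon <- runif(30, 90, 100); lat <- runif(30, 25, 35)
  center <- c(lon = 95, lat = 30)
  d <- geo_distance_km(lon, lat, center[["lon"]], center[["lat"]])
  stats_df <- data.frame(a = d + rnorm(30, 0, 50),
                         b = rnorm(30),
                         c = -d + rnorm(30, 0, 50))
  gt <- gradient_table(stats_df, lon, lat, center)
  expect_equal(gt$statistic, c("a", "b", "c"))
  expect_equal(gt$q, fdr_adjust(gt$p))
  expect_true(all(gt$q >= gt$p))
})
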