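# Posterior predictive machinery: station PPDs, extrapolation to unseen
# locations, downscaling, polygon aggregation and uncertainty decomposition.

test_that("station PPD collapses onto mu when the noise vanishes", {
  sf <- small_fit()
  fit0 <- sf$fit
  for (ch in seq_along(fit0$samples$chains))
    fit0$samples$chains[[ch]]$draws$sigma2[] <- 1e-16
  id <- fit0$design$meta$station_id[1]
  pr <- ppd_station(fit0, id, seed = 1)
  # the predictive draws collapse onto the mu trajectory draw by draw
  expect_lt(max(abs(pr$draws - pr$mu_draws)), 1e-6)
  expect_equal(pr$mean, colMeans(pr$mu_draws), tolerance = 1e-6)
  expect_equal(pr$sd, pr$sd_mu, tolerance = 1e-6)
})

test_that("station PPD mean is the mean of mu within Monte-Carlo error", {
  sf <- small_fit()
  id <- sf$fit$design$meta$station_id[2]
  pr <- ppd_station(sf$fit, id, seed = 2)
  sg <- mean(sqrt(draws_sigma2(sf$fit, 2)))
  mc_se <- 3 * sg / sqrt(nrow(pr$draws))
  expect_lt(max(abs(pr$mean - colMeans(pr$mu_draws))), 4 * mc_se)
  # imputation: dates with missing tmax still get predictions
  d <- sf$fit$design
  miss_dates <- sf$sim$stations$date[is.na(sf$sim$stations$tmax) &
                                     sf$sim$stations$station_id == id]
  if (length(miss_dates)) {
    pm <- ppd_station(sf$fit, id, dates = miss_dates, seed = 3)
    expect_true(all(is.finite(pm$mean)))
  }
  expect_error(ppd_station(sf$fit, "no-such-station"), "lookup")
})

test_that("new-location prediction agrees with the station linear part", {
  sf <- small_fit()
  fit <- sf$fit; d <- fit$design
  j <- 3L
  cv <- d$covariates[[j]]
  pr_st <- ppd_station(fit, d$meta$station_id[j], dates = cv$times, seed = 4)
  pr_new <- ppd_new_location(fit, d$meta$lon[j], d$meta$lat[j], cv$x,
                             dates = cv$times, seed = 4)
  expect_lt(max(abs(pr_st$mu_lin_draws - pr_new$mu_lin_draws)), 1e-10)
  # law of total variance: PPD sd >= sd of the mu component (MC slack)
  expect_true(all(pr_new$sd >= pr_new$sd_mu - 0.05 * pr_new$sd))
  # reproducibility given the seed
  pr_new2 <- ppd_new_location(fit, d$meta$lon[j], d$meta$lat[j], cv$x,
                              dates = cv$times, seed = 4)
  expect_identical(pr_new$draws, pr_new2$draws)
  # missing covariate propagates to a missing prediction
  x_na <- cv$x; x_na[2] <- NA
  pr_na <- suppressWarnings(
    ppd_new_location(fit, d$meta$lon[j], d$meta$lat[j], x_na, dates = cv$times))
  expect_true(all(is.na(pr_na$draws[, 2])))
})

test_that("an identity bias map downscales to the reanalysis field itself", {
  sf <- small_fit()
  field <- sf$field
  cfg <- sf$fit$config; cfg$k_neighbours <- 1L
  fit <- identity_fit(sf$fit)
  fit$config <- cfg
  dts <- field$times[3:4]
  grid <- downscale(fit, field, resolution = 0.1, dates = dts, seed = 5)
  # grid nodes coincide with cell centers; with k = 1 the covariate is the
  # cell value and mu = x, so the mean surface is the field
  for (ti in 1:2) {
    truth <- sapply(seq_len(nrow(grid$cells)), function(ci) {
      la <- match(round(grid$cells$lat[ci], 6), round(field$lat_centers, 6))
      lo <- match(round(grid$cells$lon[ci], 6), round(field$lon_centers, 6))
      field$values[match(dts[ti], field$times), la, lo]
    })
    expect_lt(max(abs(grid$mean[, ti] - truth)), 1e-3)
  }
  # gamma* suppressed: the mean including h* equals the linear-only mean
  ud <- uncertainty_decomposition(grid, dts[1])
  expect_lt(max(abs(ud$sd_mu - ud$sd_mu_linear)), 1e-6)
})

test_that("gridded PPD mean matches a brute-force loop over draws and cells", {
  sf <- small_fit()
  grid <- downscale(sf$fit, sf$field, resolution = 0.25,
                    dates = sf$field$times[5], seed = 6)
  n_draws <- dim(grid$draws)[1]
  for (ci in seq_len(nrow(grid$cells))) {
    acc <- 0
    for (m in seq_len(n_draws)) acc <- acc + grid$draws[m, ci, 1]
    expect_equal(grid$mean[ci, 1], acc / n_draws, tolerance = 1e-12)
  }
  ud <- uncertainty_decomposition(grid)
  expect_true(all(ud$sd_ppd >= ud$sd_mu - 0.05 * ud$sd_ppd))
  expect_error(downscale(sf$fit, sf$field, resolution = -1,
                         dates = sf$field$times[1]), "resolution")
})

test_that("polygon aggregation is draw-wise cell averaging", {
  sf <- small_fit()
  field <- sf$field
  grid <- downscale(sf$fit, field, resolution = 0.2, dates = field$times[2],
                    seed = 7)
  res <- 0.2
  one_cell <- c(grid$cells$lon[4] - res / 2, grid$cells$lon[4] + res / 2,
                grid$cells$lat[4] - res / 2, grid$cells$lat[4] + res / 2)
  two_cells <- c(grid$cells$lon[1] - res / 2, grid$cells$lon[2] + res / 2,
                 grid$cells$lat[1] - res / 2, grid$cells$lat[1] + res / 2)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_regions_fixture(p, list(single = one_cell, pair = two_cells))
  regions <- read_regions_geojson(p)
  agg <- aggregate_regions(grid, regions)
  dr <- attr(agg, "draws")
  # singleton region equals the cell itself
  expect_equal(as.numeric(dr[["single"]]), grid$draws[, 4, 1], tolerance = 1e-12)
  # two-cell region is the arithmetic draw-wise mean
  expect_equal(as.numeric(dr[["pair"]]),
               (grid$draws[, 1, 1] + grid$draws[, 2, 1]) / 2, tolerance = 1e-12)
  # aggregation commutes with averaging over draws
  expect_equal(agg$mean[agg$region == "pair"],
               mean(grid$mean[1:2, 1]), tolerance = 1e-12)
  # a region containing no cell center errors by name
  p2 <- withr::local_tempfile(fileext = ".geojson")
  write_regions_fixture(p2, list(offshore = c(50, 51, 10, 11)))
  expect_error(aggregate_regions(grid, read_regions_geojson(p2)),
               "offshore")
})

test_that("region means stabilise under grid refinement on a smooth surface", {
  sf <- small_fit()
  field <- sf$field
  cfg <- sf$fit$config; cfg$k_neighbours <- 4L
  fit <- identity_fit(sf$fit)   # deterministic smooth surface, no noise
  fit$config <- cfg
  box <- c(33.0, 33.4, 34.8, 35.1)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_regions_fixture(p, list(box = box))
  regions <- read_regions_geojson(p)
  means <- sapply(c(0.1, 0.05), function(res) {
    g <- downscale(fit, field, resolution = res, dates = field$times[1],
                   bbox = box + c(0.01, -0.01, 0.01, -0.01), seed = 8)
    aggregate_regions(g, regions)$mean
  })
  expect_lt(abs(means[1] - means[2]), 0.05)
})

test_that("covariate outside the training range warns", {
  sf <- small_fit()
  d <- sf$fit$design
  expect_warning(ppd_new_location(sf$fit, d$meta$lon[1], d$meta$lat[1],
                                  max(d$x) + 10, dates = d$dates[1]),
                 "training range")
})
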