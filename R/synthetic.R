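# Synthetic data generator: reanalysis-like smooth gridded fields and
# station records drawn from the model's own generative process with known
# truth, so every stage of the pipeline is testable without external data.

#' Simulate a reanalysis-like daily Tmax field
#'
#' A smooth space-time field: a seasonal sinusoid (annual cycle) around a
#' regional mean, a smooth spatial gradient, a shared AR(1) daily anomaly
#' and small-amplitude cell-level noise. Defaults emulate an eastern
#' Mediterranean daily-Tmax climate at 0.1 degree spacing: mean 24 degC with
#' a 12 degC annual-cycle amplitude (annual range roughly 5-40 degC, so the
#' maximum absolute deviation of a multi-year series from its mean is near
#' 20-25 degC) and AR(1) synoptic anomalies with coefficient 0.8 and sd
#' 2.5 degC. Values stay inside the physically plausible (-30, 50) degC
#' range.
#'
#' @param lon_range,lat_range domain box, decimal degrees.
#' @param resolution grid spacing, degrees.
#' @param n_days number of daily steps.
#' @param seed RNG seed.
#' @param start_date first day.
#' @param mean_temp,seasonal_amp regional mean and annual-cycle amplitude.
#' @param grad_lon,grad_lat spatial gradient, degC per degree.
#' @param ar_coef,anom_sd AR(1) daily anomaly parameters.
#' @param noise_sd iid cell-level noise sd.
#' @param sea_frac fraction of cells masked entirely (emulating sea cells);
#'   masked cells are chosen deterministically from the seeded RNG.
#' @return a [reanalysis_field()].
#' @export
simulate_reanalysis <- function(lon_range = c(32, 34.6), lat_range = c(34.4, 35.7),
                                resolution = 0.1, n_days = 365, seed = 1L,
                                start_date = as.Date("2010-01-01"),
                                mean_temp = 24, seasonal_amp = 12,
                                grad_lon = 0.8, grad_lat = -1.2,
                                ar_coef = 0.8, anom_sd = 2.5,
                                noise_sd = 0.3, sea_frac = 0) {
  stopifnot(resolution > 0, n_days >= 1)
  set.seed(seed)
  lon <- seq(lon_range[1], lon_range[2], by = resolution)
  lat <- seq(lat_range[1], lat_range[2], by = resolution)
  times <- seq(start_date, by = "day", length.out = n_days)
  doy <- as.numeric(format(times, "%j"))
  seasonal <- mean_temp + seasonal_amp * sin(2 * pi * (doy - 105) / 365.25)
  spat <- outer(lat - mean(lat), lon - mean(lon),
                function(la, lo) grad_lat * la + grad_lon * lo)
  anom <- numeric(n_days)
  if (anom_sd > 0) {
    e <- stats::rnorm(n_days, 0, anom_sd * sqrt(1 - ar_coef^2))
    anom[1] <- stats::rnorm(1, 0, anom_sd)
    for (t in seq_len(n_days)[-1]) anom[t] <- ar_coef * anom[t - 1] + e[t]
  }
  vals <- array(NA_real_, c(n_days, length(lat), length(lon)))
  for (t in seq_len(n_days)) {
    layer <- seasonal[t] + anom[t] + spat
    if (noise_sd > 0)
      layer <- layer + matrix(stats::rnorm(length(layer), 0, noise_sd),
                              length(lat), length(lon))
    vals[t, , ] <- pmin(pmax(layer, -30), 50)
  }
  if (sea_frac > 0) {
    ncell <- length(lat) * length(lon)
    sea <- sample.int(ncell, round(sea_frac * ncell))
    for (s in sea) vals[, ((s - 1) %% length(lat)) + 1, ((s - 1) %/% length(lat)) + 1] <- NA_real_
  }
  reanalysis_field(lon, lat, times, vals)
}

#' Ground-truth specification for synthetic stations
#'
#' The generative truth mirrors the model: `y = alpha0 + f(s) + g(s) x +
#' h_j(x) + N(0, sigma_j^2)`, contaminated with probability `1 - pi_j` by a
#' Uniform outlier and masked by block missingness. Default surfaces are the
#' identity bias map (f = 0, g = 1) with a modest station-specific sinusoidal
#' non-linearity, per-station noise sd around 2 degC and pi_j = 0.99.
#'
#' @param alpha0 overall intercept, degC.
#' @param f_fun,g_fun functions of (lon, lat) giving the intercept and slope
#'   surfaces.
#' @param h_amp amplitude bound of the per-station non-linear deviation; the
#'   deviation is `a_j sin(2 pi (x - x_min) / range(x))` with
#'   `a_j ~ U(-h_amp, h_amp)`.
#' @param sigma_base,sigma_jitter per-station noise sd is
#'   `sigma_base * U(1 - sigma_jitter, 1 + sigma_jitter)`.
#' @param pi_j non-outlier probability per station.
#' @param outlier_pad synthetic outliers are drawn from
#'   `Unif(min(y) - outlier_pad, max(y) + outlier_pad)` (clipped to the
#'   mixture support); the default 30 keeps some outliers "hard".
#' @param missing_frac target fraction of values masked in contiguous blocks.
#' @return a list of class `truth_spec`.
#' @export
truth_spec <- function(alpha0 = 1.5,
                       f_fun = function(lon, lat) rep(0, length(lon)),
                       g_fun = function(lon, lat) rep(1, length(lon)),
                       h_amp = 0.5,
                       sigma_base = 2, sigma_jitter = 0.25,
                       pi_j = 0.99, outlier_pad = 30, missing_frac = 0.05) {
  structure(list(alpha0 = alpha0, f_fun = f_fun, g_fun = g_fun, h_amp = h_amp,
                 sigma_base = sigma_base, sigma_jitter = sigma_jitter,
                 pi_j = pi_j, outlier_pad = outlier_pad,
                 missing_frac = missing_frac), class = "truth_spec")
}

#' Simulate station records from known truth
#'
#' Places `J` stations uniformly inside the field's interior, derives each
#' station's covariate with the fitted change-of-support rule, and generates
#' observations from the mixture model under `truth`. Every generated
#' quantity (surfaces at the stations, per-station sigma and pi, outlier
#' indices, missingness mask) is recorded so recovery is fully assessable.
#'
#' @param field a [reanalysis_field()].
#' @param J number of stations (>= 3).
#' @param truth a [truth_spec()].
#' @param seed RNG seed.
#' @param k_neighbours,idw_power change-of-support settings (match the fit).
#' @param u_min,u_max mixture support for clipping synthetic outliers.
#' @return list: `stations` (a `station_data` with covariate column `x`),
#'   `truth` (the spec plus realised per-station values, outlier row
#'   indices and the missingness mask).
#' @export
simulate_stations <- function(field, J, truth = truth_spec(), seed = 1L,
                              k_neighbours = 10, idw_power = 1,
                              u_min = -80, u_max = 80) {
  stopifnot(J >= 3)
  set.seed(seed)
  lon_r <- range(field$lon_centers); lat_r <- range(field$lat_centers)
  pad_lon <- 0.05 * diff(lon_r); pad_lat <- 0.05 * diff(lat_r)
  lon <- stats::runif(J, lon_r[1] + pad_lon, lon_r[2] - pad_lon)
  lat <- stats::runif(J, lat_r[1] + pad_lat, lat_r[2] - pad_lat)
  sigma <- truth$sigma_base * stats::runif(J, 1 - truth$sigma_jitter,
                                           1 + truth$sigma_jitter)
  pi_j <- rep(truth$pi_j, length.out = J)
  a_j <- stats::runif(J, -truth$h_amp, truth$h_amp)
  f_s <- truth$f_fun(lon, lat); g_s <- truth$g_fun(lon, lat)

  rows <- NULL
  x_all <- list()
  for (j in seq_len(J)) {
    cv <- match_station(field, lon[j], lat[j], k = k_neighbours,
                        power = idw_power, station_id = sprintf("S%02d", j))
    x_all[[j]] <- cv$x
    rows <- rbind(rows, data.frame(
      station_id = sprintf("S%02d", j), name = sprintf("synthetic-%02d", j),
      lon = lon[j], lat = lat[j], elevation = round(stats::runif(1, 0, 250)),
      date = as.Date(cv$times), x = cv$x))
  }
  xr <- range(unlist(x_all))
  h_fun <- function(a, x) a * sin(2 * pi * (x - xr[1]) / max(diff(xr), 1e-9))
  st <- match(rows$station_id, sprintf("S%02d", seq_len(J)))
  mu <- truth$alpha0 + f_s[st] + g_s[st] * rows$x + h_fun(a_j[st], rows$x)
  y <- stats::rnorm(nrow(rows), mu, sigma[st])
  is_out <- stats::runif(nrow(rows)) > pi_j[st]
  if (any(is_out)) {
    lo <- max(min(y) - truth$outlier_pad, u_min + 1)
    hi <- min(max(y) + truth$outlier_pad, u_max - 1)
    y[is_out] <- stats::runif(sum(is_out), lo, hi)
  }
  # block missingness: contiguous runs per station until the target fraction
  miss <- rep(FALSE, nrow(rows))
  if (truth$missing_frac > 0) {
    for (j in seq_len(J)) {
      idx <- which(st == j)
      target <- round(truth$missing_frac * length(idx))
      got <- 0L
      while (got < target) {
        len <- min(sample(5:30, 1), target - got)
        s0 <- sample.int(length(idx) - len + 1L, 1)
        sel <- idx[s0:(s0 + len - 1L)]
        got <- got + sum(!miss[sel])
        miss[sel] <- TRUE
      }
    }
  }
  rows$tmax <- ifelse(miss, NA_real_, y)
  stations <- validate_stations(rows[, c("station_id", "name", "lon", "lat",
                                         "elevation", "date", "tmax")],
                                u_min = u_min, u_max = u_max)
  # re-attach covariate in the validated (sorted) row order
  key <- paste(rows$station_id, rows$date)
  stations$x <- rows$x[match(paste(stations$station_id, stations$date), key)]
  truth_out <- c(truth, list(
    lon = lon, lat = lat, sigma = sigma, sigma2 = sigma^2, pi = pi_j,
    h_coef = a_j, f_at_stations = f_s, g_at_stations = g_s,
    outlier_keys = paste(rows$station_id, rows$date)[is_out & !miss],
    missing_keys = paste(rows$station_id, rows$date)[miss],
    seed = seed))
  list(stations = stations, truth = truth_out)
}

#' Parameter-recovery suite
#'
#' Simulates `n_replicates` synthetic datasets, fits the full model to each
#' and reports per-parameter recovery: bias and 95% credible-interval
#' coverage for alpha_0, posterior means of the slope surface g at the
#' station locations against truth, and bias/coverage for sigma_j^2 and
#' pi_j. Failed fits are recorded, not fatal.
#'
#' @param config a [blend_config()] used for every fit.
#' @param truth a [truth_spec()].
#' @param n_replicates number of simulated datasets.
#' @param J,n_days dataset size per replicate.
#' @param seed base seed; replicate r uses `seed + r` for data and field.
#' @return data.frame, one row per replicate: alpha0 posterior mean/CI and
#'   coverage indicator, RMSE of the g surface at stations, max |g - truth|,
#'   mean sigma2 relative bias, mean pi bias, and an `ok` flag.
#' @export
recovery_suite <- function(config = blend_config(), truth = truth_spec(),
                           n_replicates = 10, J = 6, n_days = 300, seed = 100L) {
  out <- NULL
  for (r in seq_len(n_replicates)) {
    row <- tryCatch({
      field <- simulate_reanalysis(n_days = n_days, seed = seed + r)
      sim <- simulate_stations(field, J = J, truth = truth, seed = seed + r,
                               k_neighbours = config$k_neighbours,
                               idw_power = config$idw_power)
      cfg <- config; cfg$seed <- as.integer(seed + r)
      fit <- tmax_blend(sim$stations, field, cfg)
      al0 <- draws_matrix(fit, "alpha")[, 1]
      ci <- stats::quantile(al0, c(0.025, 0.975), names = FALSE)
      be <- draws_matrix(fit, "beta")
      g_hat <- colMeans(be %*% t(fit$design$basis_g$model_matrix))
      ord <- match(fit$design$meta$station_id, sprintf("S%02d", seq_len(J)))
      g_true <- sim$truth$g_at_stations[ord]
      sg <- colMeans(draws_matrix(fit, "sigma2"))
      pp <- colMeans(draws_matrix(fit, "pi"))
      data.frame(replicate = r,
                 alpha0_mean = mean(al0), alpha0_lo = ci[1], alpha0_hi = ci[2],
                 alpha0_covered = sim$truth$alpha0 >= ci[1] & sim$truth$alpha0 <= ci[2],
                 g_rmse = sqrt(mean((g_hat - g_true)^2)),
                 g_max_abs_err = max(abs(g_hat - g_true)),
                 sigma2_rel_bias = mean(sg / sim$truth$sigma2[ord] - 1),
                 pi_bias = mean(pp - sim$truth$pi[ord]),
                 ok = TRUE)
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      data.frame(replicate = r, alpha0_mean = NA, alpha0_lo = NA, alpha0_hi = NA,
                 alpha0_covered = NA, g_rmse = NA, g_max_abs_err = NA,
                 sigma2_rel_bias = NA, pi_bias = NA, ok = FALSE)
    })
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
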