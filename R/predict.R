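# Posterior predictive simulation: checking/imputation at observed stations,
# spatial extrapolation at unseen locations (station-specific terms integrated
# out), downscaling to fine grids, polygon aggregation and uncertainty
# decomposition.

new_prediction_result <- function(draws, mu_draws, mu_lin_draws, dates, point,
                                  level = 0.95) {
  a <- (1 - level) / 2
  qcol <- function(m, p) apply(m, 2, function(v) {
    if (all(is.na(v))) NA_real_ else stats::quantile(v, p, names = FALSE, na.rm = TRUE)
  })
  structure(list(
    point = point, dates = dates, draws = draws,
    mean = colMeans(draws),
    lower = qcol(draws, a),
    upper = qcol(draws, 1 - a),
    sd = apply(draws, 2, stats::sd),
    sd_mu = apply(mu_draws, 2, stats::sd),
    sd_mu_linear = apply(mu_lin_draws, 2, stats::sd),
    mu_draws = mu_draws, mu_lin_draws = mu_lin_draws,
    level = level
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %d dates x %d draws; mean %.2f degC (PPD sd %.2f)\n",
              length(x$dates), nrow(x$draws), mean(x$mean), mean(x$sd)))
  invisible(x)
}

#' Posterior predictive distribution at a fitted station
#'
#' Per retained posterior draw, computes the station's mean mu with that
#' draw's alpha, beta and gamma_j and simulates `N(mu, sigma_j^2)`. Works
#' both for observed dates (model checking) and dates with missing
#' temperature (imputation), using the stored covariate series.
#'
#' @param fit a [tmax_blend()] fit.
#' @param station_id station identifier.
#' @param dates `Date` vector; default all dates in the station's covariate
#'   series (or its observed dates if the fit carried a precomputed
#'   covariate).
#' @param level central prediction-interval level.
#' @param seed RNG seed for the predictive noise.
#' @return a `prediction_result`.
#' @export
ppd_station <- function(fit, station_id, dates = NULL, level = 0.95, seed = NULL) {
  d <- fit$design
  j <- match(as.character(station_id), d$meta$station_id)
  if (is.na(j)) stop("lookup error: unknown station id ", station_id)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(d$covariates)) {
    cv <- d$covariates[[j]]
    if (is.null(dates)) dates <- cv$times
    x <- cv$x[match(as.Date(dates), as.Date(cv$times))]
  } else {
    rows <- d$station == j
    if (is.null(dates)) dates <- d$dates[rows]
    x <- d$x[rows][match(as.Date(dates), as.Date(d$dates[rows]))]
  }
  if (anyNA(x)) stop("no covariate available at some requested dates")
  al <- draws_matrix(fit, "alpha"); be <- draws_matrix(fit, "beta")
  sg2 <- draws_matrix(fit, "sigma2")[, j]
  Bf <- d$basis_f$model_matrix[j, ]; Bg <- d$basis_g$model_matrix[j, ]
  a0f <- al[, 1] + as.numeric(al[, -1, drop = FALSE] %*% Bf)
  gj <- as.numeric(be %*% Bg)
  Hx <- evaluate_basis(d$basis_h, x)
  hdr <- tcrossprod(gamma_draws_station(fit, j), Hx)  # draws x dates
  mu_lin <- a0f + outer(gj, x)
  mu <- mu_lin + hdr
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu)) * sqrt(sg2)
  new_prediction_result(mu + eps, mu, mu_lin, as.Date(dates),
                        c(lon = d$meta$lon[j], lat = d$meta$lat[j]), level)
}

#' Posterior predictive distribution at an unseen location
#'
#' Spatially extrapolates only the linear part of the bias model: per
#' posterior draw the surfaces f and g are evaluated at the new point, while
#' the station-specific terms are integrated out as random effects — a fresh
#' `gamma* ~ N(0, (lambda_h S_h)^-1)` forms a new non-linear deviation
#' h*(x), and a fresh `sigma*^2 ~ InvGamma(alpha_sigma, beta_sigma)` supplies
#' the observation noise. Covariate values outside the training range are
#' evaluated by the basis's natural extrapolation with a warning.
#'
#' @param fit a [tmax_blend()] fit.
#' @param lon,lat target coordinates, decimal degrees.
#' @param x covariate values at the target (one per date).
#' @param dates `Date` vector aligned with `x`.
#' @param level central interval level.
#' @param seed RNG seed for the fresh random effects and noise.
#' @return a `prediction_result`; `NA` covariate entries propagate to
#'   missing predictions.
#' @export
ppd_new_location <- function(fit, lon, lat, x, dates = NULL, level = 0.95,
                             seed = NULL) {
  d <- fit$design
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dates)) dates <- seq_along(x)
  rng <- range(d$x)
  ok <- !is.na(x)
  if (any(x[ok] < rng[1] - 1e-9 | x[ok] > rng[2] + 1e-9))
    warning("covariate outside the training range; basis extrapolation in use")
  al <- draws_matrix(fit, "alpha"); be <- draws_matrix(fit, "beta")
  lam_h <- draws_matrix(fit, "lambda")[, "h"]
  bs <- draws_matrix(fit, "beta_sigma")
  n_draws <- nrow(al)
  pt <- matrix(c(lon, lat), 1)
  Bf <- as.numeric(evaluate_basis(d$basis_f, pt))
  Bg <- as.numeric(evaluate_basis(d$basis_g, pt))
  a0f <- al[, 1] + as.numeric(al[, -1, drop = FALSE] %*% Bf)
  gs <- as.numeric(be %*% Bg)
  xx <- ifelse(ok, x, 0)
  Hx <- evaluate_basis(d$basis_h, xx)
  pg <- ncol(Hx)
  # one fresh gamma* and sigma*^2 per posterior draw
  Rh <- chol(d$Sh)
  gstar <- t(backsolve(Rh, matrix(stats::rnorm(pg * n_draws), pg))) / sqrt(lam_h)
  sig2s <- 1 / stats::rgamma(n_draws, shape = fit$config$alpha_sigma, rate = bs)
  mu_lin <- a0f + outer(gs, xx)
  mu <- mu_lin + tcrossprod(gstar, Hx)
  ystar <- mu + matrix(stats::rnorm(length(mu)), n_draws) * sqrt(sig2s)
  ystar[, !ok] <- NA_real_; mu[, !ok] <- NA_real_; mu_lin[, !ok] <- NA_real_
  new_prediction_result(ystar, mu, mu_lin, dates, c(lon = lon, lat = lat), level)
}

#' @export
#' @describeIn tmax_blend predict method: `type = "station"` calls
#'   [ppd_station()]; `type = "location"` calls [ppd_new_location()] (supply
#'   `lon`, `lat` and either `x` or a `field` to derive the covariate from).
predict.tmax_blend <- function(object, type = c("station", "location"),
                               station = NULL, lon = NULL, lat = NULL,
                               x = NULL, field = NULL, dates = NULL,
                               level = 0.95, seed = NULL, ...) {
  type <- match.arg(type)
  if (type == "station") {
    ppd_station(object, station %||% object$design$meta$station_id[1],
                dates = dates, level = level, seed = seed)
  } else {
    if (is.null(lon) || is.null(lat)) stop("location prediction needs lon and lat")
    if (is.null(x)) {
      if (is.null(field)) stop("supply covariate x or a reanalysis field")
      cv <- match_station(field, lon, lat, k = object$config$k_neighbours,
                          power = object$config$idw_power)
      if (is.null(dates)) dates <- cv$times
      x <- cv$x[match(as.Date(dates), as.Date(cv$times))]
    }
    ppd_new_location(object, lon, lat, x, dates = dates, level = level, seed = seed)
  }
}

#' Downscale the fitted model to a fine regular grid
#'
#' Runs [ppd_new_location()] at every node of a `resolution`-degree grid
#' spanning the reanalysis domain (or `bbox`), deriving each node's
#' covariate by the fitted change-of-support rule. Returns per-cell PPD
#' draws plus the mean-component draws needed for uncertainty
#' decomposition.
#'
#' @param fit a [tmax_blend()] fit.
#' @param field the daily [reanalysis_field()] covariate source.
#' @param resolution grid spacing in degrees (e.g. 0.01).
#' @param dates `Date` vector of target days.
#' @param bbox optional `c(lon_min, lon_max, lat_min, lat_max)`; default the
#'   field's cell-center bounding box.
#' @param seed RNG seed.
#' @return an object of class `tmax_grid`: `cells` (lon/lat per cell),
#'   `dates`, arrays `draws`, `mu_draws`, `mu_lin_draws`
#'   (draw x cell x date) and `mean`/`sd` matrices (cell x date).
#' @export
downscale <- function(fit, field, resolution, dates, bbox = NULL, seed = NULL) {
  if (resolution <= 0) stop("config error: resolution must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bbox))
    bbox <- c(min(field$lon_centers), max(field$lon_centers),
              min(field$lat_centers), max(field$lat_centers))
  lons <- seq(bbox[1], bbox[2], by = resolution)
  lats <- seq(bbox[3], bbox[4], by = resolution)
  cells <- expand.grid(lon = lons, lat = lats)
  dates <- as.Date(dates)
  ti <- match(dates, as.Date(field$times))
  if (anyNA(ti)) stop("requested dates outside the reanalysis period")
  n_draws <- fit$samples$n_keep * length(fit$samples$chains)
  nc <- nrow(cells); nt <- length(dates)
  draws <- array(NA_real_, c(n_draws, nc, nt))
  mu_d <- array(NA_real_, c(n_draws, nc, nt))
  mu_l <- array(NA_real_, c(n_draws, nc, nt))
  for (ci in seq_len(nc)) {
    cv <- suppressWarnings(
      match_station(field, cells$lon[ci], cells$lat[ci],
                    k = fit$config$k_neighbours, power = fit$config$idw_power))
    pr <- suppressWarnings(
      ppd_new_location(fit, cells$lon[ci], cells$lat[ci], cv$x[ti], dates))
    draws[, ci, ] <- pr$draws
    mu_d[, ci, ] <- pr$mu_draws
    mu_l[, ci, ] <- pr$mu_lin_draws
  }
  structure(list(cells = cells, lons = lons, lats = lats, dates = dates,
                 draws = draws, mu_draws = mu_d, mu_lin_draws = mu_l,
                 mean = apply(draws, c(2, 3), mean),
                 sd = apply(draws, c(2, 3), stats::sd),
                 resolution = resolution),
            class = "tmax_grid")
}

#' @export
print.tmax_grid <- function(x, ...) {
  cat(sprintf("tmax_grid: %d cells at %.3f deg, %d dates, %d draws\n",
              nrow(x$cells), x$resolution, length(x$dates), dim(x$draws)[1]))
  invisible(x)
}

#' Aggregate gridded predictions over polygon regions
#'
#' Approximates the integral of the predictive random field over each
#' region: per posterior draw the region value is the arithmetic mean of the
#' draw's simulated values at the grid-cell centers the region contains
#' (point-in-polygon on cell centers; a cell on a shared boundary goes to
#' the first region in file order).
#'
#' @param grid a [downscale()] result.
#' @param regions regions from [read_regions_geojson()], or a list of
#'   two-column ring matrices.
#' @param level central interval level.
#' @return data.frame with one row per region x date: mean, lower, upper,
#'   sd, n_cells; attribute `draws` holds the per-region draw arrays.
#' @export
aggregate_regions <- function(grid, regions, level = 0.95) {
  if (!length(regions)) stop("no regions supplied")
  assignment <- rep(NA_integer_, nrow(grid$cells))
  pts <- as.matrix(grid$cells)
  for (ri in seq_along(regions)) {
    inside <- region_contains(regions[[ri]], pts)
    assignment[is.na(assignment) & inside] <- ri
  }
  a <- (1 - level) / 2
  out <- NULL
  draw_list <- list()
  for (ri in seq_along(regions)) {
    cells <- which(assignment == ri)
    rid <- regions[[ri]]$id %||% as.character(ri)
    if (!length(cells))
      stop("empty-region error: region ", rid, " contains no grid-cell centers")
    rd <- apply(grid$draws[, cells, , drop = FALSE], c(1, 3), mean)
    draw_list[[rid]] <- rd
    out <- rbind(out, data.frame(
      region = rid, date = grid$dates,
      mean = colMeans(rd),
      lower = apply(rd, 2, stats::quantile, probs = a, names = FALSE),
      upper = apply(rd, 2, stats::quantile, probs = 1 - a, names = FALSE),
      sd = apply(rd, 2, stats::sd),
      n_cells = length(cells)))
  }
  rownames(out) <- NULL
  attr(out, "draws") <- draw_list
  out
}

#' Decompose predictive uncertainty on a grid
#'
#' For one date, returns three per-cell standard-deviation surfaces: the
#' full PPD sd; the sd of the mean mu = alpha_0 + f + g x + h* across draws;
#' and the sd of the linear part alpha_0 + f + g x only. The gap between the
#' last two isolates the contribution of the integrated-out non-linear term.
#'
#' @param grid a [downscale()] result.
#' @param date which date (default the first).
#' @return data.frame per cell: lon, lat, sd_ppd, sd_mu, sd_mu_linear.
#' @export
uncertainty_decomposition <- function(grid, date = grid$dates[1]) {
  ti <- match(as.Date(date), grid$dates)
  if (is.na(ti)) stop("date not present in the grid")
  data.frame(lon = grid$cells$lon, lat = grid$cells$lat,
             sd_ppd = apply(grid$draws[, , ti, drop = FALSE], 2, stats::sd),
             sd_mu = apply(grid$mu_draws[, , ti, drop = FALSE], 2, stats::sd),
             sd_mu_linear = apply(grid$mu_lin_draws[, , ti, drop = FALSE], 2, stats::sd))
}

#' Read region polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features (outer rings
#' only; holes are ignored) with an `id` property.
#'
#' @param path GeoJSON file path.
#' @return list of regions, each `list(id, rings)` where `rings` is a list
#'   of two-column lon/lat matrices.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("schema error: not a GeoJSON FeatureCollection")
  lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    id <- as.character(ft$properties$id %||% i)
    geom <- ft$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    rings <- switch(geom$type,
      Polygon = list(ring_mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(poly) ring_mat(poly[[1]])),
      stop("unsupported geometry type: ", geom$type))
    list(id = id, rings = rings)
  })
}

region_contains <- function(region, pts) {
  rings <- if (!is.null(region$rings)) region$rings else list(as.matrix(region))
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) inside <- inside | mgcv::in.out(r, pts)
  inside
}
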