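#' Gridded reanalysis field
#'
#' Container for a gridded (regular lon/lat) temperature field such as a
#' reanalysis daily-maximum product. Values are stored as a 3-D array
#' (time x lat x lon) in degrees Celsius; cells that are always missing
#' (e.g. over sea for a land-only product) are allowed.
#'
#' @param lon_centers,lat_centers ascending cell-center coordinates, decimal
#'   degrees, constant spacing.
#' @param times ordered `Date` (daily) or `POSIXct` (sub-daily) timestamps.
#' @param values numeric array `length(times)` x `length(lat_centers)` x
#'   `length(lon_centers)`; `NA` marks missing.
#' @return an object of class `reanalysis_field`.
#' @export
reanalysis_field <- function(lon_centers, lat_centers, times, values) {
  lon_centers <- as.numeric(lon_centers); lat_centers <- as.numeric(lat_centers)
  check_regular <- function(x, nm) {
    if (length(x) > 1L) {
      dx <- diff(x)
      if (any(dx <= 0)) stop(nm, " centers must be strictly ascending")
      if (max(dx) - min(dx) > 1e-9) stop(nm, " grid spacing is not constant")
    }
  }
  check_regular(lon_centers, "lon"); check_regular(lat_centers, "lat")
  if (is.character(times)) times <- as.Date(times)
  if (any(diff(as.numeric(times)) <= 0)) stop("timestamps must be strictly increasing")
  values <- array(as.numeric(values),
                  dim = c(length(times), length(lat_centers), length(lon_centers)))
  structure(list(lon_centers = lon_centers, lat_centers = lat_centers,
                 times = times, values = values),
            class = "reanalysis_field")
}

#' @export
print.reanalysis_field <- function(x, ...) {
  cat(sprintf("reanalysis_field: %d x %d grid, %d time steps (%s .. %s)\n",
              length(x$lat_centers), length(x$lon_centers), length(x$times),
              format(x$times[1]), format(x$times[length(x$times)])))
  invisible(x)
}

#' Reduce an hourly field to daily maxima
#'
#' Collapses a sub-daily field to one value per calendar day per cell, the
#' maximum over that day's non-missing hours; a cell missing all hours of a
#' day is missing that day.
#'
#' @param hourly_field a [reanalysis_field()] with sub-daily timestamps.
#' @return a daily [reanalysis_field()].
#' @export
daily_max <- function(hourly_field) {
  stopifnot(inherits(hourly_field, "reanalysis_field"))
  if (length(hourly_field$times) == 0L) stop("empty field")
  days <- as.Date(hourly_field$times)
  uday <- unique(days)
  dm <- dim(hourly_field$values)
  out <- array(NA_real_, c(length(uday), dm[2], dm[3]))
  for (i in seq_along(uday)) {
    sl <- hourly_field$values[days == uday[i], , , drop = FALSE]
    out[i, , ] <- apply(sl, c(2, 3), function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  }
  reanalysis_field(hourly_field$lon_centers, hourly_field$lat_centers, uday, out)
}

#' Station-level covariate by k-nearest-neighbour inverse-distance averaging
#'
#' Converts the gridded field into a point-location covariate series by
#' averaging the `k` non-missing grid cells nearest to the station
#' (Euclidean distance in degrees) with normalised inverse-distance weights
#' \eqn{w_i \propto 1/d_i^p}. A station coincident with a cell center
#' receives weight one on that cell. Weights are constant over time, so the
#' series is the fixed weighted average of the k cell series; the default
#' ten-neighbour average is the model's change-of-support device.
#'
#' @param field a [reanalysis_field()] (daily).
#' @param station_lon,station_lat station coordinates, decimal degrees.
#' @param k number of neighbour cells (default 10).
#' @param power inverse-distance power p (default 1).
#' @param station_id identifier carried into the output.
#' @return a `covariate_series`: list with `station_id`, `times`, `x` and
#'   `weights_used` (data.frame of lat/lon indices and weights).
#' @export
match_station <- function(field, station_lon, station_lat, k = 10L, power = 1,
                          station_id = NA_character_) {
  stopifnot(inherits(field, "reanalysis_field"), k >= 1L)
  nlat <- length(field$lat_centers); nlon <- length(field$lon_centers)
  # cells with at least one non-missing value are usable (land cells)
  usable <- apply(field$values, c(2, 3), function(v) any(!is.na(v)))
  idx <- which(usable, arr.ind = TRUE)                      # (lat, lon) indices
  if (nrow(idx) < k)
    stop(sprintf("coverage error: only %d usable cells but k = %d", nrow(idx), k))
  lon_c <- field$lon_centers[idx[, 2]]
  lat_c <- field$lat_centers[idx[, 1]]
  dlon <- if (nlon > 1) diff(field$lon_centers[1:2]) else 1
  dlat <- if (nlat > 1) diff(field$lat_centers[1:2]) else 1
  if (station_lon < min(field$lon_centers) - dlon || station_lon > max(field$lon_centers) + dlon ||
      station_lat < min(field$lat_centers) - dlat || station_lat > max(field$lat_centers) + dlat)
    warning("station lies outside the reanalysis grid bounding box (extrapolating)")
  d <- sqrt((lon_c - station_lon)^2 + (lat_c - station_lat)^2)
  # deterministic tie-break on the k-th distance: (lat index, lon index)
  ord <- order(d, idx[, 1], idx[, 2])[seq_len(k)]
  dk <- d[ord]
  if (any(dk == 0)) {
    w <- as.numeric(dk == 0); w <- w / sum(w)
  } else {
    w <- 1 / dk^power; w <- w / sum(w)
  }
  sel <- idx[ord, , drop = FALSE]
  series <- matrix(NA_real_, length(field$times), k)
  for (i in seq_len(k)) series[, i] <- field$values[, sel[i, 1], sel[i, 2]]
  x <- as.numeric(series %*% w)
  structure(list(station_id = station_id, times = field$times, x = x,
                 weights_used = data.frame(lat_index = sel[, 1],
                                           lon_index = sel[, 2],
                                           distance = dk, weight = w)),
            class = "covariate_series")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("covariate_series %s: %d days, %d-cell weighted average\n",
              x$station_id, length(x$times), nrow(x$weights_used)))
  invisible(x)
}

#' Read / write a reanalysis field as long-format CSV
#'
#' Long format columns: `time, lon, lat, value` (ISO-8601 dates, missing as
#' empty). The grid is reconstructed from the distinct coordinates.
#'
#' @param path file path.
#' @export
read_reanalysis_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lon", "lat", "value")
  if (!all(need %in% names(df)))
    stop("schema error: reanalysis CSV needs columns time, lon, lat, value")
  if (nrow(df) == 0L) stop("empty input: no reanalysis rows")
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  times <- sort(unique(as.Date(df$time)))
  arr <- array(NA_real_, c(length(times), length(lat), length(lon)))
  ti <- match(as.Date(df$time), times)
  la <- match(df$lat, lat); lo <- match(df$lon, lon)
  arr[cbind(ti, la, lo)] <- df$value
  reanalysis_field(lon, lat, times, arr)
}

#' @rdname read_reanalysis_csv
#' @param field a [reanalysis_field()].
#' @export
write_reanalysis_csv <- function(field, path) {
  grid <- expand.grid(lat = field$lat_centers, lon = field$lon_centers)
  rows <- do.call(rbind, lapply(seq_along(field$times), function(i) {
    data.frame(time = format(field$times[i]), lon = grid$lon, lat = grid$lat,
               value = as.numeric(field$values[i, , ]))
  }))
  rows <- rows[!is.na(rows$value), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a station covariate series as CSV
#' @param series a `covariate_series`.
#' @param path file path.
#' @export
write_covariate_csv <- function(series, path) {
  utils::write.csv(data.frame(station_id = series$station_id,
                              date = format(series$times), x = series$x),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
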