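#' Read and validate station daily-Tmax records
#'
#' Station records are long-format CSV with columns
#' `station_id,name,lon,lat,elevation,date,tmax` (`name` optional), ISO-8601
#' dates and missing temperatures as empty fields. Validation enforces the
#' observation key (station, date) being unique, strictly increasing dates
#' per station, and temperatures inside the mixture support
#' (`u_min`, `u_max`): the outlier component has bounded support, so values
#' outside it have zero density under the model and are rejected at load.
#'
#' @param path CSV path.
#' @param u_min,u_max mixture support bounds used for validation (degrees C).
#' @return a `data.frame` of class `station_data` with columns
#'   `station_id, name, lon, lat, elevation, date, tmax`.
#' @export
read_station_csv <- function(path, u_min = -80, u_max = 80) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(station_id = "character"))
  if (nrow(df) == 0L) stop("empty input: no station rows")
  validate_stations(df, u_min = u_min, u_max = u_max)
}

#' @rdname read_station_csv
#' @param df a data.frame in the station schema.
#' @export
validate_stations <- function(df, u_min = -80, u_max = 80) {
  need <- c("station_id", "lon", "lat", "elevation", "date", "tmax")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing station columns: ", paste(miss, collapse = ", "))
  if (!"name" %in% names(df)) df$name <- as.character(df$station_id)
  df$station_id <- as.character(df$station_id)
  dts <- as.Date(df$date)
  if (anyNA(dts)) {
    bad <- which(is.na(dts))[1]
    stop(sprintf("schema error: malformed date at row %d: %s", bad, df$date[bad]))
  }
  df$date <- dts
  key <- paste(df$station_id, df$date)
  if (anyDuplicated(key)) {
    bad <- key[duplicated(key)][1]
    stop("duplicate (station, date) row: ", bad)
  }
  out_of_support <- which(!is.na(df$tmax) & (df$tmax <= u_min | df$tmax >= u_max))
  if (length(out_of_support)) {
    i <- out_of_support[1]
    stop(sprintf("validation error: tmax %.2f at row %d (station %s, %s) outside support (%g, %g)",
                 df$tmax[i], i, df$station_id[i], format(df$date[i]), u_min, u_max))
  }
  if (any(!is.finite(df$tmax) & !is.na(df$tmax)))
    stop("validation error: non-finite tmax present")
  for (co in c("lon", "lat", "elevation")) {
    v <- tapply(df[[co]], df$station_id, function(x) length(unique(x)))
    if (any(v > 1)) stop("validation error: station metadata (", co, ") varies within a station")
  }
  df <- df[order(df$station_id, df$date),
           c("station_id", "name", "lon", "lat", "elevation", "date", "tmax")]
  rownames(df) <- NULL
  class(df) <- c("station_data", "data.frame")
  df
}

#' @rdname read_station_csv
#' @export
write_station_csv <- function(df, path) {
  out <- as.data.frame(df)
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-station metadata table
#' @param df a `station_data` data.frame.
#' @return one row per station: id, name, lon, lat, elevation, n, n_missing.
#' @export
station_table <- function(df) {
  sp <- split(df, df$station_id)
  out <- do.call(rbind, lapply(sp, function(s) {
    data.frame(station_id = s$station_id[1], name = s$name[1],
               lon = s$lon[1], lat = s$lat[1], elevation = s$elevation[1],
               n = nrow(s), n_missing = sum(is.na(s$tmax)))
  }))
  rownames(out) <- NULL
  out[order(out$station_id), ]
}
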