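#' Temperature-humidity index (THI)
#'
#' `THI = 0.8 * tsa + (hra / 100) * (tsa - 14.4) + 46.4`, where `tsa` is the
#' ambient dry temperature in degrees Celsius and `hra` the ambient relative
#' humidity in percent. The humidity term vanishes at 14.4 degrees C; values
#' above ~68 indicate heat-stress conditions for dairy cattle.
#'
#' @param tsa Dry temperature (degrees C).
#' @param hra Relative humidity (%), in \[0, 100\].
#' @return Numeric THI, vectorized over inputs.
#' @export
compute_thi <- function(tsa, hra) {
  if (any(hra < 0 | hra > 100, na.rm = TRUE))
    stop("relative humidity must lie in [0, 100]")
  0.8 * tsa + (hra / 100) * (tsa - 14.4) + 46.4
}

#' Assign each location to its nearest weather station
#'
#' Point-based nearest-neighbour assignment in planar coordinates, which is
#' exactly Voronoi-cell membership for point locations. Distance ties are
#' broken toward the lexicographically smallest `station_id`.
#'
#' @param locations Data frame with columns `location_id`, `x`, `y`.
#' @param stations Data frame with columns `station_id`, `x`, `y`
#'   (unique station ids).
#' @return Data frame of `location_id`, `station_id`, `distance`.
#' @export
assign_nearest_station <- function(locations, stations) {
  if (nrow(stations) == 0) stop("empty station set")
  if (anyDuplicated(stations$station_id)) stop("station ids must be unique")
  if (!all(is.finite(c(locations$x, locations$y, stations$x, stations$y))))
    stop("coordinates must be finite")
  ord <- order(stations$station_id)
  stations <- stations[ord, , drop = FALSE]
  d <- outer(locations$x, stations$x, "-")^2 +
       outer(locations$y, stations$y, "-")^2
  # max.col(ties.method = "first") + ascending station order = lowest-id tie rule
  best <- max.col(-d, ties.method = "first")
  data.frame(location_id = locations$location_id,
             station_id = stations$station_id[best],
             distance = sqrt(d[cbind(seq_len(nrow(d)), best)]),
             stringsAsFactors = FALSE)
}

#' Merge daily weather (THI) onto milk records
#'
#' Each record receives the THI of its herd's assigned station on its
#' sampling date. Records with no matching station-date weather row are
#' flagged (`thi_missing = TRUE`) and kept.
#'
#' @param records Record data frame (`herd_id`, `date`, ...).
#' @param assignments Data frame mapping `location_id` (= herd id) to
#'   `station_id`, as returned by [assign_nearest_station()].
#' @param weather Data frame of `station_id`, `date`, `tsa`, `hra`
#'   (one row per station-day); a `thi` column is computed if absent.
#' @return `records` with added `thi` and `thi_missing` columns.
#' @export
join_weather <- function(records, assignments, weather) {
  if (!("thi" %in% colnames(weather)))
    weather$thi <- compute_thi(weather$tsa, weather$hra)
  st <- assignments$station_id[match(records$herd_id,
                                     assignments$location_id)]
  key <- paste(st, as.character(records$date))
  wkey <- paste(weather$station_id, as.character(weather$date))
  records$thi <- weather$thi[match(key, wkey)]
  records$thi_missing <- is.na(records$thi)
  records
}

#' Simulate a daily station weather table
#'
#' Seasonal sinusoidal temperature with optional heat-wave windows, for
#' exercising the weather merge on synthetic data.
#'
#' @param stations Data frame with `station_id`.
#' @param dates Vector of dates to cover.
#' @param seed Integer seed.
#' @param heat_wave Optional list with `start`, `end` (dates) and `delta`
#'   (degrees C added within the window).
#' @return Data frame of `station_id`, `date`, `tsa`, `hra`, `thi`.
#' @export
simulate_weather <- function(stations, dates, seed = 1L, heat_wave = NULL) {
  set.seed(seed)
  dates <- sort(unique(as.Date(dates)))
  grid <- expand.grid(station_id = stations$station_id, date = dates,
                      stringsAsFactors = FALSE)
  doy <- as.integer(format(grid$date, "%j"))
  tsa <- 10 + 8 * sin(2 * pi * (doy - 105) / 365) +
    stats::rnorm(nrow(grid), sd = 2)
  if (!is.null(heat_wave)) {
    inwave <- grid$date >= as.Date(heat_wave$start) &
      grid$date <= as.Date(heat_wave$end)
    tsa[inwave] <- tsa[inwave] + heat_wave$delta
  }
  hra <- pmin(100, pmax(0, 75 - 0.8 * (tsa - 10) +
                          stats::rnorm(nrow(grid), sd = 5)))
  grid$tsa <- tsa
  grid$hra <- hra
  grid$thi <- compute_thi(tsa, hra)
  grid
}
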