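#' Configuration for the synthetic GPS-collar trajectory generator
#'
#' The generator emulates the statistical profile of a single-collar
#' Bornean-elephant deployment: fixes every two hours over several years,
#' coordinates confined to a small home range (latitude about 5.0--5.4,
#' longitude about 118.4--119.0), collar temperature near 29 C.  Movement is
#' a sum of three components in local east/north kilometres around
#' `home_center`:
#'
#' * a deterministic diurnal foraging loop of radius `diurnal_amp_km`
#'   (elephants commute between feeding and resting sites on a daily rhythm);
#' * a slow seasonal drift of the range centre along the longitude axis with
#'   amplitude `seasonal_amp_km` and an annual period (seasonal range shifts);
#' * a first-order autoregressive (Ornstein--Uhlenbeck-style) jitter with
#'   per-step `persistence` and stationary standard deviation `home_sd_km`,
#'   pulling the animal back toward the (moving) range centre.
#'
#' With probability `excursion_prob` per fix the animal leaves on a
#' multi-step excursion toward `plantation` at `excursion_speed_kmh`,
#' dwells nearby, and returns, so that long tracks contain fixes within a
#' few kilometres of the hazard site.
#'
#' @param n_obs number of fixes to generate.
#' @param start_date first calendar date (ISO 8601 string or `Date`).
#' @param cadence_hours hours between consecutive fixes (default 2).
#' @param home_center named numeric `c(latitude=, longitude=)` range centre.
#' @param home_sd_km stationary SD of the autoregressive jitter, km (> 0).
#' @param persistence lag-1 autocorrelation of the jitter, in \[0, 1).
#' @param diurnal_amp_km radius of the daily foraging loop, km (>= 0).
#' @param seasonal_amp_km amplitude of the annual east-west range drift, km.
#' @param plantation named numeric `c(latitude=, longitude=)` hazard site.
#' @param excursion_prob per-fix probability of starting an excursion.
#' @param excursion_speed_kmh travel speed during excursions, km/h.
#' @param temp_mean_c,temp_sd_c collar temperature mean and SD, Celsius.
#' @param lat_bounds,lon_bounds coordinate clamps, decimal degrees.
#' @param populate_sensor_fields when `TRUE`, fill the normally-zero
#'   ExtTemp/Activity/Speed/Direction columns with plausible values.
#' @param seed integer RNG seed; the same seed reproduces the table exactly.
#' @return a list of class `"trajectory_config"`.
#' @export
trajectory_config <- function(n_obs = 9168,
                              start_date = "2012-01-01",
                              cadence_hours = 2,
                              home_center = c(latitude = 5.20, longitude = 118.66),
                              home_sd_km = 3,
                              persistence = 0.95,
                              diurnal_amp_km = 2,
                              seasonal_amp_km = 8,
                              plantation = c(latitude = 5.25, longitude = 118.70),
                              excursion_prob = 0.02,
                              excursion_speed_kmh = 0.8,
                              temp_mean_c = 29.2,
                              temp_sd_c = 1.93,
                              lat_bounds = c(5.01, 5.38),
                              lon_bounds = c(118.44, 118.95),
                              populate_sensor_fields = FALSE,
                              seed = 1L) {
  stopifnot(is.numeric(n_obs), length(n_obs) == 1L, n_obs >= 0)
  stopifnot(cadence_hours > 0, home_sd_km > 0,
            persistence >= 0, persistence < 1,
            diurnal_amp_km >= 0, seasonal_amp_km >= 0,
            excursion_prob >= 0, excursion_prob <= 1,
            excursion_speed_kmh > 0)
  check_coords(home_center[["latitude"]], home_center[["longitude"]])
  check_coords(plantation[["latitude"]], plantation[["longitude"]])
  structure(list(
    n_obs = as.integer(n_obs), start_date = as.Date(start_date),
    cadence_hours = cadence_hours, home_center = home_center,
    home_sd_km = home_sd_km, persistence = persistence,
    diurnal_amp_km = diurnal_amp_km, seasonal_amp_km = seasonal_amp_km,
    plantation = plantation, excursion_prob = excursion_prob,
    excursion_speed_kmh = excursion_speed_kmh,
    temp_mean_c = temp_mean_c, temp_sd_c = temp_sd_c,
    lat_bounds = lat_bounds, lon_bounds = lon_bounds,
    populate_sensor_fields = populate_sensor_fields,
    seed = as.integer(seed)
  ), class = "trajectory_config")
}

obs_columns <- c("obs_id", "local_date", "local_time", "latitude", "longitude",
                 "temperature", "ext_temp", "activity", "speed", "direction",
                 "cov", "hdop", "distance", "count")

empty_obs_table <- function() {
  tibble::tibble(
    obs_id = integer(), local_date = as.Date(character()),
    local_time = character(), latitude = double(), longitude = double(),
    temperature = double(), ext_temp = double(), activity = double(),
    speed = double(), direction = double(), cov = double(), hdop = double(),
    distance = double(), count = integer()
  )
}

#' Simulate a GPS-collar observation table
#'
#' Generates `config$n_obs` fixes at the configured cadence with the movement
#' model described in [trajectory_config()].  The run is fully reproducible:
#' the same configuration (including `seed`) yields a byte-identical table.
#'
#' @param config a [trajectory_config()].
#' @return a tibble of class `"collar_obs"` with one row per fix, columns
#'   `obs_id, local_date, local_time, latitude, longitude, temperature,
#'   ext_temp, activity, speed, direction, cov, hdop, distance, count`.
#' @examples
#' obs <- simulate_trajectory(trajectory_config(n_obs = 48, seed = 7))
#' head(obs)
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  n <- config$n_obs
  if (n == 0L) {
    out <- empty_obs_table()
    class(out) <- c("collar_obs", class(out))
    return(out)
  }
  set.seed(config$seed)

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n) - 1) * config$cadence_hours * 3600
  hour_frac <- as.numeric(format(times, "%H")) +
    as.numeric(format(times, "%M")) / 60
  doy <- as.numeric(format(times, "%j")) + hour_frac / 24

  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  home_lat <- config$home_center[["latitude"]]
  home_lon <- config$home_center[["longitude"]]
  coslat <- cos(deg2rad(home_lat))
  # hazard site in local km east/north of the home centre
  plant_e <- (config$plantation[["longitude"]] - home_lon) * km_per_deg * coslat
  plant_n <- (config$plantation[["latitude"]] - home_lat) * km_per_deg

  # deterministic components
  det_e <- config$diurnal_amp_km * sin(2 * pi * hour_frac / 24) +
    config$seasonal_amp_km * sin(2 * pi * doy / 365.25)
  det_n <- config$diurnal_amp_km * cos(2 * pi * hour_frac / 24)

  phi <- config$persistence
  sigma_step <- config$home_sd_km * sqrt(1 - phi^2)
  step_km <- config$excursion_speed_kmh * config$cadence_hours

  pos_e <- numeric(n); pos_n <- numeric(n)
  z <- rnorm(2, 0, config$home_sd_km)
  mode <- "home"; dwell_left <- 0L
  cur_e <- det_e[1] + z[1]; cur_n <- det_n[1] + z[2]
  pos_e[1] <- cur_e; pos_n[1] <- cur_n
  for (t in 2:max(n, 2)) {
    if (t > n) break
    if (mode == "home") {
      z <- phi * z + rnorm(2, 0, sigma_step)
      cur_e <- det_e[t] + z[1]; cur_n <- det_n[t] + z[2]
      if (config$excursion_prob > 0 && runif(1) < config$excursion_prob) {
        mode <- "out"
      }
    } else if (mode == "out") {
      de <- plant_e - cur_e; dn <- plant_n - cur_n
      dist <- sqrt(de^2 + dn^2)
      adv <- min(step_km, dist)
      cur_e <- cur_e + adv * de / max(dist, 1e-9) + rnorm(1, 0, sigma_step / 2)
      cur_n <- cur_n + adv * dn / max(dist, 1e-9) + rnorm(1, 0, sigma_step / 2)
      if (sqrt((plant_e - cur_e)^2 + (plant_n - cur_n)^2) < 1) {
        dwell_left <- 1L + stats::rgeom(1, 0.3)
        mode <- "dwell"
      }
    } else if (mode == "dwell") {
      cur_e <- plant_e + rnorm(1, 0, sigma_step / 2)
      cur_n <- plant_n + rnorm(1, 0, sigma_step / 2)
      dwell_left <- dwell_left - 1L
      if (dwell_left <= 0L) mode <- "in"
    } else { # inbound
      de <- det_e[t] - cur_e; dn <- det_n[t] - cur_n
      dist <- sqrt(de^2 + dn^2)
      adv <- min(step_km, dist)
      cur_e <- cur_e + adv * de / max(dist, 1e-9) + rnorm(1, 0, sigma_step / 2)
      cur_n <- cur_n + adv * dn / max(dist, 1e-9) + rnorm(1, 0, sigma_step / 2)
      if (sqrt((det_e[t] - cur_e)^2 + (det_n[t] - cur_n)^2) < 1) {
        z <- c(cur_e - det_e[t], cur_n - det_n[t])
        mode <- "home"
      }
    }
    pos_e[t] <- cur_e; pos_n[t] <- cur_n
  }

  lat <- home_lat + pos_n / km_per_deg
  lon <- home_lon + pos_e / (km_per_deg * coslat)
  lat <- pmin(pmax(lat, config$lat_bounds[1]), config$lat_bounds[2])
  lon <- pmin(pmax(lon, config$lon_bounds[1]), config$lon_bounds[2])

  temperature <- rnorm(n, config$temp_mean_c, config$temp_sd_c)
  cov <- pmin(pmax(rnorm(n, 1.23, 1.89), 0), 5)
  hdop <- pmin(pmax(rnorm(n, 2.21, 2.07), 0), 21)
  if (config$populate_sensor_fields) {
    ext_temp <- rnorm(n, config$temp_mean_c - 2, config$temp_sd_c)
    activity <- round(runif(n, 0, 255))
    speed <- pmax(rnorm(n, 0.5, 0.4), 0)
    direction <- runif(n, 0, 360)
  } else {
    ext_temp <- activity <- speed <- direction <- rep(0, n)
  }
  distance <- c(0, haversine_km(lat[-n], lon[-n], lat[-1], lon[-1])) * 1000

  out <- tibble::tibble(
    obs_id = seq_len(n),
    local_date = as.Date(format(times, "%Y-%m-%d")),
    local_time = format(times, "%H:%M:%S"),
    latitude = lat, longitude = lon,
    temperature = temperature, ext_temp = ext_temp, activity = activity,
    speed = speed, direction = direction, cov = cov, hdop = hdop,
    distance = distance, count = 2199L + seq_len(n) - 1L
  )
  class(out) <- c("collar_obs", class(out))
  out
}

csv_header_map <- c(
  ObsId = "obs_id", LocalDate = "local_date", LocalTime = "local_time",
  Lat = "latitude", Long = "longitude", Temperature = "temperature",
  ExtTemp = "ext_temp", Activity = "activity", Speed = "speed",
  Direction = "direction", Cov = "cov", HDOP = "hdop",
  Distance = "distance", Count = "count"
)

#' Write a GPS-collar observation table to CSV
#'
#' RFC 4180 CSV with the collar-export column set
#' (`ObsId,LocalDate,LocalTime,Lat,Long,Temperature,ExtTemp,Activity,Speed,
#' Direction,Cov,HDOP,Distance,Count`), dates in ISO 8601 and times as
#' `HH:MM:SS`.  Numeric fields round-trip exactly through
#' [read_observations_csv()].
#'
#' @param table an observation tibble as produced by [simulate_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(table, path) {
  missing_cols <- setdiff(unname(csv_header_map), names(table))
  if (length(missing_cols) > 0) {
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- table[unname(csv_header_map)]
  names(out) <- names(csv_header_map)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a GPS-collar observation table from CSV
#'
#' Parses the column set written by [write_observations_csv()].  A missing
#' required column raises a schema error listing the absent names; a row with
#' an unparseable value raises an error naming the file line.
#'
#' @param path CSV file path.
#' @return an observation tibble of class `"collar_obs"`.
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(names(csv_header_map), header)
  if (length(missing_cols) > 0) {
    stop("CSV schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # all columns are read as text and converted with base R numeric parsing,
  # which is correctly rounded, so doubles round-trip bit-exactly
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  numeric_cols <- setdiff(names(csv_header_map), c("LocalDate", "LocalTime"))
  bad_lines <- integer(0)
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed) & !is.na(tab[[col]]))
    bad_lines <- union(bad_lines, bad + 1L)  # +1 for the header line
    tab[[col]] <- parsed
  }
  dates <- as.Date(tab$LocalDate, format = "%Y-%m-%d")
  bad_lines <- union(bad_lines, which(is.na(dates) & !is.na(tab$LocalDate)) + 1L)
  tab$LocalDate <- dates
  if (length(bad_lines) > 0) {
    stop("CSV parse error at file line(s): ",
         paste(sort(bad_lines), collapse = ", "), call. = FALSE)
  }
  tab$ObsId <- as.integer(tab$ObsId)
  tab$Count <- as.integer(tab$Count)
  tab <- tab[names(csv_header_map)]
  names(tab) <- unname(csv_header_map)
  class(tab) <- c("collar_obs", class(tab))
  tab
}

#' Plot a collar trajectory
#'
#' Track in longitude/latitude coloured by date, with optional hazard-site
#' marker and buffer ring.
#'
#' @param object a `"collar_obs"` tibble.
#' @param plantation optional named numeric `c(latitude=, longitude=)`.
#' @param radius_km buffer radius drawn around the plantation.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot collar_obs
#' @export
autoplot.collar_obs <- function(object, plantation = NULL, radius_km = 5, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$longitude, y = .data$latitude)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$local_date), alpha = 0.6) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (deg E)", y = "Latitude (deg N)",
                  colour = "Date")
  if (!is.null(plantation)) {
    ring <- buffer_ring(plantation[["latitude"]], plantation[["longitude"]],
                        radius_km)
    p <- p +
      ggplot2::geom_path(data = ring, colour = "red", linetype = 2) +
      ggplot2::annotate("point", x = plantation[["longitude"]],
                        y = plantation[["latitude"]], colour = "red", size = 2)
  }
  p
}
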