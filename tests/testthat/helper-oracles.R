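# Independent distance oracle: spherical law of cosines on the same sphere.
# Kept free of any package internals so it can disagree with haversine_km.
slc_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  ca <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  radius_km * acos(pmin(pmax(ca, -1), 1))
}

random_points <- function(n, lat_range = c(-80, 80), lon_range = c(-179, 179)) {
  tibble::tibble(lat = runif(n, lat_range[1], lat_range[2]),
                 lon = runif(n, lon_range[1], lon_range[2]))
}

# small observation table with hand-set values
tiny_obs <- function() {
  tibble::tibble(
    obs_id = 1:3,
    local_date = as.Date(c("2015-07-04", "2015-07-04", "2015-07-05")),
    local_time = c("12:00:00", "14:00:00", "02:00:00"),
    latitude = c(5.2, 5.21, 5.19),
    longitude = c(118.66, 118.67, 118.65),
    temperature = c(29.1, 29.5, 28.8),
    ext_temp = 0, activity = 0, speed = 0, direction = 0,
    cov = c(1.2, 0.8, 2.0), hdop = c(2.1, 1.9, 3.0),
    distance = c(0, 1500, 2400), count = 2199:2201
  )
}

smooth_sim_config <- function(n_obs = 2000, seed = 42) {
  trajectory_config(n_obs = n_obs, seed = seed, home_sd_km = 0.3,
                    diurnal_amp_km = 2, seasonal_amp_km = 0,
                    excursion_prob = 0)
}

make_linear_data <- function(n = 400, noise = 0.005, seed = 1) {
  set.seed(seed)
  feats <- tibble::tibble(day = rep(1:20, n / 20),
                          month = rep(1:4, each = n / 4),
                          year = rep(2014:2015, each = n / 2),
                          hour = rep(seq(0, 22, 2), length.out = n))
  # coordinate-scale linear map of the calendar features plus tiny noise
  labs <- tibble::tibble(
    u = 5.2 + 0.01 * feats$day - 0.004 * feats$hour + rnorm(n, 0, noise),
    v = 118.66 + 0.005 * feats$month + 0.02 * (feats$year - 2014) +
      rnorm(n, 0, noise))
  list(features = feats, labels = labs)
}
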