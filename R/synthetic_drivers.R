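#' Climate parameters for the synthetic weather generator
#'
#' Sinusoidal annual cycles for temperature and relative humidity with AR(1)
#' day-to-day persistence ("a warm day tends to follow a warm day"),
#' Bernoulli-Gamma precipitation, Magnus saturation vapor pressure, and a
#' single plant-available soil-water bucket. Defaults emulate a temperate
#' lowland grassland site.
#'
#' @param t_mean,t_amp annual mean and amplitude of daily mean temperature
#'   (deg C).
#' @param t_sd,t_ar1 SD and lag-1 autocorrelation of temperature anomalies.
#' @param t_range mean diurnal range used to place the daily minimum below
#'   the mean; `t_min_sd` adds day-to-day variation.
#' @param t_min_sd SD of the diurnal-range variation (deg C).
#' @param rh_mean,rh_amp,rh_sd,rh_ar1 same structure for relative humidity
#'   (%); the humidity cycle peaks in winter (opposite phase to temperature).
#' @param rain_prob daily probability of rain; `rain_shape`, `rain_mean_mm`
#'   shape and mean of the Gamma amount on wet days.
#' @param rain_shape Gamma shape parameter of wet-day amounts.
#' @param rain_mean_mm mean wet-day precipitation (mm).
#' @param soil_capacity_mm plant-available water capacity of the soil bucket.
#' @param peak_doy day of year when temperature peaks.
#' @return Named list of class `isocow_climate`.
#' @export
climate_params <- function(t_mean = 9, t_amp = 9, t_sd = 2.2, t_ar1 = 0.7,
                           t_range = 7, t_min_sd = 1,
                           rh_mean = 77, rh_amp = 6, rh_sd = 6, rh_ar1 = 0.5,
                           rain_prob = 0.45, rain_shape = 0.7,
                           rain_mean_mm = 4.5,
                           soil_capacity_mm = 120, peak_doy = 200) {
  p <- as.list(environment())
  class(p) <- c("isocow_climate", "list")
  p
}

# AR(1) anomaly series with stationary SD `sd`
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0) {
    return(numeric(n))
  }
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(max(0, 1 - phi^2)))
    for (i in 2:n) e[i] <- phi * e[i - 1] + innov[i - 1]
  }
  e
}

# Magnus saturation vapor pressure (hPa) over water
saturation_vp <- function(t_c) {
  6.112 * exp(17.62 * t_c / (243.12 + t_c))
}

#' Generate a synthetic daily weather table
#'
#' @param n_days number of days (>= 1).
#' @param seed integer seed; a fixed seed reproduces the table bit-identically.
#' @param climate see [climate_params()].
#' @param start_date first calendar day.
#' @return data.frame with columns `date`, `t_av`, `t_min`, `rh` (0-100),
#'   `precip` (mm/d), `vp` (hPa) and `soil_water` (mm, plant-available
#'   bucket bookkeeping driven by rain and a temperature-dependent
#'   evapotranspiration demand).
#' @examples
#' w <- gen_weather(365, seed = 1)
#' summary(w$t_av)
#' @export
gen_weather <- function(n_days, seed, climate = climate_params(),
                        start_date = as.Date("2000-01-01")) {
  if (length(n_days) != 1 || n_days < 1) {
    stop("n_days must be a positive scalar")
  }
  n_days <- as.integer(n_days)
  set.seed(as.integer(seed))
  date <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(format(date, "%j"))
  phase <- 2 * pi * (doy - climate$peak_doy) / 365.25

  t_av <- climate$t_mean + climate$t_amp * cos(phase) +
    ar1_noise(n_days, climate$t_sd, climate$t_ar1)
  drop <- pmax(0.5, climate$t_range / 2 +
    stats::rnorm(n_days, 0, climate$t_min_sd))
  t_min <- t_av - drop

  rh <- climate$rh_mean - climate$rh_amp * cos(phase) +
    ar1_noise(n_days, climate$rh_sd, climate$rh_ar1)
  if (any(rh < 0 | rh > 100)) {
    warning("relative humidity outside [0, 100] clipped")
    rh <- pmin(100, pmax(0, rh))
  }

  wet <- stats::runif(n_days) < climate$rain_prob
  amount <- stats::rgamma(n_days, shape = climate$rain_shape,
                          scale = climate$rain_mean_mm / climate$rain_shape)
  precip <- ifelse(wet, amount, 0)

  vp <- rh / 100 * saturation_vp(t_av)

  # single-bucket plant-available water bookkeeping
  et <- pmax(0.3, 0.16 * pmax(t_av, 0))
  soil <- numeric(n_days)
  s <- climate$soil_capacity_mm / 2
  for (i in seq_len(n_days)) {
    s <- min(climate$soil_capacity_mm, max(0, s + precip[i] - et[i]))
    soil[i] <- s
  }

  out <- data.frame(
    date = date, t_av = t_av, t_min = t_min, rh = rh,
    precip = precip, vp = vp, soil_water = soil
  )
  validate_weather(out)
  out
}

validate_weather <- function(w) {
  stopifnot(
    all(w$rh >= 0 & w$rh <= 100),
    all(w$precip >= 0),
    all(w$t_min <= w$t_av),
    all(w$vp >= 0)
  )
  invisible(w)
}

#' Parameters of the synthetic isotope forcings
#'
#' @param precip_mean annual mean delta-18O of precipitation (per mil VSMOW).
#' @param seasonal_contrast warm-half-year minus cold-half-year mean
#'   delta-18O of precipitation (per mil); the seasonal sinusoid is scaled
#'   so this contrast emerges exactly in expectation.
#' @param t_anom_slope coupling of precipitation delta to the day's
#'   temperature anomaly (per mil per deg C), so the temperature -
#'   precipitation-delta correlation emerges.
#' @param precip_sd day-to-day noise SD of precipitation delta (per mil).
#' @param groundwater constant groundwater (= drinking water) delta.
#' @param stem_window_d trailing window over which stem water integrates
#'   precipitation delta (soil mixing).
#' @param leaf_enrich_coef daytime evaporative enrichment of leaf over stem
#'   water, scaled by (1 - RH/100) (per mil).
#' @param leaf_range diurnal range of leaf-water delta (per mil; max minus
#'   min of the 24 hourly values).
#' @param leaf_peak_hour hour of the afternoon leaf-water maximum; the
#'   minimum sits 12 h earlier (pre-dawn).
#' @param leaf_noise_sd day-level noise on the leaf mean (per mil).
#' @param peak_doy day of year of the warm-season peak (must match the
#'   weather generator's).
#' @return Named list of class `isocow_isoparams`.
#' @export
isotope_params <- function(precip_mean = -8.7, seasonal_contrast = 3.0,
                           t_anom_slope = 0.3, precip_sd = 1.2,
                           groundwater = -10, stem_window_d = 30,
                           leaf_enrich_coef = 25, leaf_range = 7,
                           leaf_peak_hour = 15, leaf_noise_sd = 0.5,
                           peak_doy = 200) {
  p <- as.list(environment())
  class(p) <- c("isocow_isoparams", "list")
  p
}

# trailing mean with partial windows at the series start
trailing_mean <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1, i - window + 1)
  (cs - c(0, cs)[lo]) / (i - lo + 1)
}

#' Generate synthetic isotope forcings matched to a weather table
#'
#' Precipitation delta-18O follows a seasonal sinusoid in phase with
#' temperature (warm-season values higher), plus a coupling to the day's
#' temperature anomaly and white noise. Groundwater (= drinking water) is
#' constant. Stem water integrates precipitation over a trailing window.
#' Leaf water carries a fixed diurnal template (pre-dawn minimum,
#' mid-afternoon maximum) scaled to the configured range and centred on a
#' day mean enriched over stem water in proportion to the saturation
#' deficit.
#'
#' @param weather a weather table from [gen_weather()].
#' @param seed integer seed.
#' @param params see [isotope_params()].
#' @return list with `daily` (data.frame: `date`, `delta_precip`,
#'   `delta_stem`, `delta_groundwater`, `leaf_day_mean`) and `leaf_diurnal`
#'   (long data.frame: `date`, `hour` 0-23, `delta`).
#' @examples
#' w <- gen_weather(365, seed = 1)
#' f <- gen_isotope_forcings(w, seed = 1)
#' head(f$daily)
#' @export
gen_isotope_forcings <- function(weather, seed, params = isotope_params()) {
  if (nrow(weather) < 1) {
    stop("weather table is empty")
  }
  set.seed(as.integer(seed))
  n <- nrow(weather)
  doy <- as.integer(format(weather$date, "%j"))
  phase <- 2 * pi * (doy - params$peak_doy) / 365.25

  # amplitude such that warm-half minus cold-half mean equals the contrast
  amp <- params$seasonal_contrast * pi / 4
  t_anom <- weather$t_av - trailing_mean(weather$t_av, 31)
  delta_precip <- params$precip_mean + amp * cos(phase) +
    params$t_anom_slope * t_anom +
    stats::rnorm(n, 0, params$precip_sd)

  delta_stem <- trailing_mean(delta_precip, params$stem_window_d)
  leaf_day_mean <- delta_stem +
    params$leaf_enrich_coef * (1 - weather$rh / 100) +
    stats::rnorm(n, 0, params$leaf_noise_sd)

  hour <- 0:23
  template <- -cos(2 * pi * (hour - (params$leaf_peak_hour - 12)) / 24)
  leaf_diurnal <- data.frame(
    date = rep(weather$date, each = 24),
    hour = rep(hour, n),
    delta = rep(leaf_day_mean, each = 24) +
      params$leaf_range / 2 * rep(template, n)
  )

  list(
    daily = data.frame(
      date = weather$date,
      delta_precip = delta_precip,
      delta_stem = delta_stem,
      delta_groundwater = rep(params$groundwater, n),
      leaf_day_mean = leaf_day_mean
    ),
    leaf_diurnal = leaf_diurnal
  )
}

#' Husbandry parameters for the synthetic herd calendar
#'
#' @param grazing_start_doy,grazing_end_doy day-of-year bounds of the
#'   grazing (pasture) season; outside them the animal is in the stall.
#' @param calving_days integer day indices (1-based into the run) on which
#'   a calf is born; lactation then runs for `weaning_age_d` days.
#' @param weaning_age_d calf age at weaning (d).
#' @param gestation_d gestation length; gravidity days count up over the
#'   `gestation_d` days preceding each calving.
#' @param bw_mean,bw_amp mean and seasonal amplitude of body weight (kg).
#' @param bw_sd weighing-to-weighing noise (kg).
#' @param weighing_interval_d days between weighings; body weight is
#'   linearly interpolated between weighings.
#' @return Named list of class `isocow_husbandry`.
#' @export
husbandry_params <- function(grazing_start_doy = 105, grazing_end_doy = 315,
                             calving_days = integer(), weaning_age_d = 250,
                             gestation_d = 283,
                             bw_mean = 637, bw_amp = 20, bw_sd = 8,
                             weighing_interval_d = 60) {
  p <- as.list(environment())
  class(p) <- c("isocow_husbandry", "list")
  p
}

#' Generate a synthetic herd calendar
#'
#' @param n_days number of days.
#' @param seed integer seed (used for the weighing noise).
#' @param husbandry see [husbandry_params()].
#' @param start_date first calendar day.
#' @return data.frame with columns `date`, `keeping` ("pasture"/"stall"),
#'   `lactating`, `calf_age` (d, NA outside lactation), `gravidity_day`
#'   (0 outside gestation) and `body_weight` (kg, linearly interpolated
#'   between weighings).
#' @examples
#' cal <- gen_calendar(365, seed = 1,
#'                     husbandry = husbandry_params(calving_days = 100))
#' table(cal$keeping)
#' @export
gen_calendar <- function(n_days, seed, husbandry = husbandry_params(),
                         start_date = as.Date("2000-01-01")) {
  if (length(n_days) != 1 || n_days < 1) {
    stop("n_days must be a positive scalar")
  }
  n_days <- as.integer(n_days)
  set.seed(as.integer(seed))
  date <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(format(date, "%j"))
  keeping <- ifelse(
    doy >= husbandry$grazing_start_doy & doy < husbandry$grazing_end_doy,
    "pasture", "stall"
  )

  lactating <- rep(FALSE, n_days)
  calf_age <- rep(NA_real_, n_days)
  cd <- sort(as.integer(husbandry$calving_days))
  if (length(cd) > 1 && any(diff(cd) < husbandry$weaning_age_d)) {
    stop("overlapping lactation windows: calvings closer than weaning age")
  }
  for (c0 in cd) {
    idx <- c0:min(n_days, c0 + husbandry$weaning_age_d - 1)
    idx <- idx[idx >= 1]
    lactating[idx] <- TRUE
    calf_age[idx] <- idx - c0
  }

  gravidity_day <- rep(0L, n_days)
  for (c0 in cd) {
    idx <- max(1, c0 - husbandry$gestation_d):(c0 - 1)
    idx <- idx[idx >= 1 & idx <= n_days]
    gravidity_day[idx] <- husbandry$gestation_d - (c0 - idx)
  }

  weigh_idx <- unique(c(
    seq(1, n_days, by = husbandry$weighing_interval_d),
    n_days
  ))
  bw_at_weigh <- husbandry$bw_mean +
    husbandry$bw_amp * cos(2 * pi * (doy[weigh_idx] - 240) / 365.25) +
    stats::rnorm(length(weigh_idx), 0, husbandry$bw_sd)
  bw <- if (length(weigh_idx) == 1) {
    rep(bw_at_weigh, n_days)
  } else {
    stats::approx(weigh_idx, bw_at_weigh, xout = seq_len(n_days))$y
  }
  stopifnot(all(bw > 0))

  data.frame(
    date = date, keeping = keeping, lactating = lactating,
    calf_age = calf_age, gravidity_day = gravidity_day, body_weight = bw
  )
}

#' Default feed property sets
#'
#' Fresh grass on pasture (90% of the intake as leaves, the rest as
#' pseudo-stems) and a silage+hay composite in the stall. Water contents
#' are fractions of fresh mass; crude protein and digestibility are
#' fractions of dry matter; `me_mj_per_kg_dm` is the metabolizable-energy
#' density used to convert the energy requirement into dry matter intake.
#'
#' @param grass,silage_hay optional named lists overriding single fields.
#' @return list with elements `grass` and `silage_hay`.
#' @examples
#' default_feed()$grass$water_content
#' @export
default_feed <- function(grass = NULL, silage_hay = NULL) {
  feed <- list(
    grass = list(
      feed_type = "grass", water_content = 0.80, crude_protein = 0.153,
      digestibility = 0.72, leaf_fraction = 0.9, me_mj_per_kg_dm = 10.5
    ),
    silage_hay = list(
      feed_type = "silage_hay", water_content = 0.55, crude_protein = 0.129,
      digestibility = 0.70, leaf_fraction = 0, me_mj_per_kg_dm = 9.5
    )
  )
  if (!is.null(grass)) feed$grass <- modify_named(feed$grass, grass, "feed field")
  if (!is.null(silage_hay)) {
    feed$silage_hay <- modify_named(feed$silage_hay, silage_hay, "feed field")
  }
  for (f in feed) {
    fr <- unlist(f[c("water_content", "crude_protein", "digestibility",
                     "leaf_fraction")])
    if (any(fr < 0 | fr > 1)) stop("feed fractions must lie in [0, 1]")
  }
  feed
}

#' Generate a complete synthetic driver bundle
#'
#' Convenience wrapper producing aligned weather, isotope forcings and herd
#' calendar from one master seed (sub-generators receive distinct derived
#' seeds).
#'
#' @param n_days number of days.
#' @param seed master integer seed.
#' @param climate,iso_params,husbandry parameter sets for the three
#'   generators.
#' @param start_date first calendar day.
#' @return list with `weather`, `isotopes` (daily forcings), `leaf_diurnal`
#'   and `calendar`.
#' @examples
#' d <- gen_drivers(120, seed = 1)
#' names(d)
#' @export
gen_drivers <- function(n_days, seed, climate = climate_params(),
                        iso_params = isotope_params(),
                        husbandry = husbandry_params(
                          calving_days = if (n_days >= 100) {
                            seq(100, n_days, by = 365)
                          } else {
                            integer()
                          }
                        ),
                        start_date = as.Date("2000-01-01")) {
  seed <- as.integer(seed)
  weather <- gen_weather(n_days, seed, climate, start_date)
  forc <- gen_isotope_forcings(weather, seed + 1000L, iso_params)
  calendar <- gen_calendar(n_days, seed + 2000L, husbandry, start_date)
  list(
    weather = weather,
    isotopes = forc$daily,
    leaf_diurnal = forc$leaf_diurnal,
    calendar = calendar
  )
}
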