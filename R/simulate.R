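#' Run the daily body-water isotope simulation
#'
#' Computes every O input and output flux for each day from the drivers,
#' closes the water and oxygen balances, assigns delta-18O to the input
#' fluxes, advances the body-water recursion (after a spin-up at day-1
#' drivers, initialised at the day-1 steady state), and emits the daily
#' table of flux amounts and deltas. Output-flux deltas are body water plus
#' the constant fractionation offsets; fecal, urinary, sweat and milk water
#' leave at body-water delta.
#'
#' @param drivers list with aligned `weather`, `isotopes`, `leaf_diurnal`
#'   and `calendar` tables, as produced by [gen_drivers()] or read back via
#'   [read_driver_tables()].
#' @param feed feed property sets, see [default_feed()].
#' @param config run configuration, see [run_config()].
#' @param delta_overrides named list of daily vectors (or scalars) that
#'   replace computed input deltas; names among `d_fw`, `d_bO`, `d_vapor`,
#'   `d_dw`. Used by the hold-constant variance experiments.
#' @param flux_overrides named list of daily vectors replacing computed
#'   flux amounts (mol O/d) before balance closure, e.g. `m_dw`.
#' @return data.frame with one row per day: keeping, THI (and its panting
#'   flag), all flux amounts (mol O/d), input deltas, `d_bw`, the deltas of
#'   every output flux, and the daily keratin delta `d_keratin`.
#' @examples
#' d <- gen_drivers(200, seed = 1)
#' sim <- simulate_body_water(d)
#' range(sim$d_bw)
#' @export
simulate_body_water <- function(drivers, feed = default_feed(),
                                config = run_config(),
                                delta_overrides = list(),
                                flux_overrides = list()) {
  weather <- drivers$weather
  iso <- drivers$isotopes
  leaf <- drivers$leaf_diurnal
  calendar <- drivers$calendar
  n <- nrow(weather)
  if (is.null(iso) || is.null(leaf) || is.null(calendar)) {
    stop("drivers must contain weather, isotopes, leaf_diurnal and calendar")
  }
  if (nrow(iso) != n || nrow(calendar) != n || nrow(leaf) != 24 * n) {
    stop("driver series are not aligned: weather ", n, " d, isotopes ",
         nrow(iso), " d, calendar ", nrow(calendar), " d, leaf_diurnal ",
         nrow(leaf) / 24, " d")
  }
  num <- c(weather$t_av, weather$rh, weather$vp, iso$delta_precip,
           iso$delta_stem, leaf$delta, calendar$body_weight)
  if (any(!is.finite(num))) {
    stop("drivers contain non-finite values")
  }
  coeffs <- default_coefficients(config$coefficients)
  eps <- config$eps
  stoi <- coeffs$stoichiometry

  keeping <- as.character(calendar$keeping)
  pasture <- keeping == "pasture"
  day_feed <- list(
    water_content = ifelse(pasture, feed$grass$water_content,
                           feed$silage_hay$water_content),
    crude_protein = ifelse(pasture, feed$grass$crude_protein,
                           feed$silage_hay$crude_protein),
    digestibility = ifelse(pasture, feed$grass$digestibility,
                           feed$silage_hay$digestibility),
    leaf_fraction = ifelse(pasture, feed$grass$leaf_fraction,
                           feed$silage_hay$leaf_fraction),
    me_mj_per_kg_dm = ifelse(pasture, feed$grass$me_mj_per_kg_dm,
                             feed$silage_hay$me_mj_per_kg_dm)
  )

  milk <- ifelse(calendar$lactating, suckled_milk(calendar$calf_age, coeffs), 0)
  energy <- dry_matter_intake(calendar$body_weight, milk,
                              calendar$gravidity_day, day_feed, coeffs)
  drink <- drinking_water(weather$t_av, weather$t_min, weather$rh,
                          weather$precip, keeping, energy$dmi, milk,
                          calendar$body_weight, weather$soil_water, coeffs)
  resp <- respiration_fluxes(weather$t_av, weather$vp, weather$rh,
                             calendar$body_weight, coeffs)
  gas <- co2_and_products(energy, day_feed$digestibility,
                          day_feed$crude_protein, milk,
                          calendar$gravidity_day, coeffs)

  internal_kg <- energy$dmi * day_feed$water_content /
    (1 - day_feed$water_content)
  feed_water_kg <- internal_kg + drink$adhering_rain_kg + drink$dew_kg

  fluxes <- data.frame(
    m_air = air_o_uptake(energy$me, coeffs),
    m_vapor = resp$m_vapor_in,
    m_bO = gas$m_bO,
    m_fw = feed_water_kg * stoi$mol_o_per_kg_water,
    m_dw = drink$drinking_kg * stoi$mol_o_per_kg_water,
    m_co2 = gas$m_co2,
    m_oral = resp$m_oral,
    m_nasal = resp$m_nasal,
    m_cutan = transcutaneous_vapor(weather$t_av, calendar$body_weight, coeffs),
    m_milk = milk * coeffs$products$milk_water_fraction *
      stoi$mol_o_per_kg_water,
    m_products = gas$m_products,
    m_urea = gas$m_urea
  )
  for (nm in names(flux_overrides)) {
    if (!nm %in% names(fluxes)) {
      stop("unknown flux override '", nm, "'")
    }
    fluxes[[nm]] <- rep_len(flux_overrides[[nm]], n)
  }
  fluxes <- close_balances(fluxes)

  # input deltas ------------------------------------------------------------
  d_vapor <- delta_vapor_from_temperature(weather$t_av, coeffs)
  leaf_mat <- matrix(leaf$delta, nrow = n, ncol = 24, byrow = TRUE)
  leaf_ingested <- ingested_leaf_water_delta(leaf_mat, config$feeding_peaks)
  silage_d <- silage_water_delta(coeffs$silage$exposure_h, d_vapor,
                                 weather$rh, coeffs = coeffs)
  d_fw <- feed_moisture_delta(
    keeping, leaf_ingested, iso$delta_stem, day_feed$leaf_fraction,
    internal_kg, drink$adhering_rain_kg, drink$dew_kg,
    iso$delta_precip, iso$delta_stem, silage_d
  )
  d_bO <- bound_o_delta_series(keeping, leaf_ingested, iso$delta_stem, coeffs)
  deltas <- list(
    d_air = rep(coeffs$deltas$d_air, n),
    d_vapor = d_vapor,
    d_bO = d_bO,
    d_fw = d_fw,
    d_dw = iso$delta_groundwater
  )
  for (nm in names(delta_overrides)) {
    if (!nm %in% names(deltas)) {
      stop("unknown delta override '", nm, "'")
    }
    deltas[[nm]] <- rep_len(delta_overrides[[nm]], n)
  }

  # body-water recursion ----------------------------------------------------
  m_bw <- config$pool_fraction * calendar$body_weight *
    stoi$mol_o_per_kg_water
  m_in <- fluxes$m_air + fluxes$m_vapor + fluxes$m_bO + fluxes$m_fw +
    fluxes$m_dw
  d_in <- weighted_input_delta(fluxes, deltas)
  meps <- sum_flux_eps(fluxes, eps)

  d_bw <- numeric(n)
  d_prev <- d_in[1] - meps[1] / m_in[1] # day-1 steady state
  if (config$spin_up_days > 0) {
    for (k in seq_len(config$spin_up_days)) {
      d_prev <- (m_in[1] * d_in[1] + m_bw[1] * d_prev - meps[1]) /
        (m_in[1] + m_bw[1])
    }
  }
  for (i in seq_len(n)) {
    d_prev <- (m_in[i] * d_in[i] + m_bw[i] * d_prev - meps[i]) /
      (m_in[i] + m_bw[i])
    d_bw[i] <- d_prev
  }

  thi_day <- thi(weather$t_av, weather$rh)
  panting <- thi_day >= coeffs$thi$threshold
  if (any(panting)) {
    warning(sum(panting), " day(s) with THI >= ", coeffs$thi$threshold,
            ": outside the validated (non-panting) range")
  }

  out <- data.frame(
    date = weather$date,
    keeping = keeping,
    milk_kg = milk,
    dmi = energy$dmi,
    drinking_kg = drink$drinking_kg,
    thi = thi_day,
    thi_flag = panting,
    fluxes,
    d_air = deltas$d_air,
    d_vapor = deltas$d_vapor,
    d_bO = deltas$d_bO,
    d_fw = deltas$d_fw,
    d_dw = deltas$d_dw,
    d_input = d_in,
    d_bw = d_bw,
    d_co2 = d_bw + eps$eps_co2,
    d_products = d_bw + eps$eps_products,
    d_oral = d_bw + eps$eps_oral,
    d_nasal = d_bw + eps$eps_nasal,
    d_cutan = d_bw + eps$eps_cutan,
    d_urea = d_bw + eps$eps_urea,
    d_milk = d_bw,
    d_residual = d_bw,
    d_keratin = d_bw + eps$eps_keratin
  )
  attr(out, "config_hash") <- config_hash(config)
  out
}

# Bound-O (cellulose) delta series: trailing-window mixture of leaf and stem
# water plus biosynthetic enrichment on pasture days; on stall days the mean
# over the previous contiguous pasture block (previous growing season), with
# the packaged fallback when the run starts in the stall.
bound_o_delta_series <- function(keeping, leaf_delta, stem_delta, coeffs) {
  ce <- coeffs$cellulose
  n <- length(keeping)
  cell <- (1 - ce$exchange_fraction) * trailing_mean(leaf_delta, ce$window_d) +
    ce$exchange_fraction * trailing_mean(stem_delta, ce$window_d) +
    ce$enrichment
  pasture <- keeping == "pasture"
  out <- cell
  season_mean <- ce$fallback_delta
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && pasture[j + 1] == pasture[i]) j <- j + 1
    if (pasture[i]) {
      season_mean <- mean(cell[i:j])
    } else {
      out[i:j] <- season_mean
    }
    i <- j + 1
  }
  out
}
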