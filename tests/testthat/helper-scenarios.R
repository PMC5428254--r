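# Shared scenario builders used across the test files.

# Drivers with every source of day-to-day variation switched off, so the
# simulated body water must sit exactly on the closed-form steady state.
constant_drivers <- function(n = 120, seed = 1) {
  climate <- climate_params(
    t_mean = 10, t_amp = 0, t_sd = 0, t_min_sd = 0,
    rh_mean = 75, rh_amp = 0, rh_sd = 0, rain_prob = 0
  )
  iso <- isotope_params(
    seasonal_contrast = 0, t_anom_slope = 0, precip_sd = 0,
    leaf_noise_sd = 0
  )
  husb <- husbandry_params(
    grazing_start_doy = 1, grazing_end_doy = 367,
    calving_days = integer(), bw_amp = 0, bw_sd = 0
  )
  d <- gen_drivers(n, seed = seed, climate = climate, iso_params = iso,
                   husbandry = husb)
  # the soil bucket drains without rain; pin it so truly nothing varies
  d$weather$soil_water <- 50
  d
}

# Default multi-season scenario with lactation windows every 365 d.
seasonal_drivers <- function(n = 730, seed = 1) {
  gen_drivers(n, seed = seed,
              husbandry = husbandry_params(
                calving_days = seq(100, n, by = 365)
              ))
}

# Minimal simulation-shaped table for attribution tests: every flux zero
# except those supplied; deltas default to body water (zero spacing).
fake_sim <- function(n = 10, d_bw = 0, amounts = list(), deltas = list()) {
  flux_cols <- c("m_co2", "m_dw", "m_air", "m_bO", "m_cutan", "m_nasal",
                 "m_oral", "m_fw", "m_vapor", "m_products", "m_urea",
                 "m_residual_water")
  delta_cols <- c("d_co2", "d_dw", "d_air", "d_bO", "d_cutan", "d_nasal",
                  "d_oral", "d_fw", "d_vapor", "d_products", "d_urea",
                  "d_residual")
  sim <- data.frame(keeping = rep("pasture", n), d_bw = rep(d_bw, n))
  for (cl in flux_cols) sim[[cl]] <- 0
  for (cl in delta_cols) sim[[cl]] <- d_bw
  for (cl in names(amounts)) sim[[cl]] <- amounts[[cl]]
  for (cl in names(deltas)) sim[[cl]] <- deltas[[cl]]
  sim
}

# One day of balanced fluxes for recursion tests.
balanced_fluxes <- function(m_air = 450, m_vapor = 60, m_bO = 150,
                            m_fw = 1600, m_dw = 2100, m_co2 = 420,
                            m_oral = 120, m_nasal = 60, m_cutan = 220,
                            m_milk = 250, m_products = 15, m_urea = 5) {
  close_balances(data.frame(
    m_air = m_air, m_vapor = m_vapor, m_bO = m_bO, m_fw = m_fw,
    m_dw = m_dw, m_co2 = m_co2, m_oral = m_oral, m_nasal = m_nasal,
    m_cutan = m_cutan, m_milk = m_milk, m_products = m_products,
    m_urea = m_urea
  ))
}

default_deltas <- function(d_air = 15.1, d_vapor = -18, d_bO = 24,
                           d_fw = -2, d_dw = -10) {
  list(d_air = d_air, d_vapor = d_vapor, d_bO = d_bO, d_fw = d_fw,
       d_dw = d_dw)
}
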