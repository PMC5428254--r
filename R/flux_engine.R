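#' Temperature-humidity index
#'
#' THI = (1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26). Days at or above
#' the panting threshold (78) are outside the validated range of the
#' respiration and drinking sub-models and are flagged by the simulator.
#'
#' @param t_av mean daily air temperature (deg C).
#' @param rh relative humidity (%).
#' @return numeric THI.
#' @export
thi <- function(t_av, rh) {
  (1.8 * t_av + 32) - (0.55 - 0.0055 * rh) * (1.8 * t_av - 26)
}

#' Suckled milk output
#'
#' Linear decline from 10 kg/d at birth to the 5 kg/d weaning plateau at a
#' rate of 0.02 kg/d per day of calf age. `NA` calf age (no calf) gives 0.
#'
#' @param calf_age_d calf age in days (vectorized).
#' @param coeffs coefficient sets, see [default_coefficients()].
#' @return suckled milk (kg/d).
#' @examples
#' suckled_milk(c(0, 100, 250))
#' @export
suckled_milk <- function(calf_age_d, coeffs = default_coefficients()) {
  if (any(calf_age_d < 0, na.rm = TRUE)) {
    stop("calf age must be non-negative")
  }
  s <- coeffs$suckling
  out <- pmax(s$weaning_kg_per_d,
              s$birth_kg_per_d - s$decline_kg_per_d2 * calf_age_d)
  out[is.na(calf_age_d)] <- 0
  out
}

#' Metabolizable from digestible energy
#'
#' Ruminants lose a substantial share of digestible energy as methane, so
#' metabolizable energy is only 82% of digestible energy by default.
#'
#' @param de digestible energy (MJ/d).
#' @param coeffs coefficient sets.
#' @return metabolizable energy (MJ/d).
#' @examples
#' me_from_de(100)
#' @export
me_from_de <- function(de, coeffs = default_coefficients()) {
  de * coeffs$energy$me_de_ratio
}

#' Dry matter intake from the energy requirement
#'
#' The metabolizable-energy requirement is the sum of maintenance (scaling
#' with metabolic body weight BW^0.75), lactation (linear in suckled milk)
#' and gravidity (exponential in gravidity day). Dry matter intake is the
#' requirement divided by the feed's ME density; digestible energy follows
#' from the ME/DE ratio.
#'
#' @param body_weight kg (vectorized).
#' @param milk_kg suckled milk (kg/d).
#' @param gravidity_day day of gestation (0 if not pregnant).
#' @param feed one feed property set, e.g. `default_feed()$grass`.
#' @param coeffs coefficient sets.
#' @return data.frame with `dmi` (kg DM/d), `de`, `me`, `me_requirement`
#'   (MJ/d).
#' @examples
#' dry_matter_intake(600, 0, 0, default_feed()$grass)
#' @export
dry_matter_intake <- function(body_weight, milk_kg, gravidity_day,
                              feed, coeffs = default_coefficients()) {
  if (any(feed$me_mj_per_kg_dm <= 0)) {
    stop("feed ME density must be positive")
  }
  en <- coeffs$energy
  me_req <- en$maintenance_mj_per_kg075 * body_weight^0.75 +
    en$lactation_mj_per_kg_milk * milk_kg +
    ifelse(gravidity_day > 0,
           en$gravidity_a_mj * exp(en$gravidity_b_per_d * gravidity_day), 0)
  dmi <- me_req / feed$me_mj_per_kg_dm
  data.frame(
    dmi = dmi,
    de = me_req / en$me_de_ratio,
    me = me_req,
    me_requirement = me_req
  )
}

#' Drinking water intake and adhering water
#'
#' Two seasonal branches. In the stall, intake follows a linear predictor
#' in dry matter intake, milk yield, minimum temperature and relative
#' humidity, centred so the intercept is the intake of an average stall
#' day. On pasture, intake follows a linear predictor in mean temperature,
#' relative humidity, precipitation, plant-available soil water and milk
#' yield, plus 0.1 kg water per kg body weight above the reference weight.
#' The pasture branch also returns the rain intercepted by the sward and
#' the dew-rise water that the animal ingests with the herbage. Negative
#' predictions are clipped to zero with a warning.
#'
#' @param t_av,t_min,rh,precip daily weather (vectorized).
#' @param keeping "pasture" or "stall" per day.
#' @param dmi dry matter intake (kg/d).
#' @param milk_kg suckled milk (kg/d).
#' @param bw body weight (kg).
#' @param soil_water plant-available soil water (mm); required on pasture
#'   days.
#' @param coeffs coefficient sets.
#' @return data.frame with `drinking_kg`, `adhering_rain_kg`, `dew_kg`
#'   (kg water/d).
#' @export
drinking_water <- function(t_av, t_min, rh, precip, keeping, dmi, milk_kg,
                           bw, soil_water, coeffs = default_coefficients()) {
  keeping <- as.character(keeping)
  if (!all(keeping %in% c("pasture", "stall"))) {
    stop("keeping must be 'pasture' or 'stall'")
  }
  pasture <- keeping == "pasture"
  if (any(pasture & !is.finite(soil_water))) {
    stop("soil_water is required on pasture days")
  }
  st <- coeffs$drinking_stall
  pa <- coeffs$drinking_pasture

  stall_kg <- st$intercept_kg +
    st$coef_dmi * (dmi - st$center_dmi) +
    st$coef_milk * (milk_kg - st$center_milk) +
    st$coef_t_min * (t_min - st$center_t_min) +
    st$coef_rh * (rh - st$center_rh)
  past_kg <- pa$intercept_kg +
    pa$coef_t_av * (t_av - pa$center_t_av) +
    pa$coef_rh * (rh - pa$center_rh) +
    pa$coef_precip * (precip - pa$center_precip) +
    pa$coef_soil_water * (soil_water - pa$center_soil_water) +
    pa$coef_milk * (milk_kg - pa$center_milk) +
    pa$bw_slope_kg_per_kg * (bw - pa$reference_bw_kg)

  drinking <- ifelse(pasture, past_kg, stall_kg)
  if (any(drinking < 0)) {
    warning("negative drinking-water prediction clipped to 0 on ",
            sum(drinking < 0), " day(s)")
    drinking <- pmax(0, drinking)
  }

  adhering <- ifelse(
    pasture,
    pmin(pa$rain_interception_max_kg, pa$rain_interception_kg_per_mm * precip),
    0
  )
  dew <- ifelse(
    pasture,
    pa$dew_max_kg * pmax(0, (rh - pa$dew_rh_threshold) /
                           (100 - pa$dew_rh_threshold)),
    0
  )
  data.frame(drinking_kg = drinking, adhering_rain_kg = adhering,
             dew_kg = dew)
}

#' Respiratory water fluxes and inhaled vapor
#'
#' Lung ventilation follows a quadratic temperature response around a
#' thermoneutral reference (cold thermogenesis and heat-induced panting
#' both raise it), scaled by body weight. Inhaled vapor is ventilation
#' times the ambient vapor concentration; exhaled water is ventilation
#' times saturation at the exhalation temperature, which interpolates
#' between ambient and core temperature. The respiratory water output is
#' split exactly 2/3 oral and 1/3 nasal. The temperature relation is
#' validated for -12 to +40 deg C; outside, a warning is issued and the
#' relation extrapolated.
#'
#' @param t_av air temperature (deg C, vectorized).
#' @param vp ambient vapor pressure (hPa).
#' @param rh relative humidity (%); > 100 is an error.
#' @param bw body weight (kg).
#' @param coeffs coefficient sets.
#' @return data.frame with `m_oral`, `m_nasal`, `m_vapor_in` (mol O/d).
#' @export
respiration_fluxes <- function(t_av, vp, rh, bw,
                               coeffs = default_coefficients()) {
  if (any(rh > 100)) {
    stop("relative humidity above 100%")
  }
  re <- coeffs$respiration
  if (any(t_av < re$t_valid_min_c | t_av > re$t_valid_max_c)) {
    warning("air temperature outside the validated range [",
            re$t_valid_min_c, ", ", re$t_valid_max_c,
            "] deg C; extrapolating the ventilation relation")
  }
  dt <- t_av - re$t_ref
  vent <- re$vent_ref_m3_per_d * (bw / re$reference_bw_kg) *
    pmax(re$vent_min_fraction,
         1 + re$t_lin_per_c * dt + re$t_quad_per_c2 * dt^2)

  mol_per_kg <- coeffs$stoichiometry$mol_o_per_kg_water
  rv <- 461.5 # J/(kg K), water vapor gas constant
  rho_in <- vp * 100 / (rv * (t_av + 273.15)) # kg/m^3
  t_ex <- pmin(re$exhale_t_max_c,
               pmax(re$exhale_t_min_c, re$exhale_t0_c + re$exhale_t_slope * t_av))
  rho_ex <- saturation_vp(t_ex) * 100 / (rv * (t_ex + 273.15))

  m_vapor_in <- vent * rho_in * mol_per_kg
  m_resp <- vent * rho_ex * mol_per_kg
  data.frame(
    m_oral = re$oral_fraction * m_resp,
    m_nasal = (1 - re$oral_fraction) * m_resp,
    m_vapor_in = m_vapor_in
  )
}

#' Transcutaneous vapor flux
#'
#' Skin surface area from a Meeh-type allometry (`area_coef * BW^area_exp`)
#' and a cutaneous latent-heat flux rising exponentially with air
#' temperature, converted to water by the latent heat of vaporization.
#'
#' @param t_av air temperature (deg C, vectorized).
#' @param bw body weight (kg).
#' @param coeffs coefficient sets.
#' @return transcutaneous water loss (mol O/d).
#' @examples
#' transcutaneous_vapor(20, 600)
#' @export
transcutaneous_vapor <- function(t_av, bw, coeffs = default_coefficients()) {
  tc <- coeffs$transcutaneous
  stopifnot(all(bw > 0))
  area <- tc$area_coef * bw^tc$area_exp # m^2
  e_flux <- tc$e0_w_per_m2 * exp(tc$t_scale_per_c * t_av) # W/m^2
  kg <- e_flux * area * 86400 / (tc$latent_heat_mj_per_kg * 1e6)
  kg * coeffs$stoichiometry$mol_o_per_kg_water
}

#' Air O uptake
#'
#' O2 consumption from the metabolizable energy turned over, at the energy
#' equivalent of oxygen; counted as mol O atoms (2 per O2).
#'
#' @param me metabolizable energy (MJ/d).
#' @param coeffs coefficient sets.
#' @return air O uptake (mol O/d).
#' @export
air_o_uptake <- function(me, coeffs = default_coefficients()) {
  2 * coeffs$stoichiometry$mol_o2_per_mj * me
}

#' CO2, organic products, bound feed O and urea
#'
#' Bound O is dry matter intake times digestibility times the effective O
#' density of digestible dry matter. CO2 (counted as 2 mol O per mol CO2)
#' comes from the oxidation of the digested matter at the ruminant energy
#' extraction factor, minus the O diverted into organic products (milk
#' solids and fetal growth). Urea O follows from the crude-protein N
#' balance.
#'
#' @param energy energy budget (list or data.frame with `dmi`, `me`), see
#'   [dry_matter_intake()].
#' @param digestibility fraction of DM digested (in `[0, 1]`).
#' @param crude_protein crude protein fraction of DM.
#' @param milk_kg suckled milk (kg/d).
#' @param gravidity_day day of gestation (0 if open).
#' @param coeffs coefficient sets.
#' @return data.frame with `m_co2`, `m_products`, `m_bO`, `m_urea`
#'   (mol O/d).
#' @export
co2_and_products <- function(energy, digestibility, crude_protein, milk_kg,
                             gravidity_day, coeffs = default_coefficients()) {
  if (any(digestibility < 0 | digestibility > 1)) {
    stop("digestibility must lie in [0, 1]")
  }
  st <- coeffs$stoichiometry
  pr <- coeffs$products
  ur <- coeffs$urea

  m_bO <- energy$dmi * digestibility * st$bound_o_mol_per_kg_dm

  p_milk <- milk_kg * pr$milk_solids_fraction * pr$solids_o_mass_fraction /
    pr$kg_per_mol_o
  p_fetal <- ifelse(gravidity_day > 0,
                    pr$fetal_a_kg_per_d * exp(pr$fetal_b_per_d * gravidity_day) *
                      pr$fetal_o_mass_fraction / pr$kg_per_mol_o, 0)
  m_products <- p_milk + p_fetal

  n_excreted <- energy$dmi * crude_protein * digestibility *
    ur$n_per_crude_protein * (1 - ur$n_retention_fraction)
  m_urea <- n_excreted / ur$kg_n_per_mol_n / 2 # 2 N, 1 O per urea

  m_co2 <- pmax(0, st$mol_o_per_mol_co2 * st$respiratory_quotient *
                  st$mol_o2_per_mj * energy$me - m_products)

  data.frame(m_co2 = m_co2, m_products = m_products, m_bO = m_bO,
             m_urea = m_urea)
}

#' Close the water and oxygen mass balances
#'
#' Metabolic water O is the O entering with air and bound feed O that is
#' not exported as CO2, products or urea; it joins vapor, feed moisture and
#' drinking water as a water input. The residual water flux (fecal, urinary
#' and sweat water considered together) is set to the difference between
#' total water input and all other water losses, which closes the water
#' balance exactly and makes the oxygen balance close identically. A
#' negative residual (other losses exceeding intake) is a hard error naming
#' the dominating loss, since it signals inconsistent drivers.
#'
#' @param fluxes data.frame with columns `m_air`, `m_vapor`, `m_bO`,
#'   `m_fw`, `m_dw`, `m_co2`, `m_oral`, `m_nasal`, `m_cutan`, `m_milk`,
#'   `m_products`, `m_urea` (mol O/d).
#' @return the input with `m_metabolic` and `m_residual_water` added; the
#'   relative O-balance residual is checked to be below 1e-9.
#' @export
close_balances <- function(fluxes) {
  need <- c("m_air", "m_vapor", "m_bO", "m_fw", "m_dw", "m_co2", "m_oral",
            "m_nasal", "m_cutan", "m_milk", "m_products", "m_urea")
  missing <- setdiff(need, names(fluxes))
  if (length(missing)) {
    stop("missing flux columns: ", paste(missing, collapse = ", "))
  }
  m_metabolic <- fluxes$m_air + fluxes$m_bO - fluxes$m_co2 -
    fluxes$m_products - fluxes$m_urea
  if (any(m_metabolic < 0)) {
    stop("negative metabolic water: gas-side O exports exceed air + bound O")
  }
  water_in <- fluxes$m_vapor + fluxes$m_fw + fluxes$m_dw + m_metabolic
  other_losses <- fluxes$m_oral + fluxes$m_nasal + fluxes$m_cutan +
    fluxes$m_milk
  residual <- water_in - other_losses
  if (any(residual < 0)) {
    i <- which.min(residual)
    losses <- c(oral = fluxes$m_oral[i], nasal = fluxes$m_nasal[i],
                cutan = fluxes$m_cutan[i], milk = fluxes$m_milk[i])
    stop("water losses exceed intake on day ", i, "; dominating flux: ",
         names(which.max(losses)))
  }
  fluxes$m_metabolic <- m_metabolic
  fluxes$m_residual_water <- residual

  s_in <- fluxes$m_air + fluxes$m_vapor + fluxes$m_bO + fluxes$m_fw +
    fluxes$m_dw
  s_out <- fluxes$m_co2 + fluxes$m_oral + fluxes$m_nasal + fluxes$m_cutan +
    fluxes$m_milk + fluxes$m_products + fluxes$m_urea +
    fluxes$m_residual_water
  stopifnot(all(abs(s_in - s_out) / s_in <= 1e-9))
  fluxes
}
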