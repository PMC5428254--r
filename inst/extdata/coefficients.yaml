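# Default sub-model coefficient sets for the daily oxygen mass balance.
# Each set carries a `provenance` string describing where its parametric
# form and default values come from.  All can be overridden from a run
# config (see load_config()).
stoichiometry:
  provenance: >-
    Molar bookkeeping: 1 kg water = 55.51 mol O; 1 mol CO2 = 2 mol O;
    O2 consumption from heat production at 20.1 kJ per L O2 (22.414 L/mol);
    ruminant respiratory quotient below 1 so metabolic water O is always
    non-negative; bound O as effective O content of digestible dry matter.
  mol_o_per_kg_water: 55.51
  mol_o_per_mol_co2: 2
  mol_o2_per_mj: 2.2197
  respiratory_quotient: 0.95
  bound_o_mol_per_kg_dm: 20
energy:
  provenance: >-
    Metabolizable-energy requirement of a suckler cow: maintenance scaling
    with metabolic body weight (MJ ME per kg^0.75), linear lactation term
    per kg suckled milk, exponential gravidity term rising toward term;
    ME/DE ratio 0.82 reflecting ruminant methane losses.
  maintenance_mj_per_kg075: 0.53
  lactation_mj_per_kg_milk: 5.3
  gravidity_a_mj: 0.2
  gravidity_b_per_d: 0.02
  me_de_ratio: 0.82
suckling:
  provenance: >-
    Linear decline of suckled milk from 10 kg/d at birth to a 5 kg/d
    weaning plateau at 0.02 kg/d per day of calf age.
  birth_kg_per_d: 10
  decline_kg_per_d2: 0.02
  weaning_kg_per_d: 5
drinking_stall:
  provenance: >-
    Stall (winter) drinking-water intake: linear predictor in dry matter
    intake, milk yield, minimum temperature and relative humidity,
    re-centred so the intercept is the intake of an average stall day.
  intercept_kg: 45
  center_dmi: 11
  center_milk: 5
  center_t_min: 2
  center_rh: 80
  coef_dmi: 1.6
  coef_milk: 1.2
  coef_t_min: 0.5
  coef_rh: -0.1
drinking_pasture:
  provenance: >-
    Grazing drinking-water intake: linear predictor in mean temperature,
    relative humidity, precipitation, plant-available soil water and milk
    yield, re-centred on an average grazing day, plus 0.1 kg water per kg
    body weight above the reference weight; also yields intercepted rain
    and dew-rise water adhering to the grazed herbage.
  intercept_kg: 35
  center_t_av: 15
  center_rh: 75
  center_precip: 2
  center_soil_water: 50
  center_milk: 5
  coef_t_av: 1.0
  coef_rh: -0.15
  coef_precip: -0.3
  coef_soil_water: -0.08
  coef_milk: 1.2
  bw_slope_kg_per_kg: 0.1
  reference_bw_kg: 600
  rain_interception_kg_per_mm: 0.3
  rain_interception_max_kg: 3
  dew_max_kg: 1.2
  dew_rh_threshold: 70
respiration:
  provenance: >-
    Lung ventilation with a quadratic temperature response around a
    thermoneutral reference (rising ventilation in both cold thermogenesis
    and heat-induced panting), scaled by body weight; exhaled air saturated
    at an exhalation temperature interpolating between ambient and core;
    valid for ambient temperature -12..+40 C; respiratory water split
    exactly 2/3 oral and 1/3 nasal.
  vent_ref_m3_per_d: 140
  reference_bw_kg: 600
  t_ref: 15
  t_lin_per_c: 0.01
  t_quad_per_c2: 0.0015
  vent_min_fraction: 0.5
  exhale_t0_c: 20
  exhale_t_slope: 0.33
  exhale_t_min_c: 15
  exhale_t_max_c: 38.6
  oral_fraction: 0.66666666666666663
  t_valid_min_c: -12
  t_valid_max_c: 40
transcutaneous:
  provenance: >-
    Transcutaneous vapor: skin surface area from a Meeh-type allometry
    (A = 0.14 BW^0.57 m^2) and a cutaneous latent-heat flux rising
    exponentially with air temperature; converted to water via the latent
    heat of vaporization.
  area_coef: 0.14
  area_exp: 0.57
  e0_w_per_m2: 8
  t_scale_per_c: 0.085
  latent_heat_mj_per_kg: 2.43
products:
  provenance: >-
    O exported in organic products: milk solids at a fixed solids fraction
    and O mass fraction, plus fetal growth rising exponentially with
    gravidity day; milk water fraction used for the milk water flux.
  milk_solids_fraction: 0.125
  milk_water_fraction: 0.87
  solids_o_mass_fraction: 0.30
  fetal_a_kg_per_d: 0.02
  fetal_b_per_d: 0.012
  fetal_o_mass_fraction: 0.30
  kg_per_mol_o: 0.016
urea:
  provenance: >-
    Urea O from the crude-protein nitrogen balance: digestible N not
    retained in products is excreted as urea (2 N and 1 O per molecule).
  n_per_crude_protein: 0.16
  n_retention_fraction: 0.2
  kg_n_per_mol_n: 0.014
silage:
  provenance: >-
    Silage/hay water delta-18O: first-order relaxation of the initial
    (soil-equilibrated) value toward an ambient evaporative equilibrium
    built from vapor delta, an equilibrium enrichment and a kinetic term
    growing with the saturation deficit; default 24 h air exposure.
  initial_delta: -11
  rate_per_h: 0.02
  eps_equilibrium: 9.8
  kinetic_coef: 15
  exposure_h: 24
cellulose:
  provenance: >-
    Chemically bound feed O approximated by cellulose synthesised from a
    mixture of trailing-mean leaf and stem water over the preceding 30 d
    with a biosynthetic enrichment of +27; stall value is the mean over the
    previous growing season.
  enrichment: 27
  exchange_fraction: 0.4
  window_d: 30
  fallback_delta: 24
deltas:
  provenance: >-
    Constant delta-18O of air O utilized in the lungs (15.1, includes
    pulmonary uptake fractionation) and the site regression of vapor
    delta-18O on mean daily temperature (0.34 T - 21.52).
  d_air: 15.1
  vapor_slope: 0.34
  vapor_intercept: -21.52
thi:
  provenance: >-
    Temperature-humidity index THI = (1.8 T + 32) - (0.55 - 0.0055 RH)
    (1.8 T - 26); 78 is the panting threshold for cattle, beyond which the
    respiration and drinking sub-models are outside their validated range.
  threshold: 78
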