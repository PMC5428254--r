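#' Relative isoflux contributions
#'
#' An isoflux is a flux amount weighted by its isotopic distance from body
#' water, `M_j * |d_bw - d_j|`; it measures the leverage of flux j on the
#' body-water delta. The relative contribution of each flux is its isoflux
#' summed over the period, normalized across all fluxes, times 100.
#' Unfractionated output fluxes (fecal/urinary/sweat residual, milk, and
#' urea at its default zero offset) leave at body-water delta and
#' contribute zero.
#'
#' @param sim daily simulation table from [simulate_body_water()].
#' @param periods optional named list of logical day masks; defaults to
#'   whole year plus the grazing and stall seasons from the `keeping`
#'   column.
#' @return data.frame with `flux`, `period`, `contribution` (%); within
#'   each period the contributions sum to 100 before rounding.
#' @export
isoflux_contributions <- function(sim, periods = NULL) {
  if (is.null(periods)) {
    periods <- list(
      whole_year = rep(TRUE, nrow(sim)),
      grazing = sim$keeping == "pasture",
      stall = sim$keeping == "stall"
    )
  }
  fluxes <- list(
    co2 = c("m_co2", "d_co2"),
    drinking_water = c("m_dw", "d_dw"),
    air_o = c("m_air", "d_air"),
    bound_o = c("m_bO", "d_bO"),
    transcutaneous = c("m_cutan", "d_cutan"),
    nasal = c("m_nasal", "d_nasal"),
    oral = c("m_oral", "d_oral"),
    feed_moisture = c("m_fw", "d_fw"),
    air_vapor = c("m_vapor", "d_vapor"),
    products = c("m_products", "d_products"),
    urea = c("m_urea", "d_urea"),
    unfractionated = c("m_residual_water", "d_residual")
  )
  out <- list()
  for (p in names(periods)) {
    mask <- periods[[p]]
    if (!any(mask)) {
      next
    }
    iso <- vapply(fluxes, function(f) {
      sum(sim[[f[1]]][mask] * abs(sim$d_bw[mask] - sim[[f[2]]][mask]))
    }, numeric(1))
    tot <- sum(iso)
    if (tot <= 0) {
      stop("all isofluxes are zero in period '", p, "'")
    }
    out[[p]] <- data.frame(
      flux = names(fluxes), period = p,
      contribution = 100 * iso / tot, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Hold-constant variance experiment
#'
#' Re-runs the simulation with one factor's daily series replaced by its
#' long-term mean and reports the change in the SD of the daily keratin
#' delta relative to the full model, per period. The variance that
#' disappears when a factor is flattened measures how much of the seasonal
#' hair signal that factor generates.
#'
#' Factors: any weather or isotope driver column (`t_av`, `t_min`, `rh`,
#' `vp`, `precip`, `soil_water`, `delta_precip`, `delta_stem`), the
#' composite `ambient` (temperature, humidity and vapor pressure acting on
#' the animal, with the feed-side deltas pinned to their full-model
#' series), `leaf_water` (the leaf diurnal series), `feed_internal_water`
#' (delta of ingested feed moisture), `drinking_water` (the intake
#' amount), or `all` (every driver flattened; the residual SD is zero).
#'
#' @param drivers driver bundle, see [simulate_body_water()].
#' @param factor factor name, see Details.
#' @param feed,config forwarded to the simulator.
#' @return data.frame with `factor`, `period`, `sd_full`, `sd_held`,
#'   `sd_change` (per mil; positive = the factor generated variance).
#' @export
hold_constant_experiment <- function(drivers, factor,
                                     feed = default_feed(),
                                     config = run_config()) {
  full <- simulate_body_water(drivers, feed, config)
  held_drivers <- drivers
  delta_overrides <- list()
  flux_overrides <- list()

  flatten <- function(df, cols) {
    for (cl in cols) df[[cl]] <- mean(df[[cl]])
    df
  }
  weather_cols <- c("t_av", "t_min", "rh", "vp", "precip", "soil_water")
  iso_cols <- c("delta_precip", "delta_stem")

  if (factor %in% weather_cols) {
    held_drivers$weather <- flatten(held_drivers$weather, factor)
  } else if (factor %in% iso_cols) {
    held_drivers$isotopes <- flatten(held_drivers$isotopes, factor)
  } else if (factor == "leaf_water") {
    held_drivers$leaf_diurnal$delta <- mean(held_drivers$leaf_diurnal$delta)
  } else if (factor == "feed_internal_water") {
    delta_overrides$d_fw <- mean(full$d_fw)
  } else if (factor == "drinking_water") {
    flux_overrides$m_dw <- mean(full$m_dw)
  } else if (factor == "ambient") {
    held_drivers$weather <- flatten(held_drivers$weather, weather_cols)
    # feed path unchanged: pin feed-side deltas to the full-model series
    delta_overrides$d_fw <- full$d_fw
    delta_overrides$d_bO <- full$d_bO
  } else if (factor == "all") {
    held_drivers$weather <- flatten(held_drivers$weather, weather_cols)
    held_drivers$isotopes <- flatten(held_drivers$isotopes, iso_cols)
    held_drivers$leaf_diurnal$delta <- mean(held_drivers$leaf_diurnal$delta)
    cal <- held_drivers$calendar
    cal$keeping <- names(which.max(table(cal$keeping)))
    cal$lactating <- FALSE
    cal$calf_age <- NA_real_
    cal$gravidity_day <- 0L
    cal$body_weight <- mean(cal$body_weight)
    held_drivers$calendar <- cal
  } else {
    stop("unknown factor '", factor, "'")
  }

  held <- simulate_body_water(held_drivers, feed, config,
                              delta_overrides = delta_overrides,
                              flux_overrides = flux_overrides)
  periods <- list(
    whole_year = rep(TRUE, nrow(full)),
    grazing = full$keeping == "pasture",
    stall = full$keeping == "stall"
  )
  rows <- lapply(names(periods), function(p) {
    mask <- periods[[p]]
    if (sum(mask) < 2) {
      return(NULL)
    }
    sd_full <- stats::sd(full$d_keratin[mask])
    sd_held <- stats::sd(held$d_keratin[mask])
    data.frame(factor = factor, period = p, sd_full = sd_full,
               sd_held = sd_held, sd_change = sd_full - sd_held)
  })
  do.call(rbind, rows)
}

#' Summary statistics between two aligned series
#'
#' RMSE, mean difference, paired t-test p-value, and the least-squares
#' regression of `b` on `a` (slope, intercept, R^2).
#'
#' @param a,b numeric series of equal length (>= 3).
#' @return list with `rmse`, `mean_diff` (mean of b - a), `paired_t_p`,
#'   `slope`, `intercept`, `r2`.
#' @examples
#' summary_stats(1:10, 1:10 + 2)
#' @export
summary_stats <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("series must have equal length >= 3")
  }
  d <- b - a
  rmse <- sqrt(mean(d^2))
  mean_diff <- mean(d)
  paired_t_p <- if (stats::sd(d) == 0) {
    NA_real_
  } else {
    stats::t.test(b, a, paired = TRUE)$p.value
  }
  if (stats::sd(a) == 0) {
    stop("degenerate predictor variance for the regression")
  }
  fit <- stats::lm(b ~ a)
  list(
    rmse = rmse,
    mean_diff = mean_diff,
    paired_t_p = paired_t_p,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared
  )
}
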