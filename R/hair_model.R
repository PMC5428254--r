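#' Keratin delta-18O from body water
#'
#' Hair keratin forms from body water with a constant fractionation offset
#' (prior 15 per mil; values fitted from segment series are typically near
#' 14).
#'
#' @param d_bw body-water delta-18O (per mil, vectorized).
#' @param eps_keratin body water - keratin fractionation (per mil).
#' @return keratin delta-18O (per mil).
#' @examples
#' keratin_delta(-3.6, 14)
#' @export
keratin_delta <- function(d_bw, eps_keratin = default_eps()$eps_keratin) {
  d_bw + eps_keratin
}

#' Assign growth periods to hair segments
#'
#' With a constant growth rate, a segment of length L cm corresponds to
#' `10 * L / rate` days (13.2 d for 1 cm at 0.76 mm/d). Segment 1 is the
#' newest (root side); positions increase away from the root, so older
#' segments carry earlier periods. Segments tile the hair without gaps.
#'
#' @param collection_day day index (or date) of hair collection.
#' @param n_segments number of 1-cm segments (>= 1).
#' @param rate_mm_per_d hair growth rate (default 0.76 mm/d).
#' @param segment_length_cm segment length (default 1 cm).
#' @return data.frame with `segment` (1 = root), `position_cm`,
#'   `start_day`, `end_day` (half-open `[start, end)`, `end_day` of
#'   segment 1 equal to the collection day).
#' @examples
#' assign_segment_periods(100, 3)
#' @export
assign_segment_periods <- function(collection_day, n_segments,
                                   rate_mm_per_d = 0.76,
                                   segment_length_cm = 1) {
  if (rate_mm_per_d <= 0) {
    stop("growth rate must be positive")
  }
  if (n_segments < 1) {
    stop("need at least one segment")
  }
  dur <- 10 * segment_length_cm / rate_mm_per_d
  k <- seq_len(n_segments)
  data.frame(
    segment = k,
    position_cm = (k - 1) * segment_length_cm,
    start_day = as.numeric(collection_day) - k * dur,
    end_day = as.numeric(collection_day) - (k - 1) * dur
  )
}

#' Aggregate a daily keratin series to hair segments
#'
#' Each segment's delta is the unweighted mean of the daily keratin deltas
#' over its growth period (days whose index falls in `[start, end)`).
#'
#' @param daily_deltas daily keratin delta series.
#' @param days day indices of `daily_deltas` (default `1:length`).
#' @param periods data.frame from [assign_segment_periods()].
#' @return `periods` with a `delta` column added.
#' @export
aggregate_to_segments <- function(daily_deltas, periods,
                                  days = seq_along(daily_deltas)) {
  if (any(periods$start_day < min(days) - 1 |
            periods$end_day > max(days) + 1)) {
    stop("a segment period falls outside the daily series")
  }
  periods$delta <- vapply(seq_len(nrow(periods)), function(i) {
    sel <- days >= periods$start_day[i] & days < periods$end_day[i]
    if (!any(sel)) {
      stop("segment ", i, " covers no days of the series")
    }
    mean(daily_deltas[sel])
  }, numeric(1))
  periods
}

#' Align two delta series by RMSE-minimizing lag
#'
#' Successive hairs overlap in the periods they record; the offset between
#' them is recovered by sliding one series against the other and taking
#' the lag that minimizes the RMSE over the overlap (statistical pattern
#' matching). Ties are broken toward the smallest absolute lag. A positive
#' lag means `series_b` is `series_a` delayed by that many steps.
#'
#' @param series_a,series_b numeric series on a common step (days).
#' @param max_lag maximum absolute lag searched.
#' @param min_overlap smallest admissible overlap length.
#' @return integer lag.
#' @examples
#' a <- sin(1:50 / 5)
#' match_series_offset(a, c(rep(NA, 3), a)[1:50], max_lag = 10)
#' @export
match_series_offset <- function(series_a, series_b, max_lag,
                                min_overlap = 5) {
  lags <- -max_lag:max_lag
  rmse <- rep(NA_real_, length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    ia <- seq_along(series_a)
    ib <- ia + lag
    keep <- ib >= 1 & ib <= length(series_b)
    a <- series_a[ia[keep]]
    b <- series_b[ib[keep]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= min_overlap) {
      rmse[k] <- sqrt(mean((a[ok] - b[ok])^2))
    }
  }
  if (all(is.na(rmse))) {
    stop("no admissible overlap at any lag within +/-", max_lag)
  }
  best <- which(rmse <= min(rmse, na.rm = TRUE) + 1e-12)
  lags[best[which.min(abs(lags[best]))]]
}

#' Fit the body water - keratin fractionation
#'
#' With a constant offset model the RMSE-minimizing epsilon is the mean
#' residual between measured segment deltas and the segment-aggregated
#' body-water deltas (closed form). Segments from different hairs covering
#' the same period should be averaged per period first (see
#' `average_segments_per_period`).
#'
#' @param measured_deltas measured segment deltas (per mil).
#' @param modeled_d_bw daily modeled body-water delta series.
#' @param periods data.frame from [assign_segment_periods()] dating the
#'   measured segments on the day axis of `modeled_d_bw`.
#' @param days day indices of `modeled_d_bw`.
#' @return fitted epsilon (per mil).
#' @export
fit_keratin_fractionation <- function(measured_deltas, modeled_d_bw, periods,
                                      days = seq_along(modeled_d_bw)) {
  if (length(measured_deltas) < 2) {
    stop("need at least two segments to fit the fractionation")
  }
  if (length(measured_deltas) != nrow(periods)) {
    stop("one period per measured segment required")
  }
  agg <- aggregate_to_segments(modeled_d_bw, periods, days)
  mean(measured_deltas - agg$delta)
}

#' Average replicate hair segments per growth period
#'
#' Two to three segments from different hairs typically cover the same
#' growth period; they are averaged per period before fitting.
#'
#' @param segments data.frame with `start_day`, `end_day`, `delta` (and
#'   optionally `hair_id`).
#' @return data.frame with one row per distinct period, deltas averaged.
#' @export
average_segments_per_period <- function(segments) {
  key <- paste(segments$start_day, segments$end_day)
  agg <- stats::aggregate(segments$delta, by = list(key = key), FUN = mean)
  first <- !duplicated(key)
  out <- segments[first, c("start_day", "end_day"), drop = FALSE]
  out$delta <- agg$x[match(paste(out$start_day, out$end_day), agg$key)]
  out[order(out$start_day), , drop = FALSE]
}
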