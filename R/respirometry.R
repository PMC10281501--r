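#' Convert oxygen saturation to oxygen concentration
#'
#' Intermittent-flow respirometry systems report dissolved oxygen as percent
#' air saturation. Concentration (mgO2 L^-1) is obtained as
#' `saturation/100 * alpha_o2 * bp_mmHg`, where `alpha_o2` is the
#' temperature-corrected oxygen solubility coefficient (mgO2 L^-1 mmHg^-1)
#' and `bp_mmHg` the barometric pressure.
#'
#' @param saturation_pct Percent air saturation (0--110).
#' @param alpha_o2 Oxygen solubility coefficient, mgO2 L^-1 mmHg^-1. Must be
#'   positive. See [o2_solubility()].
#' @param bp_mmHg Barometric pressure in mmHg. Must be positive.
#' @return Oxygen concentration in mgO2 L^-1, same length as
#'   `saturation_pct`.
#' @seealso [fit_period_slope()], [mo2_from_slope()]
#' @export
#' @examples
#' o2_concentration(87.5, 0.0563, 760)
o2_concentration <- function(saturation_pct, alpha_o2, bp_mmHg) {
  if (any(!is.finite(alpha_o2)) || any(alpha_o2 <= 0)) {
    abort("`alpha_o2` must be positive and finite.", class = "aeroscope_invalid_physics")
  }
  if (any(!is.finite(bp_mmHg)) || any(bp_mmHg <= 0)) {
    abort("`bp_mmHg` must be positive and finite.", class = "aeroscope_invalid_physics")
  }
  saturation_pct / 100 * alpha_o2 * bp_mmHg
}

#' Oxygen solubility coefficient in fresh water
#'
#' Benson--Krause fit for the air-saturation concentration of dissolved
#' oxygen in fresh water at 1 atm, divided by 760 mmHg to give the solubility
#' coefficient used by [o2_concentration()]. Used by the synthetic trace
#' generator to place saturation traces on a physically sensible scale.
#'
#' @param temp_C Water temperature, degrees Celsius.
#' @return Solubility coefficient, mgO2 L^-1 mmHg^-1.
#' @export
o2_solubility <- function(temp_C) {
  tk <- temp_C + 273.15
  do_sat <- exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
                  1.2438e10 / tk^3 - 8.621949e11 / tk^4)
  do_sat / 760
}

#' Least-squares oxygen depletion slope for one sealed period
#'
#' Regresses oxygen concentration on time over the samples falling inside a
#' sealed measurement period. The slope (mgO2 L^-1 s^-1) is signed: negative
#' values indicate depletion by the fish; positive slopes indicate anomalous
#' oxygen gain and are preserved so QC can see them.
#'
#' @param samples Data frame with columns `time_s` and `saturation_pct`,
#'   sampled roughly once per second.
#' @param start_s,end_s Period boundaries in seconds (inclusive).
#' @param alpha_o2,bp_mmHg Passed to [o2_concentration()].
#' @param min_samples Minimum samples required inside the period.
#' @return One-row tibble: `start_s`, `end_s`, `slope_mgO2_L_s`, `r_squared`,
#'   `min_saturation_pct`, `n_samples`. A zero-variance (flat) trace reports
#'   `r_squared = 0` so it deterministically fails any linearity filter.
#' @export
fit_period_slope <- function(samples, start_s, end_s, alpha_o2, bp_mmHg,
                             min_samples = 30) {
  stopifnot(is.data.frame(samples))
  keep <- samples$time_s >= start_s & samples$time_s <= end_s
  t <- samples$time_s[keep]
  sat <- samples$saturation_pct[keep]
  if (length(t) < min_samples) {
    abort(
      sprintf("Period [%s, %s] contains %d samples; at least %d required.",
              start_s, end_s, length(t), min_samples),
      class = "aeroscope_insufficient_data"
    )
  }
  conc <- o2_concentration(sat, alpha_o2, bp_mmHg)
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  slope <- sum(tc * conc) / sxx
  fitted <- mean(conc) + slope * tc
  sst <- sum((conc - mean(conc))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum((conc - fitted)^2) / sst
  tibble(
    start_s = start_s, end_s = end_s,
    slope_mgO2_L_s = slope,
    r_squared = max(0, min(1, r2)),
    min_saturation_pct = min(sat),
    n_samples = length(t)
  )
}

#' Convert a depletion slope to mass-specific metabolic rate
#'
#' MO2 = |R| x V / M x 60, where R is the concentration slope
#' (mgO2 L^-1 s^-1), V the sealed respirometer volume (L), M the fish mass
#' (kg) and 60 converts from per second to per minute.
#'
#' @param slope_mgO2_L_s Signed concentration slope from
#'   [fit_period_slope()].
#' @param volume_L Respirometer volume, litres.
#' @param mass_kg Fish mass, kilograms.
#' @param gain_tolerance Positive slopes larger than this trigger a QC
#'   warning (the value is still computed from the magnitude).
#' @return MO2 in mgO2 kg^-1 min^-1 (vectorised).
#' @export
mo2_from_slope <- function(slope_mgO2_L_s, volume_L, mass_kg,
                           gain_tolerance = 1e-8) {
  if (any(volume_L <= 0) || any(mass_kg <= 0)) {
    abort("`volume_L` and `mass_kg` must be positive.",
          class = "aeroscope_invalid_physics")
  }
  if (any(slope_mgO2_L_s > gain_tolerance)) {
    warn("Positive (oxygen-gain) slope encountered; MO2 computed from magnitude.",
         class = "aeroscope_gain_slope")
  }
  abs(slope_mgO2_L_s) * volume_L / mass_kg * 60
}

#' Routine metabolic rate from per-period MO2 values
#'
#' RMR is the mean of the three lowest per-period MO2 values after removing
#' periods during which the fish was seen swimming. Ties in the "three
#' lowest" are broken by earliest period start time so the selection is
#' deterministic.
#'
#' @param mo2_values Numeric vector of per-period MO2 values.
#' @param activity_flags Logical vector, `TRUE` if the fish was active during
#'   the period (excluded before selection).
#' @param start_s Optional period start times used only for tie-breaking.
#' @return List with `rmr` (mean of three lowest retained values), `n_used`
#'   (always 3) and `idx_used` (indices into `mo2_values`).
#' @export
extract_rmr <- function(mo2_values, activity_flags = rep(FALSE, length(mo2_values)),
                        start_s = seq_along(mo2_values)) {
  stopifnot(length(activity_flags) == length(mo2_values),
            length(start_s) == length(mo2_values))
  keep <- which(!activity_flags & is.finite(mo2_values))
  if (length(keep) < 3) {
    abort(
      sprintf("Only %d usable periods after activity exclusion; 3 required.",
              length(keep)),
      class = "aeroscope_insufficient_periods"
    )
  }
  ord <- keep[order(mo2_values[keep], start_s[keep])]
  idx <- ord[1:3]
  list(rmr = mean(mo2_values[idx]), n_used = 3L, idx_used = idx)
}

#' Maximum metabolic rate via an exhaustive sliding-window scan
#'
#' MMR is the highest metabolic rate sustained over a minimum window length
#' (default 300 s) during swimming. Every contiguous sub-window of at least
#' `min_window_s` within each sealed swim period is refit by least squares
#' (scan step one sample) and the steepest depletion wins.
#'
#' @param samples Data frame with `time_s`, `saturation_pct`.
#' @param periods Data frame of sealed swim periods with `start_s`, `end_s`.
#' @param alpha_o2,bp_mmHg Passed to [o2_concentration()].
#' @param volume_L,mass_kg Passed to [mo2_from_slope()].
#' @param min_window_s Minimum window duration in seconds.
#' @return List: `mmr` (mgO2 kg^-1 min^-1), `window` (one-row tibble with the
#'   winning window's period bounds, start/end, slope and duration).
#' @export
extract_mmr <- function(samples, periods, alpha_o2, bp_mmHg,
                        volume_L, mass_kg, min_window_s = 300) {
  stopifnot(is.data.frame(periods), nrow(periods) >= 0)
  best <- NULL
  for (p in seq_len(nrow(periods))) {
    keep <- samples$time_s >= periods$start_s[p] & samples$time_s <= periods$end_s[p]
    t <- samples$time_s[keep]
    conc <- o2_concentration(samples$saturation_pct[keep], alpha_o2, bp_mmHg)
    n <- length(t)
    if (n < 2 || (t[n] - t[1]) < min_window_s) next
    # prefix sums give O(1) least-squares slopes for any contiguous window
    ct <- cumsum(t); ct2 <- cumsum(t^2); cc <- cumsum(conc); ctc <- cumsum(t * conc)
    psum <- function(cs, i, j) cs[j] - c(0, cs)[i]
    for (L in seq_len(n)) {
      i <- seq_len(n - L + 1)
      j <- i + L - 1
      dur <- t[j] - t[i]
      ok <- dur >= min_window_s
      if (!any(ok)) next
      i <- i[ok]; j <- j[ok]
      nn <- L
      st <- psum(ct, i, j); st2 <- psum(ct2, i, j)
      sc <- psum(cc, i, j); stc <- psum(ctc, i, j)
      sxx <- st2 - st^2 / nn
      slopes <- (stc - st * sc / nn) / sxx
      w <- which.min(slopes)  # steepest depletion
      if (is.null(best) || slopes[w] < best$slope) {
        best <- list(slope = slopes[w], win_start = t[i[w]], win_end = t[j[w]],
                     period_start = periods$start_s[p], period_end = periods$end_s[p])
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf("No sealed swim window of >= %g s available.", min_window_s),
          class = "aeroscope_no_mmr_window")
  }
  mmr <- suppressWarnings(mo2_from_slope(best$slope, volume_L, mass_kg))
  list(
    mmr = mmr,
    window = tibble(
      period_start_s = best$period_start, period_end_s = best$period_end,
      window_start_s = best$win_start, window_end_s = best$win_end,
      duration_s = best$win_end - best$win_start,
      slope_mgO2_L_s = best$slope
    )
  )
}

#' Aerobic scope
#'
#' The difference between maximum and routine metabolic rate. A negative
#' result (MMR below RMR) is returned as-is with a warning rather than
#' silently clipped, so downstream QC can act on it.
#'
#' @param rmr,mmr Metabolic rates in mgO2 kg^-1 min^-1.
#' @return `mmr - rmr` (vectorised).
#' @export
aerobic_scope <- function(rmr, mmr) {
  stopifnot(all(is.finite(rmr)), all(is.finite(mmr)))
  if (any(mmr < rmr)) {
    warn("MMR below RMR for at least one fish; negative aerobic scope returned.",
         class = "aeroscope_negative_scope")
  }
  mmr - rmr
}

#' Fulton's condition factor
#'
#' K = 100 * mass (g) / fork length (cm)^3. Invariant to isometric scaling.
#'
#' @param mass_g Wet mass in grams.
#' @param fork_length_cm Fork length in centimetres.
#' @return Condition factor (vectorised).
#' @export
fulton_k <- function(mass_g, fork_length_cm) {
  if (any(mass_g <= 0) || any(fork_length_cm <= 0)) {
    abort("Mass and fork length must be positive.", class = "aeroscope_invalid_input")
  }
  100 * mass_g / fork_length_cm^3
}

#' Quality-control filter for per-fish metabolic results
#'
#' Drops fish that died during the trial or recovery, fish that were active
#' during the periods used for RMR, and fish whose used sealed periods let
#' oxygen saturation fall below the floor (default 80%). Every exclusion is
#' logged with a reason code; retained + excluded always partitions the
#' input.
#'
#' @param results Tibble from [process_respirometry()] (one row per fish,
#'   with a `qc_flags` list-column).
#' @param saturation_floor Minimum allowed saturation (%) on used periods.
#' @return List with `retained` (clean rows) and `exclusions` (tibble of
#'   `fish_id`, `reason`).
#' @export
qc_filter <- function(results, saturation_floor = 80) {
  reasons <- purrr::map(seq_len(nrow(results)), function(i) {
    fl <- results$qc_flags[[i]]
    out <- character()
    if ("mortality" %in% fl) out <- c(out, "mortality")
    if ("activity_excluded" %in% fl) out <- c(out, "activity_excluded")
    if ("low_r2" %in% fl) out <- c(out, "low_r2")
    if (is.finite(results$min_saturation_used[i]) &&
        results$min_saturation_used[i] < saturation_floor) {
      out <- c(out, "saturation_floor")
    }
    if (!is.finite(results$rmr[i]) || !is.finite(results$mmr[i])) {
      out <- c(out, "incomplete")
    }
    out
  })
  drop <- purrr::map_lgl(reasons, ~ length(.x) > 0)
  exclusions <- tibble(
    fish_id = rep(results$fish_id, purrr::map_int(reasons, length)),
    reason = unlist(reasons)
  )
  list(retained = results[!drop, , drop = FALSE], exclusions = exclusions)
}

#' Process respirometry traces into per-fish metabolic results
#'
#' The full trace-to-trait chain for a batch of fish: per-period least-squares
#' depletion slopes, a programmatic linearity filter (r-squared threshold
#' standing in for visual inspection), conversion to MO2, routine metabolic
#' rate as the mean of the three lowest periods, maximum metabolic rate from
#' an exhaustive >= 5 min window scan over the swim phase, and aerobic scope
#' as their difference. QC flags are accumulated per fish; use [qc_filter()]
#' to split retained fish from the exclusion log.
#'
#' @param samples Long tibble of trace samples: `fish_id`, `time_s`,
#'   `saturation_pct`.
#' @param phases Tibble of phase annotations: `fish_id`, `start_s`, `end_s`,
#'   `kind` ("sealed"/"flush"), `context` ("routine"/"swim"), `activity`
#'   (logical; fish seen swimming during a routine period).
#' @param meta Tibble of fish metadata: `fish_id`, `test_temp_C`,
#'   `acclim_temp_C`, `population`, `tunnel_id`, `tunnel_volume_L`,
#'   `fish_mass_kg`, `barometric_pressure_mmHg`, `alpha_o2`, `survived`
#'   (logical).
#' @param r2_threshold Periods with r-squared below this are dropped before
#'   RMR/MMR selection (default 0.90).
#' @param min_window_s Minimum MMR window duration, seconds.
#' @return Tibble with one row per fish: identifiers, `rmr`, `mmr`,
#'   `aerobic_scope`, `n_periods_used`, `min_saturation_used`, `qc_flags`
#'   (list-column of character codes).
#' @export
process_respirometry <- function(samples, phases, meta,
                                 r2_threshold = 0.90, min_window_s = 300) {
  validate_respirometry_inputs(samples, phases, meta)
  rows <- purrr::map(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    s <- samples[samples$fish_id == m$fish_id, , drop = FALSE]
    ph <- phases[phases$fish_id == m$fish_id, , drop = FALSE]
    flags <- character()
    if (!isTRUE(m$survived)) flags <- c(flags, "mortality")

    routine <- ph[ph$kind == "sealed" & ph$context == "routine", , drop = FALSE]
    fits <- purrr::map(seq_len(nrow(routine)), function(p) {
      fit_period_slope(s, routine$start_s[p], routine$end_s[p],
                       m$alpha_o2, m$barometric_pressure_mmHg)
    }) %>% purrr::list_rbind()
    fits$activity <- routine$activity
    linear <- fits[fits$r_squared >= r2_threshold, , drop = FALSE]
    if (nrow(linear) < nrow(fits)) flags <- c(flags, "low_r2_periods_dropped")

    rmr <- NA_real_; n_used <- NA_integer_; min_sat_used <- NA_real_
    if (nrow(linear) > 0) {
      mo2 <- suppressWarnings(
        mo2_from_slope(linear$slope_mgO2_L_s, m$tunnel_volume_L, m$fish_mass_kg))
      res <- tryCatch(
        extract_rmr(mo2, linear$activity, linear$start_s),
        aeroscope_insufficient_periods = function(e) NULL
      )
      if (is.null(res)) {
        flags <- c(flags, if (any(linear$activity)) "activity_excluded" else "low_r2")
      } else {
        rmr <- res$rmr; n_used <- res$n_used
        min_sat_used <- min(linear$min_saturation_pct[res$idx_used])
      }
    } else {
      flags <- c(flags, "low_r2")
    }

    swim <- ph[ph$kind == "sealed" & ph$context == "swim", , drop = FALSE]
    mmr <- NA_real_
    if (nrow(swim) > 0) {
      mm <- tryCatch(
        extract_mmr(s, swim, m$alpha_o2, m$barometric_pressure_mmHg,
                    m$tunnel_volume_L, m$fish_mass_kg, min_window_s),
        aeroscope_no_mmr_window = function(e) NULL
      )
      if (is.null(mm)) {
        flags <- c(flags, "no_mmr_window")
      } else {
        mmr <- mm$mmr
        win_sat <- min(s$saturation_pct[s$time_s >= mm$window$period_start_s &
                                          s$time_s <= mm$window$period_end_s])
        min_sat_used <- suppressWarnings(min(min_sat_used, win_sat, na.rm = TRUE))
      }
    } else {
      flags <- c(flags, "no_mmr_window")
    }

    as_val <- if (is.finite(rmr) && is.finite(mmr)) {
      suppressWarnings(aerobic_scope(rmr, mmr))
    } else NA_real_

    tibble(
      fish_id = m$fish_id, population = m$population,
      acclim_temp_C = m$acclim_temp_C, test_temp_C = m$test_temp_C,
      fish_mass_kg = m$fish_mass_kg,
      rmr = rmr, mmr = mmr, aerobic_scope = as_val,
      n_periods_used = n_used,
      min_saturation_used = if (is.finite(min_sat_used)) min_sat_used else NA_real_,
      qc_flags = list(flags)
    )
  })
  purrr::list_rbind(rows)
}

validate_respirometry_inputs <- function(samples, phases, meta) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("%s is missing columns: %s", what, paste(miss, collapse = ", ")),
            class = "aeroscope_schema_error")
    }
  }
  need(samples, c("fish_id", "time_s", "saturation_pct"), "`samples`")
  need(phases, c("fish_id", "start_s", "end_s", "kind", "context"), "`phases`")
  need(meta, c("fish_id", "tunnel_volume_L", "fish_mass_kg",
               "barometric_pressure_mmHg", "alpha_o2"), "`meta`")
  bad <- samples$saturation_pct < 0 | samples$saturation_pct > 110
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("%d sample(s) have saturation outside [0, 110]%%.", sum(bad)),
          class = "aeroscope_schema_error")
  }
  invisible(TRUE)
}
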