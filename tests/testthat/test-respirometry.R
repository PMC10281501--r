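test_that("oxygen concentration follows the saturation-solubility-pressure product", {
  expect_equal(o2_concentration(0, 0.05, 760), 0)
  expect_equal(o2_concentration(100, 0.0563, 755), 0.0563 * 755)
  # frozen arithmetic: 0.875 * 0.0563 * 760
  expect_equal(o2_concentration(87.5, 0.0563, 760), 37.4395, tolerance = 1e-10)
  expect_error(o2_concentration(50, -0.01, 760), class = "aeroscope_invalid_physics")
  expect_error(o2_concentration(50, 0.05, 0), class = "aeroscope_invalid_physics")
})

test_that("oxygen concentration is linear in each argument", {
  set.seed(42)
  for (i in 1:20) {
    s <- runif(1, 1, 100); a <- runif(1, 0.01, 0.1); p <- runif(1, 600, 800)
    k <- runif(1, 0.5, 3)
    base <- o2_concentration(s, a, p)
    expect_equal(o2_concentration(k * s, a, p), k * base)
    expect_equal(o2_concentration(s, k * a, p), k * base)
    expect_equal(o2_concentration(s, a, k * p), k * base)
  }
})

test_that("period slope fitting matches the closed-form least-squares oracle", {
  t <- 0:899
  # noiseless line
  sat <- 100 - 0.002 * t
  df <- tibble::tibble(time_s = t, saturation_pct = sat)
  fit <- fit_period_slope(df, 0, 899, alpha_o2 = 0.05, bp_mmHg = 760)
  expect_equal(fit$slope_mgO2_L_s, -0.002 * 0.05 * 760 / 100, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$min_saturation_pct, min(sat))

  # flat trace: zero slope, r-squared reported as 0, not NaN
  flat <- tibble::tibble(time_s = t, saturation_pct = rep(95, length(t)))
  ffit <- fit_period_slope(flat, 0, 899, 0.05, 760)
  expect_equal(ffit$slope_mgO2_L_s, 0)
  expect_equal(ffit$r_squared, 0)

  # Gaussian noise: independent normal-equations oracle
  set.seed(7)
  noisy <- 100 - 0.0015 * t + rnorm(length(t), 0, 0.1)
  ndf <- tibble::tibble(time_s = t, saturation_pct = noisy)
  nfit <- fit_period_slope(ndf, 0, 899, 0.04, 750)
  conc <- noisy / 100 * 0.04 * 750
  oracle <- sum((t - mean(t)) * (conc - mean(conc))) / sum((t - mean(t))^2)
  expect_equal(nfit$slope_mgO2_L_s, oracle, tolerance = 1e-10)

  expect_error(fit_period_slope(df, 0, 10, 0.05, 760),
               class = "aeroscope_insufficient_data")
})

test_that("MO2 conversion applies volume, inverse mass and per-minute scaling", {
  expect_equal(mo2_from_slope(0, 5, 0.025), 0)
  # 0.002 * 5 / 0.025 * 60
  expect_equal(mo2_from_slope(-0.002, 5, 0.025), 24)
  expect_equal(mo2_from_slope(-0.002, 10, 0.025), 2 * 24)
  expect_warning(mo2_from_slope(0.001, 5, 0.025), class = "aeroscope_gain_slope")
  expect_equal(suppressWarnings(mo2_from_slope(0.001, 5, 0.025)),
               mo2_from_slope(-0.001, 5, 0.025))
  expect_error(mo2_from_slope(-0.002, 0, 0.025), class = "aeroscope_invalid_physics")
})

test_that("RMR is the mean of the three lowest retained periods", {
  expect_equal(extract_rmr(c(5, 4, 3, 2, 1))$rmr, 2)
  expect_equal(extract_rmr(rep(3.3, 6))$rmr, 3.3)

  # brute-force oracle over the retained set
  set.seed(11)
  vals <- runif(10, 1, 8)
  flags <- rep(FALSE, 10); flags[c(3, 7)] <- TRUE
  oracle <- mean(sort(vals[!flags])[1:3])
  expect_equal(extract_rmr(vals, flags)$rmr, oracle)

  # ties broken by earliest start time
  tied <- c(2, 2, 2, 2, 5)
  res <- extract_rmr(tied, start_s = c(50, 40, 30, 20, 10))
  expect_equal(sort(res$idx_used), c(2, 3, 4))

  expect_error(extract_rmr(c(1, 2, 3), activity_flags = c(TRUE, FALSE, FALSE)),
               class = "aeroscope_insufficient_periods")
})

test_that("MMR window scan equals the exhaustive brute-force oracle", {
  # piecewise-linear depletion with the steepest segment mid-period
  t <- 0:239
  rate <- c(rep(0.01, 80), rep(0.05, 80), rep(0.02, 80))
  sat <- 100 - cumsum(rate)
  samples <- tibble::tibble(time_s = t, saturation_pct = sat)
  periods <- tibble::tibble(start_s = 0, end_s = 239)
  got <- extract_mmr(samples, periods, alpha_o2 = 0.05, bp_mmHg = 760,
                     volume_L = 5, mass_kg = 0.025, min_window_s = 60)

  # independent oracle: plain loop over every window of >= 60 s
  conc <- sat / 100 * 0.05 * 760
  best <- Inf
  for (i in seq_along(t)) {
    for (j in seq_along(t)) {
      if (t[j] - t[i] < 60) next
      tt <- t[i:j]; cc <- conc[i:j]
      sl <- sum((tt - mean(tt)) * (cc - mean(cc))) / sum((tt - mean(tt))^2)
      if (sl < best) best <- sl
    }
  }
  expect_equal(got$window$slope_mgO2_L_s, best, tolerance = 1e-12)
  expect_equal(got$mmr, abs(best) * 5 / 0.025 * 60, tolerance = 1e-12)
  # steepest window falls inside the fast-depletion segment
  expect_gte(got$window$window_start_s, 60)
  expect_lte(got$window$window_end_s, 180)

  # constant depletion: window MO2 equals the whole-period MO2
  sat2 <- 100 - 0.02 * t
  got2 <- extract_mmr(tibble::tibble(time_s = t, saturation_pct = sat2),
                      periods, 0.05, 760, 5, 0.025, min_window_s = 60)
  expect_equal(got2$mmr, 0.02 / 100 * 0.05 * 760 * 5 / 0.025 * 60,
               tolerance = 1e-9)

  # two periods, second steeper: value comes from the second
  t2 <- 300:539
  sat3 <- 100 - 0.04 * (t2 - 300)
  both <- dplyr::bind_rows(tibble::tibble(time_s = t, saturation_pct = sat2),
                           tibble::tibble(time_s = t2, saturation_pct = sat3))
  got3 <- extract_mmr(both, tibble::tibble(start_s = c(0, 300), end_s = c(239, 539)),
                      0.05, 760, 5, 0.025, min_window_s = 60)
  expect_equal(got3$window$period_start_s, 300)

  expect_error(
    extract_mmr(samples, tibble::tibble(start_s = 0, end_s = 30),
                0.05, 760, 5, 0.025, min_window_s = 300),
    class = "aeroscope_no_mmr_window"
  )
})

test_that("aerobic scope is MMR minus RMR and negative values are flagged", {
  expect_equal(aerobic_scope(2, 10), 8)
  expect_equal(aerobic_scope(4.2, 4.2), 0)
  expect_warning(out <- aerobic_scope(5, 3), class = "aeroscope_negative_scope")
  expect_equal(out, -2)
  # magnitudes like the warm-acclimated treatments round-trip exactly
  expect_equal(2.4 + aerobic_scope(2.4, 2.4 + 8.9), 2.4 + 8.9)
})

test_that("Fulton's condition factor uses the cubic-length convention", {
  expect_equal(fulton_k(10, 10), 1)
  expect_equal(fulton_k(23.03, 12.4), 100 * 23.03 / 12.4^3, tolerance = 1e-12)
  expect_equal(fulton_k(8 * 5, 2 * 3), fulton_k(5, 3))  # isometric scaling
  expect_error(fulton_k(-1, 10), class = "aeroscope_invalid_input")
})

test_that("QC filter drops mortality, activity and saturation-floor violations", {
  mk <- function(id, flags = character(), minsat = 95, rmr = 2, mmr = 10) {
    tibble::tibble(fish_id = id, rmr = rmr, mmr = mmr,
                   aerobic_scope = mmr - rmr, n_periods_used = 3L,
                   min_saturation_used = minsat, qc_flags = list(flags))
  }
  results <- dplyr::bind_rows(
    mk("f1"), mk("f2"), mk("f3"), mk("f4"), mk("f5"), mk("f6"), mk("f7"),
    mk("f8", flags = "mortality"),
    mk("f9", flags = "activity_excluded"),
    mk("f10", minsat = 79.9)
  )
  out <- qc_filter(results)
  expect_equal(nrow(out$retained), 7)
  expect_setequal(out$exclusions$fish_id, c("f8", "f9", "f10"))
  expect_true("saturation_floor" %in% out$exclusions$reason)

  clean <- dplyr::bind_rows(mk("a"), mk("b"))
  expect_equal(qc_filter(clean)$retained, clean)
  # boundary: exactly at the floor is retained
  expect_equal(nrow(qc_filter(mk("c", minsat = 80))$retained), 1)
})

test_that("trace processing recovers generating RMR and MMR exactly at zero noise", {
  inp <- one_fish_inputs(target_rmr = 2.5, target_mmr = 11, sat_noise_sd = 0)
  res <- process_respirometry(inp$samples, inp$phases, inp$meta)
  expect_lt(abs(res$rmr - 2.5) / 2.5, 1e-6)
  expect_lt(abs(res$mmr - 11) / 11, 1e-6)
  expect_equal(res$aerobic_scope + res$rmr, res$mmr)
  expect_equal(res$qc_flags[[1]], character(0))
  expect_equal(res$n_periods_used, 3L)
})

test_that("activity-flagged periods are excluded from RMR selection", {
  # activity periods have inflated MO2; with them flagged the RMR is clean
  inp <- one_fish_inputs(target_rmr = 2.0, target_mmr = 9, sat_noise_sd = 0,
                         activity_periods = c(1, 2))
  res <- process_respirometry(inp$samples, inp$phases, inp$meta)
  expect_lt(abs(res$rmr - 2.0) / 2.0, 1e-6)
})

test_that("per-period r-squared approaches 1 as noise vanishes", {
  r2_at <- function(noise, seed = 3) {
    tr <- generate_o2_trace(2.5, 11, 16, 0.024, cohort_config(), seed = seed,
                            sat_noise_sd = noise, n_routine = 2, n_swim = 1)
    p <- tr$phases[tr$phases$kind == "sealed" & tr$phases$context == "routine", ][1, ]
    fit_period_slope(tr$samples, p$start_s, p$end_s, 0.05, 760)$r_squared
  }
  r2 <- vapply(c(0.3, 0.05, 0.005, 0), r2_at, numeric(1))
  expect_true(all(diff(r2) >= 0))
  expect_equal(r2[4], 1)
  expect_gt(r2[3], 0.999)
})

test_that("schema validation names the offending columns and ranges", {
  inp <- one_fish_inputs()
  bad_samples <- inp$samples
  bad_samples$saturation_pct[5] <- 150
  expect_error(process_respirometry(bad_samples, inp$phases, inp$meta),
               class = "aeroscope_schema_error")
  expect_error(process_respirometry(inp$samples[, "time_s"], inp$phases, inp$meta),
               class = "aeroscope_schema_error")
})
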