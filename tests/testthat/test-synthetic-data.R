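test_that("the default cohort reproduces the study design structure", {
  truth <- synthetic_truth()
  cohort <- generate_cohort(cohort_config(), truth, 61)
  treatments <- dplyr::distinct(cohort, population, acclim)
  expect_equal(nrow(treatments), 18)
  expect_equal(length(unique(cohort$population)), 6)

  # bit-reproducible under a fixed seed
  expect_identical(cohort, generate_cohort(cohort_config(), truth, 61))
  expect_false(identical(cohort, generate_cohort(cohort_config(), truth, 62)))

  # degenerate size distribution
  all_equal <- generate_cohort(cohort_config(mass_sd_g = 0), truth, 63)
  expect_equal(sd(all_equal$mass_g), 0)
})

test_that("growth data follow treatment-level lines with mean-preserving noise", {
  cfg <- cohort_config()
  zero <- synthetic_truth(growth_log_sd = 1e-12)
  g0 <- generate_growth_data(zero, cfg, 64)
  expect_equal(nrow(g0), 6 * 3 * 30 * 4)
  one <- g0[g0$population == "Coleman" & g0$acclim == 20, ]
  fitted <- lm(mass_g ~ time_days, one)
  truth_row <- zero$growth[zero$growth$population == "Coleman" &
                             zero$growth$acclim == 20, ]
  expect_equal(unname(coef(fitted)[2]), truth_row$slope_g_day, tolerance = 1e-6)
  expect_lt(sigma(fitted), 1e-6)

  # noisy data: OLS slope within 3 standard errors of the generating slope
  truth <- synthetic_truth()
  g <- generate_growth_data(truth, cfg, 65)
  bad <- 0
  for (pop in unique(g$population)) {
    for (acc in unique(g$acclim)) {
      sub <- g[g$population == pop & g$acclim == acc, ]
      f <- lm(mass_g ~ time_days, sub)
      slope_true <- truth$growth$slope_g_day[truth$growth$population == pop &
                                               truth$growth$acclim == acc]
      se <- summary(f)$coefficients[2, 2]
      if (abs(coef(f)[2] - slope_true) > 3 * se) bad <- bad + 1
    }
  }
  expect_lte(bad, 2)  # 18 treatments, 3-SE exceedances should be rare
})

test_that("CT_max ramps heat at the configured constant rate", {
  truth <- synthetic_truth()
  out <- generate_ctmax_trials(truth, cohort_config(ctmax_n = 3), 66)
  slopes <- out$series %>%
    dplyr::filter(phase == "ramp") %>%
    dplyr::group_by(fish_id) %>%
    dplyr::summarise(slope = coef(lm(temp_C ~ time_min))[2], .groups = "drop")
  expect_equal(mean(slopes$slope), 0.33, tolerance = 0.005)
  expect_true(all(abs(slopes$slope - 0.33) < 0.02))

  # ramp starts at the acclimation temperature after the hold
  hold <- out$series %>% dplyr::filter(phase == "hold")
  joined <- dplyr::left_join(hold, out$trials[, c("fish_id", "acclim")], "fish_id")
  expect_true(all(abs(joined$temp_C - joined$acclim) < 0.2))
})

test_that("loss-of-equilibrium temperatures follow the treatment truth", {
  zero <- synthetic_truth()
  zero$ctmax$sd_C <- 0
  out0 <- generate_ctmax_trials(zero, cohort_config(ctmax_n = 4), 67)
  j <- dplyr::left_join(out0$trials,
                        dplyr::mutate(zero$ctmax, acclim = acclim), c("population", "acclim"))
  expect_equal(j$loe_temp_C, j$mean_C, tolerance = 1e-9)

  # CLT check at larger n
  truth <- synthetic_truth()
  out <- generate_ctmax_trials(truth, cohort_config(ctmax_n = 60), 68)
  cole <- out$trials[out$trials$population == "Coleman" & out$trials$acclim == 16, ]
  mu <- truth$ctmax$mean_C[truth$ctmax$population == "Coleman" &
                             truth$ctmax$acclim == 16]
  s <- truth$ctmax$sd_C[truth$ctmax$population == "Coleman" &
                          truth$ctmax$acclim == 16]
  expect_lt(abs(mean(cole$loe_temp_C) - mu), 3 * s / sqrt(nrow(cole)))

  # roughly the configured non-recovery fraction
  expect_lt(abs(mean(!out$trials$recovered) - 0.06), 0.03)
})

test_that("noisy saturation traces recover RMR within 5% on average", {
  errs <- numeric(20)
  for (r in 1:20) {
    inp <- one_fish_inputs(target_rmr = 2.5, target_mmr = 11,
                           sat_noise_sd = 0.3, seed = 200 + r)
    res <- process_respirometry(inp$samples, inp$phases, inp$meta,
                                r2_threshold = 0.5)
    errs[r] <- (res$rmr - 2.5) / 2.5
  }
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(max(abs(errs)), 0.15)
})

test_that("an injected steeper swim segment captures the MMR window", {
  inp <- one_fish_inputs(target_rmr = 2, target_mmr = 12, sat_noise_sd = 0)
  res <- process_respirometry(inp$samples, inp$phases, inp$meta)
  # the steepest window must land in the final (fastest) swim step
  swim <- inp$phases[inp$phases$kind == "sealed" & inp$phases$context == "swim", ]
  last <- swim[which.max(swim$start_s), ]
  mm <- extract_mmr(inp$samples, swim, inp$meta$alpha_o2,
                    inp$meta$barometric_pressure_mmHg,
                    inp$meta$tunnel_volume_L, inp$meta$fish_mass_kg)
  expect_equal(mm$window$period_start_s, last$start_s)
  expect_lt(abs(res$mmr - 12) / 12, 1e-6)
})

test_that("the generator shortens periods that would breach the floor", {
  # a huge metabolic rate cannot deplete below the floor
  tr <- generate_o2_trace(40, 80, 16, 0.03, cohort_config(), seed = 69,
                          sat_noise_sd = 0)
  expect_gt(nrow(tr$shortened), 0)
  expect_gt(min(tr$samples$saturation_pct), 79)
})

test_that("the bundled predictor table carries the published geography", {
  tab <- generate_env_table("published")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$`Mig.D`[tab$population == "Coleman"], 441)
  expect_equal(tab$`Mig.D`[tab$population == "Trask River"], 28)
  expect_equal(tab$`Mig.D`[tab$population == "Priest Rapids"], 631)
  expect_equal(tab$Latitude[tab$population == "Feather River"], 39.519)
  # range columns are max minus min by construction
  expect_equal(tab$CARange, tab$CAMax - tab$CAMin)
  expect_equal(tab$HARange, tab$HAMax - tab$HAMin)
  expect_equal(names(tab)[-1], env_predictor_names())
})

test_that("random predictor tables realise the requested collinearity", {
  cors <- purrr::map_dbl(1:30, function(s) {
    tab <- generate_env_table("random", seed = s, target_cor = 0.9)
    cor(tab$CAMax, tab$CRMax)
  })
  expect_lt(abs(mean(abs(cors)) - 0.9), 0.15)
  t2 <- generate_env_table("random", seed = 3)
  expect_equal(t2$CARange, t2$CAMax - t2$CAMin)
})

test_that("environmental effect injection shifts only the targeted truth", {
  truth <- synthetic_truth()
  tab <- generate_env_table("published")
  expect_identical(inject_env_effect(truth, tab, "ctmax", "CRCMax", 0), truth)
  shifted <- inject_env_effect(truth, tab, "ctmax", "CRCMax", 0.5)
  cfg <- cohort_config(ctmax_n = 200)
  base <- generate_ctmax_trials(truth, cfg, 70)$trials
  inj <- generate_ctmax_trials(shifted, cfg, 70)$trials
  by_pop <- dplyr::inner_join(
    base %>% dplyr::group_by(population) %>% dplyr::summarise(m0 = mean(loe_temp_C)),
    inj %>% dplyr::group_by(population) %>% dplyr::summarise(m1 = mean(loe_temp_C)),
    by = "population")
  z <- (tab$CRCMax - mean(tab$CRCMax)) / sd(tab$CRCMax)
  expected <- 0.5 * z[match(by_pop$population, tab$population)]
  expect_lt(max(abs((by_pop$m1 - by_pop$m0) - expected)), 0.12)

  expect_error(inject_env_effect(truth, tab, "ctmax", "Nope", 1),
               class = "aeroscope_invalid_input")
  expect_error(inject_env_effect(truth, tab, "height", "CRCMax", 1),
               class = "aeroscope_invalid_input")
})

test_that("the full trace-to-optimum round trip recovers the generating optima", {
  truth <- synthetic_truth()
  cfg <- pipeline_config(
    seed = 881,
    cohort = cohort_config(populations = c("Coleman", "Elk River", "Trask River"),
                           resp_n = 12),
    control = sampler_control(chains = 2, warmup = 300, iter = 1000),
    topt_draws = 300, respirometry_mode = "traces"
  )
  res <- run_pipeline(cfg, truth = truth, stages = c("metabolic", "topt"))
  est <- res$topt$estimates
  j <- dplyr::inner_join(
    est, dplyr::mutate(truth$metabolic, acclim = as.character(acclim)),
    by = c("population", "acclim"))
  expect_equal(nrow(j), 9)
  errs <- j$topt_C.x - j$topt_C.y
  # the estimator is calibrated, not super-efficient: the treatment-averaged
  # error stays within half a degree and each cell within its own posterior
  expect_lt(abs(mean(errs)), 0.5)
  expect_true(all(abs(errs) < 4 * j$sd_C + 0.5))
})

test_that("emitted tables pass the pipeline's input validation", {
  truth <- synthetic_truth()
  cfg <- small_config()
  expect_silent(validate_inputs(
    growth = generate_growth_data(truth, cfg, 71),
    ctmax = generate_ctmax_trials(truth, cfg, 72)$trials,
    metabolic = generate_metabolic_data(truth, cfg, 73)
  ))
})
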