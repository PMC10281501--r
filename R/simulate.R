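#' Ground truth for the synthetic study
#'
#' Builds the parameter set the generators draw from: per-treatment growth
#' slopes (g/day), critical-thermal-maximum means and SDs, routine metabolic
#' rate exponential coefficients (reference rate at 16 C and Q10),
#' aerobic-scope quadratic coefficients (peak scope, thermal optimum,
#' curvature), implied maximum-metabolic-rate log2 coefficients, observation
#' noise SDs, and (initially zero) environmental-effect coefficients.
#' Default magnitudes are seeded from the published treatment summaries
#' ([published_table()]) so synthetic output is visually comparable to the
#' study's figures; they are an emulation, not data.
#'
#' @param as_curvature Quadratic coefficient of the aerobic-scope curve
#'   (mgO2 kg^-1 min^-1 per C^2; must be negative).
#' @param sat_noise_sd Sensor noise SD on percent saturation.
#' @param growth_log_sd SD of Gaussian noise on log mass.
#' @param rmr_log_sd,mmr_sd Observation noise for the model-scale metabolic
#'   generator (log units and mgO2 kg^-1 min^-1).
#' @param min_as Floor on aerobic scope used when the quadratic dips low at
#'   extreme test temperatures (keeps MMR above RMR).
#' @return A list of class `synthetic_truth` with elements `growth`,
#'   `ctmax`, `metabolic` (per-treatment tibbles), `noise`, `env_effects`.
#' @export
synthetic_truth <- function(as_curvature = -0.025, sat_noise_sd = 0.05,
                            growth_log_sd = 0.18, rmr_log_sd = 0.08,
                            mmr_sd = 0.5, min_as = 0.8) {
  stopifnot(as_curvature < 0, sat_noise_sd >= 0)
  growth <- published_table("growth") %>%
    mutate(slope_g_day = .data$growth_g_day, intercept_g = 7.9) %>%
    select("population", acclim = "acclim_C", "time_days",
           "slope_g_day", "intercept_g")
  ctmax <- published_table("ctmax") %>%
    mutate(mean_C = .data$modeled_mean_C, sd_C = .data$observed_sd) %>%
    select("population", acclim = "acclim_C", "mean_C", "sd_C")
  met <- published_table("metabolic") %>%
    mutate(
      rmr_ref_16 = 2.4,                       # mgO2 kg^-1 min^-1 at 16 C
      rmr_b = log(.data$rmr_q10) / 10,        # exponential temperature slope
      as_max = .data$as_at_topt,
      topt_C = .data$topt_C,
      as_a = as_curvature
    ) %>%
    select("population", acclim = "acclim_C", "rmr_ref_16", "rmr_b",
           "as_max", "topt_C", "as_a")
  # implied MMR = RMR + AS projected onto a + b log2(T) over the tested range
  grid <- seq(8, 26, by = 0.5)
  proj <- purrr::pmap(
    list(met$rmr_ref_16, met$rmr_b, met$as_max, met$topt_C, met$as_a),
    function(r16, b, amax, topt, a) {
      mmr <- r16 * exp(b * (grid - 16)) + pmax(amax + a * (grid - topt)^2, min_as)
      cf <- coef(lm(mmr ~ log2(grid)))
      tibble(mmr_log2_int = cf[[1]], mmr_log2_slope = cf[[2]])
    }) %>% purrr::list_rbind()
  met <- dplyr::bind_cols(met, proj)
  structure(
    list(growth = growth, ctmax = ctmax, metabolic = met,
         noise = list(sat_sd = sat_noise_sd, growth_log_sd = growth_log_sd,
                      rmr_log_sd = rmr_log_sd, mmr_sd = mmr_sd),
         min_as = min_as,
         env_effects = tibble(target = character(), predictor = character(),
                              beta = numeric())),
    class = "synthetic_truth"
  )
}

#' Study design configuration for the synthetic cohort
#'
#' Defaults emulate the study design: six populations crossed with three
#' acclimation temperatures (18 treatment groups), two rearing tanks per
#' treatment, 30 growth measurements per treatment per biweekly date,
#' 18--25 CT_max fish and 32--46 respirometry fish per treatment spread over
#' acute test temperatures 8--26 C.
#'
#' @param populations Population names (default the six studied hatcheries).
#' @param acclim_temps Acclimation temperatures, C.
#' @param tanks_per_treatment Rearing tanks per treatment group.
#' @param growth_n_per_date Fish measured per treatment per sampling date.
#' @param n_dates,date_spacing_days Biweekly sampling schedule.
#' @param ctmax_n Fish per treatment in the CT_max assay.
#' @param resp_n Fish per treatment in respirometry trials.
#' @param test_temps Acute test temperature menu, C.
#' @param mass_mean_g,mass_sd_g Fish size distribution at testing.
#' @param tunnel_volume_L,bp_mmHg Respirometer volume and barometric
#'   pressure.
#' @param ramp_rate_C_min CT_max heating rate.
#' @param nonrecovery_rate Fraction of CT_max fish failing 24-h recovery.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(populations = published_table("populations")$population,
                          acclim_temps = c(11, 16, 20),
                          tanks_per_treatment = 2,
                          growth_n_per_date = 30,
                          n_dates = 4, date_spacing_days = 14,
                          ctmax_n = 20, resp_n = 36,
                          test_temps = c(8, 10, 12, 14, 16, 18, 20, 22, 24, 25, 26),
                          mass_mean_g = 23, mass_sd_g = 4,
                          tunnel_volume_L = 5, bp_mmHg = 760,
                          ramp_rate_C_min = 0.33,
                          nonrecovery_rate = 0.06) {
  stopifnot(growth_n_per_date > 0, ctmax_n > 0, resp_n > 0,
            all(test_temps >= 8 & test_temps <= 26))
  structure(as.list(environment()), class = "cohort_config")
}

env_shift <- function(truth, target, population) {
  # population-level truth shift injected by inject_env_effect()
  eff <- truth$env_effects[truth$env_effects$target == target, , drop = FALSE]
  if (!nrow(eff)) return(0)
  sum(purrr::map_dbl(seq_len(nrow(eff)), function(i) {
    z <- eff$pred_z[[i]]
    eff$beta[i] * z[[population]]
  }))
}

#' Generate the base fish cohort
#'
#' One row per fish per assay stream (CT_max and respirometry share the
#' size distribution), with tank assignment, mass, fork length (from a
#' condition factor near 1.2) and age. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param truth A [synthetic_truth()].
#' @param seed Integer seed.
#' @return Tibble of treatments (`population`, `acclim`, `tank`) expanded to
#'   fish with `fish_id`, `mass_g`, `fork_length_cm`, `age_dph`.
#' @export
generate_cohort <- function(config, truth, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  treatments <- crossing(population = config$populations,
                         acclim = config$acclim_temps)
  n <- config$resp_n
  fish <- treatments %>%
    mutate(fish = purrr::map2(.data$population, .data$acclim, function(p, a) {
      mass <- pmax(rnorm(n, config$mass_mean_g, config$mass_sd_g), 5)
      k <- rnorm(n, 1.2, 0.06)
      tibble(
        tank = rep_len(seq_len(config$tanks_per_treatment), n),
        mass_g = mass,
        fork_length_cm = (100 * mass / k)^(1 / 3),
        age_dph = round(rnorm(n, 180, 15))
      )
    })) %>%
    tidyr::unnest("fish") %>%
    mutate(fish_id = sprintf("F%04d", row_number()), .before = 1)
  fish
}

#' Generate biweekly growth measurements
#'
#' Treatment-level linear growth: expected mass is
#' `intercept + slope * days`, observed masses are lognormal around it
#' (mean-preserving), 30 fish per treatment per date by default. Fish are
#' not individually tracked, mirroring repeated cross-sectional sampling.
#'
#' @param truth,config,seed See [synthetic_truth()], [cohort_config()].
#' @return Long tibble: `population`, `acclim`, `tank`, `time_days`,
#'   `mass_g`, `fork_length_cm`.
#' @export
generate_growth_data <- function(truth, config, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- truth$noise$growth_log_sd
  days <- (seq_len(config$n_dates) - 1) * config$date_spacing_days
  out <- truth$growth %>%
    filter(.data$population %in% config$populations,
           .data$acclim %in% config$acclim_temps) %>%
    select(-dplyr::any_of("time_days")) %>%
    crossing(time_days = days) %>%
    mutate(rows = purrr::pmap(
      list(.data$population, .data$acclim, .data$time_days,
           .data$slope_g_day, .data$intercept_g),
      function(pop, acc, day, slope, int) {
        slope <- slope + env_shift(truth, "growth", pop)
        m <- int + slope * day
        n <- config$growth_n_per_date
        mass <- exp(rnorm(n, log(m) - s^2 / 2, s))   # E[mass] = m exactly
        k <- rnorm(n, 1.2, 0.06)
        tibble(tank = rep_len(seq_len(config$tanks_per_treatment), n),
               mass_g = mass,
               fork_length_cm = (100 * mass / k)^(1 / 3))
      }))
  out %>%
    select("population", "acclim", "time_days", "rows") %>%
    tidyr::unnest("rows")
}

#' Generate critical thermal maximum trials with ramp series
#'
#' Each trial starts at the fish's acclimation temperature, holds 30 min,
#' then heats at the configured constant rate (default 0.33 C/min) until the
#' fish's loss-of-equilibrium temperature (drawn from the treatment's normal
#' distribution) is reached. Beaker temperature is logged every 5 minutes
#' with a small thermocouple noise. About 6% of fish are flagged as failing
#' 24-h recovery and should be excluded from analysis.
#'
#' @param truth,config,seed See [synthetic_truth()], [cohort_config()].
#' @param thermocouple_sd SD of temperature reading noise, C.
#' @return List with `trials` (one row per fish: identifiers, covariates,
#'   `loe_temp_C`, `chamber`, `recovered`) and `series` (long tibble of the
#'   logged ramp: `fish_id`, `time_min`, `temp_C`, `phase`).
#' @export
generate_ctmax_trials <- function(truth, config, seed, thermocouple_sd = 0.02) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  trt <- truth$ctmax %>%
    filter(.data$population %in% config$populations,
           .data$acclim %in% config$acclim_temps)
  trials <- list(); series <- list(); id <- 0L
  for (i in seq_len(nrow(trt))) {
    pop <- trt$population[i]; acc <- trt$acclim[i]
    mu <- trt$mean_C[i] + env_shift(truth, "ctmax", pop)
    for (f in seq_len(config$ctmax_n)) {
      id <- id + 1L
      fid <- sprintf("C%04d", id)
      loe <- rnorm(1, mu, trt$sd_C[i])
      mass <- pmax(rnorm(1, config$mass_mean_g, config$mass_sd_g), 5)
      k <- rnorm(1, 1.2, 0.06)
      ramp_min <- (loe - acc) / config$ramp_rate_C_min
      tmax <- 30 + ramp_min
      t_log <- seq(0, tmax, by = 5)
      temp <- ifelse(t_log <= 30, acc, acc + (t_log - 30) * config$ramp_rate_C_min)
      temp <- temp + rnorm(length(temp), 0, thermocouple_sd)
      trials[[id]] <- tibble(
        fish_id = fid, population = pop, acclim = acc,
        mass_g = mass, fork_length_cm = (100 * mass / k)^(1 / 3),
        age_dph = round(rnorm(1, 180, 15)),
        chamber = ((id - 1L) %% 6L) + 1L,
        loe_temp_C = loe,
        recovered = runif(1) > config$nonrecovery_rate
      )
      series[[id]] <- tibble(fish_id = fid, time_min = t_log, temp_C = temp,
                             phase = ifelse(t_log <= 30, "hold", "ramp"))
    }
  }
  list(trials = purrr::list_rbind(trials), series = purrr::list_rbind(series))
}

# per-treatment true metabolic curves
true_rmr <- function(met_row, temp_C) {
  met_row$rmr_ref_16 * exp(met_row$rmr_b * (temp_C - 16))
}
true_as <- function(met_row, temp_C, min_as) {
  pmax(met_row$as_max + met_row$as_a * (temp_C - met_row$topt_C)^2, min_as)
}

#' Generate model-scale metabolic observations
#'
#' The fast path for fitting the trait models: one row per respirometry
#' fish with RMR drawn lognormally around the treatment's exponential
#' temperature curve, aerobic scope from the concave quadratic, MMR as
#' their sum plus Gaussian noise, and AS recomputed as MMR - RMR so the
#' identity holds exactly in the emitted data. Test temperatures cycle
#' through the configured menu.
#'
#' @param truth,config,seed See [synthetic_truth()], [cohort_config()].
#' @return Tibble: identifiers, `tunnel_id`, `test_temp_C`, size covariates,
#'   `rmr`, `mmr`, `aerobic_scope` (mgO2 kg^-1 min^-1), `true_rmr`,
#'   `true_as` for recovery checks.
#' @export
generate_metabolic_data <- function(truth, config, seed) {
  fish <- generate_cohort(config, truth, seed)
  set.seed((as.integer(seed) + 1L) %% .Machine$integer.max)
  met <- truth$metabolic
  fish <- fish %>%
    group_by(.data$population, .data$acclim) %>%
    mutate(test_temp_C = rep_len(config$test_temps, n()),
           tunnel_id = paste0("T", rep_len(1:4, n()))) %>%
    ungroup()
  fish <- fish %>% left_join(met, by = c("population", "acclim"))
  shift_for <- function(target) {
    sh <- purrr::map_dbl(unique(fish$population), ~ env_shift(truth, target, .x))
    sh[match(fish$population, unique(fish$population))]
  }
  n <- nrow(fish)
  rmr_mu <- fish$rmr_ref_16 * exp(fish$rmr_b * (fish$test_temp_C - 16)) *
    exp(shift_for("rmr"))
  as_mu <- pmax(fish$as_max + fish$as_a * (fish$test_temp_C - fish$topt_C)^2,
                truth$min_as) + shift_for("as")
  rmr <- rmr_mu * exp(rnorm(n, 0, truth$noise$rmr_log_sd))
  mmr <- rmr_mu + pmax(as_mu, 0.1) + rnorm(n, 0, truth$noise$mmr_sd) +
    shift_for("mmr")
  mmr <- pmax(mmr, rmr + 0.1)
  fish %>%
    select(-"rmr_ref_16", -"rmr_b", -"as_max", -"topt_C", -"as_a",
           -"mmr_log2_int", -"mmr_log2_slope") %>%
    mutate(rmr = rmr, mmr = mmr, aerobic_scope = mmr - rmr,
           true_rmr = rmr_mu, true_as = as_mu,
           condition_k = fulton_k(.data$mass_g, .data$fork_length_cm))
}

#' Generate an oxygen-saturation trace for one fish
#'
#' Inverts the respirometry equations: the target routine and maximum
#' metabolic rates are converted to concentration slopes
#' (`R = MO2 * M / (V * 60)`) and then to percent-saturation depletion
#' rates, which drive sealed measurement periods separated by flush periods
#' that restore saturation. The swim phase steps metabolic rate up from RMR
#' to MMR across velocity increments, so the steepest >= 5 min window
#' encodes MMR exactly. If a requested period would push saturation below
#' the floor the period is shortened and the event logged in the returned
#' metadata.
#'
#' @param target_rmr,target_mmr Target metabolic rates, mgO2 kg^-1 min^-1.
#' @param test_temp_C Acute test temperature (sets oxygen solubility).
#' @param mass_kg Fish mass in kilograms.
#' @param config A [cohort_config()] (tunnel volume, barometric pressure).
#' @param seed Integer seed.
#' @param n_routine Number of sealed routine periods.
#' @param routine_s,flush_s,swim_s Period durations, seconds.
#' @param n_swim Number of sealed swim steps (metabolic rate ramps linearly
#'   from RMR to MMR over the steps).
#' @param sat_noise_sd Sensor noise SD, percent saturation.
#' @param activity_periods Indices of routine periods to flag as
#'   activity-contaminated (their depletion is steepened).
#' @param saturation_floor Minimum saturation the generator will allow.
#' @return List: `samples` (tibble `time_s`, `saturation_pct`), `phases`
#'   (tibble with kind/context/velocity/activity), `meta` (alpha, pressure,
#'   volume, shortened-period log).
#' @export
generate_o2_trace <- function(target_rmr, target_mmr, test_temp_C, mass_kg,
                              config = cohort_config(), seed = 1,
                              n_routine = 6, routine_s = 900, flush_s = 240,
                              n_swim = 3, swim_s = 960,
                              sat_noise_sd = NULL,
                              activity_periods = integer(),
                              saturation_floor = 80) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  alpha <- o2_solubility(test_temp_C)
  bp <- config$bp_mmHg
  V <- config$tunnel_volume_L
  conc_100 <- alpha * bp
  mo2_to_sat_rate <- function(mo2) mo2 * mass_kg / (V * 60) / conc_100 * 100

  shortened <- list()
  t <- 0; sat <- 100
  times <- list(); sats <- list(); phases <- list()
  add_sealed <- function(mo2, dur, context, velocity, activity) {
    rate <- mo2_to_sat_rate(mo2)
    max_dur <- floor((sat - (saturation_floor + 1)) / rate)
    if (dur > max_dur) {
      shortened[[length(shortened) + 1]] <<- tibble(
        context = context, requested_s = dur, used_s = max_dur)
      dur <- max_dur
    }
    tt <- seq(0, dur)
    times[[length(times) + 1]] <<- t + tt
    sats[[length(sats) + 1]] <<- sat - rate * tt
    phases[[length(phases) + 1]] <<- tibble(
      start_s = t, end_s = t + dur, kind = "sealed", context = context,
      velocity_cm_s = velocity, activity = activity)
    sat <<- sat - rate * dur
    t <<- t + dur + 1
  }
  add_flush <- function(dur) {
    tt <- seq(0, dur)
    times[[length(times) + 1]] <<- t + tt
    sats[[length(sats) + 1]] <<- sat + (100 - sat) * tt / dur
    phases[[length(phases) + 1]] <<- tibble(
      start_s = t, end_s = t + dur, kind = "flush", context = "routine",
      velocity_cm_s = 0, activity = FALSE)
    sat <<- 100
    t <<- t + dur + 1
  }

  for (p in seq_len(n_routine)) {
    mo2 <- if (p %in% activity_periods) target_rmr * 1.6 else target_rmr
    add_sealed(mo2, routine_s, "routine", 0, p %in% activity_periods)
    add_flush(flush_s)
  }
  vel <- 30
  for (s in seq_len(n_swim)) {
    mo2 <- target_rmr + (target_mmr - target_rmr) * s / n_swim
    add_sealed(mo2, swim_s, "swim", vel, FALSE)
    add_flush(flush_s)
    vel <- vel + min(0.1 * vel, 6)   # 10% increments capped at 6 cm/s
  }

  sat_sd <- sat_noise_sd %||% 0
  samples <- tibble(time_s = unlist(times), saturation_pct = unlist(sats))
  if (sat_sd > 0) {
    samples$saturation_pct <- samples$saturation_pct +
      rnorm(nrow(samples), 0, sat_sd)
  }
  list(samples = samples,
       phases = purrr::list_rbind(phases),
       meta = tibble(alpha_o2 = alpha, barometric_pressure_mmHg = bp,
                     tunnel_volume_L = V, fish_mass_kg = mass_kg,
                     test_temp_C = test_temp_C),
       shortened = if (length(shortened)) purrr::list_rbind(shortened) else tibble())
}

#' Generate the environmental predictor table
#'
#' `mode = "published"` returns the bundled per-population predictor table
#' (real latitude, migration distance and slope; synthetic stream
#' temperature metrics, see [published_table()]). `mode = "random"` draws a
#' table with a shared "habitat warmth" factor so temperature metrics are
#' mutually correlated at roughly `target_cor`, emulating the strong
#' collinearity among real stream-temperature predictors; range columns are
#' max minus min by construction.
#'
#' @param mode `"published"` or `"random"`.
#' @param seed Integer seed (random mode).
#' @param target_cor Desired correlation among temperature metrics.
#' @param populations Population names for random mode.
#' @return Tibble, one row per population, 15 predictor columns.
#' @export
generate_env_table <- function(mode = c("published", "random"), seed = 1,
                               target_cor = 0.8,
                               populations = published_table("populations")$population) {
  mode <- match.arg(mode)
  if (mode == "published") return(published_table("env"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- length(populations)
  w <- rnorm(n)                       # shared habitat-warmth factor
  lam <- sqrt(target_cor)
  mix <- function() lam * w + sqrt(1 - target_cor) * rnorm(n)
  camax <- 19 + 2 * mix(); hamax <- 15.5 + 2 * mix()
  carange <- 10 + 2 * abs(rnorm(n)); harange <- 10 + 2 * abs(rnorm(n))
  tbl <- tibble(
    population = populations,
    Latitude = runif(n, 39, 47),
    Mig.D = exp(runif(n, log(20), log(650))),
    CAMax = camax, CAMin = camax - carange, CARange = carange,
    CRMax = 12 + 1.5 * mix(), CRCMax = 10.5 + 1.5 * mix(),
    CRAve = 9.2 + 1.2 * mix(),
    HAMax = hamax, HAMin = hamax - harange, HARange = harange,
    HRMax = 10 + 1.5 * mix(), HRCMax = 9 + 1.5 * mix(),
    HRAve = 7.5 + 1.2 * mix()
  )
  tbl$`Mig.S` <- runif(n, 10, 600) / tbl$`Mig.D`
  tbl[, c("population", env_predictor_names())]
}

#' The fifteen environmental predictor names
#' @return Character vector in canonical order.
#' @export
env_predictor_names <- function() {
  c("Latitude", "Mig.D", "Mig.S",
    "CAMax", "CAMin", "CARange", "CRMax", "CRCMax", "CRAve",
    "HAMax", "HAMin", "HARange", "HRMax", "HRCMax", "HRAve")
}

#' Inject an environmental effect into the synthetic truth
#'
#' Shifts population-level trait parameters linearly with the standardized
#' value of a predictor, enabling power and calibration experiments for the
#' association screen. Targets: `"growth"` (g/day per SD), `"ctmax"` (C per
#' SD), `"rmr"` (log-units per SD), `"mmr"`/`"as"` (mgO2 kg^-1 min^-1 per
#' SD). Zero coefficients leave the truth untouched.
#'
#' @param truth A [synthetic_truth()].
#' @param table Environmental predictor table ([generate_env_table()]).
#' @param target Trait parameter to shift.
#' @param predictor Predictor column name.
#' @param beta Effect size per predictor SD.
#' @return The modified truth.
#' @export
inject_env_effect <- function(truth, table, target, predictor, beta) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!predictor %in% names(table)) {
    abort(sprintf("Unknown predictor `%s`.", predictor),
          class = "aeroscope_invalid_input")
  }
  if (!target %in% c("growth", "ctmax", "rmr", "mmr", "as")) {
    abort(sprintf("Unknown target `%s`.", target), class = "aeroscope_invalid_input")
  }
  if (beta == 0) return(truth)
  x <- table[[predictor]]
  z <- setNames(as.list((x - mean(x)) / sd(x)), table$population)
  truth$env_effects <- bind_rows(
    truth$env_effects,
    tibble(target = target, predictor = predictor, beta = beta, pred_z = list(z))
  )
  truth
}
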