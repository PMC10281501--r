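# shared fixtures, all built in code

# small three-population design used by most model-fitting tests
small_config <- function(...) {
  cohort_config(
    populations = c("Coleman", "Elk River", "Trask River"),
    growth_n_per_date = 10, n_dates = 3,
    ctmax_n = 10, resp_n = 12,
    ...
  )
}

# truth with no interpopulation differences: every population shares the
# acclimation-level parameter means, so any detected environmental
# association is a false positive by construction
uniform_truth <- function(...) {
  truth <- synthetic_truth(...)
  pool <- function(df, cols) {
    df %>%
      dplyr::group_by(acclim) %>%
      dplyr::mutate(dplyr::across(dplyr::all_of(cols), mean)) %>%
      dplyr::ungroup()
  }
  truth$growth <- pool(truth$growth, c("slope_g_day", "intercept_g"))
  truth$ctmax <- pool(truth$ctmax, c("mean_C", "sd_C"))
  truth$metabolic <- pool(truth$metabolic,
                          c("rmr_ref_16", "rmr_b", "as_max", "topt_C", "as_a",
                            "mmr_log2_int", "mmr_log2_slope"))
  truth
}

# a minimal single-fish trace bundle for process_respirometry()
one_fish_inputs <- function(target_rmr = 2.5, target_mmr = 11,
                            test_temp = 16, mass_kg = 0.024,
                            sat_noise_sd = 0, seed = 1, ...) {
  tr <- generate_o2_trace(target_rmr, target_mmr, test_temp, mass_kg,
                          cohort_config(), seed = seed,
                          sat_noise_sd = sat_noise_sd, ...)
  list(
    samples = dplyr::mutate(tr$samples, fish_id = "F1"),
    phases = dplyr::mutate(tr$phases, fish_id = "F1"),
    meta = dplyr::bind_cols(
      tibble::tibble(fish_id = "F1", population = "Coleman",
                     acclim_temp_C = 16, survived = TRUE),
      tr$meta
    ),
    trace = tr
  )
}

# fast sampler settings that still satisfy the >= 2000 retained draw contract
fast_control <- function(...) sampler_control(chains = 2, warmup = 300, iter = 1000, ...)

# degenerate treatment-means tibble whose "posterior" is a point mass,
# for exact arithmetic on published cell values
point_means <- function(df, value_col, trait = "trait") {
  tibble::tibble(
    population = df$population,
    acclim = as.character(df$acclim_C),
    trait = trait,
    mean = df[[value_col]],
    sd = 0,
    draws = lapply(df[[value_col]], function(v) rep(v, 100))
  )
}
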