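#' Pipeline configuration
#'
#' Collects the fixed analysis constants in one validated object. Defaults
#' follow the study protocol: 0.945/0.85 posterior-mass significance
#' thresholds, 80% oxygen-saturation floor, 0.90 linearity threshold, 500
#' posterior draws for the thermal optimum and the 11/16/20 C reporting
#' grid for metabolic associations.
#'
#' @param seed Integer seed (mandatory).
#' @param cohort A [cohort_config()].
#' @param control A [sampler_control()].
#' @param r2_threshold Linearity filter on regression periods.
#' @param saturation_floor Minimum allowed saturation, percent.
#' @param strong,weak Posterior-mass significance thresholds.
#' @param topt_draws Posterior draws used for T_opt.
#' @param report_test_temps Test-temperature reporting grid, C.
#' @param respirometry_mode `"traces"` simulates and processes full
#'   oxygen-saturation traces; `"direct"` uses the model-scale metabolic
#'   generator (fast path).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            cohort = cohort_config(),
                            control = sampler_control(),
                            r2_threshold = 0.90,
                            saturation_floor = 80,
                            strong = 0.945, weak = 0.85,
                            topt_draws = 500,
                            report_test_temps = c(11, 16, 20),
                            respirometry_mode = c("direct", "traces")) {
  if (missing(seed)) abort("`seed` is mandatory in pipeline_config().")
  for (th in c(strong, weak, r2_threshold)) {
    if (th <= 0.5 || th >= 1) abort("Thresholds must lie in (0.5, 1).")
  }
  respirometry_mode <- match.arg(respirometry_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Header-keyed schema and range checks for the three trait tables. All
#' violations are collected and reported together in a single hard failure.
#'
#' @param growth,ctmax,metabolic Input tibbles (any may be `NULL` to skip).
#' @return Invisibly, a tibble of checks performed. Errors (listing every
#'   violation) if any check fails.
#' @export
validate_inputs <- function(growth = NULL, ctmax = NULL, metabolic = NULL) {
  problems <- character()
  checks <- list()
  req <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      problems <<- c(problems, sprintf("%s: missing columns %s", name,
                                       paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  rng <- function(x, lo, hi, name, what) {
    bad <- sum(x < lo | x > hi, na.rm = TRUE)
    if (bad > 0) problems <<- c(problems, sprintf(
      "%s: %d row(s) with %s outside [%g, %g]", name, bad, what, lo, hi))
  }
  if (!is.null(growth) && req(growth, c("population", "acclim", "time_days", "mass_g"), "growth")) {
    rng(growth$mass_g, 0.1, 500, "growth", "mass_g")
    rng(growth$time_days, 0, 400, "growth", "time_days")
    checks <- c(checks, "growth")
  }
  if (!is.null(ctmax) && req(ctmax, c("population", "acclim", "mass_g", "loe_temp_C"), "ctmax")) {
    rng(ctmax$loe_temp_C, 15, 40, "ctmax", "loe_temp_C")
    checks <- c(checks, "ctmax")
  }
  if (!is.null(metabolic) && req(metabolic, c("population", "acclim", "test_temp_C", "rmr", "mmr"), "metabolic")) {
    rng(metabolic$test_temp_C, 5, 30, "metabolic", "test_temp_C")
    if (any(metabolic$rmr < 0, na.rm = TRUE)) problems <- c(problems, "metabolic: negative RMR")
    checks <- c(checks, "metabolic")
  }
  if (length(problems)) {
    abort(paste0("Input validation failed:\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "aeroscope_schema_error")
  }
  invisible(tibble(table = unlist(checks), status = "ok"))
}

#' Prepare raw trait tables for model fitting
#'
#' Coerces design factors and attaches the standardized covariate columns
#' the default model specs expect (z-scored mass, condition factor and test
#' temperature; 0--1 scaled time and age; log2 test temperature for the MMR
#' family).
#'
#' @param data Raw table from the generators or external CSV.
#' @return Standardized tibble carrying a `"scaling"` attribute.
#' @name prepare_data
NULL

#' @rdname prepare_data
#' @export
prepare_growth_data <- function(data) {
  data$population <- factor(data$population)
  data$acclim <- factor(data$acclim)
  standardize(data, unit_cols = "time_days")
}

#' @rdname prepare_data
#' @export
prepare_ctmax_data <- function(data) {
  data$population <- factor(data$population)
  data$acclim <- factor(data$acclim)
  data <- rename(data, ctmax_C = "loe_temp_C")
  standardize(data, z_cols = "mass_g", unit_cols = "age_dph")
}

#' @rdname prepare_data
#' @export
prepare_metabolic_data <- function(data) {
  data$population <- factor(data$population)
  data$acclim <- factor(data$acclim)
  if (is.null(data$condition_k)) {
    data$condition_k <- fulton_k(data$mass_g, data$fork_length_cm)
  }
  data$log2_temp <- log2(data$test_temp_C)
  standardize(data,
              z_cols = c("mass_g", "condition_k", "test_temp_C", "log2_temp"),
              unit_cols = if ("age_dph" %in% names(data)) "age_dph" else character())
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a cohort from the supplied truth, runs the requested stages in
#' order — respirometry (trace processing or direct metabolic generation),
#' trait model fits, treatment means and contrasts, acclimation capacities,
#' thermal optima, and optionally the environmental screen — and returns a
#' results bundle with a reproducibility manifest. Stages absent from
#' `stages` are skipped; reruns with the same config are identical.
#'
#' @param config A [pipeline_config()].
#' @param truth A [synthetic_truth()].
#' @param stages Character subset of
#'   `c("growth", "ctmax", "metabolic", "topt", "env")`.
#' @param env_predictors Predictors for the screen stage.
#' @return List of class `pipeline_results`: input tables, fits, means,
#'   contrasts, capacities, T_opt estimates, screen results and `manifest`.
#' @export
run_pipeline <- function(config, truth = synthetic_truth(),
                         stages = c("growth", "ctmax", "metabolic", "topt"),
                         env_predictors = env_predictor_names()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  res <- list(config = config)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S"), " ", msg))
  }
  exclusion_counts <- tibble(reason = character(), n = integer())

  if ("growth" %in% stages) {
    say("growth: simulating and fitting")
    raw <- generate_growth_data(truth, config$cohort, seed + 11L)
    validate_inputs(growth = raw)
    d <- prepare_growth_data(raw)
    fit <- fit_trait_model(d, default_trait_specs()$growth,
                           control = config$control, seed = seed + 12L)
    means <- treatment_means(fit)
    res$growth <- list(
      data = d, fit = fit, means = means,
      contrasts = pairwise_contrasts(means, config$strong, config$weak),
      capacity = purrr::map(unique(as.character(d$population)),
                            ~ acclimation_capacity(means, .x,
                                                   strong = config$strong,
                                                   weak = config$weak)) %>%
        purrr::list_rbind()
    )
  }

  if ("ctmax" %in% stages) {
    say("ctmax: simulating and fitting")
    tr <- generate_ctmax_trials(truth, config$cohort, seed + 21L)
    raw <- tr$trials %>% filter(.data$recovered)
    n_excl <- sum(!tr$trials$recovered)
    exclusion_counts <- bind_rows(exclusion_counts,
                                  tibble(reason = "ctmax_nonrecovery", n = n_excl))
    validate_inputs(ctmax = tr$trials)
    d <- prepare_ctmax_data(raw)
    fit <- fit_trait_model(d, default_trait_specs()$ctmax,
                           control = config$control, seed = seed + 22L)
    means <- treatment_means(fit)
    res$ctmax <- list(
      trials = tr$trials, series = tr$series, data = d, fit = fit, means = means,
      contrasts = pairwise_contrasts(means, config$strong, config$weak),
      capacity = purrr::map(unique(as.character(d$population)),
                            ~ acclimation_capacity(means, .x,
                                                   strong = config$strong,
                                                   weak = config$weak)) %>%
        purrr::list_rbind()
    )
  }

  if ("metabolic" %in% stages) {
    if (config$respirometry_mode == "traces") {
      say("metabolic: simulating traces and processing respirometry")
      met <- simulate_and_process_traces(truth, config, seed + 31L)
      exclusion_counts <- bind_rows(exclusion_counts, met$exclusion_counts)
      raw <- met$results
    } else {
      say("metabolic: direct model-scale generation")
      raw <- generate_metabolic_data(truth, config$cohort, seed + 31L)
    }
    validate_inputs(metabolic = raw)
    d <- prepare_metabolic_data(raw)
    specs <- default_trait_specs()
    res$metabolic <- list(data = d)
    for (trait in c("rmr", "mmr", "as")) {
      say("metabolic: fitting %s", trait)
      fit <- fit_trait_model(d, specs[[trait]], control = config$control,
                             seed = seed + 32L + match(trait, c("rmr", "mmr", "as")))
      res$metabolic[[trait]] <- list(fit = fit, means = treatment_means(fit))
    }
  }

  if ("topt" %in% stages) {
    if (is.null(res$metabolic)) {
      say("topt: skipped (metabolic stage not run)")
    } else {
      say("topt: estimating thermal optima")
      est <- estimate_topt(res$metabolic$as$fit, n_draws = config$topt_draws,
                           seed = seed + 41L)
      pops <- unique(est$population)
      res$topt <- list(
        estimates = est,
        delta = purrr::map(pops, ~ delta_topt(est, .x)) %>% purrr::list_rbind()
      )
    }
  }

  if ("env" %in% stages) {
    say("env: screening environmental predictors")
    table <- generate_env_table("published")
    data_list <- list()
    if (!is.null(res$growth)) data_list$growth <- res$growth$data
    if (!is.null(res$ctmax)) data_list$ctmax <- res$ctmax$data
    if (!is.null(res$metabolic)) {
      data_list$rmr <- res$metabolic$data
      data_list$mmr <- res$metabolic$data
      data_list$as <- res$metabolic$data
    }
    res$env <- list(
      table = table,
      correlations = correlation_matrix(table),
      results = screen_env_associations(
        data_list, table, predictors = env_predictors, seed = seed + 51L,
        control = config$control, strong = config$strong, weak = config$weak,
        report_test_temps = config$report_test_temps)
    )
  }

  res$manifest <- tibble(
    config_hash = rlang::hash(config[setdiff(names(config), "")]),
    truth_hash = rlang::hash(truth),
    seed = seed,
    stages = paste(intersect(stages, c("growth", "ctmax", "metabolic", "topt", "env")),
                   collapse = ","),
    finished_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("aeroscope")),
    exclusions = list(exclusion_counts)
  )
  res$log <- log_lines
  class(res) <- "pipeline_results"
  res
}

# trace-level respirometry for the pipeline's metabolic stage
simulate_and_process_traces <- function(truth, config, seed) {
  fish <- generate_metabolic_data(truth, config$cohort, seed)
  n_routine <- 4
  all_samples <- list(); all_phases <- list(); metas <- list()
  for (i in seq_len(nrow(fish))) {
    fr <- fish[i, ]
    tr <- generate_o2_trace(
      fr$true_rmr, fr$true_rmr + pmax(fr$true_as, 0.1), fr$test_temp_C,
      fr$mass_g / 1000, config$cohort, seed = seed + i,
      n_routine = n_routine, sat_noise_sd = truth$noise$sat_sd
    )
    all_samples[[i]] <- mutate(tr$samples, fish_id = fr$fish_id)
    all_phases[[i]] <- mutate(tr$phases, fish_id = fr$fish_id)
    metas[[i]] <- dplyr::bind_cols(
      tibble(fish_id = fr$fish_id, population = fr$population,
             acclim_temp_C = fr$acclim, survived = TRUE),
      tr$meta
    )
  }
  results <- process_respirometry(
    purrr::list_rbind(all_samples), purrr::list_rbind(all_phases),
    purrr::list_rbind(metas), r2_threshold = config$r2_threshold
  )
  qc <- qc_filter(results, config$saturation_floor)
  merged <- qc$retained %>%
    select("fish_id", "rmr", "mmr", "aerobic_scope") %>%
    left_join(fish %>% select("fish_id", "population", "acclim", "tank",
                              "mass_g", "fork_length_cm", "age_dph",
                              "test_temp_C", "tunnel_id", "condition_k"),
              by = "fish_id")
  list(results = merged,
       exclusion_counts = qc$exclusions %>% group_by(.data$reason) %>%
         summarise(n = dplyr::n(), .groups = "drop"))
}

#' Assemble summary report tables from a pipeline run
#'
#' Produces the headline tables: per-treatment trait means, contrast
#' matrices for growth and CT_max, the thermal-optimum table (mean, SD,
#' extrapolation flag, warm-minus-cold shift) and the association grid. When
#' `dir` is given each table is also written as CSV.
#'
#' @param results A `pipeline_results` bundle.
#' @param dir Optional output directory for CSVs.
#' @return Named list of tibbles.
#' @export
render_report <- function(results, dir = NULL) {
  out <- list()
  means <- list()
  for (trait in c("growth", "ctmax")) {
    if (!is.null(results[[trait]])) {
      means[[trait]] <- results[[trait]]$means %>% select(-"draws")
      out[[paste0(trait, "_contrasts")]] <- results[[trait]]$contrasts
      out[[paste0(trait, "_capacity")]] <- results[[trait]]$capacity %>% select(-"draws")
    }
  }
  if (!is.null(results$metabolic)) {
    for (trait in c("rmr", "mmr", "as")) {
      means[[trait]] <- results$metabolic[[trait]]$means %>% select(-"draws")
    }
  }
  if (length(means)) out$treatment_means <- purrr::list_rbind(means)
  if (!is.null(results$topt)) {
    out$topt <- results$topt$estimates %>% select(-"draws") %>%
      left_join(results$topt$delta %>%
                  select("population", "delta_topt_C", delta_sd_C = "sd_C"),
                by = "population")
  }
  if (!is.null(results$env)) {
    out$association_grid <- results$env$results
  } else {
    out$association_grid <- tibble(trait = character(), predictor = character(),
                                   acclim = character(), test_temp_C = numeric(),
                                   direction = character(), significance = character())
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  out
}
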