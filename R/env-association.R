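#' Build the model specification for one trait x predictor association
#'
#' Takes the trait's base model and swaps in a single environmental
#' predictor (standardized, joined by population) as `env_z`, with source
#' population as a random intercept. The predictor interacts with
#' acclimation temperature for every trait, and additionally with the
#' (linear) test-temperature term for the metabolic traits so the
#' association can be evaluated across the acute thermal gradient. Growth
#' keeps its time interaction so the estimand is an effect on growth rate.
#'
#' @param trait One of `"growth"`, `"ctmax"`, `"rmr"`, `"mmr"`, `"as"`.
#' @param predictor One of [env_predictor_names()].
#' @param extra_random Additional random-intercept grouping columns (e.g.
#'   CT_max chamber or swim tunnel), appended to the population intercept.
#' @return A [trait_spec()].
#' @export
build_env_spec <- function(trait, predictor, extra_random = character()) {
  if (!predictor %in% env_predictor_names()) {
    abort(sprintf("Unknown predictor `%s`.", predictor),
          class = "aeroscope_invalid_input")
  }
  fixed <- switch(trait,
    growth = ~ acclim * time_days_01 * env_z,
    ctmax = ~ env_z * acclim + mass_g_z + age_dph_01,
    rmr = ~ env_z * acclim + test_temp_C_z + env_z:test_temp_C_z,
    mmr = ~ env_z * acclim + log2_temp_z + env_z:log2_temp_z,
    as = ~ env_z * acclim + test_temp_C_z + I(test_temp_C_z^2) +
      env_z:test_temp_C_z,
    abort(sprintf("Unknown trait `%s`.", trait), class = "aeroscope_invalid_input")
  )
  base <- default_trait_specs()[[trait]]
  trait_spec(
    trait = trait, response = base$response, fixed = fixed,
    random = union("population", extra_random),
    response_transform = base$response_transform,
    report = "level",
    time_col = base$time_col, temp_col = base$temp_col
  )
}

#' Attach a standardized environmental predictor to trait data
#'
#' Joins the predictor by population and adds `env_z`, its z-score across
#' populations (each population contributes one distinct value).
#'
#' @param data Trait data containing a `population` column.
#' @param table Environmental predictor table.
#' @param predictor Predictor column name.
#' @return `data` with `env_z` appended.
#' @export
attach_env_predictor <- function(data, table, predictor) {
  x <- table[[predictor]]
  if (is.null(x)) abort(sprintf("Predictor `%s` not in table.", predictor))
  pops <- table$population
  if (sd(x) == 0) abort("Predictor is constant across populations.",
                        class = "aeroscope_zero_variance")
  z <- (x - mean(x)) / sd(x)
  data$env_z <- z[match(as.character(data$population), pops)]
  if (anyNA(data$env_z)) abort("Some populations lack a predictor value.")
  data
}

# per-draw association effect (difference in linear predictor for +1 SD of
# the predictor) at one acclimation group / test temperature cell
env_effect_draws <- function(fit, trait, acclim, test_temp_C = NULL) {
  data <- fit$data
  base_row <- function(env) {
    nd <- tibble(acclim = factor(acclim, levels = levels(factor(data$acclim))),
                 env_z = env)
    vars <- setdiff(all.vars(stats::delete.response(fit$terms)),
                    c("acclim", "env_z"))
    for (v in vars) {
      x <- data[[v]]
      if (v == "test_temp_C_z" && !is.null(test_temp_C)) {
        sc <- fit$scaling[fit$scaling$column == "test_temp_C", ]
        nd[[v]] <- (test_temp_C - sc$mean) / sc$sd
      } else if (v == "log2_temp_z" && !is.null(test_temp_C)) {
        sc <- fit$scaling[fit$scaling$column == "log2_temp", ]
        nd[[v]] <- (log2(test_temp_C) - sc$mean) / sc$sd
      } else if (is.numeric(x)) {
        nd[[v]] <- mean(x)
      } else {
        nd[[v]] <- factor(levels(factor(x))[1], levels = levels(factor(x)))
      }
    }
    nd
  }
  if (identical(trait, "growth")) {
    tcol <- paste0(fit$spec$time_col, "_01")
    eta <- function(env, t) {
      nd <- base_row(env); nd[[tcol]] <- t
      drop(posterior_linpred(fit, nd))
    }
    (eta(1, 1) - eta(1, 0)) - (eta(0, 1) - eta(0, 0))
  } else {
    drop(posterior_linpred(fit, base_row(1)) - posterior_linpred(fit, base_row(0)))
  }
}

#' Enumerate the reporting cells of an association screen
#'
#' Growth and CT_max report one cell per acclimation temperature; the
#' metabolic traits report one cell per acclimation x test temperature.
#'
#' @param traits Traits screened.
#' @param predictors Predictors screened.
#' @param acclim_temps Acclimation temperatures.
#' @param report_test_temps Test-temperature reporting grid for metabolic
#'   traits.
#' @return Tibble with one row per association cell (`trait`, `predictor`,
#'   `acclim`, `test_temp_C`; the latter `NA` for growth/CT_max).
#' @export
association_cells <- function(traits = c("growth", "ctmax", "rmr", "mmr", "as"),
                              predictors = env_predictor_names(),
                              acclim_temps = c(11, 16, 20),
                              report_test_temps = c(11, 16, 20)) {
  metabolic <- c("rmr", "mmr", "as")
  purrr::map(traits, function(trait) {
    base <- crossing(trait = trait, predictor = predictors,
                     acclim = as.character(acclim_temps))
    if (trait %in% metabolic) {
      crossing(base, test_temp_C = report_test_temps)
    } else {
      mutate(base, test_temp_C = NA_real_)
    }
  }) %>% purrr::list_rbind()
}

#' Screen environmental predictors against physiological traits
#'
#' Fits one single-predictor model per trait x predictor combination
#' (population as a random intercept) and classifies the directional
#' significance of the association in every reporting cell: per acclimation
#' temperature for growth and CT_max (3 cells each), and per acclimation x
#' test temperature for the metabolic traits (9 cells each, default test
#' temperatures 11/16/20 C). Cells from non-converged fits are reported with
#' `significance = "unavailable"` rather than classified.
#'
#' @param data_list Named list of prepared trait data frames; names among
#'   `growth`, `ctmax`, `rmr`, `mmr`, `as` select which traits are screened.
#' @param table Environmental predictor table (one row per population).
#' @param predictors Predictor columns to screen (default all 15).
#' @param seed Integer seed; each model gets a derived seed.
#' @param control Sampler control ([sampler_control()]); non-convergence is
#'   always flagged, never fatal, inside the screen.
#' @param strong,weak Posterior-mass thresholds for classification.
#' @param report_test_temps Test temperatures at which metabolic-trait
#'   effects are reported.
#' @param extra_random Passed to [build_env_spec()].
#' @return Tibble of association cells: `trait`, `predictor`, `acclim`,
#'   `test_temp_C` (NA for growth/CT_max), `mean`, `sd`, `direction`,
#'   `significance`, `p`, `converged`.
#' @export
screen_env_associations <- function(data_list, table,
                                    predictors = env_predictor_names(),
                                    seed, control = sampler_control(),
                                    strong = 0.945, weak = 0.85,
                                    report_test_temps = c(11, 16, 20),
                                    extra_random = character()) {
  if (missing(seed)) abort("`seed` is mandatory for the screen.")
  control$on_nonconverged <- "flag"
  metabolic <- c("rmr", "mmr", "as")
  counter <- 0L
  out <- list()
  for (trait in names(data_list)) {
    data <- data_list[[trait]]
    for (pred in predictors) {
      counter <- counter + 1L
      d <- attach_env_predictor(data, table, pred)
      spec <- build_env_spec(trait, pred, extra_random)
      fit <- fit_trait_model(d, spec, control = control,
                             seed = (as.integer(seed) + counter) %% .Machine$integer.max)
      acclims <- sort(unique(as.character(d$acclim)))
      cells <- association_cells(trait, pred, acclims, report_test_temps) %>%
        select("acclim", "test_temp_C")
      res <- purrr::map(seq_len(nrow(cells)), function(i) {
        tt <- cells$test_temp_C[i]
        if (!fit$converged) {
          return(tibble(trait = trait, predictor = pred,
                        acclim = cells$acclim[i], test_temp_C = tt,
                        mean = NA_real_, sd = NA_real_,
                        direction = NA_character_,
                        significance = "unavailable", p = NA_real_,
                        converged = FALSE))
        }
        dr <- env_effect_draws(fit, trait, cells$acclim[i],
                               if (is.na(tt)) NULL else tt)
        cl <- classify_significance(dr, strong, weak)
        tibble(trait = trait, predictor = pred,
               acclim = cells$acclim[i], test_temp_C = tt,
               mean = mean(dr), sd = sd(dr),
               direction = cl$direction, significance = cl$significance,
               p = cl$p, converged = TRUE)
      })
      out <- c(out, res)
    }
  }
  res <- purrr::list_rbind(out)
  class(res) <- c("association_results", class(res))
  res
}

#' Robustness of growth associations to an outlier population
#'
#' Growth associations are only trusted when the same direction and
#' significance class emerge with and without the outlying population (the
#' slow-growing hatchery whose alternate life history makes it weakly
#' comparable). Cells that disagree are marked non-robust and demoted to
#' "none".
#'
#' @param results_with,results_without Growth rows of
#'   [screen_env_associations()] run on the full data and on data excluding
#'   the outlier population.
#' @return Merged growth results with `robust_to_exclusion`, the with/without
#'   classes, and the effective `significance`.
#' @export
trinity_robustness <- function(results_with, results_without) {
  keys <- c("trait", "predictor", "acclim", "test_temp_C")
  w <- results_with %>% filter(.data$trait == "growth")
  wo <- results_without %>% filter(.data$trait == "growth")
  if (nrow(w) != nrow(wo)) {
    abort("Mismatched cell sets between the two screens.",
          class = "aeroscope_invalid_input")
  }
  merged <- left_join(
    w, wo %>% select(all_of(keys), direction_without = "direction",
                     significance_without = "significance"),
    by = keys
  )
  if (anyNA(merged$significance_without)) {
    abort("Mismatched cell sets between the two screens.",
          class = "aeroscope_invalid_input")
  }
  merged %>%
    mutate(
      robust_to_exclusion = .data$direction == .data$direction_without &
        .data$significance == .data$significance_without,
      significance_with = .data$significance,
      significance = ifelse(.data$robust_to_exclusion, .data$significance, "none")
    )
}

#' Pairwise correlations among environmental predictors
#'
#' The collinearity report justifying single-predictor association models.
#'
#' @param table Environmental predictor table (>= 3 populations).
#' @return Pearson correlation matrix over the 15 predictors; entries for
#'   constant columns are `NA` (with a warning).
#' @export
correlation_matrix <- function(table) {
  preds <- intersect(env_predictor_names(), names(table))
  m <- as.matrix(table[, preds])
  if (nrow(m) < 3) abort("At least three populations required.")
  const <- apply(m, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("Constant predictor column(s): %s; correlations set to NA.",
                 paste(preds[const], collapse = ", ")))
  }
  suppressWarnings(cor(m))
}
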