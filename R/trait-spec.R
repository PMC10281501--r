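#' Specify a Bayesian trait model
#'
#' A lightweight description of one Gaussian mixed model: which response it
#' explains, how the response is transformed before z-scoring, its fixed
#' formula (written in terms of already-standardized columns, see
#' [standardize()]), random-intercept grouping factors, and optional
#' candidate terms for [stepwise_select()].
#'
#' @param trait One of `"growth"`, `"ctmax"`, `"rmr"`, `"mmr"`, `"as"`, or a
#'   free-form label for ad-hoc models.
#' @param response Name of the response column in the data (natural scale).
#' @param fixed One-sided formula of fixed effects.
#' @param random Character vector of grouping columns for random intercepts.
#' @param response_transform `"identity"` or `"log"` applied before
#'   z-scoring (metabolic rates modelled as exponential functions of
#'   temperature use `"log"`).
#' @param report `"level"` (cell means on the response scale) or
#'   `"rate_per_day"` (growth: the per-day slope of the response with respect
#'   to the 0--1 scaled time covariate, converted back to natural units).
#' @param time_col,temp_col Raw column names behind the scaled time and
#'   test-temperature covariates, used for back-conversion and for the
#'   thermal-optimum grid.
#' @param candidates Named list with optional `fixed` (character vector of
#'   term labels) and `random` (character vector of grouping columns) to be
#'   searched by [stepwise_select()].
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(trait, response, fixed, random = character(),
                       response_transform = c("identity", "log"),
                       report = c("level", "rate_per_day"),
                       time_col = NULL, temp_col = NULL,
                       candidates = list()) {
  response_transform <- match.arg(response_transform)
  report <- match.arg(report)
  stopifnot(inherits(fixed, "formula"))
  structure(
    list(trait = trait, response = response, fixed = fixed, random = random,
         response_transform = response_transform, report = report,
         time_col = time_col, temp_col = temp_col, candidates = candidates),
    class = "trait_spec"
  )
}

#' @export
print.trait_spec <- function(x, ...) {
  cat("<trait_spec>", x$trait, "\n")
  cat("  response:", x$response,
      if (x$response_transform == "log") "(log)" else "", "\n")
  cat("  fixed:", deparse(x$fixed), "\n")
  if (length(x$random)) cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  invisible(x)
}

#' Default model specifications for the five physiological traits
#'
#' Encodes the model family used for each trait: growth as a linear function
#' of scaled time by treatment; critical thermal maximum with mass and age
#' covariates; routine metabolic rate as an exponential function of test
#' temperature (log response, linear temperature); maximum metabolic rate as
#' a function of log2 test temperature; aerobic scope as a second-order
#' polynomial of test temperature. Every spec carries the population by
#' acclimation interaction.
#'
#' @return Named list of [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  list(
    growth = trait_spec(
      "growth", response = "mass_g",
      fixed = ~ population * acclim * time_days_01,
      random = character(),
      report = "rate_per_day", time_col = "time_days",
      candidates = list(random = "tank")
    ),
    ctmax = trait_spec(
      "ctmax", response = "ctmax_C",
      fixed = ~ population * acclim + mass_g_z + age_dph_01,
      random = character(),
      candidates = list(random = "chamber")
    ),
    rmr = trait_spec(
      "rmr", response = "rmr",
      fixed = ~ population * acclim * test_temp_C_z,
      random = character(),
      response_transform = "log", temp_col = "test_temp_C",
      candidates = list(fixed = c("age_dph_01"), random = "tunnel_id")
    ),
    mmr = trait_spec(
      "mmr", response = "mmr",
      fixed = ~ population * acclim * log2_temp_z,
      random = character(),
      temp_col = "test_temp_C",
      candidates = list(fixed = c("condition_k_z", "age_dph_01"), random = "tunnel_id")
    ),
    as = trait_spec(
      "as", response = "aerobic_scope",
      fixed = ~ population * acclim * (test_temp_C_z + I(test_temp_C_z^2)),
      random = character(),
      temp_col = "test_temp_C",
      candidates = list(fixed = c("condition_k_z"))
    )
  )
}
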