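#' Plot treatment means with credible intervals
#'
#' Point estimates with 89% equal-tailed credible intervals per population,
#' coloured by acclimation temperature.
#'
#' @param object A [treatment_means()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot treatment_means
#' @export
autoplot.treatment_means <- function(object, ...) {
  df <- object %>%
    mutate(lo = purrr::map_dbl(.data$draws, quantile, 0.055),
           hi = purrr::map_dbl(.data$draws, quantile, 0.945))
  ggplot(df, aes(x = .data$population, y = .data$mean,
                 colour = factor(.data$acclim))) +
    geom_pointrange(aes(ymin = .data$lo, ymax = .data$hi),
                    position = position_dodge(width = 0.5)) +
    labs(x = NULL, y = unique(df$trait), colour = "Acclimation (°C)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Plot thermal optima
#'
#' @param object An [estimate_topt()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot topt_estimates
#' @export
autoplot.topt_estimates <- function(object, ...) {
  ggplot(object, aes(x = .data$population, y = .data$topt_C,
                     colour = factor(.data$acclim))) +
    geom_pointrange(aes(ymin = .data$topt_C - .data$sd_C,
                        ymax = .data$topt_C + .data$sd_C),
                    position = position_dodge(width = 0.5)) +
    geom_point(data = object[object$extrapolated, ], shape = 1, size = 4) +
    labs(x = NULL, y = "Thermal optimum (°C)",
         colour = "Acclimation (°C)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Association grid plot
#'
#' Tile grid of predictor-by-cell association classes (the screening
#' figure): direction sets the colour, significance the opacity; cells that
#' failed robustness or convergence appear grey.
#'
#' @param object An [screen_env_associations()] result tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot association_results
#' @export
autoplot.association_results <- function(object, ...) {
  df <- object %>%
    mutate(
      cell = ifelse(is.na(.data$test_temp_C),
                    paste0(.data$acclim, "°C"),
                    paste0(.data$acclim, "°C @", .data$test_temp_C)),
      class = dplyr::case_when(
        .data$significance %in% c("unavailable") ~ "unavailable",
        .data$significance == "none" ~ "none",
        TRUE ~ paste(.data$direction, .data$significance)
      )
    )
  ggplot(df, aes(x = .data$cell, y = .data$predictor, fill = .data$class)) +
    geom_tile(colour = "white") +
    facet_grid(cols = vars(.data$trait), scales = "free_x", space = "free_x") +
    scale_fill_manual(values = c(
      "positive strong" = "#b2182b", "positive weak" = "#ef8a62",
      "negative strong" = "#2166ac", "negative weak" = "#67a9cf",
      "none" = "grey90", "unavailable" = "grey60")) +
    labs(x = NULL, y = NULL, fill = "Association") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Thermal performance scatter with quadratic fit
#'
#' Observed aerobic scope against acute test temperature, with a quadratic
#' least-squares guide per acclimation group, faceted by population.
#'
#' @param data Metabolic data with `test_temp_C`, `aerobic_scope`,
#'   `population`, `acclim`.
#' @return A ggplot.
#' @export
plot_thermal_performance <- function(data) {
  ggplot(data, aes(x = .data$test_temp_C, y = .data$aerobic_scope,
                   colour = factor(.data$acclim))) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_smooth(method = "lm", formula = y ~ x + I(x^2), se = FALSE,
                linewidth = 0.6) +
    facet_wrap(vars(.data$population)) +
    labs(x = "Test temperature (°C)",
         y = "Aerobic scope (mgO₂ kg⁻¹ min⁻¹)",
         colour = "Acclimation (°C)") +
    theme_minimal()
}
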