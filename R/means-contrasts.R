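#' Posterior treatment means on the natural scale
#'
#' For every population by acclimation cell present in the training data the
#' fixed-effect linear predictor is evaluated per posterior draw at a
#' reference grid: z-scored covariates at their training means (z = 0),
#' 0--1 scaled time/age covariates at the cell-specific mean, factors other
#' than population/acclimation at their first level, and random intercepts
#' at zero. Draws are back-transformed from the z scale (and exponentiated
#' for log-response models). For growth (`report = "rate_per_day"`) the cell
#' quantity is the per-day growth rate implied by the time slope rather than
#' a mass level.
#'
#' @param fit A `trait_fit`.
#' @param draw_idx Optional subset of posterior draws.
#' @return Tibble: `population`, `acclim`, `trait`, `mean`, `sd`, and a
#'   `draws` list-column with the per-draw cell values (natural scale).
#' @export
treatment_means <- function(fit, draw_idx = NULL) {
  data <- fit$data
  if (!all(c("population", "acclim") %in% names(data))) {
    abort("Data behind the fit must contain `population` and `acclim`.")
  }
  cells <- distinct(data, .data$population, .data$acclim) %>%
    arrange(.data$population, .data$acclim)

  vars <- all.vars(stats::delete.response(fit$terms))
  covars <- setdiff(vars, c("population", "acclim"))

  ref_row <- function(pop, acc, overrides = list()) {
    row <- tibble(population = factor(pop, levels = levels(factor(data$population))),
                  acclim = factor(acc, levels = levels(factor(data$acclim))))
    cell_data <- data[data$population == pop & data$acclim == acc, , drop = FALSE]
    for (v in covars) {
      if (v %in% names(overrides)) { row[[v]] <- overrides[[v]]; next }
      x <- data[[v]]
      if (is.numeric(x)) {
        row[[v]] <- if (grepl("_01$", v)) mean(cell_data[[v]]) else mean(x)
      } else {
        row[[v]] <- factor(levels(factor(x))[1], levels = levels(factor(x)))
      }
    }
    row
  }

  # match factor handling to the training frame
  if (!is.factor(data$population)) data$population <- factor(data$population)
  if (!is.factor(data$acclim)) data$acclim <- factor(data$acclim)

  out <- purrr::map(seq_len(nrow(cells)), function(i) {
    pop <- as.character(cells$population[i]); acc <- as.character(cells$acclim[i])
    if (identical(fit$spec$report, "rate_per_day")) {
      tcol <- paste0(fit$spec$time_col, "_01")
      eta1 <- posterior_linpred(fit, ref_row(pop, acc, setNames(list(1), tcol)), draw_idx)
      eta0 <- posterior_linpred(fit, ref_row(pop, acc, setNames(list(0), tcol)), draw_idx)
      slope_z <- drop(eta1 - eta0)
      sc <- fit$scaling[fit$scaling$column == fit$spec$time_col, ]
      days <- sc$max - sc$min
      draws <- slope_z * fit$response_scaling$sd / days
    } else {
      eta <- drop(posterior_linpred(fit, ref_row(pop, acc), draw_idx))
      draws <- back_transform_response(eta, fit$response_scaling)
    }
    tibble(population = pop, acclim = acc, trait = fit$spec$trait,
           mean = mean(draws), sd = sd(draws), draws = list(draws))
  }) %>% purrr::list_rbind()
  class(out) <- c("treatment_means", class(out))
  out
}

#' Classify the directional significance of a posterior quantity
#'
#' Applies the posterior-mass rule: let p be the larger of Pr(q > 0) and
#' Pr(q < 0). The quantity is "strong" if p >= 0.945, "weak" if
#' 0.85 <= p < 0.945, and "none" otherwise; the direction is the sign
#' holding the majority mass. Thresholds are closed (>=).
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param strong,weak Posterior-mass thresholds.
#' @return List with `significance` ("strong"/"weak"/"none"), `direction`
#'   ("positive"/"negative"), and `p` (the majority mass).
#' @export
classify_significance <- function(draws, strong = 0.945, weak = 0.85) {
  if (length(draws) < 100) abort("At least 100 draws required to classify.")
  p_pos <- mean(draws > 0)
  p_neg <- mean(draws < 0)
  p <- max(p_pos, p_neg)
  list(
    significance = if (p >= strong) "strong" else if (p >= weak) "weak" else "none",
    direction = if (p_pos >= p_neg) "positive" else "negative",
    p = p
  )
}

#' All pairwise posterior contrasts between treatment cells
#'
#' Differences are taken draw-by-draw (draw index pairing), so each contrast
#' is a proper posterior of the difference; classification follows
#' [classify_significance()].
#'
#' @param means A [treatment_means()] tibble (or any tibble with
#'   `population`, `acclim` and a `draws` list-column).
#' @param strong,weak Thresholds passed to [classify_significance()].
#' @return Tibble with one row per unordered pair: group labels, posterior
#'   mean/sd of the difference (A minus B), direction and significance.
#' @export
pairwise_contrasts <- function(means, strong = 0.945, weak = 0.85) {
  n <- nrow(means)
  if (n < 2) abort("At least two cells required for contrasts.")
  len <- unique(purrr::map_int(means$draws, length))
  if (length(len) != 1) abort("All cells must carry the same number of draws.")
  lab <- paste(means$population, means$acclim, sep = ":")
  pairs <- utils::combn(n, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- means$draws[[i]] - means$draws[[j]]
    cl <- classify_significance(d, strong, weak)
    tibble(group_a = lab[i], group_b = lab[j],
           mean = mean(d), sd = sd(d),
           direction = cl$direction, significance = cl$significance, p = cl$p)
  }) %>% purrr::list_rbind()
}

#' Acclimation capacity of a population
#'
#' The posterior difference in a trait mean between the warm (20 C) and cold
#' (11 C) acclimated groups of the same population, with its significance
#' class. Paired draw-by-draw.
#'
#' @param means A [treatment_means()] tibble.
#' @param population Which population to evaluate.
#' @param warm,cold Acclimation labels to difference (warm minus cold).
#' @param strong,weak Classification thresholds.
#' @return One-row tibble: population, mean, sd, direction, significance,
#'   and the difference draws as a list-column.
#' @export
acclimation_capacity <- function(means, population, warm = "20", cold = "11",
                                 strong = 0.945, weak = 0.85) {
  rows <- means[means$population == population, , drop = FALSE]
  w <- rows[as.character(rows$acclim) == warm, ]
  c_ <- rows[as.character(rows$acclim) == cold, ]
  if (nrow(w) != 1 || nrow(c_) != 1) {
    abort(sprintf("Population `%s` must have exactly one %sC and one %sC cell.",
                  population, warm, cold),
          class = "aeroscope_invalid_input")
  }
  d <- w$draws[[1]] - c_$draws[[1]]
  cl <- classify_significance(d, strong, weak)
  tibble(population = population, trait = rows$trait[1],
         mean = mean(d), sd = sd(d),
         direction = cl$direction, significance = cl$significance,
         draws = list(d))
}
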