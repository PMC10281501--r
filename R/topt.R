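#' Vertex of a quadratic thermal performance curve
#'
#' For `y = a T^2 + b T + c` the stationary point is `-b / (2a)`; it is a
#' maximum (a usable thermal optimum) only when the curve is concave
#' (`a < 0`).
#'
#' @param a,b,c Quadratic coefficients (`a` must be nonzero).
#' @return List with `vertex` (temperature) and `concave` (logical).
#' @export
quadratic_vertex <- function(a, b, c = 0) {
  if (any(a == 0)) {
    abort("Degenerate curve: quadratic coefficient is zero.",
          class = "aeroscope_degenerate_curve")
  }
  list(vertex = -b / (2 * a), concave = a < 0)
}

#' Thermal optimum of aerobic scope from the model posterior
#'
#' For each population by acclimation cell, a configurable number of
#' posterior draws (default 500) of the aerobic-scope model are used to
#' simulate the AS curve over a fixed test-temperature grid (0.5 C steps
#' over the tested range); a quadratic is refit to each simulated curve and
#' its vertex taken as that draw's thermal optimum. The cell's T_opt is the
#' mean and SD of the concave-draw vertices, in degrees Celsius. For an
#' exactly quadratic model the refit reproduces the draw's own vertex, so
#' with zero posterior uncertainty this reduces to [quadratic_vertex()].
#'
#' @param fit A `trait_fit` of the aerobic-scope (quadratic) family. The
#'   spec's `temp_col` names the raw test-temperature column.
#' @param n_draws Posterior draws to use (sampled without replacement when
#'   the posterior holds more).
#' @param seed Integer seed for the draw subsample.
#' @param temp_range Tested temperature range in C; vertices whose mean
#'   falls outside are flagged `extrapolated`.
#' @param step Grid step in C.
#' @param max_nonconcave_frac Estimation fails for a cell when more than
#'   this fraction of draws yields a non-concave curve.
#' @return Tibble: `population`, `acclim`, `topt_C`, `sd_C`, `extrapolated`,
#'   `concave_frac`, `n_draws_used`, plus the vertex draws as a list-column.
#' @export
estimate_topt <- function(fit, n_draws = 500, seed, temp_range = c(8, 26),
                          step = 0.5, max_nonconcave_frac = 0.5) {
  if (missing(seed)) abort("`seed` is mandatory for estimate_topt().")
  if (is.null(fit$spec$temp_col)) abort("Spec has no `temp_col`; not a thermal model.")
  data <- fit$data
  total <- nrow(fit$draws)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  draw_idx <- if (total > n_draws) sample.int(total, n_draws) else seq_len(total)

  grid_T <- seq(temp_range[1], temp_range[2], by = step)
  tcol <- fit$spec$temp_col
  sc <- fit$scaling[fit$scaling$column == tcol, , drop = FALSE]
  if (nrow(sc) != 1) abort(sprintf("No scaling stored for `%s`.", tcol))

  cells <- distinct(data, .data$population, .data$acclim)
  vars <- all.vars(stats::delete.response(fit$terms))
  covars <- setdiff(vars, c("population", "acclim"))

  out <- purrr::map(seq_len(nrow(cells)), function(i) {
    pop <- as.character(cells$population[i]); acc <- as.character(cells$acclim[i])
    nd <- tibble(
      population = factor(pop, levels = levels(factor(data$population))),
      acclim = factor(acc, levels = levels(factor(data$acclim)))
    )[rep(1, length(grid_T)), ]
    for (v in covars) {
      x <- data[[v]]
      if (v == paste0(tcol, "_z")) {
        nd[[v]] <- (grid_T - sc$mean) / sc$sd
      } else if (v == "log2_temp_z") {
        lsc <- fit$scaling[fit$scaling$column == "log2_temp", , drop = FALSE]
        nd[[v]] <- (log2(grid_T) - lsc$mean) / lsc$sd
      } else if (is.numeric(x)) {
        nd[[v]] <- mean(x)
      } else {
        nd[[v]] <- factor(levels(factor(x))[1], levels = levels(factor(x)))
      }
    }
    eta <- posterior_linpred(fit, nd, draw_idx)      # grid x draws, z scale
    as_nat <- back_transform_response(eta, fit$response_scaling)
    T1 <- grid_T; T2 <- grid_T^2
    verts <- vapply(seq_len(ncol(as_nat)), function(d) {
      cf <- stats::lm.fit(cbind(1, T1, T2), as_nat[, d])$coefficients
      if (!is.finite(cf[3]) || cf[3] >= 0) return(NA_real_)
      -cf[2] / (2 * cf[3])
    }, numeric(1))
    concave_frac <- mean(is.finite(verts))
    if (1 - concave_frac > max_nonconcave_frac) {
      abort(sprintf(
        "T_opt estimation failed for %s:%s (%.0f%% of draws non-concave).",
        pop, acc, 100 * (1 - concave_frac)), class = "aeroscope_topt_failure")
    }
    v <- verts[is.finite(verts)]
    tibble(
      population = pop, acclim = acc,
      topt_C = mean(v), sd_C = sd(v),
      extrapolated = mean(v) < temp_range[1] || mean(v) > temp_range[2],
      concave_frac = concave_frac,
      n_draws_used = length(v),
      draws = list(verts)
    )
  }) %>% purrr::list_rbind()
  class(out) <- c("topt_estimates", class(out))
  out
}

#' Change in thermal optimum with warm acclimation
#'
#' Difference in T_opt between two acclimation groups of the same
#' population (warm minus cold). Where both cells carry vertex draws from
#' the same posterior draw subsample the difference is paired draw-by-draw;
#' otherwise the SD combines independently as sqrt(sd1^2 + sd2^2).
#'
#' @param est A [estimate_topt()] tibble (both cells), or the warm-cell row.
#' @param population Population to difference.
#' @param warm,cold Acclimation labels.
#' @param paired Pair draws by index when available (default `TRUE`).
#' @return One-row tibble: population, `delta_topt_C`, `sd_C`, `paired`.
#' @export
delta_topt <- function(est, population, warm = "20", cold = "11", paired = TRUE) {
  rows <- est[est$population == population, , drop = FALSE]
  w <- rows[as.character(rows$acclim) == warm, ]
  c_ <- rows[as.character(rows$acclim) == cold, ]
  if (nrow(w) != 1 || nrow(c_) != 1) {
    abort(sprintf("Population `%s` needs one %sC and one %sC estimate.",
                  population, warm, cold), class = "aeroscope_invalid_input")
  }
  mean_d <- w$topt_C - c_$topt_C
  dw <- w$draws[[1]]; dc <- c_$draws[[1]]
  if (paired && length(dw) == length(dc)) {
    d <- dw - dc
    sd_d <- sd(d[is.finite(d)])
  } else {
    paired <- FALSE
    sd_d <- sqrt(w$sd_C^2 + c_$sd_C^2)
  }
  tibble(population = population, delta_topt_C = mean_d, sd_C = sd_d,
         paired = paired)
}
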