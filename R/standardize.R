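#' Standardize covariates for model fitting
#'
#' Centres and scales the named columns to z-scores (`<col>_z`) and rescales
#' the named columns to the unit interval (`<col>_01`), storing the scaling
#' parameters so every transform is invertible. Covariates such as mass,
#' condition factor and test temperature enter the trait models as z-scores;
#' time since first measurement and fish age enter as 0--1 scaled values.
#'
#' @param data A data frame.
#' @param z_cols Character vector of columns to z-score.
#' @param unit_cols Character vector of columns to rescale to \[0, 1\].
#' @return `data` with the transformed columns appended and a `"scaling"`
#'   attribute (tibble of column, mean, sd, min, max) for inversion via
#'   [unstandardize()].
#' @export
standardize <- function(data, z_cols = character(), unit_cols = character()) {
  stopifnot(is.data.frame(data))
  sc <- list()
  for (col in z_cols) {
    x <- data[[col]]
    if (!is.numeric(x)) abort(sprintf("Column `%s` is not numeric.", col))
    if (length(x) < 2) abort("At least two rows required to standardize.")
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Column `%s` has zero variance; cannot z-score.", col),
            class = "aeroscope_zero_variance")
    }
    data[[paste0(col, "_z")]] <- (x - mean(x)) / s
    sc[[length(sc) + 1]] <- tibble(column = col, mean = mean(x), sd = s,
                                   min = NA_real_, max = NA_real_)
  }
  for (col in unit_cols) {
    x <- data[[col]]
    if (!is.numeric(x)) abort(sprintf("Column `%s` is not numeric.", col))
    rng <- range(x)
    if (diff(rng) == 0) {
      abort(sprintf("Column `%s` has zero range; cannot rescale to [0, 1].", col),
            class = "aeroscope_zero_variance")
    }
    data[[paste0(col, "_01")]] <- (x - rng[1]) / diff(rng)
    sc[[length(sc) + 1]] <- tibble(column = col, mean = NA_real_, sd = NA_real_,
                                   min = rng[1], max = rng[2])
  }
  attr(data, "scaling") <- purrr::list_rbind(sc)
  data
}

#' Invert a standardization
#'
#' @param values Numeric vector on the transformed scale.
#' @param scaling The `"scaling"` attribute produced by [standardize()].
#' @param column Which original column the values belong to.
#' @return Values on the original scale.
#' @export
unstandardize <- function(values, scaling, column) {
  row <- scaling[scaling$column == column, , drop = FALSE]
  if (nrow(row) != 1) abort(sprintf("No scaling stored for column `%s`.", column))
  if (is.finite(row$sd)) values * row$sd + row$mean
  else values * (row$max - row$min) + row$min
}
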