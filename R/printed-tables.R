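#' Published treatment-level summary tables
#'
#' Accessors for the treatment-level summaries shipped with the package:
#' population metadata (hatchery latitude, elevation, outmigration
#' distance), per-treatment growth rates, modeled and observed critical
#' thermal maxima, and metabolic summaries (RMR Q10, aerobic scope at the
#' thermal optimum, T_opt). These seed the synthetic-data generator's
#' default ground truth and provide the worked-example arithmetic for
#' acclimation capacities and T_opt shifts.
#'
#' @param table One of `"populations"`, `"growth"`, `"ctmax"`,
#'   `"metabolic"`, `"env"`. The `"env"` table carries the real latitude,
#'   migration distance and migration slope per population alongside
#'   synthetic stream-temperature metrics (the field values are not published
#'   at this granularity), so it is an emulation suitable for exercising the
#'   screen, not field data.
#' @return A tibble.
#' @export
published_table <- function(table = c("populations", "growth", "ctmax",
                                      "metabolic", "env")) {
  table <- match.arg(table)
  file <- switch(table,
    populations = "population_metadata.csv",
    growth = "treatment_growth.csv",
    ctmax = "treatment_ctmax.csv",
    metabolic = "treatment_metabolic.csv",
    env = "env_predictors_synthetic.csv"
  )
  path <- system.file("extdata", file, package = "aeroscope")
  if (path == "") abort(sprintf("Bundled table `%s` not found.", file))
  as_tibble(read.csv(path, check.names = FALSE))
}
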