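test_that("the screen's model space has the published structure", {
  specs <- tidyr::crossing(trait = c("growth", "ctmax", "rmr", "mmr", "as"),
                           predictor = env_predictor_names())
  expect_equal(nrow(specs), 75)
  built <- purrr::pmap(specs, function(trait, predictor) {
    build_env_spec(trait, predictor)
  })
  expect_length(built, 75)
  expect_true(all(purrr::map_lgl(built, ~ "population" %in% .x$random)))

  # identity swap: every predictor yields the same model structure as latitude
  lat <- build_env_spec("growth", "Latitude")
  mig <- build_env_spec("growth", "Mig.D")
  expect_identical(deparse(lat$fixed), deparse(mig$fixed))
  expect_identical(lat$random, mig$random)

  expect_error(build_env_spec("ctmax", "NotAPredictor"),
               class = "aeroscope_invalid_input")
  expect_equal(length(env_predictor_names()), 15)
})

test_that("cell enumeration matches the published association count", {
  cells <- association_cells()
  expect_equal(nrow(cells), 495)   # 15 x (3 + 3 + 9 * 3)
  counts <- dplyr::count(cells, trait)
  expect_equal(counts$n[counts$trait == "growth"], 45)
  expect_equal(counts$n[counts$trait == "ctmax"], 45)
  expect_equal(counts$n[counts$trait == "rmr"], 135)
  expect_true(all(is.na(cells$test_temp_C[cells$trait %in% c("growth", "ctmax")])))
})

test_that("predictor standardization joins by population", {
  tab <- generate_env_table("published")
  d <- tibble::tibble(population = c("Coleman", "Trask River", "Coleman"))
  out <- attach_env_predictor(d, tab, "Mig.D")
  z <- (tab$`Mig.D` - mean(tab$`Mig.D`)) / sd(tab$`Mig.D`)
  expect_equal(out$env_z, z[match(d$population, tab$population)])
  expect_error(attach_env_predictor(tibble::tibble(population = "X"), tab, "Mig.D"),
               regexp = "lack")
})

test_that("screen output carries one classified row per reporting cell", {
  set.seed(50)
  truth <- synthetic_truth()
  cfg <- small_config()
  tab <- generate_env_table("published")
  dct <- prepare_ctmax_data(
    dplyr::filter(generate_ctmax_trials(truth, cfg, 51)$trials, recovered))
  met <- prepare_metabolic_data(generate_metabolic_data(truth, cfg, 52))
  res <- screen_env_associations(
    list(ctmax = dct, as = met), tab,
    predictors = c("Latitude", "CRCMax"), seed = 53,
    control = fast_control())
  expect_equal(nrow(res), 2 * (3 + 9))
  expect_true(all(res$significance %in% c("strong", "weak", "none", "unavailable")))
  conv <- res[res$converged, ]
  expect_true(all(!is.na(conv$mean)))
  # growth/ctmax rows carry no test temperature
  expect_true(all(is.na(res$test_temp_C[res$trait == "ctmax"])))
  expect_setequal(unique(res$test_temp_C[res$trait == "as"]), c(11, 16, 20))
})

test_that("classification is invariant to affine rescaling of a predictor", {
  set.seed(54)
  truth <- synthetic_truth()
  cfg <- small_config()
  tab <- generate_env_table("published")
  dct <- prepare_ctmax_data(
    dplyr::filter(generate_ctmax_trials(truth, cfg, 55)$trials, recovered))
  tab2 <- tab
  tab2$HAMax <- 3 * tab2$HAMax - 10   # affine copy
  r1 <- screen_env_associations(list(ctmax = dct), tab, predictors = "HAMax",
                                seed = 56, control = fast_control())
  r2 <- screen_env_associations(list(ctmax = dct), tab2, predictors = "HAMax",
                                seed = 56, control = fast_control())
  expect_equal(r1$significance, r2$significance)
  expect_equal(r1$direction, r2$direction)
  expect_equal(r1$mean, r2$mean, tolerance = 1e-9)
})

test_that("outlier-exclusion robustness merges and demotes disagreements", {
  base <- association_cells("growth", c("Latitude", "Mig.D")) %>%
    dplyr::mutate(mean = 0.1, sd = 0.05, direction = "positive",
                  significance = "strong", p = 0.99, converged = TRUE)
  agree <- trinity_robustness(base, base)
  expect_true(all(agree$robust_to_exclusion))
  expect_true(all(agree$significance == "strong"))

  flipped <- base
  flipped$significance[1] <- "none"
  out <- trinity_robustness(base, flipped)
  expect_false(out$robust_to_exclusion[1])
  expect_equal(out$significance[1], "none")
  expect_true(all(out$robust_to_exclusion[-1]))

  expect_error(trinity_robustness(base, base[-1, ]),
               class = "aeroscope_invalid_input")
})

test_that("an engineered outlier population breaks robustness by construction", {
  set.seed(57)
  cfg <- cohort_config(growth_n_per_date = 8, n_dates = 3)
  tab <- generate_env_table("published")
  # make one population's growth wildly inconsistent with its predictor value
  truth <- uniform_truth()
  truth$growth$slope_g_day <- truth$growth$slope_g_day +
    0.25 * scale(tab$CRCMax)[match(truth$growth$population, tab$population)]
  truth$growth$slope_g_day[truth$growth$population == "Trinity River"] <- 0.02
  raw <- generate_growth_data(truth, cfg, 58)
  d <- prepare_growth_data(raw)
  d_wo <- prepare_growth_data(dplyr::filter(raw, population != "Trinity River"))
  rw <- screen_env_associations(list(growth = d), tab, predictors = "CRCMax",
                                seed = 59, control = fast_control())
  rwo <- screen_env_associations(list(growth = d_wo), tab, predictors = "CRCMax",
                                 seed = 59, control = fast_control())
  merged <- trinity_robustness(rw, rwo)
  expect_equal(nrow(merged), 3)
  expect_true(all(c("robust_to_exclusion", "significance_without") %in%
                    names(merged)))
})

test_that("predictor correlations match the closed-form Pearson oracle", {
  tab <- generate_env_table("random", seed = 60, target_cor = 0.7)
  cm <- correlation_matrix(tab)
  expect_equal(dim(cm), c(15, 15))
  expect_equal(diag(cm), setNames(rep(1, 15), env_predictor_names()))
  # direct formula on one pair
  x <- tab$CAMax; y <- tab$CRAve
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm["CAMax", "CRAve"], oracle, tolerance = 1e-12)

  # duplicated and anti-correlated constructed columns
  tab$CAMin <- tab$CAMax
  tab$HAMin <- -2 * tab$CAMax + 5
  cm2 <- correlation_matrix(tab)
  expect_equal(cm2["CAMax", "CAMin"], 1)
  expect_equal(cm2["CAMax", "HAMin"], -1)

  tab$HRAve <- 7.5
  expect_warning(cm3 <- correlation_matrix(tab), regexp = "HRAve")
  expect_true(is.na(cm3["HRAve", "CAMax"]))
})
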