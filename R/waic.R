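#' Widely applicable information criterion
#'
#' Computed from a draws-by-observations pointwise log-likelihood matrix:
#' `lppd = sum_i log mean_d exp(ll_id)` (evaluated with log-sum-exp
#' stabilisation), `p_waic = sum_i var_d(ll_id)`, and
#' `waic = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param loglik Matrix of pointwise log-likelihoods, rows = posterior draws,
#'   columns = observations. All entries must be finite.
#' @return List with `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(loglik) {
  stopifnot(is.matrix(loglik))
  if (any(!is.finite(loglik))) {
    abort("Non-finite entries in the log-likelihood matrix.",
          class = "aeroscope_invalid_input")
  }
  nd <- nrow(loglik)
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, var))
  if (nd == 1) p_waic <- 0
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Stepwise WAIC model selection
#'
#' Greedy search over a spec's candidate terms: forward addition of the
#' candidate (fixed term or random intercept) that most lowers WAIC while
#' any lowers it, then a single backward pass attempting to drop each
#' adopted candidate. The full ledger of every model tried is returned so
#' the search path is auditable.
#'
#' @param data Model data (see [fit_trait_model()]).
#' @param spec Base [trait_spec()]; its `candidates` field lists the search
#'   space (`fixed` term labels and `random` grouping columns).
#' @param priors,control,seed Passed to [fit_trait_model()]. The control is
#'   forced to `on_nonconverged = "flag"`; non-converged candidates are
#'   recorded in the ledger and never adopted.
#' @return List with `spec` (the selected [trait_spec()]), `fit` (its
#'   `trait_fit`), and `ledger` (tibble: step, action, term, waic, adopted).
#' @export
stepwise_select <- function(data, spec, priors = prior_settings(),
                            control = sampler_control(), seed) {
  if (missing(seed)) abort("`seed` is mandatory for stepwise_select().")
  control$on_nonconverged <- "flag"
  cand_fixed <- spec$candidates$fixed %||% character()
  cand_random <- spec$candidates$random %||% character()

  amend <- function(sp, fixed_terms, random_terms) {
    out <- sp
    if (length(fixed_terms)) {
      out$fixed <- stats::update(sp$fixed,
                                 paste("~ . +", paste(fixed_terms, collapse = " + ")))
    }
    out$random <- union(sp$random, random_terms)
    out
  }

  counter <- 0L
  fit_one <- function(fx, rd) {
    counter <<- counter + 1L
    sp <- amend(spec, fx, rd)
    f <- fit_trait_model(data, sp, priors, control,
                         seed = (as.integer(seed) + counter) %% .Machine$integer.max)
    list(spec = sp, fit = f,
         waic = if (f$converged) compute_waic(f$loglik)$waic else Inf,
         converged = f$converged)
  }

  in_fixed <- character(); in_random <- character()
  current <- fit_one(in_fixed, in_random)
  ledger <- tibble(step = 0L, action = "base", term = NA_character_,
                   waic = current$waic, adopted = TRUE)
  step <- 0L

  repeat {  # forward
    remaining <- list()
    for (t in setdiff(cand_fixed, in_fixed)) remaining <- c(remaining, list(list(kind = "fixed", term = t)))
    for (g in setdiff(cand_random, in_random)) remaining <- c(remaining, list(list(kind = "random", term = g)))
    if (!length(remaining)) break
    step <- step + 1L
    trials <- purrr::map(remaining, function(r) {
      fx <- if (r$kind == "fixed") c(in_fixed, r$term) else in_fixed
      rd <- if (r$kind == "random") c(in_random, r$term) else in_random
      c(r, fit_one(fx, rd))
    })
    waics <- purrr::map_dbl(trials, "waic")
    best <- which.min(waics)
    improved <- waics[best] < current$waic
    ledger <- bind_rows(ledger, tibble(
      step = step, action = "forward-add",
      term = purrr::map_chr(trials, "term"), waic = waics,
      adopted = improved & seq_along(trials) == best
    ))
    if (!improved) break
    r <- trials[[best]]
    if (r$kind == "fixed") in_fixed <- c(in_fixed, r$term) else in_random <- c(in_random, r$term)
    current <- trials[[best]]
  }

  # single backward pass over adopted candidates
  for (t in c(in_fixed, in_random)) {
    step <- step + 1L
    fx <- setdiff(in_fixed, t); rd <- setdiff(in_random, t)
    trial <- fit_one(fx, rd)
    drop_it <- trial$waic < current$waic
    ledger <- bind_rows(ledger, tibble(
      step = step, action = "backward-drop", term = t,
      waic = trial$waic, adopted = drop_it
    ))
    if (drop_it) {
      in_fixed <- fx; in_random <- rd
      current <- trial
    }
  }

  list(spec = current$spec, fit = current$fit, ledger = ledger)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
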