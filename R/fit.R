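#' Fit a Bayesian Gaussian mixed model for one trait
#'
#' Z-scores the (optionally log-transformed) response, builds the fixed and
#' random-intercept design from the [trait_spec()], and samples the joint
#' posterior with a blocked Gibbs sampler ([sampler_control()] governs chains
#' and draw counts; at least 2000 retained draws by default). Convergence is
#' checked with split-Rhat on every parameter and a failing fit errors (or is
#' flagged, see [sampler_control()]) rather than returning silently bad
#' draws. The pointwise log-likelihood matrix is stored for WAIC.
#'
#' @param data A data frame, typically passed through [standardize()] so the
#'   columns referenced by the spec's fixed formula exist. The `"scaling"`
#'   attribute is carried into the fit for back-transformation.
#' @param spec A [trait_spec()].
#' @param priors See [prior_settings()].
#' @param control See [sampler_control()].
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `trait_fit` with posterior draws, pointwise
#'   log-likelihoods, diagnostics and design metadata. Use [tidy()] /
#'   [glance()] for summaries, [treatment_means()] and [estimate_topt()]
#'   downstream.
#' @export
fit_trait_model <- function(data, spec, priors = prior_settings(),
                            control = sampler_control(), seed) {
  if (missing(seed)) abort("`seed` is mandatory for fit_trait_model().")
  stopifnot(inherits(spec, "trait_spec"), is.data.frame(data))

  y_raw <- data[[spec$response]]
  if (is.null(y_raw)) abort(sprintf("Response column `%s` not found.", spec$response))
  if (anyNA(y_raw)) abort("Response contains missing values; filter first.")
  y_t <- if (spec$response_transform == "log") {
    if (any(y_raw <= 0)) abort("Log response transform requires positive values.")
    log(y_raw)
  } else y_raw
  mu_y <- mean(y_t); sd_y <- sd(y_t)
  if (!is.finite(sd_y) || sd_y == 0) {
    abort("Response has zero variance.", class = "aeroscope_zero_variance")
  }
  y <- (y_t - mu_y) / sd_y

  mf <- stats::model.frame(spec$fixed, data, na.action = stats::na.fail)
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  xlev <- stats::.getXlevels(trm, mf)

  Zs <- list()
  random_levels <- list()
  for (g in spec$random) {
    f <- factor(data[[g]])
    if (is.null(data[[g]])) abort(sprintf("Random grouping column `%s` not found.", g))
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- paste0(g, "[", levels(f), "]")
    Zs[[g]] <- Z
    random_levels[[g]] <- levels(f)
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  fit <- gibbs_lmm(y, X, Zs, priors, control$chains, control$warmup, control$iter)

  # diagnostics over all scalar parameters
  par_mat <- cbind(fit$theta, sigma = fit$sigma)
  if (length(Zs)) {
    tau <- fit$tau
    colnames(tau) <- paste0("tau[", names(Zs), "]")
    par_mat <- cbind(par_mat, tau)
  }
  rhat <- apply(par_mat, 2, split_rhat, chain_id = fit$chain_id)
  diagnostics <- tibble(
    parameter = colnames(par_mat),
    mean = colMeans(par_mat),
    sd = apply(par_mat, 2, sd),
    rhat = rhat
  )
  converged <- all(is.na(rhat) | rhat < control$rhat_max)
  if (!converged && control$on_nonconverged == "error") {
    worst <- diagnostics[order(-diagnostics$rhat), ]
    abort(
      paste0("Sampler did not converge (split-Rhat >= ", control$rhat_max, "): ",
             paste(sprintf("%s (%.3f)", head(worst$parameter, 3),
                           head(worst$rhat, 3)), collapse = ", ")),
      class = "aeroscope_nonconverged"
    )
  }

  # pointwise log-likelihood on the z-scored scale (constant Jacobian across
  # candidate models for the same response, so WAIC comparisons are valid)
  mu <- fit$C %*% t(fit$theta)                      # n x draws
  ll <- dnorm(y, mu, rep(fit$sigma, each = length(y)), log = TRUE)
  loglik <- t(matrix(ll, nrow = length(y)))          # draws x n

  structure(
    list(
      spec = spec,
      draws = fit$theta, sigma = fit$sigma, tau = fit$tau,
      chain_id = fit$chain_id, p_fixed = fit$p,
      terms = trm, xlev = xlev,
      random_levels = random_levels,
      response_scaling = list(mean = mu_y, sd = sd_y,
                              transform = spec$response_transform),
      scaling = attr(data, "scaling"),
      data = as_tibble(data),
      loglik = loglik,
      diagnostics = diagnostics,
      converged = converged,
      n_obs = length(y),
      seed = seed
    ),
    class = "trait_fit"
  )
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("<trait_fit>", x$spec$trait, "on", x$n_obs, "observations;",
      nrow(x$draws), "posterior draws\n")
  cat("  converged:", x$converged,
      " max Rhat:", format(max(x$diagnostics$rhat, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Posterior linear predictor at new data
#'
#' Evaluates the fixed-effect linear predictor (z-scale) for every posterior
#' draw at the rows of `newdata`. Random intercepts are marginalised at zero,
#' i.e. predictions are for a typical group.
#'
#' @param fit A `trait_fit`.
#' @param newdata Data frame containing the covariates used by the fixed
#'   formula.
#' @param draw_idx Optional integer vector selecting posterior draws.
#' @return Matrix, rows = `nrow(newdata)`, columns = draws.
#' @export
posterior_linpred <- function(fit, newdata, draw_idx = NULL) {
  trm <- stats::delete.response(fit$terms)
  mf <- stats::model.frame(trm, newdata, xlev = fit$xlev, na.action = stats::na.fail)
  Xn <- stats::model.matrix(trm, mf)
  beta <- fit$draws[, seq_len(fit$p_fixed), drop = FALSE]
  if (!is.null(draw_idx)) beta <- beta[draw_idx, , drop = FALSE]
  Xn %*% t(beta)
}

# z-scale draws -> natural response scale
back_transform_response <- function(z, response_scaling) {
  y <- z * response_scaling$sd + response_scaling$mean
  if (response_scaling$transform == "log") exp(y) else y
}

#' @rdname fit_trait_model
#' @param x A `trait_fit` object.
#' @param ... Unused.
#' @method tidy trait_fit
#' @export
tidy.trait_fit <- function(x, ...) {
  d <- x$diagnostics
  qs <- apply(cbind(x$draws, sigma = x$sigma), 2, quantile, c(0.055, 0.945))
  d$conf.low <- NA_real_; d$conf.high <- NA_real_
  common <- intersect(d$parameter, colnames(qs))
  d$conf.low[match(common, d$parameter)] <- qs[1, common]
  d$conf.high[match(common, d$parameter)] <- qs[2, common]
  d %>% rename(term = "parameter", estimate = "mean", std.error = "sd")
}

#' @rdname fit_trait_model
#' @method glance trait_fit
#' @export
glance.trait_fit <- function(x, ...) {
  w <- compute_waic(x$loglik)
  tibble(
    trait = x$spec$trait,
    n_obs = x$n_obs,
    n_draws = nrow(x$draws),
    waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
    sigma = mean(x$sigma),
    rhat_max = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$converged
  )
}
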