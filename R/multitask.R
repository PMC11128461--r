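# Multitasking (chewing while vigilant): Bernoulli mixed model over
# vigilance minutes with a random intercept per focal observation
# (session), mirroring the Dirichlet model's prior family.

#' Extract vigilance minutes with their session covariates
#'
#' One record per vigilance minute: the chewing (multitask) flag joined to
#' the session's covariates.  Vigilance minutes lacking a chewing flag are
#' dropped with a message.
#'
#' @param minutes per-minute records with `session_id`, `behavior`,
#'   `chewing`.
#' @param sessions session-level covariates with `session_id`.
#' @return A tibble of vigilance minutes with a 0/1 `multitask` column.
#' @export
extract_vigilance_minutes <- function(minutes, sessions) {
  vig <- dplyr::filter(minutes, .data$behavior == "vigilance")
  n_na <- sum(is.na(vig$chewing))
  if (n_na > 0) {
    message("dropping ", n_na, " vigilance minute(s) without a chewing flag")
    vig <- dplyr::filter(vig, !is.na(.data$chewing))
  }
  vig |>
    dplyr::transmute(session_id = .data$session_id,
                     multitask = as.integer(.data$chewing)) |>
    dplyr::inner_join(tibble::as_tibble(sessions), by = "session_id")
}

#' Fit the Bayesian multitasking model
#'
#' Logistic regression of the per-minute multitask flag on session
#' covariates with a session-level random intercept (non-centered:
#' SD ~ half-t(3, 0, 2.5), standardized effects ~ N(0, 1)); intercept prior
#' Student-t(3, 0, 2.5), flat slopes.  Risk metrics may enter raw or
#' log-transformed (see [log_risk()]) via the formula.
#'
#' @param data vigilance-minute records from [extract_vigilance_minutes()].
#' @param formula right-hand-side fixed-effects formula, e.g.
#'   `~ maternal * risk_z + openness_z`.
#' @param session name of the observation (session) grouping column, or
#'   `NULL` to omit the random effect.
#' @param response name of the 0/1 response column.
#' @param config an [mcmc_config()].
#' @param prior_only sample the prior (intercept-only, no random effect).
#' @param centered random-effect parameterization; the default non-centered
#'   form suits the few vigilance minutes per session.
#' @return An object of class `multitask_fit`.
#' @export
fit_multitask <- function(data, formula, session = "session_id",
                          response = "multitask",
                          config = mcmc_preset("fast"),
                          prior_only = FALSE, centered = FALSE) {
  y <- as.numeric(data[[response]])
  stopifnot(all(y %in% c(0, 1)))
  if (!is.null(session) && length(unique(data[[session]])) < 2) {
    stop("need vigilance minutes from at least two sessions", call. = FALSE)
  }
  if (all(y == y[1])) {
    warning("all multitask flags identical; intercept weakly identified",
            call. = FALSE)
  }
  des <- build_design(formula, data)
  W <- des$X
  q <- ncol(W)
  if (prior_only && (q > 1 || !is.null(session))) {
    stop("prior-only sampling requires an intercept-only model without ",
         "random effects", call. = FALSE)
  }
  if (qr(W)$rank < q) stop("design matrix is rank deficient", call. = FALSE)
  if (is.null(session)) {
    sidx <- integer(length(y)); S <- 0L; sess_levels <- character()
  } else {
    sf <- factor(data[[session]])
    sidx <- as.integer(sf) - 1L; S <- nlevels(sf); sess_levels <- levels(sf)
  }
  pbar <- min(max(mean(y), 0.02), 0.98)
  start <- c(stats::qlogis(pbar), rep(0, q - 1),
             if (S > 0) c(log(0.3), rep(0, S)))
  lp_grad <- function(th) {
    bernoulli_lp_cpp(th, W, y, sidx, S, prior_only, centered)
  }
  prec <- laplace_precondition(
    lp_grad, start, anchor_idx = if (S > 0) q + 1L else NULL)
  set.seed(config$seed)
  res <- bernoulli_sample_cpp(W, y, sidx, S, prec$mode, prec$L,
                              config$chains, config$warmup, config$iter,
                              config$eps0, config$jitter, config$thin_loglik,
                              config$leapfrog, prior_only, centered)
  nm <- c(colnames(W), if (S > 0) c("log_session_sd",
                                    paste0("v[", sess_levels, "]")))
  fit <- finalize_mcmc_fit(res, nm, config, "multitask_fit")
  fit$formula <- formula
  fit$terms <- des$terms
  fit$xlev <- des$xlev
  fit$dims <- list(q = q, S = S, m = length(y))
  fit$prior_only <- prior_only
  fit$centered <- centered
  fit
}

#' Predicted multitasking probability over a covariate grid
#'
#' Inverse-logit of the per-draw fixed-effect linear predictor (random
#' effect at zero), summarized by the median and an equal-tailed credible
#' interval.
#'
#' @param fit a [fit_multitask()] model.
#' @param grid data frame of covariate values.
#' @param prob credible-interval mass.
#' @return A tibble: grid columns plus `estimate`, `conf.low`, `conf.high`.
#' @export
predict_multitask <- function(fit, grid, prob = 0.9) {
  stopifnot(inherits(fit, "multitask_fit"))
  miss <- setdiff(all.vars(fit$formula), names(grid))
  if (length(miss)) {
    stop("grid lacks model covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Wn <- build_design(fit$formula, grid, xlev = fit$xlev)$X
  pr <- stats::plogis(Wn %*% t(fit$draws[, seq_len(fit$dims$q),
                                         drop = FALSE]))
  a <- (1 - prob) / 2
  out <- tibble::as_tibble(grid)
  out$estimate <- apply(pr, 1, stats::median)
  out$conf.low <- apply(pr, 1, stats::quantile, probs = a)
  out$conf.high <- apply(pr, 1, stats::quantile, probs = 1 - a)
  out
}

#' Per-observation log predictive density for new vigilance minutes
#'
#' Session effects for held-out minutes are drawn from their prior per
#' posterior draw (held-out sessions are new groups).
#'
#' @param fit a [fit_multitask()] model.
#' @param newdata held-out vigilance-minute records.
#' @param draws number of stored draws to use.
#' @param response name of the 0/1 response column.
#' @return A draws x observations matrix of log densities.
#' @export
loglik_multitask <- function(fit, newdata, draws = 400,
                             response = "multitask") {
  y <- as.numeric(newdata[[response]])
  Wn <- build_design(fit$formula, newdata, xlev = fit$xlev)$X
  S_all <- nrow(fit$draws)
  keep <- unique(round(seq(1, S_all, length.out = min(draws, S_all))))
  gam <- fit$draws[keep, seq_len(fit$dims$q), drop = FALSE]
  tau <- if (fit$dims$S > 0) exp(fit$draws[keep, "log_session_sd"]) else NULL
  sess_new <- factor(newdata$session_id %||% seq_along(y))
  out <- matrix(NA_real_, length(keep), length(y))
  for (s in seq_along(keep)) {
    eta <- drop(Wn %*% gam[s, ])
    if (!is.null(tau)) {
      v <- stats::rnorm(nlevels(sess_new))
      eta <- eta + tau[s] * v[as.integer(sess_new)]
    }
    out[s, ] <- y * eta - log1p(exp(eta))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
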