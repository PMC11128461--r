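# Bayesian Dirichlet regression of session-level behavior compositions:
# multinomial-logit link per non-reference category (reference: traveling,
# linear predictor 0), scalar log-scale precision, herd random intercepts
# per non-reference category (non-centered), MALA posterior sampling.

build_design <- function(formula, data, xlev = NULL) {
  mf <- stats::model.frame(stats::delete.response(stats::terms(formula)),
                           data, xlev = xlev, na.action = stats::na.fail)
  list(X = stats::model.matrix(attr(mf, "terms"), mf),
       terms = attr(mf, "terms"),
       xlev = stats::.getXlevels(attr(mf, "terms"), mf))
}

#' Fit the Dirichlet behavior-composition model
#'
#' Models session compositions `y_i ~ Dirichlet(mu_i * phi)` where for each
#' non-reference category `log(mu_c / mu_ref)` is a linear function of the
#' session covariates plus a herd random intercept.  Priors: flat on slopes,
#' Student-t(3, 0, 2.5) on intercepts, gamma(0.01, 0.01) on `phi`,
#' half-t(3, 0, 2.5) on the herd SD with standard-normal standardized
#' effects.  Compositions are squeezed off the boundary with
#' [squeeze_simplex()] before the likelihood is evaluated.
#'
#' @param data compositions from [sessions_to_compositions()] joined with
#'   session covariates: category proportion columns, `n_minutes`, the
#'   formula variables and the herd column.
#' @param formula right-hand-side formula of fixed effects,
#'   e.g. `~ diel + herd_size_z + risk_z`.
#' @param herd name of the herd grouping column, or `NULL` for no random
#'   effect.
#' @param reference reference behavior category (linear predictor 0).
#' @param config an [mcmc_config()].
#' @param prior_only sample the prior instead of the posterior
#'   (intercept-only models without random effects only).
#' @param centered use the centered random-effect parameterization
#'   (effects ~ N(0, sd^2)); the default, because behavior data are
#'   group-informative (many sessions per herd) and the centered geometry
#'   then mixes better.  Set `FALSE` for the non-centered form.
#' @return An object of class `dirichlet_fit` (see [tidy.mcmc_fit()],
#'   [conditional_effects()], [psis_loo()]).
#' @export
fit_behavior_dirichlet <- function(data, formula, herd = "herd_id",
                                   reference = "traveling",
                                   config = mcmc_preset("fast"),
                                   prior_only = FALSE, centered = TRUE) {
  cats <- behavior_categories()
  stopifnot(all(cats %in% names(data)), reference %in% cats)
  ord <- c(setdiff(cats, reference), reference)
  y <- squeeze_simplex(as.matrix(data[ord]), data$n_minutes)
  logY <- log(y)
  des <- build_design(formula, data)
  X <- des$X
  p <- ncol(X); K <- length(ord) - 1L
  if (prior_only && (p > 1 || !is.null(herd))) {
    stop("prior-only sampling requires an intercept-only model without ",
         "random effects (slope priors are flat)", call. = FALSE)
  }
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  if (is.null(herd)) {
    hidx <- integer(nrow(X)); H <- 0L; herd_levels <- character()
  } else {
    hf <- factor(data[[herd]])
    hidx <- as.integer(hf) - 1L; H <- nlevels(hf); herd_levels <- levels(hf)
  }
  start <- c(
    rbind(log(pmax(colMeans(y[, seq_len(K), drop = FALSE]), 1e-6) /
                max(mean(y[, K + 1]), 1e-6)),
          matrix(0, p - 1, K)),
    log(20),
    if (H > 0) c(log(0.3), rep(0, H * K))
  )
  lp_grad <- function(th) {
    dirichlet_lp_cpp(th, X, logY, hidx, H, prior_only, centered)
  }
  prec <- laplace_precondition(
    lp_grad, start, anchor_idx = if (H > 0) p * K + 2L else NULL)
  set.seed(config$seed)
  res <- dirichlet_sample_cpp(X, logY, hidx, H, prec$mode, prec$L,
                              config$chains, config$warmup, config$iter,
                              config$eps0, config$jitter, config$thin_loglik,
                              config$leapfrog, prior_only, centered)
  nm <- c(
    as.vector(outer(colnames(X), ord[seq_len(K)],
                    function(t, c) paste0(c, "~", t))),
    "log_phi",
    if (H > 0) c("log_herd_sd",
                 as.vector(outer(herd_levels, ord[seq_len(K)],
                                 function(h, c) paste0("z[", h, ",", c, "]"))))
  )
  fit <- finalize_mcmc_fit(res, nm, config, "dirichlet_fit")
  fit$categories <- ord
  fit$reference <- reference
  fit$formula <- formula
  fit$terms <- des$terms
  fit$xlev <- des$xlev
  fit$herd <- herd
  fit$herd_levels <- herd_levels
  fit$dims <- list(p = p, K = K, H = H, n = nrow(X))
  fit$prior_only <- prior_only
  fit$centered <- centered
  fit
}

# draws of beta for category c (index within non-reference order): S x p
beta_draws <- function(fit, c_idx) {
  p <- fit$dims$p
  fit$draws[, (c_idx - 1L) * p + seq_len(p), drop = FALSE]
}

#' Posterior category probabilities over a covariate grid
#'
#' For each grid point, the per-draw multinomial-logit probabilities of all
#' behavior categories (random effects at zero), summarized by the median
#' and an equal-tailed credible interval.
#'
#' @param fit a [fit_behavior_dirichlet()] model.
#' @param grid data frame of covariate values; must contain every variable
#'   in the model formula.
#' @param prob credible-interval mass (0.9).
#' @return A tibble: grid columns plus `category`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
conditional_effects <- function(fit, grid, prob = 0.9) {
  stopifnot(inherits(fit, "dirichlet_fit"))
  miss <- setdiff(all.vars(fit$formula), names(grid))
  if (length(miss)) {
    stop("grid lacks model covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Xn <- build_design(fit$formula, grid, xlev = fit$xlev)$X
  K <- fit$dims$K
  S <- nrow(fit$draws)
  n_g <- nrow(Xn)
  expEta <- array(1, dim = c(n_g, S, K + 1L))  # reference slice stays 1
  for (c_idx in seq_len(K)) {
    expEta[, , c_idx] <- exp(Xn %*% t(beta_draws(fit, c_idx)))
  }
  denom <- apply(expEta, c(1, 2), sum)
  a <- (1 - prob) / 2
  out <- lapply(seq_len(K + 1L), function(c_idx) {
    pr <- expEta[, , c_idx] / denom
    tibble::tibble(
      .row = seq_len(n_g),
      category = fit$categories[c_idx],
      estimate = apply(pr, 1, stats::median),
      conf.low = apply(pr, 1, stats::quantile, probs = a),
      conf.high = apply(pr, 1, stats::quantile, probs = 1 - a)
    )
  })
  grid <- tibble::as_tibble(grid)
  grid$.row <- seq_len(n_g)
  dplyr::bind_rows(out) |>
    dplyr::left_join(grid, by = ".row") |>
    dplyr::select(-".row") |>
    dplyr::relocate("category", "estimate", "conf.low", "conf.high",
                    .after = dplyr::last_col())
}

#' Per-observation log predictive density for new compositions
#'
#' Evaluates, for each stored posterior draw, the Dirichlet log density of
#' held-out compositions.  Herd effects for held-out data are drawn fresh
#' from their prior per posterior draw (held-out herds are new groups under
#' grouped cross-validation).
#'
#' @param fit a [fit_behavior_dirichlet()] model.
#' @param newdata held-out compositions with the same columns as the
#'   training data.
#' @param draws number of stored draws to use (thinned evenly).
#' @return A draws x observations matrix of log densities.
#' @export
loglik_dirichlet <- function(fit, newdata, draws = 400) {
  ord <- fit$categories
  y <- squeeze_simplex(as.matrix(newdata[ord]), newdata$n_minutes)
  Xn <- build_design(fit$formula, newdata, xlev = fit$xlev)$X
  K <- fit$dims$K
  S_all <- nrow(fit$draws)
  keep <- unique(round(seq(1, S_all, length.out = min(draws, S_all))))
  out <- matrix(NA_real_, length(keep), nrow(Xn))
  phi_d <- exp(fit$draws[keep, "log_phi"])
  sd_d <- if (fit$dims$H > 0) exp(fit$draws[keep, "log_herd_sd"]) else NULL
  B <- lapply(seq_len(K), function(c_idx) {
    beta_draws(fit, c_idx)[keep, , drop = FALSE]
  })
  for (s in seq_along(keep)) {
    eta <- vapply(seq_len(K), function(c_idx) {
      et <- drop(Xn %*% B[[c_idx]][s, ])
      if (!is.null(sd_d)) et <- et + sd_d[s] * stats::rnorm(length(et))
      et
    }, numeric(nrow(Xn)))
    eta <- cbind(matrix(eta, nrow = nrow(Xn)), 0)
    mu <- exp(eta - apply(eta, 1, max))
    mu <- mu / rowSums(mu)
    out[s, ] <- ddirichlet_alt(y, mu, phi_d[s])
  }
  out
}
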