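# Out-of-sample model comparison: expected log pointwise predictive density
# (ELPD) by exact k-fold refitting and by Pareto-smoothed importance
# sampling LOO, pseudo-BMA+ weights via the Bayesian bootstrap, and the
# retention / sole-top decision rules.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_elpd_estimate <- function(pointwise, method, p_eff = NA_real_,
                              p_eff_se = NA_real_, khat = NULL) {
  n <- length(pointwise)
  structure(list(
    elpd = sum(pointwise), se = stats::sd(pointwise) * sqrt(n),
    pointwise = pointwise, n = n, method = method,
    p_eff = p_eff, p_eff_se = p_eff_se, khat = khat
  ), class = "elpd_estimate")
}

#' @export
print.elpd_estimate <- function(x, ...) {
  cat(sprintf("<elpd_estimate> %s: elpd %.2f (SE %.2f), n = %d",
              x$method, x$elpd, x$se, x$n))
  if (!is.na(x$p_eff)) cat(sprintf(", p_eff %.1f", x$p_eff))
  if (!is.null(x$khat)) {
    cat(sprintf("; %d obs with Pareto k > 0.7", sum(x$khat > 0.7)))
  }
  cat("\n")
  invisible(x)
}

# Generalized-Pareto fit to exceedances (Zhang & Stephens style profile
# estimator); returns shape k (xi) and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || stats::sd(x) < 1e-12) return(list(k = 0, sigma = NA_real_))
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(floor(n / 4 + 0.5), 1)]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(t) mean(log1p(-t * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) {
    sum(exp(l_j - l_j[j]))
  }, numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  list(k = k, sigma = -k / theta_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-k) - 1) / k
}

# Pareto-smoothed importance weights for one observation's log ratios.
psis_weights <- function(lr, tail_frac = 0.2) {
  S <- length(lr)
  lw <- lr - max(lr)
  M <- ceiling(tail_frac * S)
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exc <- exp(lw[tail_idx]) - cut
  fit <- gpd_fit(exc)
  if (is.finite(fit$sigma) && fit$sigma > 0) {
    p <- (seq_len(M) - 0.5) / M
    sm <- cut + vapply(p, gpd_quantile, numeric(1), k = fit$k,
                       sigma = fit$sigma)
    sm <- pmin(sm, exp(max(lw)))          # truncate at the largest raw weight
    lw[tail_idx[order(lw[tail_idx])]] <- log(sm)
  }
  list(lw = lw, khat = fit$k)
}

#' PSIS-LOO expected log predictive density
#'
#' Leave-one-out ELPD approximated from posterior draws: per observation,
#' importance ratios `1 / p(y_i | theta_s)` are normalized over draws, their
#' largest 20% smoothed by a fitted generalized Pareto, and the pointwise
#' elpd is the log of the weighted predictive density.  The Pareto shape
#' `k-hat` is reported per observation; values above 0.7 flag unreliable
#' points.
#'
#' @param log_lik draws x observations matrix of log likelihoods (e.g.
#'   `fit$loglik` from a fitted model).
#' @return An `elpd_estimate` with `pointwise`, `khat`, `p_eff`.
#' @export
psis_loo <- function(log_lik) {
  log_lik <- as.matrix(log_lik)
  if (!all(is.finite(log_lik))) {
    stop("log-likelihood matrix must be finite", call. = FALSE)
  }
  S <- nrow(log_lik); n <- ncol(log_lik)
  pointwise <- numeric(n); khat <- numeric(n); lpd <- numeric(n)
  for (i in seq_len(n)) {
    ll <- log_lik[, i]
    lpd[i] <- log_sum_exp(ll) - log(S)
    pw <- psis_weights(-ll)
    pointwise[i] <- log_sum_exp(pw$lw + ll) - log_sum_exp(pw$lw)
    khat[i] <- pw$khat
  }
  p_point <- lpd - pointwise
  new_elpd_estimate(pointwise, "psis_loo",
                    p_eff = sum(p_point),
                    p_eff_se = stats::sd(p_point) * sqrt(n),
                    khat = khat)
}

#' Grouped fold assignment
#'
#' Assigns observations to `K` folds such that all observations sharing a
#' group label land in the same fold (herds never straddle folds), balancing
#' fold sizes greedily.
#'
#' @param groups vector of group labels, one per observation.
#' @param K number of folds.
#' @param seed RNG seed (shuffles groups of equal size).
#' @return Integer fold id per observation.
#' @export
make_folds <- function(groups, K = 10, seed = 1L) {
  groups <- as.character(groups)
  sizes <- table(groups)
  with_seed(seed, {
    ord <- sample(names(sizes))
    ord <- ord[order(-sizes[ord])]
    fold_of <- integer(length(sizes)); names(fold_of) <- ord
    load <- numeric(K)
    for (g in ord) {
      k <- which.min(load)
      fold_of[g] <- k
      load[k] <- load[k] + sizes[[g]]
    }
    unname(fold_of[groups])
  })
}

#' K-fold expected log predictive density by refitting
#'
#' Refits the model on each fold's complement and evaluates the mean
#' posterior predictive log density of the held-out records.  With `K = n`
#' (one observation per fold) this is exact leave-one-out.
#'
#' @param data full data set (rows = observations).
#' @param fit_fun function(data) returning a fitted model.
#' @param logpred_fun function(fit, newdata) returning either a draws x
#'   observations log-likelihood matrix (averaged over draws on the density
#'   scale) or a vector of log predictive densities (deterministic models).
#' @param K number of folds (10).
#' @param groups optional grouping labels for grouped folds (a group never
#'   straddles folds).
#' @param folds optional explicit fold id per observation (overrides `K`
#'   and `groups`).
#' @param seed fold-assignment seed.
#' @return An `elpd_estimate`; `$unreliable` is `TRUE` when any fold's fit
#'   reports non-convergence.
#' @export
kfold_elpd <- function(data, fit_fun, logpred_fun, K = 10, groups = NULL,
                       folds = NULL, seed = 1L) {
  n <- nrow(data)
  if (is.null(folds)) {
    if (n < K) stop("need at least K observations", call. = FALSE)
    folds <- if (is.null(groups)) {
      make_folds(seq_len(n), K, seed)
    } else {
      make_folds(groups, K, seed)
    }
  }
  pointwise <- numeric(n)
  unreliable <- FALSE
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit <- fit_fun(data[!test, , drop = FALSE])
    if (!is.null(fit$converged) && !isTRUE(fit$converged)) unreliable <- TRUE
    ll <- logpred_fun(fit, data[test, , drop = FALSE])
    pointwise[test] <- if (is.matrix(ll)) {
      apply(ll, 2, log_sum_exp) - log(nrow(ll))
    } else {
      as.numeric(ll)
    }
  }
  out <- new_elpd_estimate(pointwise,
                           if (length(unique(folds)) == n) "loo_exact"
                           else sprintf("kfold%d", length(unique(folds))))
  out$unreliable <- unreliable
  out
}

#' Pseudo-BMA+ model weights via the Bayesian bootstrap
#'
#' Dirichlet(1, ..., 1) observation weights resample each model's total
#' elpd; per replicate the weights are the softmax of the resampled totals,
#' and the final weight is the mean over replicates.
#'
#' @param pointwise list (one element per model) of pointwise-elpd vectors
#'   on a common observation set.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return Named numeric vector of weights summing to 1.
#' @export
pseudo_bma_weights <- function(pointwise, n_boot = 1000, seed = 1L) {
  lens <- lengths(pointwise)
  if (length(unique(lens)) != 1) {
    stop("models must share the same observation set", call. = FALSE)
  }
  n <- lens[[1]]
  E <- do.call(cbind, pointwise)         # n x M
  M <- ncol(E)
  with_seed(seed, {
    acc <- numeric(M)
    for (b in seq_len(n_boot)) {
      w <- stats::rgamma(n, 1)
      w <- w / sum(w)
      z <- n * colSums(w * E)
      z <- exp(z - max(z))
      acc <- acc + z / sum(z)
    }
    w_out <- acc / n_boot
    names(w_out) <- names(pointwise) %||% paste0("model", seq_len(M))
    w_out
  })
}

#' Build a model-comparison table
#'
#' @param elpds named list of `elpd_estimate`s on a common observation set.
#' @param n_boot,seed passed to [pseudo_bma_weights()].
#' @return A tibble with `model`, `elpd`, `se`, `elpd_diff`, `se_diff`,
#'   `p_eff`, `weight`, sorted by elpd; feed to [select_models()].
#' @export
compare_models <- function(elpds, n_boot = 1000, seed = 1L) {
  stopifnot(length(elpds) >= 1)
  pw <- lapply(elpds, `[[`, "pointwise")
  w <- pseudo_bma_weights(pw, n_boot = n_boot, seed = seed)
  top <- which.max(vapply(elpds, `[[`, numeric(1), "elpd"))
  tb <- tibble::tibble(
    model = names(elpds) %||% paste0("model", seq_along(elpds)),
    elpd = vapply(elpds, `[[`, numeric(1), "elpd"),
    se = vapply(elpds, `[[`, numeric(1), "se"),
    elpd_diff = vapply(seq_along(elpds), function(m) {
      sum(pw[[m]] - pw[[top]])
    }, numeric(1)),
    se_diff = vapply(seq_along(elpds), function(m) {
      d <- pw[[m]] - pw[[top]]
      stats::sd(d) * sqrt(length(d))
    }, numeric(1)),
    p_eff = vapply(elpds, `[[`, numeric(1), "p_eff"),
    weight = unname(w)
  )
  dplyr::arrange(tb, dplyr::desc(.data$elpd))
}

#' Apply the retention and sole-top decision rules
#'
#' Models within 16 elpd of the top model are retained; the top model is the
#' sole top model when it is more than 4 elpd ahead of the runner-up or
#' carries the majority (> 0.5) of the weight.
#'
#' @param comparison a tibble with `elpd_diff` (0 for the top model,
#'   negative below) and `weight` columns, e.g. from [compare_models()].
#' @return The tibble with logical `retained` and `sole_top` columns
#'   appended, sorted by `elpd_diff`.
#' @export
select_models <- function(comparison) {
  tb <- dplyr::arrange(tibble::as_tibble(comparison),
                       dplyr::desc(.data$elpd_diff))
  tb$retained <- tb$elpd_diff > -16
  runner_gap <- if (nrow(tb) >= 2) -tb$elpd_diff[2] else Inf
  top_w <- if ("weight" %in% names(tb)) tb$weight[1] else NA_real_
  tb$sole_top <- FALSE
  tb$sole_top[1] <- runner_gap > 4 || isTRUE(top_w > 0.5)
  tb
}
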