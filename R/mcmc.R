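# Shared MCMC infrastructure: sampler presets, Laplace preconditioning,
# split R-hat / effective-sample-size diagnostics, and the common surface of
# fitted posterior objects.

#' MCMC configuration
#'
#' @param chains number of chains.
#' @param warmup warmup iterations per chain (step-size adaptation).
#' @param iter sampling iterations per chain.
#' @param thin_loglik store the per-observation log-likelihood every this
#'   many sampling iterations (memory control; the stored draws feed
#'   PSIS-LOO and k-fold ELPD).
#' @param eps0 initial leapfrog step size (on the preconditioned scale).
#' @param leapfrog maximum leapfrog steps per iteration (path length is
#'   jittered uniformly between 1 and this).
#' @param jitter chain-start jitter, in posterior-SD units.
#' @param seed RNG seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 200, iter = 350,
                        thin_loglik = 2, eps0 = 0.4, jitter = 0.2,
                        leapfrog = 6, seed = 1L) {
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 thin_loglik = thin_loglik, eps0 = eps0, jitter = jitter,
                 leapfrog = leapfrog, seed = seed), class = "mcmc_config")
}

#' Named sampler presets
#'
#' `"fast"` is the default working preset for simulation studies (fixed
#' effects mix well; high-dimensional random-effect blocks may fall short
#' of the strict convergence flag); `"thorough"` comfortably meets the
#' convergence contract on the models in this package; `"full"` reproduces
#' the 16,000 + 16,000 total-iteration scheme (4 chains of 4000 + 4000).
#'
#' @param name `"fast"`, `"thorough"` or `"full"`.
#' @param seed RNG seed.
#' @return An [mcmc_config()].
#' @export
mcmc_preset <- function(name = c("fast", "thorough", "full"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         fast = mcmc_config(seed = seed),
         thorough = mcmc_config(warmup = 700, iter = 1800, leapfrog = 12,
                                thin_loglik = 4, seed = seed),
         full = mcmc_config(chains = 4, warmup = 4000, iter = 4000,
                            leapfrog = 12, thin_loglik = 16, seed = seed))
}

#' Split R-hat of one parameter
#'
#' Potential-scale-reduction statistic on split chains.
#'
#' @param x iterations x chains matrix of draws.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of one parameter
#'
#' Combined-chain ESS from pairwise-summed autocorrelations (Geyer initial
#' monotone sequence), averaged across chains.
#'
#' @param x iterations x chains matrix of draws.
#' @return Scalar effective sample size.
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::sd(x) == 0) return(n * m)
  rho <- rowMeans(apply(x, 2, function(ch) {
    if (stats::sd(ch) == 0) return(rep(0, n))
    a <- stats::acf(ch, lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }))
  # Geyer: sum pairs rho[2t]+rho[2t+1] while positive and decreasing
  tau <- 0
  prev <- Inf
  t <- 1L
  while (t + 1 <= length(rho)) {
    pair <- rho[t + 1] + ifelse(t + 2 <= length(rho), rho[t + 2], 0)
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- n * m / (1 + 2 * tau)
  max(min(ess, n * m), 1)
}

mcmc_diagnostics <- function(draws, chain, params = colnames(draws)) {
  iters <- sum(chain == chain[1])
  tibble::tibble(
    parameter = params,
    rhat = vapply(params, function(p) {
      split_rhat(matrix(draws[, p], nrow = iters))
    }, numeric(1)),
    ess = vapply(params, function(p) {
      ess_mean(matrix(draws[, p], nrow = iters))
    }, numeric(1))
  )
}

# Laplace preparation: posterior mode by BFGS on the C++ log posterior and a
# Cholesky factor of the inverse (negated, regularized) finite-difference
# Hessian, used as the HMC mass matrix.  The random-effect scale coordinate
# is anchored by a quadratic penalty during this step only: the joint mode
# of a hierarchical posterior is degenerate in the scale direction, and an
# unanchored mode would yield a useless mass matrix.  The penalty never
# enters the sampled posterior.
laplace_precondition <- function(lp_grad, start, h = 1e-4,
                                 anchor_idx = NULL, anchor_mean = log(0.3),
                                 anchor_sd = 0.5) {
  d <- length(start)
  if (!is.null(anchor_idx)) {
    base <- lp_grad
    lp_grad <- function(th) {
      r <- base(th)
      dev <- th[anchor_idx] - anchor_mean
      r$lp <- r$lp - 0.5 * sum(dev^2) / anchor_sd^2
      r$grad[anchor_idx] <- r$grad[anchor_idx] - dev / anchor_sd^2
      r
    }
  }
  opt <- stats::optim(start,
                      fn = function(th) -lp_grad(th)$lp,
                      gr = function(th) -lp_grad(th)$grad,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  mode <- opt$par
  Hn <- matrix(0, d, d)  # negative Hessian via central differences of grad
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- h
    Hn[, j] <- -(lp_grad(mode + e)$grad - lp_grad(mode - e)$grad) / (2 * h)
  }
  Hn <- (Hn + t(Hn)) / 2
  ridge <- 1e-8 * max(abs(diag(Hn)), 1)
  repeat {
    ch <- try(chol(Hn + ridge * diag(d)), silent = TRUE)
    if (!inherits(ch, "try-error")) break
    ridge <- ridge * 10
    if (ridge > 1e6) stop("Hessian could not be regularized", call. = FALSE)
  }
  # Sigma = (Hn + ridge I)^{-1}; L = lower Cholesky of Sigma
  Sigma <- chol2inv(ch)
  L <- t(chol((Sigma + t(Sigma)) / 2))
  list(mode = mode, L = L, converged = opt$convergence == 0)
}

finalize_mcmc_fit <- function(res, param_names, config, subclass) {
  draws <- res$draws
  colnames(draws) <- param_names
  diag_tb <- mcmc_diagnostics(draws, res$chain)
  converged <- all(diag_tb$rhat <= 1.01) &&
    all(diag_tb$ess > 10 * config$chains)
  structure(list(
    draws = draws, chain = res$chain,
    loglik = if (length(res$loglik)) res$loglik else NULL,
    accept = as.numeric(res$accept),
    diagnostics = diag_tb, converged = converged, config = config
  ), class = c(subclass, "mcmc_fit"))
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf(
    "<%s> %d chains x %d draws; accept %.2f; max R-hat %.3f; min ESS %.0f%s\n",
    class(x)[1], x$config$chains, x$config$iter, mean(x$accept),
    max(x$diagnostics$rhat), min(x$diagnostics$ess),
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param x a fitted `mcmc_fit` object.
#' @param prob probability mass of the equal-tailed credible interval.
#' @param ... unused.
#' @return A tibble with `term`, `estimate` (posterior median),
#'   `std.error` (posterior SD), `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.mcmc_fit <- function(x, prob = 0.9, ...) {
  a <- (1 - prob) / 2
  tibble::tibble(
    term = colnames(x$draws),
    estimate = unname(apply(x$draws, 2, stats::median)),
    std.error = unname(apply(x$draws, 2, stats::sd)),
    conf.low = unname(apply(x$draws, 2, stats::quantile, probs = a)),
    conf.high = unname(apply(x$draws, 2, stats::quantile, probs = 1 - a)),
    rhat = unname(x$diagnostics$rhat),
    ess = unname(x$diagnostics$ess)
  )
}

#' @export
glance.mcmc_fit <- function(x, ...) {
  n_tot <- nrow(x$draws)
  tibble::tibble(
    chains = x$config$chains, draws = n_tot,
    accept = mean(x$accept), max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess),
    min_ess_ratio = min(x$diagnostics$ess) / n_tot,
    converged = x$converged
  )
}
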