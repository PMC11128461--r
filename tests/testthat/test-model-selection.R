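test_that("k-fold at K = n equals an independently coded brute-force LOO", {
  set.seed(20)
  d <- tibble::tibble(y = rnorm(40, 1.5, 1))
  res <- kfold_elpd(d, normal_fit, normal_logpred, folds = seq_len(40))
  brute <- vapply(seq_len(40), function(i) {
    normal_logpred(normal_fit(d[-i, , drop = FALSE]),
                   d[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(res$pointwise, brute, tolerance = 1e-12)
  expect_identical(res$method, "loo_exact")
  expect_equal(res$elpd, sum(brute))
  expect_equal(res$se, sd(brute) * sqrt(40))
})

test_that("grouped folds never split a group and balance sizes", {
  groups <- rep(letters[1:12], times = c(8, 7, 7, 6, 6, 5, 5, 4, 4, 3, 3,
                                         2))
  f <- make_folds(groups, K = 5, seed = 1)
  expect_identical(length(f), length(groups))
  split_tbl <- table(groups, f)
  expect_true(all(rowSums(split_tbl > 0) == 1))
  expect_lt(diff(range(table(f))), 8)
})

test_that("PSIS-LOO matches the analytic LOO of a conjugate model", {
  set.seed(21)
  n <- 30
  y <- rnorm(n, 2, 1)
  v_n <- 1 / (n + 1 / 100)
  m_n <- v_n * sum(y)
  S <- 4000
  theta <- rnorm(S, m_n, sqrt(v_n))
  log_lik <- vapply(seq_len(n), function(i) {
    dnorm(y[i], theta, 1, log = TRUE)
  }, numeric(S))
  res <- psis_loo(log_lik)
  analytic <- vapply(seq_len(n), function(i) {
    v_i <- 1 / ((n - 1) + 1 / 100)
    m_i <- v_i * sum(y[-i])
    dnorm(y[i], m_i, sqrt(v_i + 1), log = TRUE)
  }, numeric(1))
  expect_lt(abs(res$elpd - sum(analytic)), 2 * res$se)
  expect_true(all(res$khat < 0.7))
  expect_gt(res$p_eff, 0)
})

test_that("PSIS-LOO tracks exact refit LOO on a small Bayesian fit", {
  d <- sim_dirichlet_comps(40, n_herds = 4, seed = 30)
  cfg <- mcmc_config(chains = 2, warmup = 250, iter = 800, seed = 12)
  fit <- fit_behavior_dirichlet(d, ~ risk_z, herd = NULL, config = cfg)
  loo_psis <- psis_loo(fit$loglik)
  refit <- kfold_elpd(
    d,
    fit_fun = function(dd) {
      fit_behavior_dirichlet(dd, ~ risk_z, herd = NULL, config = cfg)
    },
    logpred_fun = function(f, nd) loglik_dirichlet(f, nd, draws = 400),
    folds = seq_len(40))
  expect_lt(abs(loo_psis$elpd - refit$elpd), 0.5 * 40^0.5)
})

test_that("degenerate importance ratios reduce to the plain log density", {
  ll <- matrix(-1.234, nrow = 500, ncol = 6)
  res <- psis_loo(ll)
  expect_equal(res$pointwise, rep(-1.234, 6))
  expect_true(all(abs(res$khat) < 0.5))
  expect_error(psis_loo(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("pseudo-BMA+ weights behave at the symmetry and saturation limits", {
  set.seed(22)
  pw <- rnorm(100, -2, 1)
  w_same <- pseudo_bma_weights(list(a = pw, b = pw), seed = 2)
  expect_equal(unname(w_same), c(0.5, 0.5), tolerance = 0.01)
  w_far <- pseudo_bma_weights(list(a = pw, b = pw - 0.5), seed = 3)
  expect_gt(w_far[["a"]], 0.999)
  # label equivariance
  pw2 <- rnorm(100, -2, 1)
  w_ab <- pseudo_bma_weights(list(a = pw, b = pw2), seed = 4)
  w_ba <- pseudo_bma_weights(list(b = pw2, a = pw), seed = 4)
  expect_equal(w_ab[["a"]], w_ba[["a"]], tolerance = 1e-12)
  expect_equal(sum(w_ab), 1)
  expect_error(pseudo_bma_weights(list(a = pw, b = pw2[1:50])),
               "same observation")
})

test_that("duplicate model specifications tie within noise", {
  set.seed(23)
  d <- tibble::tibble(y = rnorm(60, 1, 1))
  e1 <- kfold_elpd(d, normal_fit, normal_logpred, K = 10, seed = 1)
  e2 <- kfold_elpd(d, normal_fit, normal_logpred, K = 10, seed = 2)
  diff_se <- sd(e1$pointwise - e2$pointwise) * sqrt(60)
  expect_lt(abs(e1$elpd - e2$elpd), max(2 * diff_se, 1e-6))
})

test_that("the true model wins the k-fold comparison on synthetic data", {
  wins <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 300
    x <- rnorm(n)
    mu_true <- 1 + 0.8 * x
    y <- rnorm(n, mu_true, 1)
    d <- tibble::tibble(y = y, x = x, noise = rnorm(n))
    fit_lm <- function(xcol) {
      function(dd) {
        f <- lm(stats::reformulate(xcol, "y"), data = dd)
        list(fit = f, sigma = summary(f)$sigma)
      }
    }
    pred_lm <- function(f, nd) {
      dnorm(nd$y, predict(f$fit, nd), f$sigma, log = TRUE)
    }
    e_true <- kfold_elpd(d, fit_lm("x"), pred_lm, K = 10, seed = s)
    e_noise <- kfold_elpd(d, fit_lm("noise"), pred_lm, K = 10, seed = s)
    e_true$elpd > e_noise$elpd
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("retention and sole-top rules follow the published thresholds", {
  tb <- tibble::tibble(
    model = c("m1", "m2", "m3", "m4"),
    elpd_diff = c(0, -5.93, -5.96, -19.28),
    weight = c(0.53, 0.24, 0.22, 0.01))
  out <- select_models(tb)
  expect_identical(out$retained, c(TRUE, TRUE, TRUE, FALSE))
  # runner-up within 4 elpd, but majority weight makes it sole top
  expect_true(out$sole_top[1])
  expect_false(any(out$sole_top[-1]))
  # no majority weight and runner-up within 4: not a sole top
  tb2 <- tibble::tibble(elpd_diff = c(0, -2), weight = c(0.45, 0.55))
  expect_false(select_models(tb2)$sole_top[1])
  # clear gap alone suffices
  tb3 <- tibble::tibble(elpd_diff = c(0, -5), weight = c(0.4, 0.6))
  expect_true(select_models(tb3)$sole_top[1])
  single <- select_models(tibble::tibble(elpd_diff = 0, weight = 1))
  expect_true(single$retained && single$sole_top)
})

test_that("compare_models assembles elpds, diffs, and weights", {
  set.seed(24)
  e_a <- new_elpd <- elkrisk:::new_elpd_estimate(rnorm(50, -1), "kfold10")
  e_b <- elkrisk:::new_elpd_estimate(rnorm(50, -1.5), "kfold10")
  tb <- compare_models(list(A = e_a, B = e_b), n_boot = 500, seed = 5)
  expect_identical(tb$model[1], "A")
  expect_equal(tb$elpd_diff[1], 0)
  expect_lt(tb$elpd_diff[2], 0)
  expect_equal(sum(tb$weight), 1)
})
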