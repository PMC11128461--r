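test_that("vigilance minutes are extracted with session linkage", {
  minutes <- tibble::tibble(
    session_id = rep(c("a", "b", "c"), each = 5),
    behavior = c(rep("foraging", 5),
                 c("vigilance", "vigilance", "vigilance", "vigilance",
                   "vigilance"),
                 rep("resting_ruminating", 5)),
    chewing = c(rep(NA, 5), TRUE, TRUE, TRUE, FALSE, FALSE, rep(NA, 5)))
  sessions <- tibble::tibble(session_id = c("a", "b", "c"),
                             risk_z = c(0, 1, 2))
  v <- extract_vigilance_minutes(minutes, sessions)
  expect_identical(nrow(v), 5L)
  expect_identical(sum(v$multitask), 3L)
  expect_true(all(v$risk_z == 1))
  # sessions without vigilance contribute nothing; flagless minutes drop
  minutes$chewing[6] <- NA
  expect_message(v2 <- extract_vigilance_minutes(minutes, sessions),
                 "without a chewing flag")
  expect_identical(nrow(v2), 4L)
})

test_that("the multitasking fit meets the convergence contract", {
  vig <- sim_vigilance_minutes(behavior_truth(), seed = 41)
  fit <- fit_multitask(vig, ~ maternal * risk_z + openness_z,
                       config = mcmc_preset("thorough", seed = 8))
  expect_true(fit$converged)
  expect_true(all(fit$diagnostics$rhat <= 1.01))
  expect_true(all(fit$diagnostics$ess > 10 * fit$config$chains))
  tb <- tidy(fit)
  # openness slope generated at -0.45: sign recovered
  expect_lt(tb$estimate[tb$term == "openness_z"], 0)
  # per-period risk slopes reproduce the generating sign structure
  dr <- fit$draws
  expect_gt(median(dr[, "risk_z"]), 0)
  expect_lt(median(dr[, "risk_z"] + dr[, "maternalPPP:risk_z"]), 0)
})

test_that("predicted probabilities are proper and monotone in openness", {
  vig <- sim_vigilance_minutes(behavior_truth(), seed = 42)
  fit <- fit_multitask(vig, ~ openness_z, config = mcmc_config(seed = 9))
  grid <- tibble::tibble(openness_z = seq(-2, 2, by = 0.5))
  pr <- predict_multitask(fit, grid)
  expect_true(all(pr$estimate > 0 & pr$estimate < 1))
  expect_true(all(pr$conf.low < pr$estimate & pr$estimate < pr$conf.high))
  if (all(fit$draws[, "openness_z"] < 0)) {
    expect_true(all(diff(pr$estimate) < 0))
  }
  expect_error(predict_multitask(fit, tibble::tibble(bad = 1)),
               "openness_z")
})

test_that("an intercept-centered-at-zero posterior predicts about a half", {
  tr0 <- behavior_truth(
    multitask_beta = c(`(Intercept)` = 0, openness_z = 0, risk_z = 0,
                       maternalPPP = 0, maternalSMP = 0, maternalWP = 0,
                       `maternalPPP:risk_z` = 0, `maternalSMP:risk_z` = 0,
                       `maternalWP:risk_z` = 0),
    multitask_session_sd = 0.2)
  vig <- sim_vigilance_minutes(tr0, counts_by_period = c(LMP = 2000),
                               seed = 43)
  fit <- fit_multitask(vig, ~ 1, config = mcmc_config(seed = 10))
  pr <- predict_multitask(fit, tibble::tibble(.dummy = 1))
  expect_lt(abs(pr$estimate - 0.5), 0.06)
})

test_that("identical flags trigger the identifiability warning", {
  d <- tibble::tibble(session_id = rep(c("a", "b"), each = 5),
                      multitask = 1L)
  expect_warning(
    fit_multitask(d, ~ 1, config = mcmc_config(chains = 2, warmup = 100,
                                               iter = 100)),
    "identical")
})

test_that("session random-intercept scale is recovered within half", {
  tr <- behavior_truth(multitask_session_sd = 0.8)
  vig <- sim_vigilance_minutes(tr,
                               counts_by_period = c(LMP = 500, SMP = 500),
                               minutes_per_session = 5, seed = 44)
  fit <- fit_multitask(vig, ~ risk_z,
                       config = mcmc_preset("thorough", seed = 11))
  tau_hat <- exp(median(fit$draws[, "log_session_sd"]))
  expect_gt(tau_hat, 0.4)
  expect_lt(tau_hat, 1.2)
})
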