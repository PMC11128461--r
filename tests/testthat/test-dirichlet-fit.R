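test_that("a symmetric null truth is recovered with covering intervals", {
  set.seed(10)
  n <- 300
  g <- matrix(rgamma(n * 5, shape = 0.2 * 40), n)
  p <- g / rowSums(g)
  colnames(p) <- behavior_categories()
  d <- tibble::as_tibble(p)
  d$n_minutes <- 200
  fit <- fit_behavior_dirichlet(d, ~ 1, herd = NULL,
                                config = mcmc_config(seed = 1))
  expect_true(fit$converged)
  tb <- tidy(fit, prob = 0.98)
  ints <- tb[grepl("Intercept", tb$term), ]
  # intercepts track the realized sample's log mean ratios closely ...
  sq <- squeeze_simplex(as.matrix(d[behavior_categories()]), 200)
  emp <- log(colMeans(sq) / mean(sq[, "traveling"]))
  emp <- emp[setdiff(behavior_categories(), "traveling")]
  expect_lt(max(abs(ints$estimate - unname(emp))), 0.03)
  # ... and the symmetric truth stays inside Bonferroni-widened intervals
  # up to the generator Monte-Carlo noise
  expect_true(all(ints$conf.low <= 0.1 & ints$conf.high >= -0.1))
})

test_that("prior-only sampling reproduces the intercept prior", {
  set.seed(11)
  d <- sim_dirichlet_comps(50, seed = 99)
  fit <- fit_behavior_dirichlet(
    d, ~ 1, herd = NULL, prior_only = TRUE,
    config = mcmc_config(chains = 4, warmup = 400, iter = 2000,
                         leapfrog = 8, seed = 2))
  draws <- fit$draws[, "foraging~(Intercept)"]
  thin <- draws[seq(1, length(draws), by = 20)]
  ks <- suppressWarnings(stats::ks.test(thin, function(q) {
    stats::pt(q / 2.5, df = 3)
  }))
  expect_gt(ks$p.value, 0.01)
  # and phi draws match the gamma(0.01, 0.01) prior mass below 1
  phid <- exp(fit$draws[, "log_phi"])
  expect_lt(abs(mean(phid < 1) - pgamma(1, 0.01, 0.01)), 0.03)
  expect_error(fit_behavior_dirichlet(d, ~ risk_z, herd = NULL,
                                      prior_only = TRUE), "intercept-only")
})

test_that("credible intervals contract as the sample grows", {
  d1 <- sim_dirichlet_comps(350, seed = 5)
  d2 <- sim_dirichlet_comps(1400, seed = 6)
  w <- vapply(list(d1, d2), function(d) {
    fit <- fit_behavior_dirichlet(d, ~ risk_z, config = mcmc_config(seed = 3))
    tb <- tidy(fit)
    r <- tb[tb$term == "vigilance~risk_z", ]
    r$conf.high - r$conf.low
  }, numeric(1))
  ratio <- w[2] / w[1]
  expect_lt(abs(ratio - 0.5), 0.17)
})

test_that("conditional effects are simplex-valued and respond to slopes", {
  d <- sim_dirichlet_comps(400, seed = 7)
  fit <- fit_behavior_dirichlet(d, ~ risk_z, config = mcmc_config(seed = 4))
  grid <- tibble::tibble(risk_z = seq(-2, 2, by = 1))
  ce <- conditional_effects(fit, grid)
  sums <- ce |>
    dplyr::summarise(s = sum(.data$estimate), .by = "risk_z")
  expect_true(all(abs(sums$s - 1) < 0.02))
  vig <- ce[ce$category == "vigilance", ]
  expect_gt(vig$estimate[vig$risk_z == 2], vig$estimate[vig$risk_z == -2])
  expect_error(conditional_effects(fit, tibble::tibble(zzz = 1)), "risk_z")
  # null model: flat conditional effects
  fit0 <- fit_behavior_dirichlet(d, ~ 1, herd = NULL,
                                 config = mcmc_config(seed = 5))
  ce0 <- conditional_effects(fit0, tibble::tibble(risk_z = c(-2, 2)))
  for (cat in behavior_categories()) {
    v <- ce0$estimate[ce0$category == cat]
    expect_equal(v[1], v[2])
  }
})

test_that("held-out log predictive densities are finite and sane", {
  d <- sim_dirichlet_comps(240, seed = 8)
  fit <- fit_behavior_dirichlet(d[1:200, ], ~ risk_z,
                                config = mcmc_config(seed = 6))
  ll <- loglik_dirichlet(fit, d[201:240, ], draws = 200)
  expect_identical(dim(ll), c(200L, 40L))
  expect_true(all(is.finite(ll)))
  # pointwise predictive density should beat a mismatched model's
  bad <- fit_behavior_dirichlet(
    dplyr::mutate(d[1:200, ], risk_z = rev(risk_z)), ~ risk_z,
    config = mcmc_config(seed = 7))
  ll_bad <- loglik_dirichlet(bad, d[201:240, ], draws = 200)
  lpd <- function(m) sum(apply(m, 2, function(col) {
    elkrisk:::log_sum_exp(col) - log(length(col))
  }))
  expect_gt(lpd(ll), lpd(ll_bad))
})
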