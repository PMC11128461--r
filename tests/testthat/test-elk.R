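make_session_world <- function(seed = 21) {
  L <- tiny_landscape(seed = seed)
  risk <- grid_raster(matrix(runif(100, 0, 1), 10, 10), cell_x = 300)
  list(landscape = L, risk = risk)
}

test_that("session counts match the configured period mix exactly", {
  w <- make_session_world()
  sim <- sim_elk_sessions(behavior_truth(), w$risk, w$landscape,
                          period_counts = c(PPP = 12, LMP = 18, SMP = 25,
                                            WP = 9),
                          n_herds = 5, seed = 31)
  expect_identical(nrow(sim$sessions), 64L)
  expect_identical(as.vector(table(sim$sessions$maternal)[c("PPP", "LMP",
                                                            "SMP", "WP")]),
                   c(12L, 18L, 25L, 9L))
  # generated dates are consistent with the assigned maternal labels
  expect_identical(as.character(assign_maternal(sim$sessions$date)),
                   as.character(sim$sessions$maternal))
})

test_that("per-minute states are legal and counts sum to session length", {
  w <- make_session_world(22)
  sim <- sim_elk_sessions(behavior_truth(), w$risk, w$landscape,
                          period_counts = c(PPP = 10, LMP = 10, SMP = 10,
                                            WP = 10),
                          n_herds = 4, seed = 5)
  states <- c(behavior_states(), "unknown", "disturbed")
  expect_true(all(sim$minutes$behavior %in% states))
  per <- dplyr::count(sim$minutes, session_id)
  m <- dplyr::inner_join(per, sim$sessions, by = "session_id")
  expect_identical(m$n, as.integer(m$n_minutes))
  expect_true(all(m$n_minutes >= 10 & m$n_minutes <= 40))
  # chewing flags exist exactly on vigilance minutes
  expect_true(all(is.na(sim$minutes$chewing[sim$minutes$behavior !=
                                              "vigilance"])))
  expect_true(all(!is.na(sim$minutes$chewing[sim$minutes$behavior ==
                                               "vigilance"])))
})

test_that("the generated ecosystem is bit-reproducible under a fixed seed", {
  w <- make_session_world(23)
  a <- sim_elk_sessions(behavior_truth(), w$risk, w$landscape,
                        period_counts = c(PPP = 5, LMP = 5, SMP = 5, WP = 5),
                        n_herds = 3, seed = 77)
  b <- sim_elk_sessions(behavior_truth(), w$risk, w$landscape,
                        period_counts = c(PPP = 5, LMP = 5, SMP = 5, WP = 5),
                        n_herds = 3, seed = 77)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$minutes, b$minutes)
})

test_that("symmetric truth yields near-uniform category frequencies", {
  tr <- behavior_truth(
    beta = {
      b <- matrix(0, 8, 4)
      rownames(b) <- c("(Intercept)", "dielmorning", "dielevening",
                       "herd_size_z", "risk_z", "maternalPPP",
                       "maternalSMP", "maternalWP")
      colnames(b) <- c("foraging", "vigilance", "resting_ruminating",
                       "other")
      b
    },
    phi = 5000, herd_sd = 0, p_unknown = 0, p_disturbed = 0)
  w <- make_session_world(24)
  sim <- sim_elk_sessions(tr, w$risk, w$landscape,
                          period_counts = c(PPP = 50, LMP = 50, SMP = 50,
                                            WP = 50),
                          n_herds = 4, seed = 6)
  comp <- sessions_to_compositions(sim$minutes)
  props <- colMeans(comp[behavior_categories()])
  expect_true(all(abs(props - 0.2) < 0.02))
})

test_that("empirical proportions converge to the truth-implied means", {
  tr <- behavior_truth(p_unknown = 0, p_disturbed = 0)
  w <- make_session_world(25)
  counts <- c(PPP = 300, LMP = 300, SMP = 300, WP = 300)
  sim <- sim_elk_sessions(tr, w$risk, w$landscape, period_counts = counts,
                          n_herds = 10, seed = 8)
  comp <- sessions_to_compositions(sim$minutes)
  obs <- colMeans(comp[behavior_categories()])
  # truth-implied mean composition, recomputed from the generator inputs
  s <- sim$sessions
  D <- cbind(1, s$diel == "morning", s$diel == "evening", s$herd_size_z,
             s$risk_z, s$maternal == "PPP", s$maternal == "SMP",
             s$maternal == "WP")
  zh <- sim$truth_record$z_herd
  hidx <- as.integer(factor(s$herd_id,
                            levels = sprintf("H%02d", 1:10)))
  eta <- D %*% tr$beta + tr$herd_sd * zh[hidx, ]
  E <- cbind(exp(eta), traveling = 1)
  colnames(E) <- c(colnames(tr$beta), "traveling")
  mu <- E / rowSums(E)
  want <- colMeans(mu)[behavior_categories()]
  expect_lt(max(abs(obs - want)), 0.02)
})

test_that("a saturating multitask intercept flags every vigilance minute", {
  tr <- behavior_truth(
    multitask_beta = c(`(Intercept)` = 30, openness_z = 0, risk_z = 0,
                       maternalPPP = 0, maternalSMP = 0, maternalWP = 0,
                       `maternalPPP:risk_z` = 0, `maternalSMP:risk_z` = 0,
                       `maternalWP:risk_z` = 0),
    multitask_session_sd = 0)
  w <- make_session_world(26)
  sim <- sim_elk_sessions(tr, w$risk, w$landscape,
                          period_counts = c(PPP = 20, LMP = 20, SMP = 20,
                                            WP = 20),
                          n_herds = 4, seed = 9)
  vig <- sim$minutes[sim$minutes$behavior == "vigilance", ]
  expect_gt(nrow(vig), 0)
  expect_true(all(vig$chewing))
})

test_that("direct vigilance-minute generation pins per-period counts", {
  v <- sim_vigilance_minutes(behavior_truth(), seed = 3)
  expect_identical(nrow(v), 1052L)
  expect_identical(as.vector(table(v$maternal)[c("PPP", "LMP", "SMP",
                                                 "WP")]),
                   c(164L, 367L, 421L, 100L))
  expect_true(all(v$multitask %in% 0:1))
  # null-intercept truth pools to about one half
  tr0 <- behavior_truth(
    multitask_beta = c(`(Intercept)` = 0, openness_z = 0, risk_z = 0,
                       maternalPPP = 0, maternalSMP = 0, maternalWP = 0,
                       `maternalPPP:risk_z` = 0, `maternalSMP:risk_z` = 0,
                       `maternalWP:risk_z` = 0),
    multitask_session_sd = 0)
  v0 <- sim_vigilance_minutes(tr0, counts_by_period = c(LMP = 4000),
                              seed = 4)
  expect_lt(abs(mean(v0$multitask) - 0.5), 0.02)
})
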