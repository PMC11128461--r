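test_that("zero packs yield an empty fix table with full schema", {
  L <- tiny_landscape()
  tr <- sim_wolf_tracks(L, pack_config(n_packs = 0))
  expect_identical(names(tr), c("animal_id", "pack_id", "t", "x", "y"))
  expect_identical(nrow(tr), 0L)
})

test_that("constant diel curve recovers the configured mean step length", {
  L <- tiny_landscape(extent = c(6000, 6000))
  pc <- pack_config(n_packs = 1, n_collared = 2, n_days = 200,
                    diel_speed_curve = function(h) rep(0.4, length(h)),
                    territory_centers = matrix(c(3000, 3000), 1),
                    attraction = 0.05, seed = 8)
  tr <- sim_wolf_tracks(L, pc)
  st <- track_steps(tr)
  # boundary reflection can only shorten observed displacements slightly
  expect_gt(mean(st$step_km), 0.4 * 0.9)
  expect_lt(mean(st$step_km), 0.4 * 1.1)
})

test_that("strong attraction keeps fixes near the territory center", {
  L <- tiny_landscape(extent = c(6000, 6000))
  pc <- pack_config(n_packs = 1, n_collared = 1, n_days = 60,
                    territory_centers = matrix(c(3000, 3000), 1),
                    diel_speed_curve = function(h) rep(0.05, length(h)),
                    attraction = 0.995, turn_concentration = 0.95, seed = 2)
  tr <- sim_wolf_tracks(L, pc)
  d <- sqrt((tr$x - 3000)^2 + (tr$y - 3000)^2)
  expect_lt(stats::quantile(d, 0.99), 500)
})

test_that("fix timestamps are strictly increasing per wolf", {
  L <- tiny_landscape()
  tr <- sim_wolf_tracks(L, pack_config(n_packs = 2, n_days = 10))
  by_wolf <- split(tr$t, tr$animal_id)
  expect_true(all(vapply(by_wolf, function(t) all(diff(t) > 0),
                         logical(1))))
})

test_that("territory centers outside the landscape are rejected", {
  L <- tiny_landscape()
  pc <- pack_config(n_packs = 1,
                    territory_centers = matrix(c(99999, 0), 1))
  expect_error(sim_wolf_tracks(L, pc), "outside")
})

test_that("kill sites honor sample size, schema, and selection bias", {
  L <- tiny_landscape(extent = c(6000, 6000), seed = 4)
  pc <- pack_config(n_packs = 1, n_collared = 2, n_days = 120,
                    territory_centers = matrix(c(3000, 3000), 1), seed = 5)
  tr <- sim_wolf_tracks(L, pc)
  expect_error(sim_kill_sites(tr, L, c(canopy = 0), -1), ">= 0")
  expect_identical(nrow(sim_kill_sites(tr, L, c(canopy = 0), 0)), 0L)
  ks <- sim_kill_sites(tr, L, c(canopy = 2), 400, seed = 6)
  expect_identical(nrow(ks), 400L)
  kcan <- raster_extract(ks, L$canopy, col = "canopy")$canopy
  # strong positive coefficient on canopy shifts kills toward high canopy
  terr <- elkrisk:::territory_summaries(tr)
  cen <- raster_centers(L$canopy)
  dx <- outer(rep(1, length(cen$y)), cen$x - terr$cx[1])
  dy <- outer(cen$y - terr$cy[1], rep(1, length(cen$x)))
  terr_mean <- mean(L$canopy$values[dx^2 + dy^2 <= terr$radius[1]^2])
  expect_gt(mean(kcan), terr_mean)
})

test_that("null kill model places kills uniformly over the territory", {
  # chi-square against the cell-count expectation (the territory disc is
  # clipped by the landscape), non-significant at alpha = 0.01 in most
  # seeds under kill_beta = 0
  L <- tiny_landscape(extent = c(6000, 6000), seed = 9)
  pc <- pack_config(n_packs = 1, n_collared = 2, n_days = 150,
                    territory_centers = matrix(c(3000, 3000), 1), seed = 3)
  tr <- sim_wolf_tracks(L, pc)
  terr <- elkrisk:::territory_summaries(tr)
  cen <- raster_centers(L$canopy)
  dcell <- sqrt(outer(rep(1, length(cen$y)), (cen$x - terr$cx[1])^2) +
                  outer((cen$y - terr$cy[1])^2, rep(1, length(cen$x))))
  in_terr <- dcell <= terr$radius[1]
  p_inner <- sum(dcell[in_terr] <= terr$radius[1] / sqrt(2)) /
    sum(in_terr)
  pvals <- vapply(1:20, function(s) {
    ks <- sim_kill_sites(tr, L, c(canopy = 0), 300, seed = 100 + s)
    d <- sqrt((ks$x - terr$cx[1])^2 + (ks$y - terr$cy[1])^2)
    inner <- factor(d <= terr$radius[1] / sqrt(2),
                    levels = c(FALSE, TRUE))
    stats::chisq.test(table(inner),
                      p = c(1 - p_inner, p_inner))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})
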