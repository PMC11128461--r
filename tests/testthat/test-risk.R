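make_rsf_fixture <- function(seed = 61) {
  set.seed(seed)
  d <- tibble::tibble(used = rep(c(1, 0), each = 300),
                      canopy = c(rnorm(300, 55, 9), rnorm(300, 45, 9)),
                      veg_height = rnorm(600, 2, 0.5))
  fit_selection(d, c("canopy", "veg_height"))
}

test_that("predicted wolf presence is the UD x RSF product", {
  rsf <- make_rsf_fixture()
  ud <- grid_raster(matrix(0.004, 20, 20), cell_x = 380, cell_y = 450)
  obs <- tibble::tibble(x = c(2000, 5000), y = c(3000, 6000),
                        date = as.Date("2019-06-15"),
                        canopy = rsf$constants$mean[1],
                        veg_height = rsf$constants$mean[2])
  out <- predicted_wolf_presence(obs, ud, rsf, radius = 800)
  # RSF score is exactly 1 at the training means -> metric = buffer-mean UD
  expect_equal(out$rsf_score, c(1, 1))
  expect_equal(out$risk, out$ud_mean)
  expect_identical(out$metric, rep("UDxRSF", 2))
  # zero wolf use annihilates the metric regardless of the RSF
  ud0 <- grid_raster(matrix(0, 20, 20), cell_x = 380, cell_y = 450)
  obs$canopy <- 80
  out0 <- predicted_wolf_presence(obs, ud0, rsf, radius = 800)
  expect_equal(out0$risk, c(0, 0))
  expect_error(predicted_wolf_presence(obs, ud, rsf, radius = 500))
})

test_that("changing only the UD scale changes the metric by the UD factor", {
  rsf <- make_rsf_fixture()
  ud_a <- grid_raster(matrix(0.002, 20, 20), cell_x = 380, cell_y = 450)
  ud_b <- grid_raster(matrix(0.006, 20, 20), cell_x = 380, cell_y = 450)
  obs <- tibble::tibble(x = 4000, y = 4000, date = as.Date("2019-06-15"),
                        canopy = 60, veg_height = 2.4)
  r_a <- predicted_wolf_presence(obs, ud_a, rsf, radius = 200)
  r_b <- predicted_wolf_presence(obs, ud_b, rsf, radius = 200)
  expect_equal(r_b$risk / r_a$risk, 3)
  expect_equal(r_a$rsf_score, r_b$rsf_score)
})

test_that("risky-places scores recover the generating kill intensity", {
  L <- tiny_landscape(extent = c(6000, 6000), seed = 62)
  pc <- pack_config(n_packs = 1, n_collared = 2, n_days = 200,
                    territory_centers = matrix(c(3000, 3000), 1), seed = 63)
  tr <- sim_wolf_tracks(L, pc)
  beta_true <- c(canopy = 1.2, veg_height = -0.8)
  kills <- sim_kill_sites(tr, L, beta_true, 400, seed = 64)
  avail <- tibble::tibble(x = runif(800, 100, 5900),
                          y = runif(800, 100, 5900))
  rp_data <- dplyr::bind_rows(
    dplyr::mutate(kills[c("x", "y")], used = 1L),
    dplyr::mutate(avail, used = 0L))
  for (cv in c("canopy", "veg_height")) {
    rp_data <- raster_extract(rp_data, L[[cv]], col = cv)
  }
  rp <- fit_selection(rp_data, c("canopy", "veg_height"))
  set.seed(65)
  test_pts <- tibble::tibble(x = runif(500, 100, 5900),
                             y = runif(500, 100, 5900))
  for (cv in c("canopy", "veg_height")) {
    test_pts <- raster_extract(test_pts, L[[cv]], col = cv)
  }
  scored <- risky_places(test_pts, rp)
  true_int <- exp(1.2 * scale(test_pts$canopy) -
                    0.8 * scale(test_pts$veg_height))
  expect_gt(cor(scored$risk, true_int, method = "spearman"), 0.9)
  expect_identical(unique(scored$metric), "RP")
  # UD x RP product carries the same zero-annihilation property
  ud0 <- grid_raster(matrix(0, 10, 10), xmin = 0, ymin = 0,
                     cell_x = 600, cell_y = 600)
  rel <- risky_places_relative(
    dplyr::mutate(test_pts[1:5, ], date = as.Date("2019-06-15")),
    ud0, rp, radius = 2000)
  expect_equal(rel$risk, rep(0, 5))
})

test_that("log transform of risk handles zeros with a data-driven offset", {
  x <- c(0, 0.001, 0.5, 2)
  lx <- log_risk(x)
  expect_equal(lx[2:4], log(c(0.001, 0.5, 2) + 0.001 * 1e-3))
  expect_true(is.finite(lx[1]))
  expect_lt(lx[1], lx[2])
  expect_error(log_risk(c(-1, 2)), "non-negative")
})
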