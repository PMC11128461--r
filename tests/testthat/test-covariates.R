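test_that("openness hits its extremes and matches brute force", {
  zeros <- grid_raster(matrix(0, 25, 25), cell_x = 30)
  full <- openness(zeros)
  expect_identical(full$values[13, 13], 289)
  closed <- grid_raster(matrix(100, 25, 25), cell_x = 30)
  expect_true(all(openness(closed)$values == 0))
  # single open pixel: counts equal the window-overlap indicator
  one <- matrix(100, 25, 25); one[10, 12] <- 0
  op1 <- openness(grid_raster(one, cell_x = 30))
  for (i in c(1, 3, 10, 18, 25)) {
    for (j in c(2, 12, 20)) {
      expect_identical(op1$values[i, j],
                       as.double(abs(i - 10) <= 8 && abs(j - 12) <= 8))
    }
  }
  set.seed(5)
  rc <- grid_raster(matrix(runif(900, 0, 100), 30, 30), cell_x = 30)
  op <- openness(rc)
  for (k in 1:25) {
    i <- sample(30, 1); j <- sample(30, 1)
    expect_identical(op$values[i, j], as.double(brute_openness(rc, i, j)))
  }
  expect_error(openness(grid_raster(matrix(0, 5, 5), cell_x = 90)), "30 m")
})

test_that("buffer means agree with exhaustive enumeration", {
  set.seed(6)
  r <- grid_raster(matrix(runif(30 * 28), 28, 30),
                   cell_x = 380, cell_y = 450)
  for (radius in c(200, 800, 2000)) {
    for (k in 1:8) {
      x <- runif(1, 400, 10000); y <- runif(1, 500, 11000)
      expect_equal(buffer_mean(r, x, y, radius),
                   brute_buffer_mean(r, x, y, radius))
    }
  }
  cst <- grid_raster(matrix(7, 28, 30), cell_x = 380, cell_y = 450)
  for (radius in c(200, 800, 2000)) {
    expect_equal(buffer_mean(cst, 5000, 6000, radius), 7)
  }
  # checkerboard at the widest radius averages to one half
  chk <- grid_raster(outer(1:28, 1:30, function(i, j) (i + j) %% 2),
                     cell_x = 380, cell_y = 450)
  expect_lt(abs(buffer_mean(chk, 5320, 6300, 2000) - 0.5), 0.05)
  expect_error(buffer_mean(r, -5000, 0, 200), "outside")
})

test_that("diel periods follow the twilight anchors and majority rule", {
  lat <- 33.9; lon <- -108.8
  tw <- civil_twilight(as.Date("2019-06-15"), lat, lon)
  expect_identical(as.character(assign_diel(tw$dawn + 3600, lat, lon)),
                   "morning")
  expect_identical(as.character(assign_diel(tw$dawn + 2.6 * 3600, lat, lon)),
                   "midday")
  expect_identical(as.character(assign_diel(tw$dusk - 1800, lat, lon)),
                   "evening")
  expect_identical(
    as.character(assign_diel(tw$dusk - 1800, lat, lon, scheme = "two")),
    "crepuscular")
  expect_error(assign_diel(tw$dawn - 3600, lat, lon), "daylight")
  # 20-minute session with 11 minutes of midday before the evening window
  start <- tw$dusk - 2 * 3600 - 11 * 60
  expect_identical(as.character(assign_diel_session(start, 20, lat, lon)),
                   "midday")
  expect_identical(as.character(assign_diel_session(start + 120, 20, lat,
                                                    lon)),
                   "evening")
})

test_that("maternal periods follow the parturition boundary rules", {
  expect_identical(as.character(assign_maternal(as.Date("2019-02-15"))),
                   "WP")
  part <- as.Date("2019-06-05")
  expect_identical(
    as.character(assign_maternal(as.Date(c("2019-06-04", "2019-06-05")),
                                 part)),
    c("PPP", "LMP"))
  # unknown parturition: last PPP day is Julian 134
  expect_identical(
    as.character(assign_maternal(as.Date("2019-01-01") + c(133, 134))),
    c("PPP", "LMP"))
  expect_error(assign_maternal(as.Date("2019-10-01")), "season")
})

test_that("cover classification and distance honor the thresholds", {
  cv <- grid_raster(matrix(c(10, 50, 10, 5), 2, 2), cell_x = 30)
  ht <- grid_raster(matrix(c(1, 5, 5, 1), 2, 2), cell_x = 30)
  cc <- cover_class(cv, ht)
  expect_identical(as.vector(cc$values), c(0, 1, 2, 0))
  # distance 0 at the cover cell center, Euclidean elsewhere
  cen <- raster_centers(cc)
  expect_identical(distance_to_cover(cc, cen$x[1], cen$y[2]), 0)
  expect_equal(distance_to_cover(cc, cen$x[1], cen$y[1]), 30)
  none <- cover_class(cv, grid_raster(matrix(1, 2, 2), cell_x = 30))
  expect_identical(distance_to_cover(none, 10, 10), Inf)
})

test_that("herd metrics compute size and cow proportion", {
  d <- tibble::tibble(cows = c(10, 1, 12), calves = c(5, 0, 6),
                      bulls = c(0, 0, 3), spikes = c(0, 0, 3))
  out <- herd_metrics(d)
  expect_equal(out$herd_size, c(15, 1, 24))
  expect_equal(out$prop_cows, c(2 / 3, 1, 0.5))
  expect_error(herd_metrics(tibble::tibble(cows = 0, calves = 0, bulls = 0,
                                           spikes = 0)), "herd size")
})

test_that("the collinearity screen flags what it should and nothing else", {
  set.seed(7)
  x <- rnorm(1000)
  d <- tibble::tibble(x = x, double_x = 2 * x, const = 1,
                      grp = factor(sample(letters[1:3], 1000, TRUE)))
  d$shifted <- rnorm(1000) + 3 * (as.integer(d$grp) - 2)
  rep <- screen_collinearity(d)
  expect_true(any(rep$test == "degenerate" & rep$var1 == "const"))
  expect_true(any(rep$test == "spearman" & rep$var1 == "x" &
                    rep$var2 == "double_x"))
  expect_true(any(rep$test == "kruskal-wallis" &
                    rep$var2 == "shifted" | rep$var1 == "shifted"))
  # independent uniforms rarely flagged
  flags <- vapply(1:60, function(s) {
    set.seed(900 + s)
    dd <- tibble::tibble(a = runif(1000), b = runif(1000))
    nrow(screen_collinearity(dd)) > 0
  }, logical(1))
  expect_lt(mean(flags), 0.05 + 0.05)
})

test_that("standardization round-trips and stores reusable constants", {
  d <- tibble::tibble(a = c(-1, 1, -1, 1), b = rnorm(4))
  st <- standardize_covariates(d)
  expect_equal(mean(st$data$a), 0)
  expect_equal(sd(st$data$a), 1)
  back <- apply_standardization(st$data, st$constants, invert = TRUE)
  expect_equal(back$a, d$a, tolerance = 1e-12)
  expect_equal(back$b, d$b, tolerance = 1e-12)
  new <- apply_standardization(tibble::tibble(a = 5), st$constants)
  expect_equal(new$a, (5 - mean(d$a)) / sd(d$a))
  expect_error(standardize_covariates(tibble::tibble(a = rep(2, 5))),
               "zero standard deviation")
})
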