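# Shared fixtures, all generated in code.

# Small landscape used across spatial tests.
tiny_landscape <- function(seed = 11, extent = c(3000, 3000)) {
  sim_landscape(landscape_config(extent = extent, seed = seed))
}

# Session-level compositions drawn from the Dirichlet regression's own
# data-generating process (known slope on vigilance), for recovery and
# calibration checks.
sim_dirichlet_comps <- function(n, n_herds = 12, beta_risk = 0.5, phi = 25,
                                herd_sd = 0.3, n_minutes = 200, seed = 1) {
  set.seed(seed)
  risk_z <- rnorm(n)
  herd <- sprintf("H%02d", sample(n_herds, n, TRUE))
  zh <- matrix(rnorm(n_herds * 4), n_herds) * herd_sd
  eta <- cbind(0.9 + 0.15 * risk_z, -0.3 + beta_risk * risk_z,
               0.5 - 0.4 * risk_z, -1.5) + zh[as.integer(factor(herd)), ]
  E <- cbind(exp(eta), 1)
  mu <- E / rowSums(E)
  g <- matrix(rgamma(n * 5, shape = mu * phi), n)
  g[g == 0] <- 1e-300
  p <- g / rowSums(g)
  # invert the boundary squeeze applied at fit time, so the fitted model is
  # exactly the generating process (exact simulation-based calibration)
  p <- pmax((p * n_minutes - 1 / 5) / (n_minutes - 1), 0)
  p <- p / rowSums(p)
  colnames(p) <- c("foraging", "vigilance", "resting_ruminating", "other",
                   "traveling")
  d <- tibble::as_tibble(p)
  d$n_minutes <- n_minutes
  d$risk_z <- risk_z
  d$herd_id <- herd
  d
}

# Conjugate normal-mean model (known variance 1, prior N(0, 100)): the
# closed-form oracle for ELPD machinery.  fit/logpred follow the interface
# of kfold_elpd().
normal_fit <- function(data) {
  n <- nrow(data)
  v <- 1 / (n / 1 + 1 / 100)
  list(m = v * sum(data$y), v = v, converged = TRUE)
}
normal_logpred <- function(fit, newdata) {
  dnorm(newdata$y, mean = fit$m, sd = sqrt(fit$v + 1), log = TRUE)
}

# brute-force evaluation of a buffer mean by cell enumeration
brute_buffer_mean <- function(r, x, y, radius) {
  cen <- raster_centers(r)
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(r$values))) {
    for (j in seq_len(ncol(r$values))) {
      if ((cen$x[j] - x)^2 + (cen$y[i] - y)^2 <= radius^2) {
        tot <- tot + r$values[i, j]; cnt <- cnt + 1
      }
    }
  }
  if (cnt == 0) {
    col <- floor((x - r$xmin) / r$cell_x) + 1
    row <- floor((y - r$ymin) / r$cell_y) + 1
    return(r$values[row, col])
  }
  tot / cnt
}

# brute-force openness count at one pixel
brute_openness <- function(canopy, i, j, threshold = 30, half = 8) {
  nr <- nrow(canopy$values); nc <- ncol(canopy$values)
  w <- canopy$values[max(1, i - half):min(nr, i + half),
                     max(1, j - half):min(nc, j + half), drop = FALSE]
  sum(w <= threshold)
}
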