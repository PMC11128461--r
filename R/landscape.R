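# Synthetic landscapes: stationary autocorrelated surfaces standing in for
# canopy-cover and vegetation structure rasters.  Fields are produced by
# FFT convolution of white noise with a Gaussian kernel: cheap, seedable, and
# only the autocorrelation structure matters downstream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for a synthetic landscape
#'
#' Describes three co-registered random fields: percent canopy cover, percent
#' vegetation coverage and vegetation height.  Each field is given a mean,
#' a sill (marginal variance before truncation) and an autocorrelation range
#' in meters (distance at which the empirical variogram has essentially
#' reached the sill).
#'
#' @param extent width and height of the landscape in meters.
#' @param cell_size cell size in meters (30 m, the resolution of national
#'   canopy products).
#' @param canopy,veg_coverage,veg_height per-field parameter lists with
#'   elements `mean`, `sill`, `range`.
#' @param seed integer seed; identical seeds give bit-identical rasters.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(9000, 9000), cell_size = 30,
                             canopy = list(mean = 40, sill = 600, range = 900),
                             veg_coverage = list(mean = 30, sill = 400, range = 900),
                             veg_height = list(mean = 2, sill = 2.25, range = 900),
                             seed = 1L) {
  if (any(extent <= 0) || cell_size <= 0) {
    stop("extent and cell_size must be positive", call. = FALSE)
  }
  if (any(abs(extent / cell_size - round(extent / cell_size)) > 1e-9)) {
    stop("extent must divide into whole cells", call. = FALSE)
  }
  structure(list(extent = extent, cell_size = cell_size, canopy = canopy,
                 veg_coverage = veg_coverage, veg_height = veg_height,
                 seed = seed),
            class = "landscape_config")
}

# Gaussian random field on an nr x nc grid via circular FFT convolution of
# white noise with a wrapped Gaussian kernel (sd = range/3 cells), scaled to
# variance `sill`.
gaussian_field <- function(nr, nc, range_cells, sill) {
  if (sill <= 0) return(matrix(0, nr, nc))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells <= 0) return(sqrt(sill) * z)
  s <- range_cells / 3
  kx <- stats::dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), sd = s)
  ky <- stats::dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), sd = s)
  k <- outer(ky, kx)                     # separable wrapped kernel
  k <- k / sqrt(sum(k^2))                # unit variance after convolution
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  sqrt(sill) * f
}

#' Generate a synthetic landscape
#'
#' Produces three co-registered rasters — percent canopy cover, percent
#' vegetation coverage (both clamped to \[0, 100\]) and vegetation height
#' (clamped at 0) — with the autocorrelation structure given in `config`.
#' Deterministic under `config$seed`.
#'
#' @param config a [landscape_config()].
#' @return A list of class `landscape` with elements `canopy`,
#'   `veg_coverage`, `veg_height` ([grid_raster()]s) and `config`.
#' @export
sim_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nc <- as.integer(round(config$extent[1] / config$cell_size))
  nr <- as.integer(round(config$extent[2] / config$cell_size))
  fields <- with_seed(config$seed, {
    lapply(config[c("canopy", "veg_coverage", "veg_height")], function(f) {
      f$mean + gaussian_field(nr, nc, f$range / config$cell_size, f$sill)
    })
  })
  clamp <- function(m, lo, hi = Inf) pmin(pmax(m, lo), hi)
  mk <- function(m) grid_raster(m, cell_x = config$cell_size)
  structure(list(
    canopy = mk(clamp(fields$canopy, 0, 100)),
    veg_coverage = mk(clamp(fields$veg_coverage, 0, 100)),
    veg_height = mk(clamp(fields$veg_height, 0)),
    config = config
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %g x %g m at %g m cells (seed %d)\n",
              x$config$extent[1], x$config$extent[2], x$config$cell_size,
              x$config$seed))
  invisible(x)
}

#' Empirical isotropic variogram of a raster
#'
#' Brute-force semivariance over random cell pairs, binned by separation
#' distance; used to verify the generated autocorrelation structure.
#'
#' @param r a [grid_raster()].
#' @param breaks distance bin edges in meters.
#' @param n_pairs number of random pairs to sample.
#' @param seed RNG seed for pair sampling.
#' @return A tibble with `dist` (bin midpoint), `gamma` (semivariance) and
#'   `n` (pairs per bin).
#' @export
empirical_variogram <- function(r, breaks = seq(0, 3000, by = 150),
                                n_pairs = 2e5, seed = 1L) {
  cen <- raster_centers(r)
  nr <- nrow(r$values); nc <- ncol(r$values)
  with_seed(seed, {
    i1 <- sample.int(nr * nc, n_pairs, replace = TRUE)
    i2 <- sample.int(nr * nc, n_pairs, replace = TRUE)
    r1 <- (i1 - 1L) %% nr + 1L; c1 <- (i1 - 1L) %/% nr + 1L
    r2 <- (i2 - 1L) %% nr + 1L; c2 <- (i2 - 1L) %/% nr + 1L
    d <- sqrt((cen$x[c1] - cen$x[c2])^2 + (cen$y[r1] - cen$y[r2])^2)
    sv <- 0.5 * (r$values[i1] - r$values[i2])^2
    bin <- cut(d, breaks, include.lowest = TRUE)
    tibble::tibble(
      dist = (breaks[-length(breaks)] + breaks[-1]) / 2,
      gamma = as.vector(tapply(sv, bin, mean)),
      n = as.vector(tapply(sv, bin, length))
    )
  })
}
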