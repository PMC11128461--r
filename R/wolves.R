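# Synthetic wolf GPS data: biased correlated random walks around territory
# centers with a diel speed curve, and landscape-biased kill sites.

#' Season of a date
#'
#' Fixed season scheme: spring (Apr 1 - Jun 30), monsoon (Jul 1 - Sep 30),
#' fall (Oct 1 - Dec 31), winter (Jan 1 - Mar 31).
#'
#' @param date a Date vector (or something coercible).
#' @return Factor with levels winter, spring, monsoon, fall.
#' @export
season_of <- function(date) {
  m <- lubridate::month(as.Date(date))
  s <- dplyr::case_when(
    m <= 3 ~ "winter",
    m <= 6 ~ "spring",
    m <= 9 ~ "monsoon",
    TRUE ~ "fall"
  )
  factor(s, levels = c("winter", "spring", "monsoon", "fall"))
}

#' Configuration for synthetic wolf packs
#'
#' @param n_packs number of packs.
#' @param territory_centers optional `n_packs` x 2 matrix of territory-center
#'   coordinates (meters); defaults to a jittered grid filling the landscape.
#' @param territory_scale spatial scale of a territory in meters (controls
#'   how far walks range from the center).
#' @param pack_sizes_by_season `n_packs` x 4 matrix of wolf counts with
#'   columns winter, spring, monsoon, fall; recycled from a vector.
#' @param n_collared GPS-collared wolves simulated per pack.
#' @param fix_interval_h hours between GPS fixes (2).
#' @param diel_speed_curve function of hour-of-day (0-24) returning the mean
#'   step length in km per fix interval; default is crepuscular-peaked.
#' @param step_shape gamma shape of step lengths; smaller = more
#'   overdispersed.
#' @param attraction weight in (0, 1] pulling each step's heading toward the
#'   territory center (1 = always homeward).
#' @param turn_concentration wrapped-Cauchy concentration of turning angles.
#' @param start_date first fix date.
#' @param n_days days of tracking per wolf.
#' @param seed integer seed.
#' @return A list of class `pack_config`.
#' @export
pack_config <- function(n_packs = 3, territory_centers = NULL,
                        territory_scale = 2000,
                        pack_sizes_by_season = 5, n_collared = 2,
                        fix_interval_h = 2,
                        diel_speed_curve = function(hour) {
                          0.9 + 0.5 * cos(2 * pi * (hour - 5.5) / 12)
                        },
                        step_shape = 1.5, attraction = 0.15,
                        turn_concentration = 0.5,
                        start_date = as.Date("2019-01-01"), n_days = 365,
                        seed = 1L) {
  sizes <- matrix(pack_sizes_by_season, nrow = max(n_packs, 1), ncol = 4)
  colnames(sizes) <- c("winter", "spring", "monsoon", "fall")
  if (n_packs > 0 && any(sizes < 1)) {
    stop("pack sizes must be >= 1", call. = FALSE)
  }
  structure(list(
    n_packs = n_packs, territory_centers = territory_centers,
    territory_scale = territory_scale, pack_sizes_by_season = sizes,
    n_collared = n_collared, fix_interval_h = fix_interval_h,
    diel_speed_curve = diel_speed_curve, step_shape = step_shape,
    attraction = attraction, turn_concentration = turn_concentration,
    start_date = as.Date(start_date), n_days = n_days, seed = seed
  ), class = "pack_config")
}

default_centers <- function(n, xmax, ymax, margin) {
  k <- ceiling(sqrt(n))
  gx <- seq(margin, xmax - margin, length.out = k + 2)[2:(k + 1)]
  gy <- seq(margin, ymax - margin, length.out = k + 2)[2:(k + 1)]
  g <- expand.grid(x = gx, y = gy)[seq_len(n), , drop = FALSE]
  as.matrix(g)
}

rwrapped_cauchy <- function(n, rho) {
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  scale <- (1 - rho) / (1 + rho)
  2 * atan(scale * tan(pi * (stats::runif(n) - 0.5)))
}

#' Simulate wolf GPS tracks
#'
#' Each collared wolf performs a biased correlated random walk attracted to
#' its pack's territory center.  Step lengths are gamma with mean taken from
#' the diel speed curve at the fix hour; headings mix the previous heading
#' with the homeward bearing and a wrapped-Cauchy turning error.  Fixes are
#' reflected at the landscape boundary.
#'
#' @param landscape a `landscape` from [sim_landscape()].
#' @param packs a [pack_config()].
#' @return A tibble (`FixTable`) with columns `animal_id`, `pack_id`, `t`
#'   (POSIXct, UTC), `x`, `y`.
#' @export
sim_wolf_tracks <- function(landscape, packs) {
  stopifnot(inherits(packs, "pack_config"))
  schema <- tibble::tibble(animal_id = character(), pack_id = character(),
                           t = as.POSIXct(character(), tz = "UTC"),
                           x = numeric(), y = numeric())
  if (packs$n_packs == 0) return(schema)
  xmax <- raster_xmax(landscape$canopy); ymax <- raster_ymax(landscape$canopy)
  centers <- packs$territory_centers
  if (is.null(centers)) {
    centers <- default_centers(packs$n_packs, xmax, ymax,
                               margin = packs$territory_scale)
  }
  if (any(centers[, 1] < 0 | centers[, 1] > xmax |
          centers[, 2] < 0 | centers[, 2] > ymax)) {
    stop("territory center outside landscape", call. = FALSE)
  }
  n_fix <- as.integer(packs$n_days * 24 / packs$fix_interval_h)
  times <- as.POSIXct(packs$start_date, tz = "UTC") +
    (seq_len(n_fix) - 1L) * packs$fix_interval_h * 3600
  hours <- as.numeric(format(times, "%H", tz = "UTC")) +
    as.numeric(format(times, "%M", tz = "UTC")) / 60
  mean_step_m <- pmax(packs$diel_speed_curve(hours), 1e-6) * 1000

  with_seed(packs$seed, {
    out <- vector("list", packs$n_packs * packs$n_collared)
    k <- 0L
    for (p in seq_len(packs$n_packs)) {
      for (w in seq_len(packs$n_collared)) {
        k <- k + 1L
        pos <- matrix(NA_real_, n_fix, 2)
        pos[1, ] <- centers[p, ] + stats::rnorm(2, sd = packs$territory_scale / 4)
        heading <- stats::runif(1, -pi, pi)
        for (i in seq_len(n_fix - 1L)) {
          step <- stats::rgamma(1, shape = packs$step_shape,
                                scale = mean_step_m[i] / packs$step_shape)
          to_center <- atan2(centers[p, 2] - pos[i, 2],
                             centers[p, 1] - pos[i, 1])
          a <- packs$attraction
          mu <- atan2(a * sin(to_center) + (1 - a) * sin(heading),
                      a * cos(to_center) + (1 - a) * cos(heading))
          heading <- mu + rwrapped_cauchy(1, packs$turn_concentration)
          nx <- pos[i, 1] + step * cos(heading)
          ny <- pos[i, 2] + step * sin(heading)
          # reflect at boundaries
          while (nx < 0 || nx > xmax) nx <- ifelse(nx < 0, -nx, 2 * xmax - nx)
          while (ny < 0 || ny > ymax) ny <- ifelse(ny < 0, -ny, 2 * ymax - ny)
          pos[i + 1L, ] <- c(nx, ny)
        }
        out[[k]] <- tibble::tibble(
          animal_id = sprintf("P%02dW%d", p, w),
          pack_id = sprintf("P%02d", p),
          t = times, x = pos[, 1], y = pos[, 2]
        )
      }
    }
    dplyr::bind_rows(out)
  })
}

territory_summaries <- function(tracks, prob = 0.95) {
  tracks |>
    dplyr::group_by(.data$pack_id) |>
    dplyr::summarise(
      cx = mean(.data$x), cy = mean(.data$y),
      radius = stats::quantile(sqrt((.data$x - mean(.data$x))^2 +
                                      (.data$y - mean(.data$y))^2), prob),
      t_min = min(.data$t), t_max = max(.data$t),
      .groups = "drop"
    )
}

#' Simulate kill sites biased by landscape covariates
#'
#' Kill locations are drawn cell-wise within each pack's territory (the
#' region of cells within the 95th-percentile fix radius of the pack
#' centroid) with probability proportional to
#' `exp(kill_beta . covariates)`, covariates standardized over the
#' territory's cells.  `kill_beta = 0` therefore gives uniform placement.
#'
#' @param tracks a fix table from [sim_wolf_tracks()].
#' @param landscape a `landscape`.
#' @param kill_beta named numeric vector of selection coefficients; names
#'   must match landscape rasters (`canopy`, `veg_coverage`, `veg_height`) or
#'   entries of `extra`.
#' @param n_kills total number of kills to place.
#' @param seed integer seed.
#' @param extra named list of additional [grid_raster()] covariates (e.g. an
#'   openness raster).
#' @return A tibble (`KillSiteTable`) with `pack_id`, `x`, `y`, `date`.
#' @export
sim_kill_sites <- function(tracks, landscape, kill_beta, n_kills, seed = 1L,
                           extra = list()) {
  if (n_kills < 0) stop("n_kills must be >= 0", call. = FALSE)
  schema <- tibble::tibble(pack_id = character(), x = numeric(),
                           y = numeric(), date = as.Date(character()))
  if (n_kills == 0) return(schema)
  rasters <- c(landscape[c("canopy", "veg_coverage", "veg_height")], extra)
  missing_cov <- setdiff(names(kill_beta), names(rasters))
  if (length(missing_cov)) {
    stop("kill_beta names not found among covariates: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  terr <- territory_summaries(tracks)
  base <- rasters[[1]]
  cen <- raster_centers(base)
  with_seed(seed, {
    pack_idx <- sample.int(nrow(terr), n_kills, replace = TRUE)
    kills <- lapply(seq_len(nrow(terr)), function(i) {
      n_i <- sum(pack_idx == i)
      if (n_i == 0) return(NULL)
      dx <- outer(rep(1, length(cen$y)), cen$x - terr$cx[i])
      dy <- outer(cen$y - terr$cy[i], rep(1, length(cen$x)))
      inside <- which(dx * dx + dy * dy <= terr$radius[i]^2)
      lp <- rep(0, length(inside))
      for (nm in names(kill_beta)) {
        v <- rasters[[nm]]$values[inside]
        s <- stats::sd(v)
        if (s > 0) lp <- lp + kill_beta[[nm]] * (v - mean(v)) / s
      }
      pr <- exp(lp - max(lp))
      cells <- inside[sample.int(length(inside), n_i, replace = TRUE,
                                 prob = pr)]
      row <- (cells - 1L) %% nrow(base$values) + 1L
      col <- (cells - 1L) %/% nrow(base$values) + 1L
      tibble::tibble(
        pack_id = terr$pack_id[i],
        x = base$xmin + (col - stats::runif(n_i)) * base$cell_x,
        y = base$ymin + (row - stats::runif(n_i)) * base$cell_y,
        date = as.Date(terr$t_min[i]) +
          sample.int(max(as.integer(as.Date(terr$t_max[i]) -
                                      as.Date(terr$t_min[i])), 1), n_i,
                     replace = TRUE) - 1L
      )
    })
    dplyr::bind_rows(schema, kills)
  })
}
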