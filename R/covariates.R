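# Non-risk covariates: diel periods anchored on civil twilight, maternal
# periods, canopy openness, cover classification, herd metrics, the
# collinearity screen, and covariate standardization.

deg2rad <- function(x) x * pi / 180

#' Civil twilight times
#'
#' Computes morning and evening civil twilight (sun 6 degrees below the
#' horizon) for a date and location with the standard NOAA solar-position
#' equations.
#'
#' @param date Date vector.
#' @param lat,lon latitude and longitude in decimal degrees (lon west
#'   negative).
#' @return A tibble with POSIXct (UTC) columns `dawn` and `dusk`.
#' @export
civil_twilight <- function(date, lat, lon) {
  date <- as.Date(date)
  doy <- lubridate::yday(date)
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  zen <- deg2rad(96)  # 90 deg + 6 deg civil twilight
  cos_ha <- (cos(zen) - sin(deg2rad(lat)) * sin(decl)) /
    (cos(deg2rad(lat)) * cos(decl))
  if (any(abs(cos_ha) > 1)) {
    stop("no civil twilight at this latitude/date", call. = FALSE)
  }
  ha <- acos(cos_ha) * 180 / pi
  dawn_min <- 720 - 4 * (lon + ha) - eqtime
  dusk_min <- 720 - 4 * (lon - ha) - eqtime
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tibble::tibble(dawn = midnight + dawn_min * 60,
                 dusk = midnight + dusk_min * 60)
}

diel_levels <- function(scheme) {
  if (scheme == "three") c("midday", "morning", "evening")
  else c("midday", "crepuscular")
}

#' Assign diel periods from civil twilight
#'
#' Morning runs from morning civil twilight to 2.5 h after; evening from 2 h
#' before evening civil twilight to evening civil twilight; midday is the gap
#' between.  The two-period scheme pools morning and evening into
#' `crepuscular`.  Midday is the reference level.
#'
#' @param time POSIXct vector (UTC).
#' @param lat,lon observation coordinates in decimal degrees.
#' @param scheme `"three"` or `"two"`.
#' @return Factor of diel periods.
#' @export
assign_diel <- function(time, lat, lon, scheme = c("three", "two")) {
  scheme <- match.arg(scheme)
  # the calendar day at the observation longitude (UTC timestamps from an
  # evening observation can fall on the next UTC date)
  local_date <- lubridate::as_date(time + lon / 15 * 3600)
  tw <- civil_twilight(local_date, lat, lon)
  if (any(time < tw$dawn | time > tw$dusk)) {
    stop("timestamp outside civil daylight (nocturnal observations are ",
         "out of scope)", call. = FALSE)
  }
  per <- dplyr::case_when(
    time <= tw$dawn + 2.5 * 3600 ~ "morning",
    time >= tw$dusk - 2 * 3600 ~ "evening",
    TRUE ~ "midday"
  )
  if (scheme == "two") per[per != "midday"] <- "crepuscular"
  factor(per, levels = diel_levels(scheme))
}

#' Diel period of a whole focal session
#'
#' Assigns each minute of the session and returns the period holding the
#' majority of minutes (first-encountered period on ties).
#'
#' @param start session start time (POSIXct, UTC).
#' @param n_minutes session length in minutes.
#' @inheritParams assign_diel
#' @return Length-1 factor.
#' @export
assign_diel_session <- function(start, n_minutes, lat, lon,
                                scheme = c("three", "two")) {
  scheme <- match.arg(scheme)
  minutes <- start + 60 * (seq_len(n_minutes) - 1)
  per <- assign_diel(minutes, lat, lon, scheme)
  tab <- table(per)
  factor(names(tab)[which.max(tab)], levels = diel_levels(scheme))
}

maternal_levels <- c("LMP", "PPP", "SMP", "WP")

#' Assign maternal periods
#'
#' Winter period (WP) is Jan 1 - Mar 31.  The pre-parturition period (PPP)
#' begins Apr 1 and ends the day before parturition when the date is known;
#' otherwise it ends at Julian day 134, the mean parturition Julian day (152)
#' minus 17.4 days, floored to a calendar day.  The limited mobility period
#' (LMP) is the next 45 days and the social mobility period (SMP) runs to the
#' configured end of the field season (Julian day 250, about Sep 7).  LMP is
#' the reference level.
#'
#' @param date Date vector of observation dates.
#' @param parturition_date optional Date vector (or scalar) of known
#'   parturition dates; `NA` where unknown.
#' @param smp_end_julian last Julian day of the SMP.
#' @param ppp_cutoff_julian last PPP Julian day used when parturition is
#'   unknown.
#' @return Factor with levels LMP, PPP, SMP, WP.
#' @export
assign_maternal <- function(date, parturition_date = NULL,
                            smp_end_julian = 250, ppp_cutoff_julian = 134) {
  date <- as.Date(date)
  j <- lubridate::yday(date)
  m <- lubridate::month(date)
  if (any(m > 3 & j > smp_end_julian) || any(is.na(date))) {
    stop("date outside the Jan 1 - early September observation season",
         call. = FALSE)
  }
  if (is.null(parturition_date)) {
    cutoff <- rep(ppp_cutoff_julian, length(date))
  } else {
    pj <- lubridate::yday(as.Date(parturition_date))
    cutoff <- ifelse(is.na(pj), ppp_cutoff_julian, pj - 1)
    cutoff <- rep(cutoff, length.out = length(date))
  }
  lab <- dplyr::case_when(
    m <= 3 ~ "WP",
    j <= cutoff ~ "PPP",
    j <= cutoff + 45 ~ "LMP",
    TRUE ~ "SMP"
  )
  factor(lab, levels = maternal_levels)
}

#' Canopy openness in a moving window
#'
#' For each focal pixel, counts the pixels with canopy cover at or below
#' `threshold` percent inside a centered `window` x `window` pixel square
#' (17 x 17 thirty-meter pixels, i.e. a 510 m window approximating the
#' 500 x 500 m neighborhood; maximum count 289).  Edge pixels are counted
#' over the in-bounds part of the window.
#'
#' @param canopy percent-canopy [grid_raster()] with 30 m cells.
#' @param threshold open-canopy threshold in percent.
#' @param window window side length in pixels (odd).
#' @return A [grid_raster()] of counts on the same grid.
#' @export
openness <- function(canopy, threshold = 30, window = 17) {
  if (abs(canopy$cell_x - 30) > 1e-9 || abs(canopy$cell_y - 30) > 1e-9) {
    stop("openness expects a 30 m canopy raster", call. = FALSE)
  }
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (any(canopy$values < 0 | canopy$values > 100)) {
    stop("canopy values must lie in [0, 100]", call. = FALSE)
  }
  open <- canopy$values <= threshold
  nr <- nrow(open); nc <- ncol(open)
  # summed-area table with a zero top row / left column
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(open, 2, cumsum), 1, cumsum) |> t()
  h <- (window - 1L) %/% 2L
  i <- seq_len(nr); j <- seq_len(nc)
  i1 <- pmax(i - h, 1L); i2 <- pmin(i + h, nr)
  j1 <- pmax(j - h, 1L); j2 <- pmin(j + h, nc)
  counts <- S[cbind(rep(i2 + 1L, nc), rep(j2 + 1L, each = nr))] -
    S[cbind(rep(i1, nc), rep(j2 + 1L, each = nr))] -
    S[cbind(rep(i2 + 1L, nc), rep(j1, each = nr))] +
    S[cbind(rep(i1, nc), rep(j1, each = nr))]
  grid_raster(matrix(counts, nr, nc), xmin = canopy$xmin, ymin = canopy$ymin,
              cell_x = canopy$cell_x, cell_y = canopy$cell_y)
}

#' Classify cover from vegetation structure
#'
#' Open: percent coverage <= 16 and height <= 2 m.  Cover: coverage >= 17
#' and height > 2 m.  Cells matching neither rule are `unclassified` and are
#' treated as open by [distance_to_cover()].
#'
#' @param veg_coverage,veg_height co-registered [grid_raster()]s.
#' @return A [grid_raster()] coded 0 = open, 1 = cover, 2 = unclassified.
#' @export
cover_class <- function(veg_coverage, veg_height) {
  if (!same_grid(veg_coverage, veg_height)) {
    stop("vegetation rasters are not co-registered", call. = FALSE)
  }
  cv <- veg_coverage$values; ht <- veg_height$values
  cls <- matrix(2, nrow(cv), ncol(cv))
  cls[cv <= 16 & ht <= 2] <- 0
  cls[cv >= 17 & ht > 2] <- 1
  grid_raster(cls, xmin = veg_coverage$xmin, ymin = veg_coverage$ymin,
              cell_x = veg_coverage$cell_x, cell_y = veg_coverage$cell_y)
}

#' Distance from points to the nearest cover cell
#'
#' Euclidean distance to the nearest cell center classified as cover
#' (code 1); `Inf` when the raster contains no cover.
#'
#' @param cover a [cover_class()] raster.
#' @param x,y point coordinates (meters).
#' @return Numeric vector of distances in meters.
#' @export
distance_to_cover <- function(cover, x, y) {
  idx <- which(cover$values == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(rep(Inf, length(x)))
  cen <- raster_centers(cover)
  cx <- cen$x[idx[, "col"]]; cy <- cen$y[idx[, "row"]]
  vapply(seq_along(x), function(i) {
    sqrt(min((cx - x[i])^2 + (cy - y[i])^2))
  }, numeric(1))
}

#' Herd size and proportion of cows
#'
#' @param data data frame of herd composition counts.
#' @param cows,calves,bulls,spikes column names of the demographic counts.
#' @return `data` as a tibble with `herd_size` and `prop_cows` appended.
#' @export
herd_metrics <- function(data, cows = "cows", calves = "calves",
                         bulls = "bulls", spikes = "spikes") {
  cnt <- cbind(data[[cows]], data[[calves]], data[[bulls]], data[[spikes]])
  if (any(cnt < 0)) stop("composition counts must be >= 0", call. = FALSE)
  size <- rowSums(cnt)
  if (any(size == 0)) stop("herd size of 0 in row(s) ",
                           paste(which(size == 0), collapse = ", "),
                           call. = FALSE)
  out <- tibble::as_tibble(data)
  out$herd_size <- size
  out$prop_cows <- cnt[, 1] / size
  out
}

#' Screen covariates for collinearity
#'
#' Continuous pairs are flagged when the absolute Spearman rank correlation
#' is at or above `rho_threshold`; continuous-by-categorical pairs are tested
#' by Kruskal-Wallis and flagged at `alpha`.  Constant columns are reported
#' as degenerate and excluded from the tests.  Which member of a flagged pair
#' to keep is left to the analyst.
#'
#' @param data data frame of candidate covariates.
#' @param rho_threshold Spearman threshold (0.7).
#' @param alpha Kruskal-Wallis significance level.
#' @return A tibble of flagged pairs with columns `var1`, `var2`, `test`,
#'   `statistic`, `p_value`.
#' @export
screen_collinearity <- function(data, rho_threshold = 0.7, alpha = 0.05) {
  if (ncol(data) < 2) stop("need at least two covariates", call. = FALSE)
  is_num <- vapply(data, is.numeric, logical(1))
  degen <- names(data)[is_num][vapply(data[is_num], function(x) {
    stats::sd(x) == 0
  }, logical(1))]
  out <- list()
  for (d in degen) {
    out[[length(out) + 1L]] <- tibble::tibble(
      var1 = d, var2 = NA_character_, test = "degenerate",
      statistic = NA_real_, p_value = NA_real_)
  }
  vars <- setdiff(names(data), degen)
  if (length(vars) >= 2) {
    for (a in seq_len(length(vars) - 1)) {
      for (b in (a + 1):length(vars)) {
        va <- vars[a]; vb <- vars[b]
        na <- is_num[[va]]; nb <- is_num[[vb]]
        if (na && nb) {
          rho <- stats::cor(data[[va]], data[[vb]], method = "spearman")
          if (abs(rho) >= rho_threshold) {
            out[[length(out) + 1L]] <- tibble::tibble(
              var1 = va, var2 = vb, test = "spearman",
              statistic = rho, p_value = NA_real_)
          }
        } else if (xor(na, nb)) {
          num <- if (na) data[[va]] else data[[vb]]
          grp <- factor(if (na) data[[vb]] else data[[va]])
          if (nlevels(grp) >= 2) {
            kw <- stats::kruskal.test(num, grp)
            if (kw$p.value < alpha) {
              out[[length(out) + 1L]] <- tibble::tibble(
                var1 = va, var2 = vb, test = "kruskal-wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value)
            }
          }
        }
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(var1 = character(), var2 = character(),
                      test = character(), statistic = numeric(),
                      p_value = numeric())
}

#' Center and scale covariates, keeping the constants
#'
#' @param data data frame.
#' @param cols columns to standardize; defaults to all numeric columns.
#' @return A list with `data` (standardized tibble) and `constants` (tibble
#'   of `column`, `mean`, `sd`) for prediction-time reuse.
#' @export
standardize_covariates <- function(data, cols = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  mu <- vapply(data[cols], mean, numeric(1))
  sdev <- vapply(data[cols], stats::sd, numeric(1))
  if (any(sdev == 0)) {
    stop("zero standard deviation in: ",
         paste(cols[sdev == 0], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(cols)) {
    data[[cols[i]]] <- (data[[cols[i]]] - mu[i]) / sdev[i]
  }
  list(data = data,
       constants = tibble::tibble(column = cols, mean = unname(mu),
                                  sd = unname(sdev)))
}

#' Apply (or invert) stored standardization constants
#'
#' @param data data frame with the original-scale (or standardized) columns.
#' @param constants constants tibble from [standardize_covariates()].
#' @param invert if `TRUE`, map standardized values back to the original
#'   scale.
#' @return A tibble.
#' @export
apply_standardization <- function(data, constants, invert = FALSE) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(constants))) {
    cl <- constants$column[i]
    if (!cl %in% names(data)) next
    data[[cl]] <- if (invert) {
      data[[cl]] * constants$sd[i] + constants$mean[i]
    } else {
      (data[[cl]] - constants$mean[i]) / constants$sd[i]
    }
  }
  data
}
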