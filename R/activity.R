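# Diel variation in wolf movement rate: a negative-binomial GAM of 2-h
# displacement (discretized to meters) on a cyclic smooth of hour-of-day per
# season, with a per-wolf random intercept.  Predictions at an observation's
# time and season are the temporal predation-risk metric.

#' Derive 2-h movement steps from a fix table
#'
#' Consecutive-fix displacements per wolf, labelled with the hour-of-day and
#' season of the interval start.  Intervals longer than `max_gap_h` (missed
#' fixes) are dropped.
#'
#' @param tracks fix table with `animal_id`, `t`, `x`, `y`.
#' @param max_gap_h maximum fix gap retained, in hours.
#' @return A tibble with `wolf_id`, `season`, `hour`, `step_km`.
#' @export
track_steps <- function(tracks, max_gap_h = 2.5) {
  tracks |>
    dplyr::arrange(.data$animal_id, .data$t) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      dt_h = as.numeric(difftime(dplyr::lead(.data$t), .data$t,
                                 units = "hours")),
      step_km = sqrt((dplyr::lead(.data$x) - .data$x)^2 +
                       (dplyr::lead(.data$y) - .data$y)^2) / 1000
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dt_h), .data$dt_h <= max_gap_h) |>
    dplyr::transmute(
      wolf_id = .data$animal_id,
      season = season_of(as.Date(.data$t)),
      hour = as.numeric(format(.data$t, "%H", tz = "UTC")) +
        as.numeric(format(.data$t, "%M", tz = "UTC")) / 60,
      step_km = .data$step_km
    )
}

#' Fit the diel wolf-activity model
#'
#' Negative-binomial GAM of per-interval displacement (meters, integer) on a
#' cyclic cubic spline of hour-of-day (6 knots, period 24 h) by season, with
#' a random intercept per wolf.
#'
#' @param steps step table from [track_steps()] (columns `wolf_id`,
#'   `season`, `hour`, `step_km`).
#' @param k basis dimension of the cyclic smooth.
#' @return An object of class `activity_model`.
#' @export
fit_wolf_activity <- function(steps, k = 6) {
  stopifnot(all(c("wolf_id", "season", "hour", "step_km") %in% names(steps)))
  if (length(unique(steps$wolf_id)) < 2) {
    stop("need steps from at least two wolves", call. = FALSE)
  }
  if (any(steps$step_km < 0)) stop("negative step length", call. = FALSE)
  df <- tibble::as_tibble(steps)
  df$season <- droplevels(factor(df$season))
  df$wolf_id <- factor(df$wolf_id)
  df$step_m <- as.integer(round(df$step_km * 1000))
  small <- table(df$season) < 50
  if (any(small)) {
    warning("fewer than 50 steps in season(s): ",
            paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  multi_season <- nlevels(df$season) > 1
  fml <- if (multi_season) {
    step_m ~ season + s(hour, bs = "cc", k = k, by = season) +
      s(wolf_id, bs = "re")
  } else {
    step_m ~ s(hour, bs = "cc", k = k) + s(wolf_id, bs = "re")
  }
  fit <- mgcv::gam(fml, data = df, family = mgcv::nb(),
                   knots = list(hour = c(0, 24)), method = "REML")
  structure(list(
    gam = fit, seasons = levels(df$season),
    ref_wolf = levels(df$wolf_id)[1],
    wolf_sd = tryCatch({
      vc <- utils::capture.output(
        out <- mgcv::gam.vcomp(fit, rescale = TRUE))
      unname(out["s(wolf_id)", "std.dev"])
    }, error = function(e) NA_real_),
    n_steps = nrow(df)
  ), class = "activity_model")
}

#' Predict population-level wolf movement rate
#'
#' Expected movement rate (km per 2-h interval) at an hour and season, with
#' the wolf random effect at zero.  The prediction is periodic in the hour
#' (hour 0 equals hour 24).
#'
#' @param model an [fit_wolf_activity()] model.
#' @param hour numeric hour-of-day (0-24), vectorized.
#' @param season season label, recycled.
#' @return Numeric vector of km/2-h rates.
#' @export
predict_activity <- function(model, hour, season) {
  season <- as.character(rep(season, length.out = length(hour)))
  bad <- setdiff(unique(season), model$seasons)
  if (length(bad)) {
    stop("model has no season(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nd <- data.frame(hour = hour %% 24,
                   season = factor(season, levels = model$seasons),
                   wolf_id = factor(model$ref_wolf,
                                    levels = levels(model$gam$model$wolf_id)))
  mu <- mgcv::predict.gam(model$gam, newdata = nd, type = "response",
                          exclude = "s(wolf_id)", newdata.guaranteed = TRUE)
  as.numeric(mu) / 1000
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> %d steps, seasons: %s, wolf SD %.3g\n",
              x$n_steps, paste(x$seasons, collapse = ", "), x$wolf_sd))
  invisible(x)
}

#' @export
tidy.activity_model <- function(x, ...) {
  s <- summary(x$gam)
  tibble::tibble(term = rownames(s$p.table),
                 estimate = s$p.table[, 1],
                 std.error = s$p.table[, 2])
}

#' Plot the fitted diel activity curve
#'
#' @param object an `activity_model`.
#' @param ... unused.
#' @return A ggplot of predicted km/2-h against hour, one line per season.
#' @export
autoplot.activity_model <- function(object, ...) {
  grid <- tidyr::expand_grid(hour = seq(0, 24, by = 0.25),
                             season = object$seasons)
  grid$rate <- predict_activity(object, grid$hour, grid$season)
  ggplot2::ggplot(grid, ggplot2::aes(.data$hour, .data$rate,
                                     color = .data$season)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hour of day", y = "movement rate (km/2-h)")
}
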