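# Synthetic elk focal observations: per-minute behavior states drawn from a
# covariate-driven Dirichlet-multinomial process with known generating
# parameters, plus chewing flags for vigilance minutes from a known
# multitasking process.  The generative twin of the fitted models.

#' Ground-truth parameters for the behavioral generator
#'
#' Coefficients act on the multinomial-logit scale for each non-reference
#' category (reference: traveling), over the terms intercept, diel period
#' (morning/evening vs midday), standardized herd size, standardized risk,
#' and maternal period (PPP/SMP/WP vs LMP).  The multitasking coefficients
#' act on the logit of chewing-given-vigilance, with a maternal-by-risk
#' interaction whose default reproduces a negative risk slope before
#' parturition (PPP) and a positive one after (LMP).
#'
#' @param beta terms x categories coefficient matrix (categories: foraging,
#'   vigilance, resting_ruminating, other).
#' @param phi Dirichlet precision (> 0).
#' @param herd_sd SD of the herd random intercept (>= 0).
#' @param multitask_beta named coefficients of the chewing-given-vigilance
#'   process.
#' @param multitask_session_sd SD of the per-session multitasking random
#'   intercept.
#' @param session_length_range,session_length_mean,session_length_sd
#'   session lengths in minutes: truncated-normal draw within the range.
#' @param split_other probabilities splitting the modeled `other` category
#'   into the recorded nursing / drinking / other states.
#' @param p_unknown,p_disturbed per-minute probabilities of a minute being
#'   recorded unknown or anthropogenically disturbed.
#' @param seed integer seed.
#' @return A list of class `behavior_truth`.
#' @export
behavior_truth <- function(
    beta = NULL, phi = 25, herd_sd = 0.3,
    multitask_beta = c(`(Intercept)` = -0.2, openness_z = -0.45,
                       risk_z = 0.9, maternalPPP = -0.3, maternalSMP = 0,
                       maternalWP = 0, `maternalPPP:risk_z` = -1.8,
                       `maternalSMP:risk_z` = -0.4,
                       `maternalWP:risk_z` = -1.0),
    multitask_session_sd = 0.5,
    session_length_range = c(10, 40), session_length_mean = 19,
    session_length_sd = 5,
    split_other = c(nursing = 0.3, drinking = 0.2, other = 0.5),
    p_unknown = 0.01, p_disturbed = 0.005, seed = 1L) {
  terms <- c("(Intercept)", "dielmorning", "dielevening", "herd_size_z",
             "risk_z", "maternalPPP", "maternalSMP", "maternalWP")
  cats <- c("foraging", "vigilance", "resting_ruminating", "other")
  if (is.null(beta)) {
    beta <- rbind(
      `(Intercept)` = c(0.9, -0.3, 0.5, -1.5),
      dielmorning = c(0.3, 0.1, -0.8, 0),
      dielevening = c(0.5, 0.1, -1.0, 0),
      herd_size_z = c(0, -0.3, 0, 0),
      risk_z = c(0.15, 0.5, -0.4, 0),
      maternalPPP = c(0.3, 0, -0.3, 0),
      maternalSMP = c(0, -0.2, 0.2, 0),
      maternalWP = c(0, 0, 0, -0.5)
    )
    colnames(beta) <- cats
  }
  stopifnot(identical(rownames(beta), terms), phi > 0, herd_sd >= 0)
  structure(list(
    beta = beta, phi = phi, herd_sd = herd_sd,
    multitask_beta = multitask_beta,
    multitask_session_sd = multitask_session_sd,
    session_length_range = session_length_range,
    session_length_mean = session_length_mean,
    session_length_sd = session_length_sd,
    split_other = split_other, p_unknown = p_unknown,
    p_disturbed = p_disturbed, seed = seed
  ), class = "behavior_truth")
}

maternal_windows <- function() {
  # Julian-day windows implied by the unknown-parturition boundaries
  list(WP = c(1, 90), PPP = c(91, 134), LMP = c(135, 179), SMP = c(180, 250))
}

multitask_lp <- function(b, maternal, risk_z, openness_z) {
  main <- dplyr::case_when(
    maternal == "PPP" ~ b[["maternalPPP"]],
    maternal == "SMP" ~ b[["maternalSMP"]],
    maternal == "WP" ~ b[["maternalWP"]],
    TRUE ~ 0
  )
  slope <- b[["risk_z"]] + dplyr::case_when(
    maternal == "PPP" ~ b[["maternalPPP:risk_z"]],
    maternal == "SMP" ~ b[["maternalSMP:risk_z"]],
    maternal == "WP" ~ b[["maternalWP:risk_z"]],
    TRUE ~ 0
  )
  b[["(Intercept)"]] + main + slope * risk_z +
    b[["openness_z"]] * openness_z
}

#' Simulate elk focal-observation sessions
#'
#' Generates `sum(period_counts)` sessions: a date inside each maternal
#' period's window, a daylight start time, a location, herd composition,
#' and per-minute behavior states drawn i.i.d. (given the session) from the
#' Dirichlet-multinomial truth, with chewing flags for vigilance minutes
#' from the multitasking truth.  A small fraction of minutes is recorded as
#' unknown or disturbed.  The returned truth record carries every
#' generating parameter, the standardization constants, and the realized
#' random effects.
#'
#' @param truth a [behavior_truth()].
#' @param risk_surface [grid_raster()] evaluated (buffer mean) at session
#'   locations as the risk covariate.
#' @param landscape a `landscape` (canopy drives the openness covariate).
#' @param period_counts named session counts per maternal period.
#' @param n_herds number of herds.
#' @param lat,lon study-area reference coordinates for twilight times.
#' @param year observation year.
#' @param risk_radius buffer radius (m) for the risk covariate.
#' @param seed integer seed; defaults to the truth's.
#' @return A list with `sessions`, `minutes` tibbles and `truth_record`.
#' @export
sim_elk_sessions <- function(truth, risk_surface, landscape,
                             period_counts = c(PPP = 103, LMP = 182,
                                               SMP = 345, WP = 79),
                             n_herds = 12, lat = 33.9, lon = -108.8,
                             year = 2019, risk_radius = 200,
                             seed = truth$seed) {
  stopifnot(inherits(truth, "behavior_truth"))
  wins <- maternal_windows()
  stopifnot(all(names(period_counts) %in% names(wins)))
  n <- sum(period_counts)
  open_r <- openness(landscape$canopy)
  # sampling region: intersection of landscape and risk-surface extents
  x_lo <- max(landscape$canopy$xmin, risk_surface$xmin)
  y_lo <- max(landscape$canopy$ymin, risk_surface$ymin)
  x_hi <- min(raster_xmax(landscape$canopy), raster_xmax(risk_surface))
  y_hi <- min(raster_ymax(landscape$canopy), raster_ymax(risk_surface))
  if (x_hi <= x_lo || y_hi <= y_lo) {
    stop("risk surface does not overlap the landscape", call. = FALSE)
  }
  origin <- as.Date(sprintf("%d-01-01", year)) - 1
  with_seed(seed, {
    maternal <- factor(rep(names(period_counts), period_counts),
                       levels = maternal_levels)
    jday <- vapply(as.character(maternal), function(p) {
      sample(seq(wins[[p]][1], wins[[p]][2]), 1)
    }, numeric(1))
    date <- origin + jday
    len <- pmin(pmax(round(stats::rnorm(n, truth$session_length_mean,
                                        truth$session_length_sd)),
                     truth$session_length_range[1]),
                truth$session_length_range[2])
    tw <- civil_twilight(date, lat, lon)
    u <- stats::runif(n)
    start <- tw$dawn + 60 + u * (as.numeric(tw$dusk - tw$dawn, units = "secs") -
                                   (len + 2) * 60 - 120)
    x <- stats::runif(n, x_lo + 1, x_hi - 1)
    y <- stats::runif(n, y_lo + 1, y_hi - 1)
    herd_id <- sprintf("H%02d", sample.int(n_herds, n, replace = TRUE))
    size <- pmax(round(stats::rlnorm(n, log(15), 0.8)), 1)
    comp <- t(vapply(size, function(s) {
      drop(stats::rmultinom(1, s, c(0.55, 0.25, 0.10, 0.10)))
    }, numeric(4)))
    colnames(comp) <- c("cows", "calves", "bulls", "spikes")
    sessions <- tibble::tibble(
      session_id = sprintf("S%04d", seq_len(n)),
      herd_id = herd_id, date = date, start = start, n_minutes = len,
      x = x, y = y, maternal = maternal,
      cows = comp[, 1], calves = comp[, 2], bulls = comp[, 3],
      spikes = comp[, 4]
    ) |> herd_metrics()
    sessions$diel <- factor(
      vapply(seq_len(n), function(i) {
        as.character(assign_diel_session(start[i], len[i], lat, lon))
      }, character(1)),
      levels = diel_levels("three"))
    sessions$risk <- buffer_mean(risk_surface, x, y, risk_radius)
    sessions <- raster_extract(sessions, open_r, col = "openness")
    std <- standardize_covariates(sessions[c("herd_size", "risk",
                                             "openness")])
    sessions$herd_size_z <- std$data$herd_size
    sessions$risk_z <- std$data$risk
    sessions$openness_z <- std$data$openness

    # session-level mean compositions and Dirichlet draws
    cats5 <- behavior_categories()
    D <- cbind(1,
               sessions$diel == "morning", sessions$diel == "evening",
               sessions$herd_size_z, sessions$risk_z,
               maternal == "PPP", maternal == "SMP", maternal == "WP")
    z_herd <- matrix(stats::rnorm(n_herds * ncol(truth$beta)), n_herds)
    h_idx <- as.integer(factor(herd_id, levels = sprintf("H%02d",
                                                         seq_len(n_herds))))
    eta <- D %*% truth$beta + truth$herd_sd * z_herd[h_idx, ]
    expEta <- cbind(exp(eta), traveling = 1)
    colnames(expEta) <- c(colnames(truth$beta), "traveling")
    mu <- expEta / rowSums(expEta)
    mu <- mu[, cats5]                    # canonical category order
    g <- matrix(stats::rgamma(n * 5, shape = mu * truth$phi), n, 5)
    # guard against all-zero gamma draws at tiny shapes
    g[g == 0] <- 1e-300
    p_sess <- g / rowSums(g)

    v_sess <- stats::rnorm(n)
    mt_lp <- multitask_lp(truth$multitask_beta, as.character(maternal),
                          sessions$risk_z, sessions$openness_z) +
      truth$multitask_session_sd * v_sess

    minutes <- lapply(seq_len(n), function(i) {
      cat5 <- sample(cats5, len[i], replace = TRUE, prob = p_sess[i, ])
      beh <- cat5
      is_other <- beh == "other"
      if (any(is_other)) {
        beh[is_other] <- sample(names(truth$split_other), sum(is_other),
                                replace = TRUE, prob = truth$split_other)
      }
      uu <- stats::runif(len[i])
      beh[uu < truth$p_unknown] <- "unknown"
      beh[uu >= truth$p_unknown &
            uu < truth$p_unknown + truth$p_disturbed] <- "disturbed"
      chewing <- rep(NA, len[i])
      vig <- beh == "vigilance"
      if (any(vig)) {
        chewing[vig] <- stats::runif(sum(vig)) < stats::plogis(mt_lp[i])
      }
      tibble::tibble(
        session_id = sessions$session_id[i],
        minute = seq_len(len[i]),
        t = start[i] + 60 * (seq_len(len[i]) - 1),
        behavior = beh, chewing = chewing
      )
    })
    truth_record <- c(
      unclass(truth),
      list(standardization = std$constants, z_herd = z_herd,
           v_session = v_sess, period_counts = as.list(period_counts),
           n_herds = n_herds, lat = lat, lon = lon, year = year,
           risk_radius = risk_radius, seed_used = seed)
    )
    list(sessions = sessions, minutes = dplyr::bind_rows(minutes),
         truth_record = truth_record)
  })
}

#' Simulate vigilance-minute records directly
#'
#' Generates the multitasking data set with exact per-period vigilance
#' counts (the bookkeeping published for the field data), standard-normal
#' standardized covariates, per-session random effects, and chewing flags
#' from the multitasking truth.
#'
#' @param truth a [behavior_truth()].
#' @param counts_by_period named vigilance-minute counts per maternal
#'   period.
#' @param minutes_per_session average vigilance minutes per session.
#' @param seed integer seed.
#' @return A tibble with `session_id`, `maternal`, `risk_z`, `openness_z`,
#'   `multitask`.
#' @export
sim_vigilance_minutes <- function(truth,
                                  counts_by_period = c(PPP = 164, LMP = 367,
                                                       SMP = 421, WP = 100),
                                  minutes_per_session = 5,
                                  seed = truth$seed) {
  with_seed(seed, {
    out <- lapply(names(counts_by_period), function(p) {
      m <- counts_by_period[[p]]
      S <- ceiling(m / minutes_per_session)
      sess <- sprintf("%s_S%03d", p, rep(seq_len(S),
                                         each = minutes_per_session)[seq_len(m)])
      us <- !duplicated(sess)
      risk_z <- stats::rnorm(S)[match(sess, sess[us])]
      open_z <- stats::rnorm(S)[match(sess, sess[us])]
      v <- stats::rnorm(S)[match(sess, sess[us])]
      lp <- multitask_lp(truth$multitask_beta, p, risk_z, open_z) +
        truth$multitask_session_sd * v
      tibble::tibble(
        session_id = sess,
        maternal = factor(p, levels = maternal_levels),
        risk_z = risk_z, openness_z = open_z,
        multitask = as.integer(stats::runif(m) < stats::plogis(lp))
      )
    })
    dplyr::bind_rows(out)
  })
}
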