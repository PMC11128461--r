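# Session-level behavior compositions: collapsing per-minute focal records
# to proportions over the five modeled categories, the boundary squeeze that
# maps them into the open simplex, and the Dirichlet log density in its
# alternative (mean / precision) parameterization.

#' Behavior category sets
#'
#' `behavior_states()` are the seven states recorded in the field;
#' `behavior_categories()` are the five modeled categories after nursing and
#' drinking are merged into `other` (reference category: `traveling`).
#'
#' @return Character vector of state / category names.
#' @export
behavior_states <- function() {
  c("foraging", "vigilance", "resting_ruminating", "traveling",
    "nursing", "drinking", "other")
}

#' @rdname behavior_states
#' @export
behavior_categories <- function() {
  c("foraging", "vigilance", "resting_ruminating", "traveling", "other")
}

#' Collapse per-minute records to session compositions
#'
#' Counts minutes per modeled category (nursing and drinking merge into
#' `other`), divides by the session's classified minutes, and drops sessions
#' with fewer than `min_minutes` classified minutes (with a message).
#' Unknown or disturbed minutes must already have been removed (see
#' [filter_observations()]).
#'
#' @param minutes tibble with `session_id` and `behavior` columns.
#' @param min_minutes minimum classified minutes to retain a session.
#' @return A tibble with `session_id`, `n_minutes` and one proportion column
#'   per category in [behavior_categories()].
#' @export
sessions_to_compositions <- function(minutes, min_minutes = 10) {
  bad <- setdiff(unique(minutes$behavior), behavior_states())
  if (length(bad)) {
    stop("unclassified behavior state(s): ", paste(bad, collapse = ", "),
         " (run filter_observations() first)", call. = FALSE)
  }
  cats <- behavior_categories()
  out <- minutes |>
    dplyr::mutate(category = dplyr::if_else(
      .data$behavior %in% c("nursing", "drinking"), "other",
      .data$behavior)) |>
    dplyr::count(.data$session_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in setdiff(cats, names(out))) out[[cat]] <- 0L
  out$n_minutes <- rowSums(out[cats])
  drop <- out$n_minutes < min_minutes
  if (any(drop)) {
    message("dropping ", sum(drop), " session(s) with < ", min_minutes,
            " classified minutes")
    out <- out[!drop, , drop = FALSE]
  }
  for (cat in cats) out[[cat]] <- out[[cat]] / out$n_minutes
  out[c("session_id", "n_minutes", cats)]
}

#' Squeeze boundary proportions into the open simplex
#'
#' The compositional boundary transform
#' `y* = (y * (n - 1) + 1/C) / n`, applied componentwise: proportions of 0
#' or 1 (whose Dirichlet likelihood is undefined) are pulled strictly inside
#' the simplex while row sums stay exactly 1.
#'
#' @param y matrix or data frame of proportions (rows on the closed
#'   simplex).
#' @param n_obs number of observations behind each row (scalar or vector);
#'   here, classified minutes per session.
#' @return A matrix on the open simplex.
#' @export
squeeze_simplex <- function(y, n_obs) {
  y <- as.matrix(y)
  if (any(n_obs < 2)) stop("n_obs must be >= 2", call. = FALSE)
  C <- ncol(y)
  (y * (n_obs - 1) + 1 / C) / n_obs
}

#' Dirichlet log density, mean/precision parameterization
#'
#' Log density of `y` under a Dirichlet with concentrations
#' `alpha = mu * phi`, where `mu` is the mean composition and `phi > 0` the
#' precision.
#'
#' @param y composition (vector) or matrix of compositions (rows); strictly
#'   inside the simplex.
#' @param mu mean composition(s), same shape as `y`.
#' @param phi scalar precision.
#' @return Numeric vector of log densities.
#' @export
ddirichlet_alt <- function(y, mu, phi) {
  y <- rbind(y); mu <- rbind(mu)
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  if (any(y <= 0) || any(y >= 1)) {
    stop("y must be strictly inside the simplex (squeeze_simplex() first)",
         call. = FALSE)
  }
  a <- mu * phi
  unname(lgamma(phi) - rowSums(lgamma(a)) + rowSums((a - 1) * log(y)))
}
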