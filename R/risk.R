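# The three primary predation-risk metrics evaluated at observations:
# predicted wolf presence (UD x RSF), risky places (RP), and risky places
# relative to wolf use (UD x RP).

resolve_ud <- function(ud, scale_tag, dates) {
  if (inherits(ud, "grid_raster")) {
    rep(list(ud), length(dates))
  } else {
    lapply(dates, function(d) lookup_ud(ud, scale_tag, d))
  }
}

ud_buffer_values <- function(uds, x, y, radius) {
  vapply(seq_along(uds), function(i) {
    buffer_mean(uds[[i]], x[i], y[i], radius)
  }, numeric(1))
}

#' Predicted wolf presence at observations
#'
#' The product of the buffer-mean wolf UD and the RSF score at each
#' observation: spatial wolf use weighted by landscape selection.
#'
#' @param data observations with `x`, `y`, `date` and the RSF covariate
#'   columns.
#' @param ud a single UD/risk raster, or a UD set from [build_ud_set()] (the
#'   surface is then selected by each observation's date).
#' @param rsf a [fit_selection()] model.
#' @param radius buffer radius in meters (200, 800 or 2000).
#' @param scale_tag UD scale used when `ud` is a UD set.
#' @return `data` as a tibble with columns `ud_mean`, `rsf_score`, `risk`,
#'   plus metric bookkeeping columns `metric`, `ud_scale`, `radius`.
#' @export
predicted_wolf_presence <- function(data, ud, rsf, radius = 200,
                                    scale_tag = "PackYm") {
  stopifnot(radius %in% c(200, 800, 2000))
  out <- tibble::as_tibble(data)
  uds <- resolve_ud(ud, scale_tag, out$date)
  out$ud_mean <- ud_buffer_values(uds, out$x, out$y, radius)
  out$rsf_score <- score_selection(rsf, out)
  out$risk <- out$ud_mean * out$rsf_score
  out$metric <- "UDxRSF"; out$ud_scale <- scale_tag; out$radius <- radius
  out
}

#' Risky-places score at observations
#'
#' The kill-site selection score alone: `exp` of the kill model's
#' fixed-effect linear predictor (no intercept) at each observation.
#'
#' @param data observations with the kill-model covariate columns.
#' @param rp_model a [fit_selection()] model fit to kill sites vs
#'   availability.
#' @return `data` as a tibble with `risk` (and `metric`) columns.
#' @export
risky_places <- function(data, rp_model) {
  out <- tibble::as_tibble(data)
  out$risk <- score_selection(rp_model, out)
  out$metric <- "RP"
  out
}

#' Risky places relative to wolf use
#'
#' The product of the buffer-mean wolf UD and the kill-site selection score:
#' landscape-conditioned kill likelihood weighted by how much wolves use the
#' area.
#'
#' @inheritParams predicted_wolf_presence
#' @param rp_model a [fit_selection()] kill-site model.
#' @return `data` as a tibble with `ud_mean`, `rp_score`, `risk` and
#'   bookkeeping columns.
#' @export
risky_places_relative <- function(data, ud, rp_model, radius = 2000,
                                  scale_tag = "PackSY") {
  stopifnot(radius %in% c(200, 800, 2000))
  out <- tibble::as_tibble(data)
  uds <- resolve_ud(ud, scale_tag, out$date)
  out$ud_mean <- ud_buffer_values(uds, out$x, out$y, radius)
  out$rp_score <- score_selection(rp_model, out)
  out$risk <- out$ud_mean * out$rp_score
  out$metric <- "UDxRP"; out$ud_scale <- scale_tag; out$radius <- radius
  out
}

#' Log-transform a risk metric with a data-driven offset
#'
#' Natural log of `x + eps` with `eps` the smallest positive observed value
#' times 1e-3, so zero-risk observations remain finite.
#'
#' @param x non-negative risk values.
#' @return Log-transformed values.
#' @export
log_risk <- function(x) {
  if (any(x < 0)) stop("risk values must be non-negative", call. = FALSE)
  pos <- x[x > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1e-12
  log(x + eps)
}
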