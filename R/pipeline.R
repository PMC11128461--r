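# End-to-end orchestration: synthetic world -> risk surfaces -> covariates
# -> Bayesian model fits -> model comparison, with filtering audit and a
# reproducibility manifest.

#' Remove unknown and disturbed minutes with an audit log
#'
#' @param minutes per-minute records with a `behavior` column that may
#'   include `unknown` and `disturbed` labels.
#' @return A list with `minutes` (clean tibble) and `audit` (tibble of
#'   removal counts by reason plus totals).
#' @export
filter_observations <- function(minutes) {
  minutes <- tibble::as_tibble(minutes)
  bad <- minutes$behavior %in% c("unknown", "disturbed")
  audit <- tibble::tibble(
    reason = c("unknown", "disturbed"),
    removed = c(sum(minutes$behavior == "unknown"),
                sum(minutes$behavior == "disturbed"))
  )
  attr(audit, "n_in") <- nrow(minutes)
  attr(audit, "n_out") <- sum(!bad)
  list(minutes = minutes[!bad, , drop = FALSE], audit = audit)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' The defaults define a small synthetic world that runs end to end in a
#' couple of minutes.
#'
#' @param landscape a [landscape_config()].
#' @param packs a [pack_config()].
#' @param kill_beta named kill-site selection coefficients.
#' @param n_kills number of synthetic kills.
#' @param metric primary risk metric: `"UDxRSF"`, `"RP"` or `"UDxRP"`.
#' @param ud_scale UD scale tag (PackSY, PackYm, PopSY, PopY).
#' @param radius buffer radius in meters (200, 800, 2000).
#' @param period_counts elk sessions per maternal period.
#' @param n_herds number of elk herds.
#' @param models named character vector of candidate fixed-effect formulas
#'   for the behavior model.
#' @param mcmc an [mcmc_config()].
#' @param kfold_k folds for the behavior-model ELPD comparison.
#' @param truth a [behavior_truth()].
#' @param lat,lon,year observation frame.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    landscape = landscape_config(extent = c(9000, 9000)),
    packs = pack_config(n_packs = 2, n_days = 120),
    kill_beta = c(canopy = -0.5, veg_height = -0.3),
    n_kills = 60,
    metric = "UDxRSF", ud_scale = "PackYm", radius = 200,
    period_counts = c(PPP = 24, LMP = 40, SMP = 60, WP = 20),
    n_herds = 8,
    models = c(top = "~ diel + herd_size_z + risk_z", null = "~ 1"),
    mcmc = mcmc_config(chains = 2, warmup = 200, iter = 400),
    kfold_k = 5, truth = behavior_truth(),
    lat = 33.9, lon = -108.8, year = 2019, seed = 1L) {
  if (!metric %in% c("UDxRSF", "RP", "UDxRP")) {
    stop("unknown risk metric tag: ", metric, call. = FALSE)
  }
  if (!ud_scale %in% c("PackSY", "PackYm", "PopSY", "PopY")) {
    stop("unknown UD scale tag: ", ud_scale, call. = FALSE)
  }
  if (!radius %in% c(200, 800, 2000)) {
    stop("buffer radius must be 200, 800 or 2000 m", call. = FALSE)
  }
  structure(list(
    landscape = landscape, packs = packs, kill_beta = kill_beta,
    n_kills = n_kills, metric = metric, ud_scale = ud_scale,
    radius = radius, period_counts = period_counts, n_herds = n_herds,
    models = models, mcmc = mcmc, kfold_k = kfold_k, truth = truth,
    lat = lat, lon = lon, year = year, seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()]; nested
#' blocks `landscape` and `packs` override those constructors' arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$landscape)) {
    args$landscape <- do.call(landscape_config, y$landscape)
  }
  if (!is.null(y$packs)) args$packs <- do.call(pack_config, y$packs)
  if (!is.null(y$kill_beta)) args$kill_beta <- unlist(y$kill_beta)
  if (!is.null(y$models)) args$models <- unlist(y$models)
  if (!is.null(y$period_counts)) {
    args$period_counts <- unlist(y$period_counts)
  }
  for (f in c("n_kills", "metric", "ud_scale", "radius", "n_herds",
              "kfold_k", "lat", "lon", "year", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$mcmc)) args$mcmc <- do.call(mcmc_config, y$mcmc)
  do.call(pipeline_config, args)
}

pack_sizes_tibble <- function(packs) {
  sz <- packs$pack_sizes_by_season
  tidyr::expand_grid(pack = seq_len(nrow(sz)),
                     season = colnames(sz)) |>
    dplyr::mutate(pack_id = sprintf("P%02d", .data$pack),
                  size = sz[cbind(.data$pack,
                                  match(.data$season, colnames(sz)))]) |>
    dplyr::select("pack_id", "season", "size")
}

#' Run the full analysis pipeline
#'
#' Synthetic generation, risk surfaces (UD set, RSF, kill-site model),
#' covariates, behavior-model fits with grouped k-fold ELPD comparison and
#' pseudo-BMA+ weights, the multitasking fit with PSIS-LOO, and (when
#' `out_dir` is given) all artifacts: CSV tables, ASCII-grid rasters, YAML
#' truth record and a JSON manifest with seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return A list bundle with the generated data, fitted models, comparison
#'   table and audit log.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  land <- sim_landscape(config$landscape)
  tracks <- sim_wolf_tracks(land, config$packs)
  psizes <- pack_sizes_tibble(config$packs)
  ud_set <- build_ud_set(tracks, psizes)

  # RSF: wolf fixes vs availability from the yearly population UD,
  # clipped to the landscape so covariates exist at every point
  pop_ud <- lookup_ud(ud_set, "PopY", config$packs$start_date)
  in_landscape <- function(p) {
    dplyr::filter(p, .data$x > 0, .data$y > 0,
                  .data$x < raster_xmax(land$canopy),
                  .data$y < raster_ymax(land$canopy))
  }
  rsf_covs <- c("canopy", "veg_coverage", "veg_height")
  with_seed(config$seed + 1L, {
    case <- dplyr::slice_sample(tracks, n = min(1500, nrow(tracks)))
  })
  avail <- in_landscape(sample_available(pop_ud, 2 * nrow(case),
                                         seed = config$seed + 2L))
  avail <- avail[seq_len(min(nrow(case), nrow(avail))), ]
  avail$pack_id <- sample(case$pack_id, nrow(avail), replace = TRUE)
  rsf_data <- dplyr::bind_rows(
    dplyr::mutate(case[c("x", "y", "pack_id")], used = 1L),
    dplyr::mutate(avail, used = 0L))
  for (cv in rsf_covs) rsf_data <- raster_extract(rsf_data, land[[cv]],
                                                  col = cv)
  rsf <- fit_selection(rsf_data, rsf_covs, group = "pack_id")

  # risky places: synthetic kills vs availability
  kills <- sim_kill_sites(tracks, land, config$kill_beta, config$n_kills,
                          seed = config$seed + 3L)
  n_ka <- max(4 * config$n_kills, 200)
  k_avail <- in_landscape(sample_available(pop_ud, 2 * n_ka,
                                           seed = config$seed + 4L))
  k_avail <- k_avail[seq_len(min(n_ka, nrow(k_avail))), ]
  rp_data <- dplyr::bind_rows(
    dplyr::mutate(kills[c("x", "y")], used = 1L),
    dplyr::mutate(k_avail, used = 0L))
  for (cv in rsf_covs) rp_data <- raster_extract(rp_data, land[[cv]],
                                                 col = cv)
  rp <- fit_selection(rp_data, rsf_covs)

  # risk surface driving the behavioral generator
  gen_ud <- lookup_ud(ud_set, config$ud_scale,
                      as.Date(sprintf("%d-06-15", config$year)))
  sim <- sim_elk_sessions(config$truth, gen_ud, land,
                          period_counts = config$period_counts,
                          n_herds = config$n_herds, lat = config$lat,
                          lon = config$lon, year = config$year,
                          risk_radius = config$radius,
                          seed = config$seed + 5L)
  filt <- filter_observations(sim$minutes)
  comps <- sessions_to_compositions(filt$minutes) |>
    dplyr::inner_join(sim$sessions, by = "session_id",
                      suffix = c("", ".sess"))

  # wolf diel activity (temporal secondary metric); observation seasons
  # without tracking data fall back to the nearest fitted season
  act <- suppressWarnings(fit_wolf_activity(track_steps(tracks)))
  seas <- as.character(season_of(comps$date))
  seas[!seas %in% act$seasons] <- act$seasons[length(act$seasons)]
  comps$wolf_activity <- predict_activity(
    act, lubridate::hour(comps$start) + lubridate::minute(comps$start) / 60,
    seas)

  # candidate behavior models: grouped k-fold ELPD + pseudo-BMA+ weights
  fit_one <- function(fml, data, seed_off = 0L) {
    cfg <- config$mcmc
    cfg$seed <- cfg$seed + seed_off
    fit_behavior_dirichlet(data, stats::as.formula(fml), herd = "herd_id",
                           config = cfg)
  }
  fits <- lapply(config$models, fit_one, data = comps)
  elpds <- lapply(seq_along(config$models), function(m) {
    kfold_elpd(
      comps,
      fit_fun = function(d) fit_one(config$models[[m]], d, seed_off = 100L),
      logpred_fun = function(fit, nd) loglik_dirichlet(fit, nd, draws = 300),
      K = config$kfold_k, groups = comps$herd_id,
      seed = config$seed + 6L)
  })
  names(elpds) <- names(config$models)
  comparison <- select_models(compare_models(elpds, seed = config$seed + 7L))

  # multitasking model on vigilance minutes, compared by PSIS-LOO
  vig <- extract_vigilance_minutes(filt$minutes, sim$sessions)
  mt_fit <- fit_multitask(vig, ~ maternal * risk_z + openness_z,
                          config = config$mcmc)
  mt_loo <- psis_loo(mt_fit$loglik)

  top_name <- comparison$model[1]
  ce <- conditional_effects(
    fits[[top_name]],
    tidyr::expand_grid(diel = factor("midday", levels = diel_levels("three")),
                       herd_size_z = 0,
                       risk_z = seq(-2, 2, by = 0.5)))

  bundle <- list(
    landscape = land, tracks = tracks, ud_set = ud_set, rsf = rsf, rp = rp,
    kills = kills, sessions = sim$sessions, minutes = filt$minutes,
    audit = filt$audit, compositions = comps, activity = act, fits = fits,
    comparison = comparison, multitask = mt_fit, multitask_loo = mt_loo,
    conditional_effects = ce, truth_record = sim$truth_record,
    config = config
  )
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(bundle$sessions, "sessions.csv")
  wcsv(bundle$kills, "kill_sites.csv")
  wcsv(bundle$compositions, "compositions.csv")
  wcsv(bundle$comparison, "model_comparison.csv")
  wcsv(bundle$conditional_effects, "conditional_effects.csv")
  wcsv(dplyr::bind_rows(lapply(bundle$fits, function(f) f$diagnostics),
                        .id = "model"), "diagnostics.csv")
  wcsv(bundle$audit, "filter_audit.csv")
  write_ascii_grid(bundle$landscape$canopy,
                   file.path(out_dir, "canopy.asc"))
  tr <- bundle$truth_record
  tr$beta <- as.list(as.data.frame(tr$beta))
  tr$z_herd <- NULL; tr$v_session <- NULL
  tr$standardization <- as.list(tr$standardization)
  yaml::write_yaml(tr, file.path(out_dir, "truth.yaml"))
  manifest <- list(
    package = "elkrisk",
    version = as.character(utils::packageVersion("elkrisk")),
    r_version = R.version.string,
    seed = bundle$config$seed,
    mcmc = unclass(bundle$config$mcmc),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
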