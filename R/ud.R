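# Kernel-density utilization distributions (UDs) for wolf packs and the
# population, at four spatial-temporal scales, on an anisotropic
# 380 x 450 m evaluation grid.

#' Grid specification for UD estimation
#'
#' Builds a [grid_raster()]-compatible grid covering a set of fixes with a
#' margin, at the UD evaluation resolution.
#'
#' @param fixes fix table with `x`, `y`.
#' @param cell_x,cell_y UD cell size in meters (380 x 450).
#' @param margin margin added around the fixes, in meters.
#' @return A list with `xmin`, `ymin`, `cell_x`, `cell_y`, `ncol`, `nrow`.
#' @export
ud_grid <- function(fixes, cell_x = 380, cell_y = 450, margin = 3000) {
  xr <- range(fixes$x); yr <- range(fixes$y)
  xmin <- xr[1] - margin; ymin <- yr[1] - margin
  list(xmin = xmin, ymin = ymin, cell_x = cell_x, cell_y = cell_y,
       ncol = ceiling((xr[2] + margin - xmin) / cell_x),
       nrow = ceiling((yr[2] + margin - ymin) / cell_y))
}

#' Estimate a utilization distribution by kernel density
#'
#' Bivariate Gaussian KDE (via [MASS::kde2d()]) evaluated at cell centers and
#' normalized to sum to one over the grid.  Bandwidths default to the
#' normal-reference rule per coordinate.
#'
#' @param fixes fix table with columns `x`, `y` (and optionally `pack_id`,
#'   `season`, `year` used in error messages and metadata).
#' @param grid a grid spec from [ud_grid()]; defaults to the fixes plus a
#'   3-bandwidth margin.
#' @param bandwidth length-2 kernel bandwidths (as in [MASS::kde2d()]'s `h`);
#'   default normal-reference rule.
#' @return A [grid_raster()] with subclass `ud_raster`; `$meta` records the
#'   scale tag, pack, season, year and fix count.
#' @export
estimate_ud <- function(fixes, grid = NULL, bandwidth = NULL) {
  if (nrow(fixes) < 5) {
    tag <- paste(unique(c(
      if ("pack_id" %in% names(fixes)) as.character(fixes$pack_id),
      if ("season" %in% names(fixes)) as.character(fixes$season)
    )), collapse = "/")
    stop("insufficient fixes (< 5) for UD",
         if (nzchar(tag)) paste0(" [", tag, "]"), call. = FALSE)
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(fixes$x), MASS::bandwidth.nrd(fixes$y))
  }
  if (is.null(grid)) {
    grid <- ud_grid(fixes, margin = 3 * max(bandwidth, 380))
  }
  # degenerate spread (all fixes identical): fall back to one cell per axis
  bandwidth <- pmax(bandwidth, c(grid$cell_x, grid$cell_y))
  lims <- c(grid$xmin + grid$cell_x / 2,
            grid$xmin + (grid$ncol - 0.5) * grid$cell_x,
            grid$ymin + grid$cell_y / 2,
            grid$ymin + (grid$nrow - 0.5) * grid$cell_y)
  kd <- MASS::kde2d(fixes$x, fixes$y, h = bandwidth,
                    n = c(grid$ncol, grid$nrow), lims = lims)
  z <- t(kd$z)                       # rows = y as in grid_raster
  z <- z / sum(z)
  r <- grid_raster(z, xmin = grid$xmin, ymin = grid$ymin,
                   cell_x = grid$cell_x, cell_y = grid$cell_y)
  r$meta <- list(
    n_fixes = nrow(fixes), bandwidth = bandwidth,
    pack_id = if ("pack_id" %in% names(fixes))
      paste(unique(as.character(fixes$pack_id)), collapse = "+") else NA
  )
  class(r) <- c("ud_raster", class(r))
  r
}

#' Scale pack UDs by pack size and merge
#'
#' Multiplies each pack UD cell-wise by its wolf count and sums overlapping
#' cells, producing a pack-size-weighted relative-use surface.
#'
#' @param pack_uds list of `ud_raster`s on a common grid.
#' @param pack_sizes numeric vector of wolf counts, one per UD.
#' @return A [grid_raster()] (not normalized; total mass equals the summed
#'   pack sizes).
#' @export
build_scaled_ud <- function(pack_uds, pack_sizes) {
  stopifnot(length(pack_uds) >= 1, length(pack_sizes) == length(pack_uds))
  base <- pack_uds[[1]]
  acc <- base$values * pack_sizes[1]
  for (i in seq_along(pack_uds)[-1]) {
    if (!same_grid(base, pack_uds[[i]])) {
      stop("pack UDs are not on a common grid", call. = FALSE)
    }
    acc <- acc + pack_uds[[i]]$values * pack_sizes[i]
  }
  grid_raster(acc, xmin = base$xmin, ymin = base$ymin,
              cell_x = base$cell_x, cell_y = base$cell_y)
}

representative_fixes <- function(fixes) {
  # single most-sampled wolf per pack; ties broken by smallest animal id
  counts <- fixes |>
    dplyr::count(.data$pack_id, .data$animal_id) |>
    dplyr::arrange(.data$pack_id, dplyr::desc(.data$n), .data$animal_id) |>
    dplyr::group_by(.data$pack_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  dplyr::semi_join(fixes, counts, by = c("pack_id", "animal_id"))
}

#' Population-level UD from one representative wolf per pack
#'
#' Pools the fixes of the most-sampled wolf in each pack (ties broken by
#' smallest animal id) and estimates a single normalized UD.
#'
#' @inheritParams estimate_ud
#' @return A `ud_raster`.
#' @export
build_population_ud <- function(fixes, grid = NULL, bandwidth = NULL) {
  sel <- representative_fixes(fixes)
  if (nrow(sel) == 0) stop("no fixes to pool", call. = FALSE)
  estimate_ud(sel, grid = grid, bandwidth = bandwidth)
}

#' Build the four-scale UD set
#'
#' Constructs the wolf-presence surfaces used as the spatial risk backbone:
#' * `PackSY` — per pack-season-year UDs, weighted by the seasonal pack
#'   count and summed across packs (one surface per season-year);
#' * `PackYm` — per pack-year UDs weighted by the maximum pack count across
#'   the year's seasons, summed (one per year);
#' * `PopSY` — season-year UDs pooled over one representative wolf per pack;
#' * `PopY` — yearly UDs pooled the same way.
#' All surfaces share one grid so they can be compared cell-wise.
#'
#' @param fixes fix table with `animal_id`, `pack_id`, `t`, `x`, `y`.
#' @param pack_sizes tibble with `pack_id`, `season`, `size` (wolf counts).
#' @param grid optional common grid spec from [ud_grid()].
#' @param bandwidth optional common KDE bandwidth.
#' @return A tibble with columns `scale_tag`, `year`, `season`, `raster`
#'   (list column of rasters).
#' @export
build_ud_set <- function(fixes, pack_sizes, grid = NULL, bandwidth = NULL) {
  fixes <- fixes |>
    dplyr::mutate(season = season_of(as.Date(.data$t)),
                  year = lubridate::year(.data$t))
  if (is.null(grid)) grid <- ud_grid(fixes)
  size_of <- function(pid, seas) {
    s <- pack_sizes$size[pack_sizes$pack_id == pid &
                           as.character(pack_sizes$season) == as.character(seas)]
    if (length(s) == 0) stop("no pack size for ", pid, " in ", seas,
                             call. = FALSE)
    s[1]
  }
  rows <- list()
  add <- function(tag, year, season, raster) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      scale_tag = tag, year = year,
      season = as.character(season), raster = list(raster))
  }
  for (yr in sort(unique(fixes$year))) {
    fy <- dplyr::filter(fixes, .data$year == yr)
    # PackSY: weighted sum of pack-season UDs per season
    for (seas in unique(as.character(fy$season))) {
      fs <- dplyr::filter(fy, as.character(.data$season) == seas)
      pids <- unique(fs$pack_id)
      uds <- lapply(pids, function(p) {
        estimate_ud(dplyr::filter(fs, .data$pack_id == p), grid, bandwidth)
      })
      sizes <- vapply(pids, size_of, numeric(1), seas = seas)
      add("PackSY", yr, seas, build_scaled_ud(uds, sizes))
      add("PopSY", yr, seas, build_population_ud(fs, grid, bandwidth))
    }
    # PackYm: yearly pack UDs weighted by max seasonal count
    pids <- unique(fy$pack_id)
    uds <- lapply(pids, function(p) {
      estimate_ud(dplyr::filter(fy, .data$pack_id == p), grid, bandwidth)
    })
    sizes <- vapply(pids, function(p) {
      max(pack_sizes$size[pack_sizes$pack_id == p])
    }, numeric(1))
    add("PackYm", yr, NA, build_scaled_ud(uds, sizes))
    add("PopY", yr, NA, build_population_ud(fy, grid, bandwidth))
  }
  dplyr::bind_rows(rows)
}

#' Look up the UD surface for an observation date
#'
#' @param ud_set tibble from [build_ud_set()].
#' @param scale_tag one of `"PackSY"`, `"PackYm"`, `"PopSY"`, `"PopY"`.
#' @param date observation date.
#' @return The matching raster.
#' @export
lookup_ud <- function(ud_set, scale_tag, date) {
  yr <- lubridate::year(as.Date(date))
  seas <- as.character(season_of(as.Date(date)))
  hit <- ud_set$scale_tag == scale_tag & ud_set$year == yr
  if (scale_tag %in% c("PackSY", "PopSY")) hit <- hit & ud_set$season == seas
  if (!any(hit)) {
    stop("no ", scale_tag, " UD for ", seas, " ", yr, call. = FALSE)
  }
  ud_set$raster[[which(hit)[1]]]
}
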