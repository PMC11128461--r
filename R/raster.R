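#' Lightweight regular-grid raster
#'
#' A `grid_raster` is a numeric matrix of cell values on a regular grid in a
#' projected coordinate system (meters), the spatial backbone for canopy,
#' vegetation, openness, cover-class and utilization-distribution surfaces.
#' Rows index y (row 1 = southernmost row), columns index x, so
#' `values[i, j]` sits at center
#' `(xmin + (j - 1/2) * cell_x, ymin + (i - 1/2) * cell_y)`.
#'
#' @param values numeric matrix of cell values.
#' @param xmin,ymin coordinates of the grid's lower-left corner (meters).
#' @param cell_x,cell_y cell size in meters along x and y.
#' @param crs free-text tag for the projected CRS; purely descriptive.
#'
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cell_x = 30,
                        cell_y = cell_x, crs = "local-meters") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cell_x > 0, cell_y > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cell_x = cell_x, cell_y = cell_y, crs = crs),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf(
    "<grid_raster> %d x %d cells of %g x %g m, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell_x, x$cell_y, x$xmin, x$ymin))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$cell_x
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cell_y

#' Cell-center coordinates of a raster
#'
#' @param r a [grid_raster()].
#' @return A list with numeric vectors `x` (column centers) and `y`
#'   (row centers).
#' @export
raster_centers <- function(r) {
  list(
    x = r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell_x,
    y = r$ymin + (seq_len(nrow(r$values)) - 0.5) * r$cell_y
  )
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell_x - b$cell_x) < tol && abs(a$cell_y - b$cell_y) < tol
}

raster_cell_index <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cell_x) + 1L
  row <- floor((y - r$ymin) / r$cell_y) + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  if (any(bad)) {
    stop("point(s) outside raster extent: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  cbind(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Looks up the value of the cell containing each point.
#'
#' @param data a data frame with coordinate columns.
#' @param r a [grid_raster()].
#' @param x,y names of the coordinate columns.
#' @param col name of the output column.
#' @return `data` as a tibble with the extracted column appended.
#' @export
raster_extract <- function(data, r, x = "x", y = "y", col = "value") {
  idx <- raster_cell_index(r, data[[x]], data[[y]])
  out <- tibble::as_tibble(data)
  out[[col]] <- r$values[idx]
  out
}

#' Mean raster value in a circular buffer
#'
#' Averages the cells whose centers fall within `radius` of the point; when no
#' cell center falls inside the circle the containing cell's value is
#' returned.  These are the spatial supports at which predation-risk surfaces
#' are summarized around a behavioral observation (200, 800 or 2000 m).
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates (meters); vectors of equal length.
#' @param radius buffer radius in meters.
#' @return Numeric vector of buffer means.
#' @export
buffer_mean <- function(r, x, y, radius) {
  stopifnot(length(x) == length(y), radius > 0)
  cen <- raster_centers(r)
  vapply(seq_along(x), function(i) {
    raster_cell_index(r, x[i], y[i])  # errors if outside extent
    jr <- which(abs(cen$x - x[i]) <= radius)
    ir <- which(abs(cen$y - y[i]) <= radius)
    if (length(jr) && length(ir)) {
      sub <- r$values[ir, jr, drop = FALSE]
      dx <- outer(rep(1, length(ir)), cen$x[jr] - x[i])
      dy <- outer(cen$y[ir] - y[i], rep(1, length(jr)))
      inside <- dx * dx + dy * dy <= radius^2
      if (any(inside)) return(mean(sub[inside]))
    }
    r$values[raster_cell_index(r, x[i], y[i])]
  }, numeric(1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Convert a raster to a tibble of cell centers
#'
#' @param x a [grid_raster()].
#' @param ... unused.
#' @return A tibble with columns `x`, `y`, `value`.
#' @export
as_tibble.grid_raster <- function(x, ...) {
  cen <- raster_centers(x)
  vals <- x$values
  tibble::tibble(
    x = rep(cen$x, each = nrow(vals)),
    y = rep(cen$y, times = ncol(vals)),
    value = as.vector(vals)
  )
}

#' Read / write a raster as ESRI ASCII grid
#'
#' Plain-text raster interchange: square-cell grids only (the format has a
#' single `cellsize` field).
#'
#' @param r a [grid_raster()].
#' @param path file path.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [grid_raster()].
#' @export
write_ascii_grid <- function(r, path) {
  if (abs(r$cell_x - r$cell_y) > 1e-9) {
    stop("ASCII grid requires square cells", call. = FALSE)
  }
  hdr <- c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell_x),
    "NODATA_value -9999"
  )
  vals <- r$values
  vals[!is.finite(vals)] <- -9999
  # ASCII grid rows run north -> south
  body <- apply(vals[rev(seq_len(nrow(vals))), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  m[m == vals[["nodata_value"]]] <- NA_real_
  grid_raster(m[rev(seq_len(nrow(m))), , drop = FALSE],
              xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
              cell_x = vals[["cellsize"]])
}

#' Plot a raster with ggplot2
#'
#' @param object a [grid_raster()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- as_tibble.grid_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
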