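#' Construct a gridded climate time series
#'
#' @param grid A [grid_spec()].
#' @param times_years Strictly increasing timestamps in years (e.g.
#'   100-year steps from the Last Glacial Maximum to 0 = present).
#' @param values Cells x time matrix of the climate variable.
#' @param variable,units Metadata strings.
#' @return A `climate_series` object.
#' @export
climate_series <- function(grid, times_years, values, variable = "bio1",
                           units = "") {
  stopifnot(inherits(grid, "phylogrid_grid"))
  values <- as.matrix(values)
  if (length(times_years) < 2) stop("need at least 2 time steps", call. = FALSE)
  if (any(diff(times_years) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (nrow(values) != n_cells(grid) || ncol(values) != length(times_years)) {
    stop("values must be cells x timestamps", call. = FALSE)
  }
  structure(list(grid = grid, times_years = as.numeric(times_years),
                 values = values, variable = variable, units = units),
            class = "climate_series")
}

#' Per-cell temporal trend of a climate series
#'
#' Ordinary-least-squares slope of the cell's value against time in
#' years, using the full series (not endpoints). Cells with fewer than
#' two finite values are returned as `NA`.
#'
#' @param cs A [climate_series()].
#' @return Numeric vector of slopes (units per year) over cells.
#' @export
temporal_trend <- function(cs) {
  stopifnot(inherits(cs, "climate_series"))
  t <- cs$times_years
  v <- cs$values
  apply(v, 1, function(row) {
    ok <- is.finite(row)
    if (sum(ok) < 2) return(NA_real_)
    tt <- t[ok] - mean(t[ok])
    sum(tt * row[ok]) / sum(tt^2)
  })
}

#' Spatial gradient magnitude of a raster
#'
#' Central differences on the 3x3 neighbourhood: the x- and y-components
#' are the mean of the forward and backward differences divided by the
#' cell size (one-sided at grid edges), and the magnitude is
#' sqrt(dx^2 + dy^2). For a plane a + g x the magnitude is |g|
#' everywhere.
#'
#' @param values Per-cell raster values in cell-id order.
#' @param grid The [grid_spec()].
#' @return Data frame with `dx`, `dy`, `magnitude` (units per km).
#' @export
spatial_gradient <- function(values, grid) {
  stopifnot(inherits(grid, "phylogrid_grid"))
  nr <- grid$n_rows; ncg <- grid$n_cols; h <- grid$cell_size
  m <- matrix(values, nr, ncg, byrow = TRUE)  # row 1 = bottom
  diff_axis <- function(mat, along_cols) {
    a <- if (along_cols) mat else t(mat)
    n <- ncol(a)
    d <- matrix(NA_real_, nrow(a), n)
    if (n >= 2) {
      d[, 1] <- (a[, 2] - a[, 1]) / h
      d[, n] <- (a[, n] - a[, n - 1]) / h
    }
    if (n >= 3) {
      d[, 2:(n - 1)] <- (a[, 3:n] - a[, 1:(n - 2)]) / (2 * h)
    }
    if (along_cols) d else t(d)
  }
  dx <- diff_axis(m, TRUE)
  dy <- diff_axis(m, FALSE)
  data.frame(dx = as.vector(t(dx)), dy = as.vector(t(dy)),
             magnitude = as.vector(t(sqrt(dx^2 + dy^2))))
}

#' Gradient-based climate-change velocity
#'
#' Velocity is local climatic displacement: the temporal rate of change
#' divided by the local spatial gradient, in km per year. The temporal
#' rate is the per-cell OLS trend (absolute value: speed, since layers
#' are later combined additively); the spatial gradient is computed on
#' the time-mean raster. Where the gradient falls below `gradient_floor`
#' (flat terrain) the floor is substituted to avoid division blow-up,
#' and those cells are flagged in the `floored` mask for audit.
#'
#' @param cs A [climate_series()].
#' @param gradient_floor Minimum spatial gradient (units per km).
#' @return A `velocity_raster`: list with `velocity` (km/yr), `slope`
#'   (units/yr), `gradient` (units/km), logical `floored`, and the grid.
#' @export
climate_velocity <- function(cs, gradient_floor = 1e-6) {
  slope <- temporal_trend(cs)
  grad <- spatial_gradient(rowMeans(cs$values), cs$grid)$magnitude
  floored <- is.finite(grad) & grad < gradient_floor
  g <- pmax(grad, gradient_floor)
  structure(list(grid = cs$grid, velocity = abs(slope) / g, slope = slope,
                 gradient = grad, floored = floored,
                 variable = cs$variable),
            class = "velocity_raster")
}

#' Normalize two velocity rasters to 0-1 and sum them
#'
#' Each layer is min-max rescaled over its non-missing cells, so 0 marks
#' the most climatically stable cell of a layer and 1 the fastest-moving
#' one; the combined raster is the elementwise sum, bounded in 0-2. A
#' constant layer has no range to rescale and becomes all zeros, with a
#' warning.
#'
#' @param v1,v2 `velocity_raster` objects (or bare numeric vectors) on
#'   matching grids.
#' @return Numeric vector of combined normalized velocity over cells.
#' @export
normalize_and_combine <- function(v1, v2) {
  get_v <- function(v) if (inherits(v, "velocity_raster")) v$velocity else as.numeric(v)
  a <- get_v(v1); b <- get_v(v2)
  if (length(a) != length(b)) stop("rasters must share a grid", call. = FALSE)
  rescale01 <- function(x) {
    ok <- is.finite(x)
    rng <- range(x[ok])
    if (diff(rng) == 0) {
      warning("constant raster: normalized layer set to 0")
      return(ifelse(ok, 0, NA_real_))
    }
    (x - rng[1]) / diff(rng)
  }
  rescale01(a) + rescale01(b)
}

# --- ESRI ASCII grid IO ----------------------------------------------------

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values from the
#' top row down. `NA` cells are written as the NODATA value.
#'
#' @param values Per-cell values in cell-id order (row 1 = bottom).
#' @param grid The [grid_spec()].
#' @param path Output path.
#' @param nodata NODATA sentinel.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a list with `values` and `grid`.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "phylogrid_grid"),
            length(values) == n_cells(grid))
  m <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$x0),
    sprintf("yllcorner %.10g", grid$y0),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(m[grid$n_rows:1, , drop = FALSE], 1,
                function(r) paste(format(r, digits = 15, trim = TRUE,
                                         scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[[`, character(1), 2))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  if (length(body) != ncols * nrows) stop("malformed ASCII grid", call. = FALSE)
  m <- matrix(body, nrows, ncols, byrow = TRUE)  # top row first
  m[m == nodata] <- NA_real_
  grid <- grid_spec(nrows, ncols, vals[["cellsize"]],
                    vals[["xllcorner"]], vals[["yllcorner"]])
  list(values = as.vector(t(m[nrows:1, , drop = FALSE])), grid = grid)
}

#' Write / read a climate series as a directory of ASCII rasters
#'
#' One `.asc` per time step plus a `manifest.csv` (file, time_years,
#' variable, units).
#'
#' @param cs A [climate_series()].
#' @param dir Directory (created if needed).
#' @return `write_climate_series()` returns `dir` invisibly;
#'   `read_climate_series()` returns a `climate_series`.
#' @export
write_climate_series <- function(cs, dir) {
  stopifnot(inherits(cs, "climate_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.asc", cs$variable, seq_along(cs$times_years))
  for (i in seq_along(files)) {
    write_ascii_grid(cs$values[, i], cs$grid, file.path(dir, files[i]))
  }
  write.csv(data.frame(file = files, time_years = cs$times_years,
                       variable = cs$variable, units = cs$units),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_climate_series
#' @export
read_climate_series <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  rasters <- lapply(file.path(dir, man$file), read_ascii_grid)
  values <- do.call(cbind, lapply(rasters, `[[`, "values"))
  climate_series(rasters[[1]]$grid, man$time_years, values,
                 variable = man$variable[1], units = as.character(man$units[1]))
}
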