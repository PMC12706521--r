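#' Define a regular analysis grid
#'
#' The grid is planar and equal-area: coordinates are in kilometres, cells
#' are squares of side `cell_size`, the origin is the lower-left corner of
#' the lower-left cell, and cell ids are dense row-major indices starting
#' at 0 with row 1 at the bottom.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell side length in km (> 0).
#' @param x0,y0 Coordinates (km) of the grid's lower-left corner.
#' @return An object of class `phylogrid_grid`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, x0 = 0, y0 = 0) {
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be > 0", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         x0 = as.numeric(x0), y0 = as.numeric(y0)),
    class = "phylogrid_grid"
  )
}

#' @export
print.phylogrid_grid <- function(x, ...) {
  cat(sprintf("grid: %d x %d cells of %g km, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x0, x$y0))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell ids, row/column indices and centre coordinates of a grid
#'
#' @param grid A [grid_spec()] object.
#' @return A data frame with columns `cell_id` (0-based, row-major from the
#'   lower-left), `row`, `col`, and centre coordinates `x`, `y` in km.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "phylogrid_grid"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    cell_id = (row - 1L) * grid$n_cols + (col - 1L),
    row = row, col = col,
    x = grid$x0 + (col - 0.5) * grid$cell_size,
    y = grid$y0 + (row - 0.5) * grid$cell_size
  )
}

#' Construct a gridded presence-absence community matrix
#'
#' @param occupancy Binary matrix, cells (rows, in cell-id order) by
#'   species (columns). Entries must be 0/1.
#' @param grid The [grid_spec()] the rows refer to.
#' @param species Species labels; defaults to `colnames(occupancy)`.
#' @return A `community_matrix`: occupancy, grid, and cached marginals
#'   (per-species range size `r_i` = column sums, per-cell richness `s` =
#'   row sums).
#' @export
community_matrix <- function(occupancy, grid, species = colnames(occupancy)) {
  stopifnot(inherits(grid, "phylogrid_grid"))
  occupancy <- as.matrix(occupancy)
  if (nrow(occupancy) != n_cells(grid)) {
    stop(sprintf("occupancy has %d rows but the grid has %d cells",
                 nrow(occupancy), n_cells(grid)), call. = FALSE)
  }
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(occupancy)))
  if (anyDuplicated(species)) {
    stop("species labels must be unique", call. = FALSE)
  }
  if (length(species) != ncol(occupancy)) {
    stop("species labels do not match the number of columns", call. = FALSE)
  }
  if (!all(occupancy %in% c(0, 1))) {
    stop("occupancy entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(occupancy) <- "integer"
  dimnames(occupancy) <- list(NULL, species)
  structure(
    list(occupancy = occupancy, grid = grid, species = species),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix: %d cells x %d species, %d presences\n",
              nrow(x$occupancy), ncol(x$occupancy), sum(x$occupancy)))
  print(x$grid)
  invisible(x)
}

# Accept either a community_matrix or a bare binary matrix.
as_occupancy <- function(cm) {
  if (inherits(cm, "community_matrix")) return(cm$occupancy)
  m <- as.matrix(cm)
  if (!all(m %in% c(0, 1))) stop("matrix entries must be 0 or 1", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

# Rebuild an object of the same type as `template` around new occupancy.
rewrap_occupancy <- function(template, occupancy) {
  if (inherits(template, "community_matrix")) {
    out <- template
    out$occupancy <- occupancy
    return(out)
  }
  occupancy
}

#' Per-species range sizes (occupied-cell counts)
#' @param cm A `community_matrix` or binary matrix.
#' @return Named integer vector `r_i`.
#' @export
range_sizes <- function(cm) colSums(as_occupancy(cm))

#' Species richness per grid cell
#'
#' SR(cell) is the number of species present, i.e. the row sum of the
#' presence-absence matrix.
#'
#' @inheritParams range_sizes
#' @return Numeric vector over cells, in cell-id order.
#' @export
species_richness <- function(cm) rowSums(as_occupancy(cm))

#' Weighted endemism per grid cell
#'
#' WE(cell) = sum over resident species of 1 / r_i, where r_i is the
#' number of grid cells the species occupies across the study area. A
#' single-cell endemic therefore contributes exactly 1 to its cell, and
#' summed over all cells WE equals the number of (occurring) species.
#' Species occupying no cell carry no defined weight and are skipped.
#'
#' @inheritParams range_sizes
#' @return Numeric vector over cells.
#' @export
weighted_endemism <- function(cm) {
  m <- as_occupancy(cm)
  r <- colSums(m)
  w <- ifelse(r > 0, 1 / r, 0)
  as.vector(m %*% w)
}

#' NODF nestedness of a binary matrix
#'
#' NODF (nestedness metric based on overlap and decreasing fill) averages,
#' over all row pairs and all column pairs, the paired-overlap percentage,
#' where a pair only contributes when its marginal totals strictly
#' decrease (pairs with equal totals score 0). Pairs are ordered by their
#' marginal totals, i.e. the matrix is arranged by decreasing fill before
#' scoring - the standard formulation - so the value does not depend on
#' the arrangement of the input rows and columns. Computation is
#' delegated to [vegan::nestednodf()] (ordered, unweighted).
#'
#' @inheritParams range_sizes
#' @return NODF on the 0-100 scale.
#' @export
nodf <- function(cm) {
  m <- as_occupancy(cm)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("NODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (sum(m) == 0) stop("NODF is undefined for an all-zero matrix", call. = FALSE)
  res <- vegan::nestednodf(m, order = TRUE, weighted = FALSE)
  unname(res$statistic["NODF"])
}

#' Bin point occurrences into a gridded community matrix
#'
#' Presence is recorded where at least one occurrence falls in a cell.
#' Cells are half-open intervals `[left, right) x [bottom, top)`, so a
#' point on a cell's lower or left edge belongs to that cell and points on
#' the grid's upper or right outer edge fall outside. Out-of-grid records
#' are dropped and counted, not an error.
#'
#' @param occurrences Data frame with columns `species`, `x`, `y`
#'   (km, same datum as the grid).
#' @param grid A [grid_spec()].
#' @param species Optional label set fixing the column order (defaults to
#'   sorted unique labels in the data).
#' @return A `community_matrix`; the number of dropped records is attached
#'   as attribute `n_out_of_grid`.
#' @export
points_to_matrix <- function(occurrences, grid, species = NULL) {
  stopifnot(inherits(grid, "phylogrid_grid"))
  if (NROW(occurrences) == 0) {
    stop("no occurrence records supplied", call. = FALSE)
  }
  if (!all(c("species", "x", "y") %in% names(occurrences))) {
    stop("occurrences must have columns species, x, y", call. = FALSE)
  }
  if (!all(is.finite(occurrences$x)) || !all(is.finite(occurrences$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (is.null(species)) species <- sort(unique(as.character(occurrences$species)))
  col <- floor((occurrences$x - grid$x0) / grid$cell_size) + 1
  row <- floor((occurrences$y - grid$y0) / grid$cell_size) + 1
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  m <- matrix(0L, n_cells(grid), length(species),
              dimnames = list(NULL, species))
  if (any(inside)) {
    cell <- (row[inside] - 1) * grid$n_cols + col[inside]  # 1-based row-major
    sp <- match(as.character(occurrences$species[inside]), species)
    if (anyNA(sp)) stop("occurrence species not in the supplied label set", call. = FALSE)
    m[cbind(cell, sp)] <- 1L
  }
  out <- community_matrix(m, grid, species)
  attr(out, "n_out_of_grid") <- sum(!inside)
  out
}

# --- polygon rasterization -------------------------------------------------

# Sutherland-Hodgman clip of a polygon (2-column matrix of vertices, open
# ring) against an axis-aligned rectangle. Returns the clipped vertex
# matrix, possibly with 0 rows.
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    ins <- inside(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (ins[i]) {
        out <- rbind(out, pts[i, ])
        if (!ins[j]) out <- rbind(out, intersect(pts[i, ], pts[j, ]))
      } else if (ins[j]) {
        out <- rbind(out, intersect(pts[i, ], pts[j, ]))
      }
    }
    out
  }
  ix <- function(p, q, x) {  # intersection with vertical line
    t <- (x - p[1]) / (q[1] - p[1])
    c(x, p[2] + t * (q[2] - p[2]))
  }
  iy <- function(p, q, y) {
    t <- (y - p[2]) / (q[2] - p[2])
    c(p[1] + t * (q[1] - p[1]), y)
  }
  poly <- clip_edge(poly, function(p) p[, 1] >= xmin, function(p, q) ix(p, q, xmin))
  poly <- clip_edge(poly, function(p) p[, 1] <= xmax, function(p, q) ix(p, q, xmax))
  poly <- clip_edge(poly, function(p) p[, 2] >= ymin, function(p, q) iy(p, q, ymin))
  poly <- clip_edge(poly, function(p) p[, 2] <= ymax, function(p, q) iy(p, q, ymax))
  poly
}

# Shoelace area (absolute) of an open-ring polygon.
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Rasterize species range polygons onto a grid
#'
#' A species is marked present in every cell whose rectangle it overlaps
#' with nonzero area (not a cell-centre rule: a range that merely brushes
#' a cell still counts, matching how expert range maps are gridded).
#' Species whose polygon misses the grid entirely are kept as all-zero
#' columns and reported via the `empty_species` attribute.
#'
#' Polygons are supplied directly as vertex lists (one simple,
#' non-self-intersecting ring per species) in the grid's km coordinates;
#' see [read_polygons_csv()] for the plain-text on-disk format.
#'
#' @param polygons Named list, one element per species, each a 2-column
#'   matrix or data frame of ring vertices (x, y; the closing vertex may
#'   be omitted).
#' @param grid A [grid_spec()].
#' @return A `community_matrix` with attribute `empty_species`.
#' @export
rasterize_ranges <- function(polygons, grid) {
  stopifnot(inherits(grid, "phylogrid_grid"))
  species <- names(polygons)
  if (is.null(species) || anyDuplicated(species)) {
    stop("polygons must be a named list with unique species names", call. = FALSE)
  }
  cc <- cell_centers(grid)
  h <- grid$cell_size / 2
  eps <- 1e-12 * grid$cell_size^2
  m <- matrix(0L, n_cells(grid), length(species), dimnames = list(NULL, species))
  for (s in seq_along(species)) {
    poly <- as.matrix(polygons[[s]])
    if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- poly[-nrow(poly), , drop = FALSE]
    }
    if (nrow(poly) < 3) {
      stop(sprintf("polygon for species '%s' is degenerate (<3 vertices)",
                   species[s]), call. = FALSE)
    }
    bb <- c(range(poly[, 1]), range(poly[, 2]))
    cand <- which(cc$x + h > bb[1] & cc$x - h < bb[2] &
                  cc$y + h > bb[3] & cc$y - h < bb[4])
    for (i in cand) {
      clp <- clip_polygon_rect(poly, cc$x[i] - h, cc$x[i] + h,
                               cc$y[i] - h, cc$y[i] + h)
      if (polygon_area(clp) > eps) m[i, s] <- 1L
    }
  }
  out <- community_matrix(m, grid, species)
  attr(out, "empty_species") <- species[colSums(m) == 0]
  out
}

# --- plain-text IO ---------------------------------------------------------

#' Write / read a community matrix as CSV
#'
#' The layout is one row per cell: `cell_id`, centre `x`, `y`, then one
#' 0/1 column per species.
#'
#' @param cm A `community_matrix`.
#' @param path File path.
#' @return `write_community_csv()` returns `path` invisibly;
#'   `read_community_csv()` returns a `community_matrix`.
#' @export
write_community_csv <- function(cm, path) {
  stopifnot(inherits(cm, "community_matrix"))
  cc <- cell_centers(cm$grid)
  df <- cbind(cc[, c("cell_id", "x", "y")], as.data.frame(cm$occupancy))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param grid The [grid_spec()] the file refers to (the CSV stores cell
#'   ids and centres, not the grid definition).
#' @rdname write_community_csv
#' @export
read_community_csv <- function(path, grid) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("cell_id", "x", "y") %in% names(df)))
  df <- df[order(df$cell_id), , drop = FALSE]
  sp <- setdiff(names(df), c("cell_id", "x", "y"))
  community_matrix(as.matrix(df[, sp, drop = FALSE]), grid, sp)
}

#' Read species range polygons from a vertex CSV
#'
#' Expects columns `species`, `x`, `y`: consecutive rows of one species
#' form the ring, in order.
#'
#' @param path CSV path.
#' @return Named list of vertex matrices suitable for [rasterize_ranges()].
#' @export
read_polygons_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("species", "x", "y") %in% names(df)))
  lapply(split(df[, c("x", "y")], df$species), as.matrix)
}
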