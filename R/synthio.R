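#' Define a synthetic-data scenario
#'
#' Bundles everything needed to generate a reproducible gridded study
#' system: the analysis grid, a pure-birth phylogeny, and contiguous
#' species ranges with an optional endemism hotspot. Hotspot types plant
#' known signal for the endemism analyses: under `"neo"` the species on
#' the shortest fraction `hotspot_quantile` of terminal branches are
#' confined to the hotspot block with small ranges; under `"paleo"` the
#' longest-terminal-branch species are; `"mixed"` confines both sets.
#'
#' @param n_rows,n_cols,cell_size Grid layout (see [grid_spec()]).
#' @param n_species Number of species (>= 2).
#' @param birth_rate Speciation rate of the pure-birth tree (> 0).
#' @param range_mean,range_dispersion Mean and dispersion (negative
#'   binomial `size`) of background range sizes in cells.
#' @param hotspot_rows,hotspot_cols Inclusive row/column index ranges
#'   (length-2 integer vectors) of the hotspot block; must lie inside
#'   the grid. Required unless `hotspot_type = "none"`.
#' @param hotspot_type `"none"`, `"neo"`, `"paleo"` or `"mixed"`.
#' @param hotspot_quantile Fraction of species assigned to each hotspot
#'   set (default 0.2).
#' @param hotspot_range_mean Mean range size (cells) of hotspot
#'   endemics; kept small so they are range-restricted.
#' @param seed Integer seed driving every random draw in the scenario.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(n_rows, n_cols, cell_size = 25, n_species,
                          birth_rate = 1, range_mean = 10,
                          range_dispersion = 5,
                          hotspot_rows = NULL, hotspot_cols = NULL,
                          hotspot_type = c("none", "neo", "paleo", "mixed"),
                          hotspot_quantile = 0.2, hotspot_range_mean = 2,
                          seed = 1L) {
  hotspot_type <- match.arg(hotspot_type)
  grid <- grid_spec(n_rows, n_cols, cell_size)
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (hotspot_type != "none") {
    if (is.null(hotspot_rows) || is.null(hotspot_cols)) {
      stop("hotspot block required for hotspot_type != 'none'", call. = FALSE)
    }
    if (hotspot_rows[1] < 1 || hotspot_rows[2] > n_rows ||
        hotspot_cols[1] < 1 || hotspot_cols[2] > n_cols ||
        hotspot_rows[1] > hotspot_rows[2] || hotspot_cols[1] > hotspot_cols[2]) {
      stop("hotspot block must lie inside the grid", call. = FALSE)
    }
    if (hotspot_quantile <= 0 || hotspot_quantile > 0.5) {
      stop("hotspot_quantile must be in (0, 0.5]", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, n_species = as.integer(n_species),
         birth_rate = birth_rate, range_mean = range_mean,
         range_dispersion = range_dispersion,
         hotspot_rows = hotspot_rows, hotspot_cols = hotspot_cols,
         hotspot_type = hotspot_type, hotspot_quantile = hotspot_quantile,
         hotspot_range_mean = hotspot_range_mean, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation: the root splits into two lineages at time 0; with
#' k extant lineages the next speciation arrives after an
#' Exponential(k * birth_rate) wait and hits a uniformly chosen lineage;
#' the simulation stops after the wait that follows the n-th speciation,
#' so the expected root age is sum over k = 2..n of 1 / (k * birth_rate).
#' The result is ultrametric with strictly positive branch lengths and
#' tips labelled `s1..sn`.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional integer seed.
#' @return An [ape] `phylo` object.
#' @export
simulate_phylogeny <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  n <- as.integer(n_species)
  with_seed(seed, {
    # lineage j: parent internal node lab and birth time
    lin_parent <- c(1L, 1L)
    lin_start <- c(0, 0)
    node_count <- 1L
    parent_lab <- integer(0)
    child_lab <- integer(0)
    elen <- numeric(0)
    t <- 0
    if (n > 2) {
      for (k in 2:(n - 1L)) {
        t <- t + rexp(1, k * birth_rate)
        j <- sample.int(k, 1L)
        node_count <- node_count + 1L
        parent_lab <- c(parent_lab, lin_parent[j])
        child_lab <- c(child_lab, node_count)
        elen <- c(elen, t - lin_start[j])
        lin_parent <- c(lin_parent[-j], node_count, node_count)
        lin_start <- c(lin_start[-j], t, t)
      }
    }
    t <- t + rexp(1, n * birth_rate)
    # remaining lineages become tips, in random label order
    tip_ids <- seq_len(n)
    parent_all <- c(parent_lab, lin_parent)       # internal labels
    child_is_tip <- c(rep(FALSE, length(child_lab)), rep(TRUE, n))
    child_all <- c(child_lab, tip_ids)
    elen_all <- c(elen, t - lin_start)
    # ape numbering: tips 1..n, internals n+1..2n-1 with root n+1
    map_int <- function(lab) n + lab
    edge <- cbind(map_int(parent_all),
                  ifelse(child_is_tip, child_all, map_int(child_all)))
    tree <- list(edge = edge, edge.length = elen_all,
                 tip.label = paste0("s", seq_len(n)), Nnode = n - 1L)
    class(tree) <- "phylo"
    tree <- ape::reorder.phylo(tree, "cladewise")
    tree
  })
}

# Cells of the grid sorted by distance from a centre cell (ties by cell
# index): the deterministic "grown disk" used for contiguous ranges.
grow_range <- function(grid, center_idx, size, allowed = NULL) {
  cc <- cell_centers(grid)
  pool <- if (is.null(allowed)) seq_len(nrow(cc)) else allowed
  d <- sqrt((cc$x[pool] - cc$x[center_idx])^2 + (cc$y[pool] - cc$y[center_idx])^2)
  pool[order(d, pool)][seq_len(min(size, length(pool)))]
}

#' Simulate contiguous species ranges on a grid
#'
#' Each species occupies a disk-shaped block of cells grown outward from
#' a random centre until its drawn range size is reached (ties broken by
#' ring order then cell index). Range sizes are negative-binomially
#' distributed (shifted to be >= 1, capped at the grid size). Hotspot
#' endemics - selected by terminal branch length according to the
#' scenario's hotspot type - are centred inside the hotspot block, grown
#' only within it, and use the small `hotspot_range_mean`. Every species
#' occupies at least one cell.
#'
#' @param tree A `phylo` whose tips define the species set.
#' @param spec A [scenario_spec()]; `spec$seed` makes the draw
#'   reproducible.
#' @return A `community_matrix`; hotspot species names are attached as
#'   attribute `hotspot_species` and hotspot cell ids (0-based) as
#'   `hotspot_cells`.
#' @export
simulate_ranges <- function(tree, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_tree(tree)
  species <- tree$tip.label
  S <- length(species)
  if (S != spec$n_species) {
    stop("tree tip count does not match spec$n_species", call. = FALSE)
  }
  grid <- spec$grid
  nc <- n_cells(grid)
  cc <- cell_centers(grid)
  # terminal branch length per tip
  tip_edge <- match(seq_len(S), tree$edge[, 2])
  term_len <- tree$edge.length[tip_edge]

  hot_cells <- integer(0)
  hot_sp <- integer(0)
  if (spec$hotspot_type != "none") {
    in_block <- cc$row >= spec$hotspot_rows[1] & cc$row <= spec$hotspot_rows[2] &
      cc$col >= spec$hotspot_cols[1] & cc$col <= spec$hotspot_cols[2]
    hot_cells <- which(in_block)
    n_hot <- ceiling(spec$hotspot_quantile * S)
    need <- if (spec$hotspot_type == "mixed") 2L * n_hot else n_hot
    if (need > S) {
      stop("hotspot demands more species than available", call. = FALSE)
    }
    neo_sp <- order(term_len)[seq_len(n_hot)]
    paleo_sp <- order(term_len, decreasing = TRUE)[seq_len(n_hot)]
    hot_sp <- switch(spec$hotspot_type,
                     neo = neo_sp, paleo = paleo_sp,
                     mixed = c(neo_sp, paleo_sp))
  }

  with_seed(spec$seed, {
    m <- matrix(0L, nc, S, dimnames = list(NULL, species))
    for (s in seq_len(S)) {
      if (s %in% hot_sp) {
        size <- 1L + rnbinom(1, mu = max(spec$hotspot_range_mean - 1, 0),
                             size = spec$range_dispersion)
        center <- hot_cells[sample.int(length(hot_cells), 1L)]
        cells <- grow_range(grid, center, size, allowed = hot_cells)
      } else {
        size <- 1L + rnbinom(1, mu = max(spec$range_mean - 1, 0),
                             size = spec$range_dispersion)
        center <- sample.int(nc, 1L)
        cells <- grow_range(grid, center, min(size, nc))
      }
      m[cells, s] <- 1L
    }
    out <- community_matrix(m, grid, species)
    attr(out, "hotspot_species") <- species[hot_sp]
    attr(out, "hotspot_cells") <- hot_cells - 1L  # 0-based ids
    out
  })
}

#' Simulate a gridded climate series with known structure
#'
#' Cell values follow base + spatial_slope * x + temporal_slope * step +
#' Gaussian noise, with `x` the cell-centre easting in km and `step` the
#' 0-based time index. Timestamps are attached in years at `step_years`
#' spacing, ending at 0 (the present), emulating a paleoclimate series
#' at century resolution. With `noise_sd = 0` the per-cell temporal
#' trend is exactly `temporal_slope / step_years` per year and the
#' spatial gradient is exactly `|spatial_slope|`.
#'
#' @param grid A [grid_spec()] (or a [scenario_spec()], whose grid is
#'   used).
#' @param base Baseline value.
#' @param spatial_slope Units per km along x.
#' @param temporal_slope Units per time step (i.e. per century at the
#'   default spacing).
#' @param noise_sd Gaussian noise sd (0 for deterministic fields).
#' @param n_steps Number of time steps (>= 2).
#' @param seed Optional integer seed.
#' @param step_years Step spacing in years.
#' @param variable Variable name recorded in the series.
#' @return A [climate_series()].
#' @export
simulate_climate_series <- function(grid, base = 0, spatial_slope = 0,
                                    temporal_slope = 0, noise_sd = 0,
                                    n_steps = 10, seed = NULL,
                                    step_years = 100, variable = "bio1") {
  if (inherits(grid, "scenario_spec")) grid <- grid$grid
  stopifnot(inherits(grid, "phylogrid_grid"))
  if (n_steps < 2) stop("n_steps must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cc <- cell_centers(grid)
  steps <- 0:(n_steps - 1)
  times <- (steps - (n_steps - 1)) * step_years
  with_seed(seed, {
    values <- outer(base + spatial_slope * cc$x, temporal_slope * steps, "+")
    if (noise_sd > 0) {
      values <- values + matrix(rnorm(length(values), sd = noise_sd),
                                nrow(values), ncol(values))
    }
    climate_series(grid, times, values, variable = variable)
  })
}

#' Simulate a spatially autocorrelated (SAR-error) response
#'
#' Ground truth for the spatial-regression module: y = X beta + u with
#' u = lambda W u + eps and iid Gaussian innovations, realized by
#' solving (I - lambda W) u = eps. With lambda = 0 this reduces to an
#' ordinary linear model.
#'
#' @param X Predictor matrix (a design matrix including any intercept
#'   column; `beta` must match its columns).
#' @param W A row-standardized [build_weights()] object or matrix.
#' @param beta Coefficient vector, one per column of `X`.
#' @param lambda Spatial autocorrelation, |lambda| < 1.
#' @param sigma Innovation sd (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric response vector.
#' @export
simulate_sar_response <- function(X, W, beta, lambda, sigma, seed = NULL) {
  X <- as.matrix(X)
  w <- as_weight_matrix(W)
  if (abs(lambda) >= 1) stop("|lambda| must be < 1", call. = FALSE)
  if (length(beta) != ncol(X)) stop("beta must match ncol(X)", call. = FALSE)
  n <- nrow(X)
  with_seed(seed, {
    eps <- rnorm(n, sd = sigma)
    A <- diag(n) - lambda * w
    u <- tryCatch(solve(A, eps),
                  error = function(e) stop("(I - lambda W) is singular",
                                           call. = FALSE))
    as.vector(X %*% beta + u)
  })
}

#' Reference hotspot scenario
#'
#' The package's standard synthetic study system for endemism analyses:
#' a 10 x 10 grid of 25-km cells holding 100 species from a pure-birth
#' tree (birth rate 1), background ranges of 12 cells on average
#' (negative binomial, dispersion 5), and a 3 x 3 hotspot block in the
#' lower-left corner. The hotspot confines the top 20% of species by
#' terminal branch length (longest for `"paleo"`, shortest for `"neo"`,
#' both for `"mixed"`) to small ranges of 4 cells on average, so every
#' hotspot cell hosts a concentration of range-restricted branches -
#' the spatial structure the endemism classifiers are built to detect -
#' while background cells carry no planted signal.
#'
#' @param hotspot_type `"paleo"`, `"neo"`, `"mixed"` or `"none"`.
#' @param seed Scenario seed.
#' @return A [scenario_spec()].
#' @export
hotspot_scenario <- function(hotspot_type = "paleo", seed = 1L) {
  scenario_spec(
    n_rows = 10, n_cols = 10, cell_size = 25, n_species = 100,
    birth_rate = 1, range_mean = 12, range_dispersion = 5,
    hotspot_rows = if (hotspot_type == "none") NULL else c(1, 3),
    hotspot_cols = if (hotspot_type == "none") NULL else c(1, 3),
    hotspot_type = hotspot_type, hotspot_quantile = 0.2,
    hotspot_range_mean = 4, seed = seed
  )
}

#' Materialize a full synthetic scenario
#'
#' Generates the phylogeny and community matrix of a [scenario_spec()]
#' in one call (tree seed is derived from the scenario seed).
#'
#' @param spec A [scenario_spec()].
#' @return List with `tree` and `cm`.
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tree <- simulate_phylogeny(spec$n_species, spec$birth_rate,
                             seed = spec$seed + 1000L)
  list(tree = tree, cm = simulate_ranges(tree, spec))
}
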