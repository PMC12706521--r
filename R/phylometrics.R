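#' Parse a Newick string into a rooted tree
#'
#' A validating wrapper around [ape::read.tree()]: the result must be a
#' rooted tree with unique tip labels and strictly positive branch
#' lengths on every edge. Zero-length or missing edges are rejected with
#' guidance rather than silently propagated, because downstream metrics
#' (PD, PE, TILD) interpret every edge as evolutionary time.
#'
#' @param text A Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse failed: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse failed", call. = FALSE)
  validate_tree(tree)
  tree
}

#' @param tree A `phylo` object.
#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("every edge must carry a branch length", call. = FALSE)
  }
  if (any(tree$edge.length <= 0)) {
    stop("branch lengths must be > 0; collapse or perturb zero-length edges ",
         "before computing diversity metrics", call. = FALSE)
  }
  invisible(tree)
}

# Edge-by-tip descendant incidence: a logical matrix with one row per edge
# of `tree` and one column per tip, TRUE where the tip descends from the
# edge. This is the workhorse behind PD/PE/beta: a branch is "in" a cell
# exactly when its descendant set intersects the cell's species.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  M <- matrix(FALSE, ne, nt, dimnames = list(NULL, tree$tip.label))
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2L]
    M[e, below[[child]]] <- TRUE
    parent <- tree$edge[e, 1L]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  M
}

# Cells-by-edges branch presence for a community matrix on a tree.
# Species absent from the tree raise a missing-taxon error.
branch_presence <- function(cm, tree, incidence = NULL) {
  m <- as_occupancy(cm)
  sp <- colnames(m)
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing)) {
    stop("species missing from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(incidence)) incidence <- edge_tip_incidence(tree)
  D <- incidence[, sp, drop = FALSE]  # edges x species
  (m %*% t(D)) > 0                    # cells x edges
}

#' Faith's phylogenetic diversity per grid cell
#'
#' PD(cell) is the total branch length of the rooted subtree spanning the
#' cell's species, including the path to the root (so a single-species
#' cell scores its full root-to-tip path, the convention used throughout
#' the CANAPE literature). Empty cells score 0.
#'
#' @param cm A `community_matrix` (or bare binary matrix with species
#'   column names).
#' @param tree Rooted ultrametric-or-not `phylo` with branch lengths;
#'   every community species must be a tip.
#' @return Numeric vector of PD over cells, in branch-length units.
#' @export
faith_pd <- function(cm, tree) {
  validate_tree(tree)
  pres <- branch_presence(cm, tree)
  as.vector(pres %*% tree$edge.length)
}

#' Rosauer's phylogenetic endemism per grid cell
#'
#' Each branch of the cell's rooted spanning subtree contributes its
#' length divided by its range R_b, the number of grid cells holding at
#' least one of its descendant tips. Range-restricted branches therefore
#' weigh more; summed over all cells PE recovers the total length of all
#' occupied branches.
#'
#' @inheritParams faith_pd
#' @return Numeric vector of PE over cells.
#' @export
phylogenetic_endemism <- function(cm, tree) {
  validate_tree(tree)
  pres <- branch_presence(cm, tree)
  rb <- colSums(pres)
  w <- ifelse(rb > 0, tree$edge.length / rb, 0)
  as.vector(pres %*% w)
}

#' Comparison tree with equalized branch lengths
#'
#' Returns the same topology with every branch set to the mean branch
#' length, preserving total tree length. PD and PE on this tree isolate
#' the effect of tree shape from branch-length variation; their ratios to
#' the originals (RPD, RPE) are dimensionless and centred near 1.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A `phylo` with constant branch lengths.
#' @export
comparison_tree <- function(tree) {
  validate_tree(tree)
  out <- tree
  out$edge.length <- rep(sum(tree$edge.length) / length(tree$edge.length),
                         length(tree$edge.length))
  out
}

#' Relative phylogenetic diversity and endemism
#'
#' RPD = PD(original) / PD(comparison tree); RPE likewise for PE. Values
#' above 1 flag concentrations of longer-than-average (old) branches,
#' below 1 of short (young) branches. Empty cells are returned as `NA`.
#'
#' @inheritParams faith_pd
#' @return Data frame with columns `rpd`, `rpe`, one row per cell.
#' @export
relative_metrics <- function(cm, tree) {
  comp <- comparison_tree(tree)
  num_pd <- faith_pd(cm, tree)
  den_pd <- faith_pd(cm, comp)
  num_pe <- phylogenetic_endemism(cm, tree)
  den_pe <- phylogenetic_endemism(cm, comp)
  rpd <- ifelse(den_pd > 0, num_pd / den_pd, NA_real_)
  rpe <- ifelse(den_pe > 0, num_pe / den_pe, NA_real_)
  if (any(den_pd == 0 & num_pd > 0)) {
    warning("zero comparison-tree PD with nonzero PD; cells flagged NA")
  }
  data.frame(rpd = rpd, rpe = rpe)
}

#' Time-integrated lineage diversity per grid cell
#'
#' For each cell, the lineage-through-time curve N(t) of the subtree
#' spanning the cell's species is integrated on a log scale from the
#' subtree's own root (the MRCA of the resident species, at age T) to the
#' present: TILD = sum over inter-node intervals of ln(N) x duration.
#' N(t) is piecewise constant, so the integral is an exact finite sum.
#' Cells with zero or one species score 0 (ln 1 = 0); two species
#' diverging at age T score T ln 2. Requires an ultrametric tree, since
#' lineage counts through time are only well defined when tips are
#' contemporaneous.
#'
#' @inheritParams faith_pd
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Numeric vector over cells, in time x log-lineage units.
#' @export
tild <- function(cm, tree, tol = 1e-8) {
  validate_tree(tree)
  if (!ape::is.ultrametric(tree, tol = tol)) {
    stop("TILD requires an ultrametric tree (contemporaneous tips)",
         call. = FALSE)
  }
  m <- as_occupancy(cm)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing)) {
    stop("species missing from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nt <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(nt)]) - depth  # node ages, tips ~ 0
  age[abs(age) < 1e-12 * max(depth)] <- 0 # snap contemporaneous tips to 0
  parent_age <- age[tree$edge[, 1L]]
  child_age <- age[tree$edge[, 2L]]
  inc <- edge_tip_incidence(tree)
  tip_idx <- match(colnames(m), tree$tip.label)
  root_age <- max(age)
  vapply(seq_len(nrow(m)), function(i) {
    tips <- tip_idx[m[i, ] == 1L]
    if (length(tips) < 2) return(0)
    cnt <- rowSums(inc[, tips, drop = FALSE])
    on_path <- cnt > 0                  # edges with a resident descendant
    full <- cnt == length(tips)         # edges subtending the MRCA or above
    mrca_age <- if (any(full)) min(child_age[full]) else root_age
    keep <- on_path & parent_age <= mrca_age * (1 + 1e-12)
    ev <- sort(unique(c(0, child_age[keep], mrca_age)))
    tild_i <- 0
    for (k in seq_len(length(ev) - 1L)) {
      dt <- ev[k + 1L] - ev[k]
      if (dt < 1e-12 * mrca_age) next
      mid <- (ev[k] + ev[k + 1L]) / 2
      n_lin <- sum(child_age[keep] <= mid & parent_age[keep] > mid)
      tild_i <- tild_i + log(n_lin) * dt
    }
    tild_i
  }, numeric(1))
}

#' Full per-cell metric table
#'
#' Computes SR, WE, PD, PE, RPD, RPE and TILD for every grid cell in one
#' pass, the per-cell summary used by the null-model and regression
#' stages.
#'
#' @inheritParams faith_pd
#' @return Data frame keyed by `cell_id` with centre coordinates and the
#'   seven metrics (ratios `NA` in empty cells).
#' @export
diversity_metrics <- function(cm, tree) {
  stopifnot(inherits(cm, "community_matrix"))
  cc <- cell_centers(cm$grid)
  rel <- relative_metrics(cm, tree)
  data.frame(
    cell_id = cc$cell_id, x = cc$x, y = cc$y,
    sr = species_richness(cm),
    we = weighted_endemism(cm),
    pd = faith_pd(cm, tree),
    pe = phylogenetic_endemism(cm, tree),
    rpd = rel$rpd, rpe = rel$rpe,
    tild = tild(cm, tree)
  )
}
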