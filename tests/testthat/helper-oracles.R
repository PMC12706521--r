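# Independent oracles and fixture builders used across the suite. All of
# these deliberately avoid the package's own internals (edge incidence,
# clipping, chains) so each check is a genuine dual-route comparison.

# A random Yule tree plus a random binary community on its tips.
random_instance <- function(n_tip = 10, n_cells = 6, p = 0.4, seed = 1) {
  tree <- simulate_phylogeny(n_tip, 1, seed = seed)
  set.seed(seed + 10000)
  m <- matrix(rbinom(n_cells * n_tip, 1, p), n_cells, n_tip,
              dimnames = list(NULL, tree$tip.label))
  list(tree = tree, m = m)
}

# Star phylogeny with unit branch lengths: PD reduces to SR, PE to WE.
star_tree <- function(n) {
  tree <- ape::stree(n, type = "star")
  tree$tip.label <- paste0("s", seq_len(n))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# PD oracle: exhaustively test every branch for descendant intersection,
# with descendant tip sets taken from phangorn rather than the package.
oracle_pd <- function(tree, present) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  hit <- vapply(desc, function(d) any(tree$tip.label[d] %in% present),
                logical(1))
  sum(tree$edge.length[hit])
}

# PE oracle: per branch, find the cells holding any descendant and share
# the branch length equally among them.
oracle_pe <- function(tree, m) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  pe <- numeric(nrow(m))
  for (e in seq_along(desc)) {
    sp <- tree$tip.label[desc[[e]]]
    cells <- which(rowSums(m[, sp, drop = FALSE]) > 0)
    if (length(cells)) pe[cells] <- pe[cells] + tree$edge.length[e] / length(cells)
  }
  pe
}

# TILD oracle: prune to the cell's tips (ape roots the pruned tree at
# their MRCA), then integrate the step function exactly from the
# branching times: N = k + 1 lineages between the k-th and (k+1)-th
# deepest branching events.
oracle_tild <- function(tree, present) {
  if (length(present) < 2) return(0)
  sub <- ape::keep.tip(tree, present)
  bt <- sort(ape::branching.times(sub), decreasing = TRUE)
  bounds <- c(unname(bt), 0)
  sum(log(seq_along(bt) + 1) * (bounds[-length(bounds)] - bounds[-1]))
}

# Direct pairwise NODF: for each unordered pair, the less-filled member
# must be strictly less filled (equal totals contribute 0); its overlap
# with the fuller member, as a percentage of its own fill, is the paired
# score. Order-invariant by construction.
oracle_nodf <- function(m) {
  paired <- function(mat) {
    tot <- rowSums(mat)
    n <- nrow(mat)
    vals <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        lo <- if (tot[i] >= tot[j]) j else i
        hi <- if (tot[i] >= tot[j]) i else j
        vals <- c(vals,
                  if (tot[hi] > tot[lo] && tot[lo] > 0) {
                    100 * sum(mat[hi, ] & mat[lo, ]) / tot[lo]
                  } else 0)
      }
    }
    vals
  }
  mean(c(paired(m), paired(t(m))))
}

# Taxonomic Sorensen similarity and Simpson turnover from species counts.
oracle_sorensen <- function(x, y) {
  a <- sum(x & y)
  2 * a / (2 * a + sum(x & !y) + sum(!x & y))
}
oracle_simpson <- function(x, y) {
  b <- sum(x & !y); c <- sum(!x & y)
  min(b, c) / (sum(x & y) + min(b, c))
}

# All binary matrices with the same row and column sums as m0, found by
# exhaustive enumeration (tiny matrices only).
enumerate_marginal_class <- function(m0) {
  n <- length(m0)
  keys <- character(0)
  out <- list()
  for (bits in 0:(2^n - 1)) {
    m <- matrix(as.integer(intToBits(bits)[1:n]), nrow(m0), ncol(m0))
    if (all(rowSums(m) == rowSums(m0)) && all(colSums(m) == colSums(m0))) {
      out[[length(out) + 1]] <- m
      keys <- c(keys, paste(m, collapse = ""))
    }
  }
  list(matrices = out, keys = keys)
}

matrix_key <- function(m) paste(m, collapse = "")

# Convex-polygon / rectangle intersection area by clipping the RECTANGLE
# against each polygon edge half-plane (independent of the package's
# Sutherland-Hodgman ring clipper).
oracle_convex_clip_area <- function(poly, xmin, xmax, ymin, ymax) {
  pts <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  n <- nrow(poly)
  # assume counter-clockwise polygon; inside = left of each directed edge
  if (sum((poly[c(2:n, 1), 1] - poly[, 1]) * (poly[c(2:n, 1), 2] + poly[, 2])) > 0) {
    poly <- poly[n:1, , drop = FALSE]  # was clockwise; flip
  }
  for (e in seq_len(n)) {
    p1 <- poly[e, ]; p2 <- poly[if (e == n) 1 else e + 1, ]
    if (nrow(pts) == 0) break
    side <- (p2[1] - p1[1]) * (pts[, 2] - p1[2]) -
      (p2[2] - p1[2]) * (pts[, 1] - p1[1])
    keep <- side >= 0
    new_pts <- matrix(numeric(0), 0, 2)
    np <- nrow(pts)
    for (i in seq_len(np)) {
      j <- if (i == np) 1 else i + 1
      if (keep[i]) new_pts <- rbind(new_pts, pts[i, ])
      if (keep[i] != keep[j]) {
        t <- side[i] / (side[i] - side[j])
        new_pts <- rbind(new_pts, pts[i, ] + t * (pts[j, ] - pts[i, ]))
      }
    }
    pts <- new_pts
  }
  if (nrow(pts) < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(seq_len(nrow(pts))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Regular n-gon approximating a disk.
disk_polygon <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Two-block beta-diversity fixture: cells 1..b use species pool A, cells
# b+1..2b pool B, each cell a random subset of its pool.
two_block_cm <- function(n_per_block = 8, pool_size = 12, seed = 1) {
  set.seed(seed)
  S <- 2 * pool_size
  tree <- simulate_phylogeny(S, 1, seed = seed)
  sp <- tree$tip.label
  m <- matrix(0L, 2 * n_per_block, S, dimnames = list(NULL, sp))
  for (i in seq_len(n_per_block)) {
    m[i, sample(seq_len(pool_size), pool_size - 2)] <- 1L
    m[n_per_block + i, pool_size + sample(seq_len(pool_size), pool_size - 2)] <- 1L
  }
  list(tree = tree, m = m, block = rep(1:2, each = n_per_block))
}
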