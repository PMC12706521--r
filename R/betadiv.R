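# Shared/total spanning-branch lengths between all cell pairs. Returns
# shared (cells x cells) and the per-cell totals; A = shared_ij,
# B = total_i - shared_ij, C = total_j - shared_ij.
branch_length_overlap <- function(cm, tree) {
  validate_tree(tree)
  pres <- branch_presence(cm, tree) * 1   # cells x edges, numeric
  L <- tree$edge.length
  shared <- pres %*% (t(pres) * L)        # sum_e L_e P_ie P_je
  total <- as.vector(pres %*% L)
  list(shared = shared, total = total)
}

#' PhyloSor similarity between grid cells
#'
#' Sorensen-type similarity on branch lengths: with A the summed length
#' of branches in both cells' rooted spanning subtrees and B, C the
#' lengths exclusive to each, PhyloSor = 2A / (2A + B + C). Identical
#' communities score 1; communities whose subtrees share no branches
#' score 0. On a star tree with unit branches it reduces to the
#' taxonomic Sorensen index on species counts. Pairs involving an empty
#' cell are undefined (`NA`).
#'
#' @inheritParams faith_pd
#' @return Symmetric cells x cells similarity matrix, diagonal 1.
#' @export
phylosor <- function(cm, tree) {
  ov <- branch_length_overlap(cm, tree)
  tot <- outer(ov$total, ov$total, "+")
  sim <- ifelse(tot > 0, 2 * ov$shared / tot, NA_real_)
  empty <- ov$total == 0
  sim[empty, ] <- NA_real_
  sim[, empty] <- NA_real_
  diag(sim)[!empty] <- 1
  sim
}

#' Phylogenetic beta diversity with turnover/nestedness decomposition
#'
#' Baselga's decomposition applied to spanning-branch lengths: total
#' dissimilarity beta_sor = (B + C) / (2A + B + C) (= 1 - PhyloSor), its
#' turnover component beta_sim = min(B, C) / (A + min(B, C))
#' (Simpson-type, insensitive to richness differences), and the
#' nestedness-resultant remainder beta_sne = beta_sor - beta_sim. When
#' one cell's subtree contains the other's, min(B, C) = 0 and all
#' dissimilarity is nestedness.
#'
#' @inheritParams faith_pd
#' @return List of three symmetric matrices: `turnover`, `nestedness`,
#'   `total`.
#' @export
phylo_beta_pair <- function(cm, tree) {
  ov <- branch_length_overlap(cm, tree)
  A <- ov$shared
  B <- pmax(outer(ov$total, rep(1, length(ov$total))) - A, 0)  # exclusive to i
  C <- t(B)
  mn <- pmin(B, C)
  tot2 <- 2 * A + B + C
  b_sor <- ifelse(tot2 > 0, (B + C) / tot2, NA_real_)
  b_sim <- ifelse(A + mn > 0, mn / (A + mn), NA_real_)
  empty <- ov$total == 0
  mask <- function(x) { x[empty, ] <- NA_real_; x[, empty] <- NA_real_; x }
  b_sor <- mask(b_sor); b_sim <- mask(b_sim)
  b_sne <- b_sor - b_sim
  list(turnover = b_sim, nestedness = b_sne, total = b_sor)
}

#' K-means regionalization of a dissimilarity matrix
#'
#' Clusters grid cells by running Lloyd's K-means on the rows of the
#' pairwise dissimilarity matrix treated as feature vectors (each cell is
#' described by its dissimilarity profile to every other cell). Rows with
#' missing values (pairs involving empty cells) are excluded and
#' reported. The best of `n_starts` random restarts by within-cluster
#' sum of squares (WSS) is returned.
#'
#' @param dm Symmetric dissimilarity matrix (e.g. a [phylo_beta_pair()]
#'   component).
#' @param K Number of clusters (1 <= K <= number of usable cells).
#' @param n_starts Random restarts.
#' @param seed Optional integer seed.
#' @return List with `cluster` (labels over all cells, `NA` where
#'   excluded), `wss` (total within-cluster sum of squares), `excluded`
#'   (indices of dropped cells).
#' @export
kmeans_regions <- function(dm, K, n_starts = 25, seed = NULL) {
  dm <- as.matrix(dm)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  usable <- which(!apply(is.na(dm), 1, all))
  X <- dm[usable, usable, drop = FALSE]
  if (anyNA(X)) stop("dissimilarity matrix has NA among non-empty cells",
                     call. = FALSE)
  if (K > nrow(X)) stop("K exceeds the number of usable cells", call. = FALSE)
  with_seed(seed, {
    if (K == nrow(X)) {
      cl <- seq_len(nrow(X)); wss <- 0
    } else {
      # manual restarts: Lloyd can abandon a start when a cluster empties,
      # so keep the best start that converges rather than failing outright
      best <- NULL
      for (st in seq_len(n_starts)) {
        fit <- tryCatch(
          suppressWarnings(kmeans(X, centers = K, nstart = 1,
                                  algorithm = "Lloyd", iter.max = 200)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
          best <- fit
        }
      }
      if (is.null(best)) {
        stop("k-means failed for every restart (K too large for the data?)",
             call. = FALSE)
      }
      cl <- best$cluster; wss <- best$tot.withinss
    }
    cluster <- rep(NA_integer_, nrow(dm))
    cluster[usable] <- cl
    list(cluster = cluster, wss = wss,
         excluded = setdiff(seq_len(nrow(dm)), usable))
  })
}

#' Elbow selection of the number of clusters
#'
#' Given WSS values for consecutive K, picks the K where the decrease in
#' WSS most sharply diminishes: the argmax of the discrete second
#' difference WSS(K-1) - 2 WSS(K) + WSS(K+1), with ties broken toward
#' smaller K. The full curve is returned for visual inspection, since
#' the elbow is conventionally read off a plot.
#'
#' @param wss Numeric WSS values for consecutive K.
#' @param K Matching K values (defaults to `1:length(wss)`).
#' @return List with `K_opt` and a data frame `table` (K, wss,
#'   second_diff where defined).
#' @export
elbow <- function(wss, K = seq_along(wss)) {
  if (length(wss) < 3) stop("need WSS for at least 3 consecutive K", call. = FALSE)
  if (length(K) != length(wss) || any(diff(K) != 1)) {
    stop("K must be consecutive and match wss", call. = FALSE)
  }
  d2 <- c(NA, diff(diff(wss)), NA)  # wss[k-1] - 2 wss[k] + wss[k+1]
  interior <- which(!is.na(d2))
  K_opt <- K[interior[which.max(d2[interior])]]
  list(K_opt = K_opt, table = data.frame(K = K, wss = wss, second_diff = d2))
}

#' Sweep K-means over K and pick the elbow
#'
#' Convenience wrapper: runs [kmeans_regions()] for `K = 1:K_max`,
#' collects the WSS curve, and applies [elbow()].
#'
#' @inheritParams kmeans_regions
#' @param K_max Largest K to try.
#' @return List with `K_opt`, `wss` (per K), and `cluster` labels at the
#'   chosen K.
#' @export
regionalize <- function(dm, K_max = 10, n_starts = 25, seed = NULL) {
  fits <- lapply(seq_len(K_max), function(k) kmeans_regions(dm, k, n_starts, seed))
  wss <- vapply(fits, `[[`, numeric(1), "wss")
  eb <- elbow(wss, seq_len(K_max))
  list(K_opt = eb$K_opt, wss = wss, table = eb$table,
       cluster = fits[[eb$K_opt]]$cluster)
}
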