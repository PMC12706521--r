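# Does the matrix contain at least one 2x2 checkerboard (a pair of rows
# and columns with pattern 10/01 or 01/10)? Cheap row-pair scan.
has_checkerboard <- function(m) {
  nr <- nrow(m)
  if (nr < 2 || ncol(m) < 2) return(FALSE)
  for (i in seq_len(nr - 1L)) {
    for (j in seq.int(i + 1L, nr)) {
      d <- m[i, ] - m[j, ]
      if (any(d > 0) && any(d < 0)) return(TRUE)
    }
  }
  FALSE
}

#' Swap randomization of a binary community matrix
#'
#' The classic fixed-fixed null model: random 2x2 submatrices are sampled
#' uniformly and, whenever they form a checkerboard (10/01), their
#' entries are swapped. Row sums (cell richness) and column sums (species
#' range sizes) are preserved exactly. `n_itr` counts *successful* swaps;
#' candidate submatrices that are not checkerboards are skipped without
#' counting. Mixing depends on this convention, so it is part of the
#' contract.
#'
#' @param cm A `community_matrix` or bare binary matrix.
#' @param n_itr Number of successful swaps to apply.
#' @param seed Optional integer seed (the global RNG state is restored).
#' @return A randomized object of the same type as `cm`.
#' @export
randomize_swap <- function(cm, n_itr, seed = NULL) {
  m <- as_occupancy(cm)
  stopifnot(n_itr >= 0)
  if (!has_checkerboard(m)) {
    warning("matrix has no 2x2 checkerboard; returning the input unchanged")
    return(rewrap_occupancy(cm, m))
  }
  with_seed(seed, {
    out <- swap_chain_cpp(m, as.integer(n_itr))
    dimnames(out) <- dimnames(m)
    rewrap_occupancy(cm, out)
  })
}

#' Curveball randomization of a binary community matrix
#'
#' Each iteration draws two distinct rows, finds the species unique to
#' each, and redistributes that exclusive pool at random between the two
#' rows, keeping each row's count (a "trade"). Row and column sums are
#' preserved; trades between rows with nested or identical species sets
#' are no-ops but still count as iterations.
#'
#' @inheritParams randomize_swap
#' @param n_itr Number of trade iterations.
#' @export
randomize_curveball <- function(cm, n_itr, seed = NULL) {
  m <- as_occupancy(cm)
  stopifnot(n_itr >= 0)
  if (nrow(m) < 2) return(rewrap_occupancy(cm, m))
  with_seed(seed, {
    out <- curveball_chain_cpp(m, as.integer(n_itr))
    dimnames(out) <- dimnames(m)
    rewrap_occupancy(cm, out)
  })
}

#' r0 randomization (fixed rows, equiprobable columns)
#'
#' Every row is independently replaced by a uniformly random species
#' subset of the same size: cell richness is preserved, species range
#' sizes are free and equiprobable.
#'
#' @inheritParams randomize_swap
#' @export
randomize_r0 <- function(cm, seed = NULL) {
  m <- as_occupancy(cm)
  with_seed(seed, {
    S <- ncol(m)
    out <- matrix(0L, nrow(m), S, dimnames = dimnames(m))
    k <- rowSums(m)
    for (i in seq_len(nrow(m))) {
      if (k[i] > 0L) out[i, sample.int(S, k[i])] <- 1L
    }
    rewrap_occupancy(cm, out)
  })
}

#' Randomization convergence diagnostic
#'
#' For each iteration count in `n_itr_grid`, runs `n_chains` independent
#' randomizations of the original matrix and records the mean proportion
#' of entries identical to the original. As chains mix this similarity
#' decays to a plateau; the smallest grid value whose similarity is
#' within `tol` of the final grid value is reported as the suggested
#' iteration count. This mirrors the usual practice of choosing `n_itr`
#' by eye from such a curve before committing to an expensive null run.
#'
#' @inheritParams randomize_swap
#' @param algorithm `"swap"` or `"curveball"`.
#' @param n_itr_grid Increasing vector of iteration counts to probe.
#' @param n_chains Chains per grid point.
#' @param tol Plateau tolerance on the similarity scale.
#' @return Data frame (`n_itr`, `similarity`) with the plateau point in
#'   attribute `n_itr_converged`.
#' @export
convergence_diagnostic <- function(cm, algorithm = c("swap", "curveball"),
                                   n_itr_grid, n_chains = 10, seed = NULL,
                                   tol = 0.01) {
  algorithm <- match.arg(algorithm)
  m <- as_occupancy(cm)
  rand <- switch(algorithm, swap = randomize_swap, curveball = randomize_curveball)
  with_seed(seed, {
    sim <- vapply(n_itr_grid, function(ni) {
      mean(vapply(seq_len(n_chains), function(ch) {
        mean(suppressWarnings(as_occupancy(rand(m, ni))) == m)
      }, numeric(1)))
    }, numeric(1))
    out <- data.frame(n_itr = n_itr_grid, similarity = sim)
    final <- sim[length(sim)]
    attr(out, "n_itr_converged") <- n_itr_grid[which(sim <= final + tol)[1L]]
    out
  })
}

# Per-cell metric block used inside the null loop: PD and PE on the
# original branch lengths L and on the comparison lengths Lc, plus the
# two ratios. `tDnum` is t(edge-by-species incidence) restricted to the
# community's species, precomputed once.
null_metric_block <- function(m, tDnum, L, Lc) {
  pres <- (m %*% tDnum) > 0
  rb <- colSums(pres)
  pos <- rb > 0
  wnum <- numeric(length(L)); wden <- wnum
  wnum[pos] <- L[pos] / rb[pos]
  wden[pos] <- Lc[pos] / rb[pos]
  pd <- as.vector(pres %*% L)
  pdc <- as.vector(pres %*% Lc)
  pe_num <- as.vector(pres %*% wnum)
  pe_den <- as.vector(pres %*% wden)
  cbind(pd = pd,
        rpd = ifelse(pdc > 0, pd / pdc, NA_real_),
        pe_num = pe_num,
        pe_den = pe_den,
        rpe = ifelse(pe_den > 0, pe_num / pe_den, NA_real_))
}

#' Null-model test of phylogenetic diversity and endemism
#'
#' Randomizes the observed matrix `n_reps` times (each replicate restarts
#' from the observed matrix, giving independent draws rather than a
#' thinned chain), recomputes PD, RPD, PE on the original tree
#' (the RPE numerator), PE on the equal-branch comparison tree (the
#' denominator) and their ratio RPE for every cell, and accumulates
#' two-sided tail counts. Monte-Carlo p-values use the standard +1 rank
#' correction: upper p = (1 + #\{null >= obs\}) / (n_reps + 1), so p is
#' never exactly zero.
#'
#' @inheritParams randomize_swap
#' @param tree Rooted `phylo` covering all community species.
#' @param algorithm `"swap"`, `"curveball"` or `"r0"`.
#' @param n_reps Number of null replicates (>= 1).
#' @param n_itr Iterations per replicate for swap/curveball.
#' @return A `null_result`: matrices (cells x metric) of observed values,
#'   null means/sds, tail counts and p-values, plus the run settings.
#' @export
null_test <- function(cm, tree, algorithm = c("swap", "curveball", "r0"),
                      n_reps, n_itr = 1000, seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_reps >= 1)
  n_itr <- as.integer(n_itr)
  validate_tree(tree)
  m <- as_occupancy(cm)
  comp <- comparison_tree(tree)
  inc <- edge_tip_incidence(tree)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing)) {
    stop("species missing from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tDnum <- t(inc[, colnames(m), drop = FALSE]) * 1  # species x edges
  L <- tree$edge.length
  Lc <- comp$edge.length
  obs <- null_metric_block(m, tDnum, L, Lc)
  nc <- nrow(obs)
  metrics <- colnames(obs)
  cnt_ge <- cnt_le <- matrix(0L, nc, length(metrics), dimnames = list(NULL, metrics))
  s1 <- s2 <- matrix(0, nc, length(metrics), dimnames = list(NULL, metrics))
  swap_ok <- TRUE
  if (algorithm == "swap" && !has_checkerboard(m)) {
    warning("matrix has no 2x2 checkerboard; swap null is degenerate")
    swap_ok <- FALSE
  }
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      mr <- switch(algorithm,
        swap = if (swap_ok) swap_chain_cpp(m, n_itr) else m,
        curveball = curveball_chain_cpp(m, n_itr),
        r0 = randomize_r0(m))
      val <- null_metric_block(mr, tDnum, L, Lc)
      ge <- !is.na(val) & !is.na(obs) & val >= obs
      le <- !is.na(val) & !is.na(obs) & val <= obs
      cnt_ge <- cnt_ge + ge
      cnt_le <- cnt_le + le
      v0 <- ifelse(is.na(val), 0, val)
      s1 <- s1 + v0
      s2 <- s2 + v0^2
    }
    null_mean <- s1 / n_reps
    null_sd <- sqrt(pmax(0, s2 / n_reps - null_mean^2))
    null_mean[is.na(obs)] <- NA_real_
    null_sd[is.na(obs)] <- NA_real_
    structure(
      list(observed = obs, null_mean = null_mean, null_sd = null_sd,
           count_ge = cnt_ge, count_le = cnt_le,
           p_upper = (1 + cnt_ge) / (n_reps + 1),
           p_lower = (1 + cnt_le) / (n_reps + 1),
           n_reps = n_reps, algorithm = algorithm,
           n_itr = if (algorithm == "r0") NA_integer_ else n_itr,
           seed = seed,
           empty_cell = rowSums(m) == 0L),
      class = "null_result"
    )
  })
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("null_result: %d cells, %d reps, algorithm '%s'\n",
              nrow(x$observed), x$n_reps, x$algorithm))
  invisible(x)
}

#' CANAPE classification of endemism centres
#'
#' Categorical Analysis of Neo- And Paleo-Endemism. A cell is a
#' *candidate* endemism centre when PE on the original tree (the RPE
#' numerator) or PE on the comparison tree (the denominator) is
#' significantly high under a one-tailed test at `alpha`. Candidates are
#' then split on the RPE ratio (two-tailed at `alpha`, i.e. `alpha/2`
#' per tail): significantly high RPE is *paleo* endemism (long
#' range-restricted branches), significantly low is *neo* (short
#' range-restricted branches), and candidates significant in both
#' numerator and denominator but not in the ratio are *mixed*. Mixed
#' cells whose numerator and denominator are both significant at
#' `alpha_super` are promoted to *super*. Everything else, and cells
#' empty in the observed matrix, is not significant. Significance means
#' p <= alpha on +1-corrected Monte-Carlo p-values.
#'
#' @param nr A [null_test()] result covering `pe_num`, `pe_den`, `rpe`.
#' @param alpha One-tailed level for the candidate and component tests.
#' @param alpha_super Stricter level for the super category.
#' @return Data frame with `cell_id` (0-based) and `category`, a factor
#'   with levels not_significant, neo, paleo, mixed, super (`NA` for
#'   empty cells); significance flags are included for audit.
#' @export
canape_classify <- function(nr, alpha = 0.05, alpha_super = 0.01) {
  stopifnot(inherits(nr, "null_result"))
  need <- c("pe_num", "pe_den", "rpe")
  if (!all(need %in% colnames(nr$p_upper))) {
    stop("null result lacks required metrics: ",
         paste(setdiff(need, colnames(nr$p_upper)), collapse = ", "),
         call. = FALSE)
  }
  num_hi <- nr$p_upper[, "pe_num"] <= alpha
  den_hi <- nr$p_upper[, "pe_den"] <= alpha
  cand <- num_hi | den_hi
  rpe_hi <- nr$p_upper[, "rpe"] <= alpha / 2
  rpe_lo <- nr$p_lower[, "rpe"] <= alpha / 2
  cat_lv <- c("not_significant", "neo", "paleo", "mixed", "super")
  category <- rep("not_significant", nrow(nr$observed))
  category[cand & rpe_hi] <- "paleo"
  category[cand & !rpe_hi & rpe_lo] <- "neo"
  mixed <- cand & !rpe_hi & !rpe_lo & num_hi & den_hi
  category[mixed] <- "mixed"
  super <- mixed & nr$p_upper[, "pe_num"] <= alpha_super &
    nr$p_upper[, "pe_den"] <= alpha_super
  category[super] <- "super"
  category[nr$empty_cell] <- NA_character_
  data.frame(
    cell_id = seq_len(nrow(nr$observed)) - 1L,
    category = factor(category, levels = cat_lv),
    num_hi = num_hi, den_hi = den_hi, rpe_hi = rpe_hi, rpe_lo = rpe_lo
  )
}
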