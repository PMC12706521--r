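test_that("swap performs the only possible move on a 2x2 checkerboard", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  out <- randomize_swap(m, 1, seed = 1)
  expect_identical(out, matrix(c(0L, 1L, 1L, 0L), 2, 2))
})

test_that("swap warns and returns input when no checkerboard exists", {
  nested <- matrix(c(1L, 1L, 1L, 0L), 2, 2)  # no checkerboard unit
  expect_warning(out <- randomize_swap(nested, 10, seed = 1), "checkerboard")
  expect_identical(out, nested)
})

test_that("randomizations preserve the required marginals", {
  set.seed(2)
  m <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30)
  sw <- randomize_swap(m, 5000, seed = 3)
  expect_identical(rowSums(sw), rowSums(m))
  expect_identical(colSums(sw), colSums(m))
  cb <- randomize_curveball(m, 5000, seed = 3)
  expect_identical(rowSums(cb), rowSums(m))
  expect_identical(colSums(cb), colSums(m))
  r0 <- randomize_r0(m, seed = 3)
  expect_identical(rowSums(r0), rowSums(m))
  # determinism under a fixed seed
  expect_identical(randomize_swap(m, 500, seed = 9),
                   randomize_swap(m, 500, seed = 9))
  expect_identical(randomize_curveball(m, 500, seed = 9),
                   randomize_curveball(m, 500, seed = 9))
})

test_that("r0 keeps degenerate rows fixed and spreads species equiprobably", {
  m <- rbind(rep(0L, 6), rep(1L, 6), c(1L, 1L, 0L, 0L, 0L, 0L))
  hits <- matrix(0, 1, 6)
  for (s in 1:2000) {
    out <- randomize_r0(m, seed = s)
    expect_identical(out[1, ], m[1, ])
    expect_identical(out[2, ], m[2, ])
    hits <- hits + out[3, ]
  }
  # each column occupied with probability k/S = 2/6
  p_hat <- hits / 2000
  se <- sqrt((2 / 6) * (4 / 6) / 2000)
  expect_true(all(abs(p_hat - 2 / 6) < 3.5 * se))
})

test_that("chains sample the fixed-marginal class according to their stationary law", {
  # Counting *successful* swaps makes the swap sampler the jump chain of
  # the uniform-proposal walk: its long-run law weights each reachable
  # matrix by its number of checkerboard units (uniform when those are
  # equal). Curveball iterations include no-op trades (self-loops), so
  # its long-run law is uniform on any class. Both laws are checked
  # against brute-force enumeration of the class.
  n_checkerboards <- function(m) {
    d <- 0
    for (i in seq_len(nrow(m) - 1)) for (j in seq.int(i + 1, nrow(m))) {
      for (a in seq_len(ncol(m) - 1)) for (b in seq.int(a + 1, ncol(m))) {
        s <- m[c(i, j), c(a, b)]
        if (s[1, 1] != s[1, 2] && s[1, 1] == s[2, 2] && s[1, 2] == s[2, 1]) {
          d <- d + 1
        }
      }
    }
    d
  }
  m0 <- matrix(c(1L, 0L, 1L,
                 0L, 1L, 0L,
                 1L, 1L, 0L), 3, 3, byrow = TRUE)
  class_ <- enumerate_marginal_class(m0)
  k <- length(class_$keys)
  expect_gt(k, 1)
  reps <- 3000

  deg <- vapply(class_$matrices, n_checkerboards, numeric(1))
  p_swap <- deg / sum(deg)
  seen <- vapply(seq_len(reps), function(s) {
    # mix odd/even swap counts so parity-structured classes are covered
    matrix_key(randomize_swap(m0, 60 + s %% 2, seed = 7000 + s))
  }, character(1))
  p_hat <- as.numeric(table(factor(seen, levels = class_$keys))) / reps
  se <- sqrt(p_swap * (1 - p_swap) / reps)
  expect_true(all(abs(p_hat - p_swap) < 3.5 * se))

  seen_cb <- vapply(seq_len(reps), function(s) {
    matrix_key(randomize_curveball(m0, 60, seed = 8000 + s))
  }, character(1))
  p_cb <- as.numeric(table(factor(seen_cb, levels = class_$keys))) / reps
  se_u <- sqrt((1 / k) * (1 - 1 / k) / reps)
  expect_true(all(abs(p_cb - 1 / k) < 3.5 * se_u))

  # on an equal-degree class (permutation matrices) the swap law is
  # uniform as well, once both parities of the swap count are drawn
  mp <- diag(3L)
  clp <- enumerate_marginal_class(mp)
  seen_p <- vapply(seq_len(reps), function(s) {
    matrix_key(randomize_swap(mp, 60 + s %% 2, seed = 9000 + s))
  }, character(1))
  p_p <- as.numeric(table(factor(seen_p, levels = clp$keys))) / reps
  kp <- length(clp$keys)
  se_p <- sqrt((1 / kp) * (1 - 1 / kp) / reps)
  expect_true(all(abs(p_p - 1 / kp) < 3.5 * se_p))
})

test_that("convergence diagnostic starts at 1, decays, and is deterministic", {
  set.seed(4)
  m <- matrix(rbinom(15 * 20, 1, 0.4), 15, 20)
  grid <- c(0, 5, 20, 80, 320, 1280)
  tab <- convergence_diagnostic(m, "swap", grid, n_chains = 20, seed = 5)
  expect_equal(tab$similarity[1], 1)
  expect_identical(tab,
                   convergence_diagnostic(m, "swap", grid, n_chains = 20, seed = 5))
  # non-increasing in expectation (slack for chain-to-chain noise at the
  # plateau; entries within a chain are correlated, so no iid SE applies)
  expect_true(all(diff(tab$similarity) < 0.02))
  expect_true(attr(tab, "n_itr_converged") <= grid[length(grid)])
})

test_that("null_test is degenerate without checkerboards and deterministic with seed", {
  nested <- matrix(c(1L, 1L, 1L, 0L), 2, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  tr <- star_tree(2)
  expect_warning(nr <- null_test(nested, tr, "swap", n_reps = 1, n_itr = 5,
                                 seed = 1), "checkerboard")
  expect_equal(unname(nr$p_upper[, "pd"]), c(1, 1))

  set.seed(6)
  m <- matrix(rbinom(48, 1, 0.5), 6, 8)
  tree <- simulate_phylogeny(8, 1, seed = 6)
  colnames(m) <- tree$tip.label
  a <- null_test(m, tree, "curveball", n_reps = 30, n_itr = 50, seed = 11)
  b <- null_test(m, tree, "curveball", n_reps = 30, n_itr = 50, seed = 11)
  expect_identical(a$count_ge, b$count_ge)
  expect_identical(a$p_lower, b$p_lower)
  expect_true(all(a$count_ge <= 30 & a$count_le <= 30))
  expect_true(all(a$null_sd >= 0, na.rm = TRUE))
})

test_that("r0 null mean of WE matches exhaustive enumeration", {
  # tiny matrix: rows of size 1 and 2 over 3 species; enumerate all
  # equiprobable subset combinations and average WE per cell
  m <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L))
  colnames(m) <- c("a", "b", "c")
  subsets1 <- utils::combn(3, 1, simplify = FALSE)
  subsets2 <- utils::combn(3, 2, simplify = FALSE)
  combos <- expand.grid(i = seq_along(subsets1), j = seq_along(subsets2))
  exact <- rowMeans(sapply(seq_len(nrow(combos)), function(k) {
    mm <- matrix(0L, 2, 3)
    mm[1, subsets1[[combos$i[k]]]] <- 1L
    mm[2, subsets2[[combos$j[k]]]] <- 1L
    weighted_endemism(mm)
  }))
  sims <- sapply(1:4000, function(s) weighted_endemism(randomize_r0(m, seed = s)))
  se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  expect_true(all(abs(rowMeans(sims) - exact) < 3.5 * se))
})

# Build a null_result by hand to exercise the classifier's decision table.
fake_null_result <- function(p_up, p_lo) {
  metrics <- c("pd", "rpd", "pe_num", "pe_den", "rpe")
  n <- nrow(p_up)
  obs <- matrix(1, n, length(metrics), dimnames = list(NULL, metrics))
  structure(list(observed = obs, null_mean = obs, null_sd = obs * 0,
                 count_ge = obs, count_le = obs,
                 p_upper = p_up, p_lower = p_lo,
                 n_reps = 999, algorithm = "swap", n_itr = 1000, seed = 1,
                 empty_cell = rep(FALSE, n)),
            class = "null_result")
}

test_that("CANAPE classification follows the decision rules", {
  metrics <- c("pd", "rpd", "pe_num", "pe_den", "rpe")
  up <- matrix(0.5, 7, 5, dimnames = list(NULL, metrics))
  lo <- matrix(0.5, 7, 5, dimnames = list(NULL, metrics))
  # cell 1: nothing significant -> not_significant
  # cell 2: candidate (num high), RPE high tail -> paleo
  up[2, "pe_num"] <- 0.01; up[2, "rpe"] <- 0.02
  # cell 3: candidate, RPE low tail -> neo
  up[3, "pe_den"] <- 0.03; lo[3, "rpe"] <- 0.01
  # cell 4: both components high at 0.05 but not 0.01, ratio neutral -> mixed
  up[4, "pe_num"] <- 0.03; up[4, "pe_den"] <- 0.04
  # cell 5: both components high at 0.01, ratio neutral -> super
  up[5, "pe_num"] <- 0.005; up[5, "pe_den"] <- 0.008
  # cell 6: RPE high but no candidate condition -> not_significant
  up[6, "rpe"] <- 0.001
  # cell 7: only one component high at 0.01, ratio neutral -> not mixed
  up[7, "pe_num"] <- 0.002
  nr <- fake_null_result(up, lo)
  cl <- canape_classify(nr)
  expect_equal(as.character(cl$category),
               c("not_significant", "paleo", "neo", "mixed", "super",
                 "not_significant", "not_significant"))
  # super implies the mixed condition holds at the stricter level
  expect_true(all(nr$p_upper[cl$category == "super", c("pe_num", "pe_den")] <= 0.01))
  expect_error(canape_classify(structure(list(p_upper = up[, 1:2]),
                                         class = "null_result")))
})

test_that("CANAPE categories are invariant to branch-length rescaling", {
  spec <- scenario_spec(6, 6, 25, n_species = 30, range_mean = 8,
                        hotspot_rows = c(1, 2), hotspot_cols = c(1, 2),
                        hotspot_type = "paleo", hotspot_range_mean = 3,
                        seed = 17)
  sc <- simulate_scenario(spec)
  tr2 <- sc$tree
  tr2$edge.length <- tr2$edge.length * 7.3
  a <- canape_classify(null_test(sc$cm, sc$tree, "curveball", n_reps = 99,
                                 n_itr = 300, seed = 8))
  b <- canape_classify(null_test(sc$cm, tr2, "curveball", n_reps = 99,
                                 n_itr = 300, seed = 8))
  expect_identical(a$category, b$category)
})
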