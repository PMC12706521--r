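test_that("predictor screening retains orthogonal sets and drops duplicates", {
  set.seed(1)
  X <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  sc <- screen_predictors(X, 0.5)
  expect_setequal(sc$kept, c("a", "b", "c"))
  X$dup <- X$a + rnorm(100, sd = 1e-6)
  sc2 <- screen_predictors(X, 0.5)
  expect_length(intersect(c("a", "dup"), sc2$kept), 1L)
  expect_warning(screen_predictors(cbind(X, z = 1), 0.5), "zero-variance")
})

test_that("greedy screening resolves a correlated hub as enumerated by hand", {
  # x1 and x2 strongly correlated, x3 independent: the member of the pair
  # with the larger mean |r| goes first, leaving the other two
  set.seed(2)
  n <- 500
  x1 <- rnorm(n)
  x2 <- x1 * 0.95 + rnorm(n, sd = sqrt(1 - 0.95^2))
  x3 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  r <- abs(cor(X)); diag(r) <- 0
  expected_drop <- colnames(X)[which.max(rowMeans(r))]
  sc <- screen_predictors(X, 0.5)
  expect_equal(sc$dropped, expected_drop)
  expect_setequal(sc$kept, setdiff(colnames(X), expected_drop))
  expect_true(max(abs(sc$correlation[sc$kept, sc$kept] -
                        diag(length(sc$kept)))) < 0.5)
})

test_that("distance-band weights give rook neighbours and proper standardization", {
  g <- grid_spec(3, 3, 10)
  cc <- cell_centers(g)
  W <- build_weights(cc[, c("x", "y")], 10.5)
  A <- (W$W > 0) * 1
  # centre cell (id 4, 1-based 5) has exactly its 4 rook neighbours
  expect_equal(sum(A[5, ]), 4)
  expect_equal(unname(which(A[5, ] > 0)), c(2, 4, 6, 8))
  expect_equal(unname(rowSums(W$W)), rep(1, 9))
  expect_equal(unname(diag(W$W)), rep(0, 9))
  # binary style and complete graph beyond the diameter
  Wb <- build_weights(cc[, c("x", "y")], 1000, style = "B")
  expect_equal(unname(rowSums(Wb$W)), rep(8, 9))
  expect_error(build_weights(cc[1:4, c("x", "y")], 1e-6), "isolated")
})

test_that("Moran's I matches a hand-computed 3-point example", {
  x <- c(1, 4, 2)
  w <- matrix(c(0, 1, 0,
                1, 0, 1,
                0, 1, 0), 3, 3, byrow = TRUE)
  z <- x - mean(x)
  I_hand <- (3 / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
  mi <- morans_i(x, w)
  expect_equal(mi$I, I_hand, tolerance = 1e-12)
  expect_equal(mi$expected, -0.5)
  expect_gt(mi$variance, 0)
  expect_error(morans_i(rep(2, 3), w), "constant")
})

test_that("Moran's I is affine invariant and calibrated under the iid null", {
  g <- grid_spec(5, 5, 25)
  W <- build_weights(cell_centers(g)[, c("x", "y")], 26)
  set.seed(10)
  x <- rnorm(25)
  expect_equal(morans_i(3 * x - 7, W)$I, morans_i(x, W)$I, tolerance = 1e-12)
  I <- vapply(1:300, function(s) {
    set.seed(1000 + s)
    morans_i(rnorm(25), W)$I
  }, numeric(1))
  expect_lt(abs(mean(I) - (-1 / 24)), 3 * sd(I) / sqrt(300))
})

test_that("correlograms flag short-range structure and stay calibrated on noise", {
  g <- grid_spec(12, 12, 25)
  cc <- cell_centers(g)
  W <- build_weights(cc[, c("x", "y")], 26)
  X <- cbind(1, scale(cc$x))
  # SAR data: first distance class significantly positive
  hits <- vapply(1:20, function(s) {
    y <- simulate_sar_response(X, W, c(0, 0), lambda = 0.7, sigma = 1,
                               seed = 600 + s)
    tab <- correlogram(y, cc[, c("x", "y")], n_classes = 6)
    first <- which(tab$n_pairs > 0)[1]
    tab$I[first] > 0 && tab$p[first] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # iid data: roughly 5% of classes significant
  set.seed(5)
  sig <- unlist(lapply(1:30, function(s) {
    tab <- correlogram(rnorm(nrow(cc)), cc[, c("x", "y")], n_classes = 6)
    tab$p < 0.05
  }))
  p_hat <- mean(sig, na.rm = TRUE)
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!is.na(sig))))
  # determinism: same data, same table
  y <- rnorm(nrow(cc))
  expect_identical(correlogram(y, cc[, c("x", "y")], 6),
                   correlogram(y, cc[, c("x", "y")], 6))
})

test_that("OLS recovers exact fits and matches the normal equations", {
  set.seed(3)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("p1", "p2")))
  beta <- c(2, -1, 0.5)
  y <- cbind(1, X) %*% beta
  fit <- fit_ols(as.vector(y), X)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  # intercept-only
  y2 <- rnorm(40)
  f0 <- fit_ols(y2, NULL)
  expect_equal(unname(f0$coefficients[1]), mean(y2), tolerance = 1e-12)
  # normal-equations oracle on a noisy instance
  yn <- as.vector(y) + rnorm(40)
  fn <- fit_ols(yn, X)
  Xd <- cbind(1, X)
  expect_equal(unname(fn$coefficients),
               as.vector(solve(crossprod(Xd), crossprod(Xd, yn))),
               tolerance = 1e-10)
  expect_error(fit_ols(yn, cbind(X, p1b = X[, 1])), "collinear")
})

test_that("SAR reduces to OLS at lambda = 0 and the two log-det routes agree", {
  g <- grid_spec(7, 7, 25)
  cc <- cell_centers(g)
  W <- build_weights(cc[, c("x", "y")], 26)
  set.seed(4)
  X <- matrix(rnorm(98), 49, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(49)
  ols <- fit_ols(y, X)
  for (model in c("error", "lag")) {
    red <- fit_sar(y, X, W, model, lambda_fixed = 0)
    expect_equal(red$coefficients, ols$coefficients, tolerance = 1e-8)
    expect_equal(red$loglik, ols$loglik, tolerance = 1e-8)
  }
  # eigenvalue log-determinant vs direct dense determinant
  ev <- Re(eigen(W$W, only.values = TRUE)$values)
  for (lambda in c(-0.4, 0.2, 0.7)) {
    direct <- determinant(diag(49) - lambda * W$W, logarithm = TRUE)$modulus
    expect_equal(sum(log(1 - lambda * ev)), as.numeric(direct),
                 tolerance = 1e-8)
  }
})

test_that("SAR-error likelihood at the optimum dominates lambda = 0 on SAR data", {
  g <- grid_spec(10, 10, 25)
  cc <- cell_centers(g)
  W <- build_weights(cc[, c("x", "y")], 26)
  X <- cbind(1, scale(cc$x))
  for (s in 1:5) {
    y <- simulate_sar_response(X, W, c(1, 0.4), lambda = 0.6, sigma = 1,
                               seed = 700 + s)
    fit <- fit_sar(y, X[, -1, drop = FALSE], W, "error")
    at0 <- fit_sar(y, X[, -1, drop = FALSE], W, "error", lambda_fixed = 0)
    expect_gte(fit$loglik, at0$loglik)
  }
})

test_that("model selection ranks by AIC with parameter tie-breaks", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30)
  f1 <- fit_ols(y, X)
  f2 <- fit_ols(y, X)
  tab <- model_select(list(f1, f2))
  expect_equal(tab$delta_aic, c(0, 0))
  g <- grid_spec(5, 6, 25)
  W <- build_weights(cell_centers(g)[, c("x", "y")], 26)
  f3 <- fit_sar(y, X, W, "error")
  tab2 <- model_select(list(f3, f1))
  expect_equal(tab2$aic, sort(tab2$aic))
  expect_error(model_select(list(f1, fit_ols(rev(y), X))), "same response")
  expect_error(model_select(list(f1)), "at least 2")
})

test_that("structural sign recovery: wetter, rugged, climatically stable cells richer", {
  g <- grid_spec(10, 10, 25)
  cc <- cell_centers(g)
  W <- build_weights(cc[, c("x", "y")], 26)
  set.seed(9)
  precip <- as.vector(scale(cc$y + rnorm(100, sd = 30)))
  rugged <- rnorm(100)
  vel <- rnorm(100)
  X <- cbind(precip = precip, rugged = rugged, velocity = vel)
  ok <- vapply(1:20, function(s) {
    y <- simulate_sar_response(cbind(1, X), W, c(5, 0.8, 0.5, -0.6),
                               lambda = 0.5, sigma = 0.5, seed = 800 + s)
    fit <- fit_sar(y, X, W, "error")
    b <- fit$coefficients
    b["precip"] > 0 && b["rugged"] > 0 && b["velocity"] < 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
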