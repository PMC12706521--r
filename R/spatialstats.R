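#' Screen predictors for collinearity
#'
#' Pairwise Pearson correlations are computed and predictors are removed
#' greedily: while any pair has |r| >= `threshold`, the predictor with
#' the largest mean absolute correlation against the remaining set is
#' dropped. Zero-variance predictors are dropped up front with a
#' warning. The retained set has all pairwise |r| below the threshold.
#'
#' @param table Data frame or matrix of candidate predictors (complete
#'   cases).
#' @param threshold Absolute-correlation cutoff (default 0.5).
#' @return List with `kept`, `dropped` (names in drop order), and the
#'   full `correlation` matrix.
#' @export
screen_predictors <- function(table, threshold = 0.5) {
  X <- as.matrix(table)
  if (ncol(X) < 2) stop("need at least 2 predictors", call. = FALSE)
  if (!all(complete.cases(X))) stop("predictors must be complete cases", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  dropped <- character(0)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictors: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    dropped <- colnames(X)[sds == 0]
    X <- X[, sds > 0, drop = FALSE]
  }
  full_cor <- cor(X)
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    r <- abs(cor(X[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) < threshold) break
    worst <- keep[which.max(rowMeans(r))]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(kept = keep, dropped = dropped, correlation = full_cor)
}

#' Distance-band spatial weights
#'
#' Neighbours are all pairs of cells with 0 < distance <= `d_max`
#' (`dnearneigh`-style). Weights are binary or row-standardized (each
#' neighbour weighted 1/degree, the standard "W" coding); rows without
#' neighbours (islands) are all-zero and reported.
#'
#' @param coords Two-column matrix/data frame of cell coordinates (km).
#' @param d_max Neighbour distance cutoff (> 0).
#' @param style `"W"` (row-standardized, default) or `"B"` (binary).
#' @return A `spatial_weights` object: `W` (dense matrix), `coords`,
#'   `style`, `d_max`, `islands` (indices).
#' @export
build_weights <- function(coords, d_max, style = c("W", "B")) {
  style <- match.arg(style)
  coords <- as.matrix(coords)
  if (!is.numeric(d_max) || d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  d <- as.matrix(dist(coords))
  A <- (d > 0 & d <= d_max) * 1
  deg <- rowSums(A)
  islands <- which(deg == 0)
  if (length(islands) == nrow(A)) {
    stop("all cells are isolated at this distance", call. = FALSE)
  }
  W <- if (style == "W") A / pmax(deg, 1) else A
  structure(list(W = W, coords = coords, style = style, d_max = d_max,
                 islands = islands),
            class = "spatial_weights")
}

as_weight_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Moran's I spatial autocorrelation
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2 with S0 the total weight. Under the null of no spatial
#' structure E\[I\] = -1/(n-1); the variance is computed under the
#' normality assumption and a two-sided p-value is derived from the
#' z-score.
#'
#' @param x Numeric values (length n >= 3, non-constant).
#' @param W A [build_weights()] object or weight matrix with zero
#'   diagonal and at least one nonzero weight.
#' @return List: `I`, `expected`, `variance`, `z`, `p`.
#' @export
morans_i <- function(x, W) {
  w <- as_weight_matrix(W)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (nrow(w) != n) stop("weights do not match x", call. = FALSE)
  if (sd(x) == 0) stop("Moran's I is undefined for constant x", call. = FALSE)
  s0 <- sum(w)
  if (s0 == 0) stop("weight matrix has no nonzero weights", call. = FALSE)
  z <- x - mean(x)
  I <- (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  ei <- -1 / (n - 1)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  vi <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - ei^2
  zscore <- (I - ei) / sqrt(vi)
  list(I = I, expected = ei, variance = vi, z = zscore,
       p = 2 * pnorm(-abs(zscore)))
}

#' Moran's I correlogram over distance classes
#'
#' Pairwise distances are binned into `n_classes` equal-width classes up
#' to half the maximum pairwise distance (beyond which few pairs remain
#' and estimates are unstable); Moran's I with binary within-bin weights
#' is computed per class. The distance up to which autocorrelation is
#' significant - the upper edge of the last class before the first
#' p >= 0.05 - is reported, the usual choice of neighbourhood radius for
#' spatial-regression weights.
#'
#' @param x Numeric values per cell.
#' @param coords Matching coordinates (km).
#' @param n_classes Number of distance classes (>= 2).
#' @param alpha Significance level for the cutoff scan.
#' @return Data frame (class, d_lower, d_upper, n_pairs, I, p) with
#'   attribute `d_signif`, the suggested neighbour cutoff (`NA` when the
#'   first class is already non-significant).
#' @export
correlogram <- function(x, coords, n_classes = 10, alpha = 0.05) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  coords <- as.matrix(coords)
  d <- as.matrix(dist(coords))
  breaks <- seq(0, max(d) / 2, length.out = n_classes + 1)
  rows <- lapply(seq_len(n_classes), function(k) {
    w <- (d > breaks[k] & d <= breaks[k + 1]) * 1
    n_pairs <- sum(w) / 2
    if (n_pairs == 0) {
      return(data.frame(class = k, d_lower = breaks[k], d_upper = breaks[k + 1],
                        n_pairs = 0, I = NA_real_, p = NA_real_))
    }
    mi <- morans_i(x, w)
    data.frame(class = k, d_lower = breaks[k], d_upper = breaks[k + 1],
               n_pairs = n_pairs, I = mi$I, p = mi$p)
  })
  out <- do.call(rbind, rows)
  nonsig <- which(!is.na(out$p) & out$p >= alpha)
  attr(out, "d_signif") <- if (length(nonsig) == 0) {
    out$d_upper[nrow(out)]
  } else if (nonsig[1] == 1) NA_real_ else out$d_upper[nonsig[1] - 1]
  out
}

# Gaussian ML log-likelihood pieces shared by ols/sar fits.
gaussian_ll <- function(rss, n, log_det = 0) {
  -n / 2 * (log(2 * pi) + log(rss / n) + 1) + log_det
}

new_sar_fit <- function(model, coefficients, spatial_param, sigma2, loglik,
                        k, residuals, fitted, y) {
  structure(list(model = model, coefficients = coefficients,
                 spatial_param = spatial_param, sigma2 = sigma2,
                 loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 residuals = residuals, fitted = fitted, y = y),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik = %.3f, AIC = %.2f", x$model, x$loglik, x$aic))
  if (!is.na(x$spatial_param)) {
    cat(sprintf(", %s = %.3f",
                if (x$model == "sar_lag") "rho" else "lambda", x$spatial_param))
  }
  cat("\ncoefficients:\n")
  print(x$coefficients)
  invisible(x)
}

# Design matrix with intercept from a predictor table (NULL or
# zero-column input gives the intercept-only model).
design_matrix <- function(X, n = NULL) {
  if (is.null(X) || NCOL(X) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrx$pivot[seq.int(qrx$rank + 1, ncol(Xd))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Xd
}

#' Ordinary least squares with Gaussian ML likelihood
#'
#' Fits y ~ X with an intercept and reports the Gaussian maximum-
#' likelihood log-likelihood and AIC on the same footing as the spatial
#' models (k = number of coefficients + 1 for the error variance), so
#' the fits are directly comparable in [model_select()]. Predictors
#' should be standardized beforehand when effect sizes are to be
#' compared across variables.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data frame (without intercept column).
#' @return A `sar_fit` with `model = "ols"`.
#' @export
fit_ols <- function(y, X) {
  Xd <- design_matrix(X, length(y))
  fit <- lm.fit(Xd, y)
  res <- fit$residuals
  n <- length(y)
  ll <- gaussian_ll(sum(res^2), n)
  new_sar_fit("ols", fit$coefficients, NA_real_, sum(res^2) / n, ll,
              k = ncol(Xd) + 1, residuals = res, fitted = fit$fitted.values,
              y = y)
}

#' Simultaneous autoregressive models (error and lag)
#'
#' Maximum-likelihood SAR fits on a row-standardized weight matrix W.
#' The error model is y = X beta + u with u = lambda W u + eps; the lag
#' model is y = rho W y + X beta + eps. For a candidate spatial
#' parameter the model reduces to OLS on spatially filtered data
#' ((I - lambda W) applied to y and X for the error model, to y alone
#' for the lag model), so beta and sigma^2 are profiled out and the
#' concentrated log-likelihood - including the Jacobian term
#' ln|I - lambda W|, evaluated through the eigenvalues of W - is
#' maximized by line search over the admissible interval
#' (1/min(eig), 1/max(eig)). Residuals are the innovations eps-hat.
#'
#' @param y Response vector.
#' @param X Predictor matrix or data frame (no intercept column).
#' @param W A [build_weights()] object or row-standardized matrix.
#' @param model `"error"` or `"lag"`.
#' @param lambda_fixed Optional: hold the spatial parameter at this value
#'   instead of maximizing over it (at 0 the fit reduces to OLS;
#'   likelihood comparability is kept by still counting the parameter).
#' @param ev Optional precomputed eigenvalues of W, to avoid repeating
#'   the decomposition across many fits on the same weights.
#' @return A `sar_fit`; `spatial_param` holds lambda (error) or rho
#'   (lag).
#' @export
fit_sar <- function(y, X, W, model = c("error", "lag"), lambda_fixed = NULL,
                    ev = NULL) {
  model <- match.arg(model)
  w <- as_weight_matrix(W)
  n <- length(y)
  stopifnot(nrow(w) == n)
  Xd <- design_matrix(X, n)
  if (is.null(ev)) ev <- eigen(w, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8) {
    warning("weight matrix has notably complex eigenvalues; using real parts")
  }
  ev <- Re(ev)
  lo <- if (min(ev) < 0) 1 / min(ev) else -1
  hi <- if (max(ev) > 0) 1 / max(ev) else 1
  interval <- c(lo + 1e-6, hi - 1e-6)
  Wy <- w %*% y
  concentrated <- function(lambda) {
    log_det <- sum(log(1 - lambda * ev))
    if (!is.finite(log_det)) return(-Inf)
    if (model == "error") {
      ys <- y - lambda * Wy
      Xs <- Xd - lambda * (w %*% Xd)
      fit <- lm.fit(Xs, as.vector(ys))
    } else {
      fit <- lm.fit(Xd, as.vector(y - lambda * Wy))
    }
    gaussian_ll(sum(fit$residuals^2), n, log_det)
  }
  if (is.null(lambda_fixed)) {
    opt <- optimize(concentrated, interval, maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    if (!is.finite(opt$objective)) {
      stop("SAR optimization failed: non-finite profile likelihood at lambda = ",
           signif(lambda, 4), call. = FALSE)
    }
  } else {
    lambda <- lambda_fixed
  }
  if (model == "error") {
    ys <- as.vector(y - lambda * Wy)
    Xs <- Xd - lambda * (w %*% Xd)
    fit <- lm.fit(Xs, ys)
    fitted <- as.vector(Xd %*% fit$coefficients)
  } else {
    fit <- lm.fit(Xd, as.vector(y - lambda * Wy))
    fitted <- as.vector(lambda * Wy + Xd %*% fit$coefficients)
  }
  rss <- sum(fit$residuals^2)
  ll <- gaussian_ll(rss, n, sum(log(1 - lambda * ev)))
  new_sar_fit(paste0("sar_", model), fit$coefficients, lambda, rss / n, ll,
              k = ncol(Xd) + 2, residuals = fit$residuals, fitted = fitted,
              y = y)
}

#' Rank fitted models by AIC
#'
#' @param fits List of `sar_fit` objects for the *same* response.
#' @return Data frame sorted by AIC ascending with `delta_aic`; AIC ties
#'   are broken by fewer parameters.
#' @export
model_select <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "sar_fit")))
  y0 <- fits[[1]]$y
  same <- vapply(fits, function(f) isTRUE(all.equal(f$y, y0)), logical(1))
  if (!all(same)) stop("fits do not share the same response", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    spatial_param = vapply(fits, `[[`, numeric(1), "spatial_param")
  )
  ord <- order(tab$aic, tab$k)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}
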