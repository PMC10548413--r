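# Kinship estimation and an exact spectral linear mixed model
# y = mu + x*beta + g + e,  Var(g) = K*sigma_g^2,  Var(e) = I*sigma_e^2.
# The null-model variance ratio delta = sigma_e^2/sigma_g^2 is profiled by
# ML once (spectral decomposition of K) and reused for every marker
# (EMMAX/P3D approximation); per-marker tests are GLS Wald t-tests.

#' Marker-based kinship matrix
#'
#' Columns (features) are mean-imputed, zero-variance features dropped,
#' standardized to zero mean and unit variance, and
#' `K = Z Z' / n_features`. Negative eigenvalues (numerical) are clipped
#' at zero so K is positive semi-definite.
#'
#' @param M samples x features matrix (genotype dosages or methylation
#'   levels; NA allowed).
#' @param kind label recorded on the result (`"genotype"` or
#'   `"methylation"`).
#' @return symmetric PSD kinship matrix with sample dimnames.
#' @export
kinship <- function(M, kind = c("genotype", "methylation")) {
  kind <- match.arg(kind)
  M <- as.matrix(M)
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- cm[idx[, 2]]
  v <- apply(M, 2, var)
  M <- M[, v > 0, drop = FALSE]
  if (ncol(M) < 2) stop("fewer than 2 usable features for kinship")
  Z <- scale(M)
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  ei <- eigen(K, symmetric = TRUE)
  if (any(ei$values < 0)) {
    K <- ei$vectors %*% (pmax(ei$values, 0) * t(ei$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(rownames(M), rownames(M))
  attr(K, "kind") <- kind
  K
}

# Restricted (intercept-projected) profile log-likelihood at variance
# ratio delta: yt and lambda live in the (n-1)-dimensional space
# orthogonal to the intercept.  Profiling the full-spectrum ML instead is
# degenerate whenever K comes from column-centred markers: K's null space
# then contains the intercept direction, whose residual the mean absorbs
# exactly, and -log(delta)/2 diverges as delta -> 0.
null_loglik <- function(delta, yt, lambda, m) {
  s2 <- sum(yt^2 / (lambda + delta)) / m
  -m / 2 * (log(2 * pi * s2) + 1) - sum(log(lambda + delta)) / 2
}

#' Kinship-corrected association scan (exact spectral LMM)
#'
#' Eigendecomposes K once; profiles the restricted likelihood of the
#' null (intercept-only) model over `delta = sigma_e^2/sigma_g^2` on a
#' log grid refined by golden-section search (REML on the
#' intercept-orthogonal space, which stays well-defined when K's null
#' space contains the intercept, as it does for kinship from centred
#' markers); then tests every marker by
#' generalized least squares in the rotated space at the null-model
#' delta (the EMMAX/P3D approximation), with two-sided Wald t-tests on
#' n - 2 degrees of freedom. Missing marker values are mean-imputed for
#' the scan; zero-variance markers get NA p-values.
#'
#' @param y response vector (here: a climate variable per sample).
#' @param X samples x markers explanatory matrix (methylation levels or
#'   genotype dosages).
#' @param K kinship matrix from [kinship()].
#' @param grid_points,grid_range log10 grid for the delta profile.
#' @return list of class `lmm_scan`: `scan` (data frame `marker, beta,
#'   se, p`), `sigma_g2`, `sigma_e2`, `delta`, `loglik`.
#' @export
fit_lmm <- function(y, X, K, grid_points = 100, grid_range = c(-5, 5)) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n >= 4, nrow(X) == n, all(dim(K) == n))
  ei <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lambda <- pmax(ei$values, 0)
  U <- ei$vectors
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))
  # delta profiled by REML in the space orthogonal to the intercept
  Qc <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  A <- crossprod(Qc, K %*% Qc)
  eiA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lamA <- pmax(eiA$values, 0)
  ytA <- drop(crossprod(eiA$vectors, crossprod(Qc, y)))
  m1 <- n - 1
  grid <- 10^seq(grid_range[1], grid_range[2], length.out = grid_points)
  ll <- vapply(grid, null_loglik, numeric(1), yt = ytA, lambda = lamA,
               m = m1)
  ibest <- which.max(ll)
  lo <- grid[max(1, ibest - 1)]; hi <- grid[min(grid_points, ibest + 1)]
  opt <- optimize(function(ld) null_loglik(exp(ld), ytA, lamA, m1),
                  lower = log(lo), upper = log(hi), maximum = TRUE,
                  tol = 1e-10)
  delta <- exp(opt$maximum)
  loglik <- opt$objective
  if (loglik < max(ll)) { delta <- grid[ibest]; loglik <- max(ll) }
  sigma_g2 <- sum(ytA^2 / (lamA + delta)) / m1
  sigma_e2 <- delta * sigma_g2
  w <- 1 / (lambda + delta)
  # mean-impute and track degenerate markers
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- cm[idx[, 2]]
  xvar <- apply(X, 2, var)
  degenerate <- xvar == 0 | is.na(xvar)
  if (any(degenerate))
    message(sum(degenerate), " zero-variance marker(s): p set missing")
  Xt <- crossprod(U, X)
  s11 <- sum(w * ot^2)
  s1y <- sum(w * ot * yt)
  syy <- sum(w * yt^2)
  s1x <- drop(crossprod(w * ot, Xt))
  sxy <- drop(crossprod(w * yt, Xt))
  sxx <- drop(crossprod(rep(1, n), w * Xt^2))
  det <- s11 * sxx - s1x^2
  det[degenerate] <- NA_real_   # avoids NaN noise; reported as NA below
  beta <- (s11 * sxy - s1x * s1y) / det
  muj <- (sxx * s1y - s1x * sxy) / det
  rss <- pmax(syy - muj * s1y - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) * s11 / det)
  tval <- beta / se
  p <- pmax(2 * pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  beta[degenerate] <- NA; se[degenerate] <- NA; p[degenerate] <- NA
  markers <- colnames(X)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(X)))
  structure(list(scan = data.frame(marker = markers, beta = beta,
                                   se = se, p = p, row.names = NULL),
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 delta = delta, loglik = loglik),
            class = "lmm_scan")
}

#' Permutation-based genome-wide significance threshold
#'
#' Per repeat: draw `subset_size` markers without replacement, permute
#' the response across samples, run the LMM scan, and record the minimum
#' p-value; the threshold is the empirical `alpha`-quantile of the
#' minima. This calibrates family-wise significance under the observed
#' marker correlation structure, typically far less stringent than
#' Bonferroni at small sample sizes.
#'
#' @param y,X,K as in [fit_lmm()].
#' @param n_repeats permutation repeats (default 200; fewer than 20 is
#'   refused).
#' @param subset_size markers drawn per repeat (default 10000; clipped to
#'   the available count with a warning).
#' @param alpha family-wise level (default 0.05).
#' @param seed integer seed.
#' @return list `threshold`, `minima`, `n_repeats`, `subset_size`.
#' @export
permutation_threshold <- function(y, X, K, n_repeats = 200,
                                  subset_size = 10000, alpha = 0.05,
                                  seed = 1L) {
  if (n_repeats < 20) stop("n_repeats < 20: quantile unstable")
  X <- as.matrix(X)
  m <- ncol(X)
  if (subset_size > m) {
    warning("subset_size clipped to ", m, " available markers")
    subset_size <- m
  }
  n <- length(y)
  minima <- with_seed(seed, vapply(seq_len(n_repeats), function(i) {
    cols <- sample.int(m, subset_size)
    yp <- y[sample.int(n)]
    fit <- fit_lmm(yp, X[, cols, drop = FALSE], K)
    min(fit$scan$p, na.rm = TRUE)
  }, numeric(1)))
  list(threshold = unname(quantile(minima, alpha, type = 1)),
       minima = minima, n_repeats = n_repeats, subset_size = subset_size)
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}
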