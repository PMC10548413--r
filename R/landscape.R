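# Geographic/environmental distance construction, climate-variable
# pre-selection, and (partial) Mantel permutation tests for IBD/IBE.

#' Great-circle distance between population sites
#'
#' Haversine distance in kilometres (Earth radius 6371.0088 km),
#' optionally natural-log transformed on the off-diagonals (the diagonal
#' stays 0).
#'
#' @param map a [population_map()].
#' @param log_transform apply `log` to off-diagonal distances.
#' @return symmetric km (or log-km) matrix with population dimnames.
#' @export
geographic_distance <- function(map, log_transform = FALSE) {
  s <- map$sites
  xy <- as.matrix(s[, c("longitude", "latitude")])
  d <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  dimnames(d) <- list(s$population, s$population)
  if (log_transform) {
    off <- row(d) != col(d)
    if (any(d[off] <= 0))
      stop("coincident sites: log of zero distance undefined; ",
           "jitter coordinates or add an offset")
    d[off] <- log(d[off])
  }
  d
}

#' Greedy selection of mutually uncorrelated climate variables
#'
#' While any variable pair has absolute Pearson correlation at or above
#' `r_max`, drops the member of the worst pair with the larger mean
#' absolute correlation to all other remaining variables (ties keep the
#' earlier input column).
#'
#' @param climate a [climate_table()].
#' @param r_max threshold (default 0.8, i.e. retain |r| < .8).
#' @return character vector of retained variable names (input order).
#' @export
select_uncorrelated <- function(climate, r_max = 0.8) {
  keep <- climate$variables
  stopifnot(length(keep) >= 2)
  repeat {
    cm <- abs(cor(climate$values[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (all(cm < r_max, na.rm = TRUE) || length(keep) == 1) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    cand <- keep[unique(as.integer(worst))]
    meanabs <- colMeans(cm[, cand, drop = FALSE])
    # drop larger mean |r|; ties keep the earlier input column
    ord <- order(-meanabs, -match(cand, climate$variables))
    keep <- setdiff(keep, cand[ord[1]])
  }
  keep
}

#' Environmental distance on leading principal components
#'
#' Variables are standardized, a PCA is taken on the correlation
#' structure, and Euclidean distances are computed on the first `n_pc`
#' scores. Zero-variance variables are dropped with a warning.
#'
#' @param climate a [climate_table()].
#' @param n_pc number of leading components (default 3).
#' @return symmetric distance matrix; attribute `explained` holds the
#'   per-component explained-variance fractions.
#' @export
environmental_distance <- function(climate, n_pc = 3) {
  v <- climate$values
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
  }
  stopifnot(n_pc <= ncol(v))
  pc <- prcomp(v, center = TRUE, scale. = TRUE)
  sc <- pc$x[, seq_len(n_pc), drop = FALSE]
  d <- as.matrix(dist(sc))
  dimnames(d) <- list(rownames(v), rownames(v))
  attr(d, "explained") <- pc$sdev^2 / sum(pc$sdev^2)
  d
}

offdiag_vec <- function(m) m[upper.tri(m)]

check_dist <- function(m, name) {
  m <- as.matrix(m)
  if (nrow(m) < 4) stop(name, " must be at least 4 x 4")
  if (!isSymmetric(unname(m), tol = 1e-8)) stop(name, " not symmetric")
  m
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper-off-diagonal vectors of two distance
#' matrices; the null is built by jointly permuting rows and columns of
#' `B`. The one-sided (upper tail) p-value is
#' `(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`; `two_sided` doubles the
#' smaller tail.
#'
#' @param A,B symmetric distance matrices with zero diagonal, same order.
#' @param n_perm permutation count (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param two_sided use a two-sided alternative.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `partial`.
#' @export
mantel <- function(A, B, n_perm = 9999, seed = 1L, two_sided = FALSE) {
  A <- check_dist(A, "A"); B <- check_dist(B, "B")
  stopifnot(all(dim(A) == dim(B)))
  va <- offdiag_vec(A); vb <- offdiag_vec(B)
  if (sd(va) == 0 || sd(vb) == 0) stop("degenerate distance matrix")
  r_obs <- cor(va, vb)
  n <- nrow(A)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n)
    cor(va, offdiag_vec(B[pm, pm]))
  }, numeric(1)))
  p_up <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  p <- if (two_sided) {
    p_lo <- (1 + sum(r_perm <= r_obs)) / (1 + n_perm)
    min(1, 2 * min(p_up, p_lo))
  } else p_up
  structure(list(r = r_obs, p = p, n_perm = n_perm, partial = FALSE,
                 controlled = NULL),
            class = "mantel_result")
}

#' Partial Mantel permutation test
#'
#' Correlates the residuals of `A ~ C` and `B ~ C` (simple linear
#' regressions on the off-diagonal vectors). The null permutes the rows
#' and columns of `A` (raw-matrix permutation) and recomputes the
#' residual correlation. When `C` has zero off-diagonal variance the test
#' reduces to the simple Mantel test with a warning.
#'
#' @inheritParams mantel
#' @param C matrix to control for.
#' @export
partial_mantel <- function(A, B, C, n_perm = 9999, seed = 1L,
                           two_sided = FALSE) {
  A <- check_dist(A, "A"); B <- check_dist(B, "B"); C <- check_dist(C, "C")
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(C)))
  vc <- offdiag_vec(C)
  if (sd(vc) == 0) {
    warning("control matrix constant; reducing to simple Mantel test")
    out <- mantel(A, B, n_perm = n_perm, seed = seed, two_sided = two_sided)
    out$partial <- TRUE
    return(out)
  }
  va <- offdiag_vec(A); vb <- offdiag_vec(B)
  if (sd(va) == 0 || sd(vb) == 0) stop("degenerate distance matrix")
  res <- function(v) v - (cov(v, vc) / var(vc)) * (vc - mean(vc)) - mean(v)
  rb <- res(vb)
  r_obs <- cor(res(va), rb)
  n <- nrow(A)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n)
    cor(res(offdiag_vec(A[pm, pm])), rb)
  }, numeric(1)))
  p_up <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  p <- if (two_sided) {
    p_lo <- (1 + sum(r_perm <= r_obs)) / (1 + n_perm)
    min(1, 2 * min(p_up, p_lo))
  } else p_up
  structure(list(r = r_obs, p = p, n_perm = n_perm, partial = TRUE,
                 controlled = deparse(substitute(C))),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (x$partial) "partial Mantel:" else "Mantel:",
      "r =", round(x$r, 4), " p =", signif(x$p, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
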