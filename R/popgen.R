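# Per-population diversity, Weir-Cockerham differentiation and classical
# PCoA.  All estimators handle missing genotypes by per-locus, per-population
# non-missing counts; theta is ratio-of-sums over loci.

# per population x locus: non-missing diploid count n, allele frequency p,
# observed heterozygote fraction h
pop_locus_stats <- function(G, map) {
  pops <- unique(map$assignments[G$samples])
  pop_of <- factor(map$assignments[G$samples], levels = pops)
  dos <- G$dosage
  ok <- !is.na(dos)
  n <- rowsum(ok + 0, pop_of)                 # pops x loci counts
  sum_alt <- rowsum(ifelse(ok, dos, 0), pop_of)
  het <- rowsum(ifelse(ok, (dos == 1) + 0, 0), pop_of)
  p <- ifelse(n > 0, sum_alt / (2 * n), 0)
  h <- ifelse(n > 0, het / n, 0)
  list(pops = pops, n = n, p = p, h = h)
}

# Weir & Cockerham (1984) per-locus variance components a, b, c from
# per-population sample sizes, allele frequencies and heterozygote
# fractions (matrices pops x loci); populations with n = 0 at a locus drop
# out of that locus.
wc_components <- function(n, p, h) {
  r <- colSums(n > 0)
  N <- colSums(n)
  usable <- r >= 2
  nbar <- N / r
  nc <- (N - colSums(n^2) / N) / (r - 1)
  pbar <- colSums(n * p) / N
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / N
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- NA; b[!usable] <- NA; cc[!usable] <- NA
  list(a = a, b = b, c = cc, he = 2 * pbar * (1 - pbar), pbar = pbar,
       usable = usable)
}

#' Per-population diversity statistics
#'
#' Per locus: unbiased nucleotide diversity `pi = 2*p*q*2n/(2n-1)`,
#' observed heterozygosity and expected heterozygosity `2*p*q`; per
#' population, `pi` and `H_O` are averaged over loci genotyped in that
#' population (per-SNP averages, since RAD data lack callable-site
#' totals), and `F_IS = 1 - mean(H_O)/mean(H_E)` as a ratio of means.
#'
#' @param G a [genotype_matrix()].
#' @param map a [population_map()] covering all samples.
#' @return data frame `population, n, pi, ho, fis`.
#' @export
diversity_stats <- function(G, map) {
  st <- pop_locus_stats(G, map)
  out <- lapply(seq_along(st$pops), function(i) {
    n <- st$n[i, ]; p <- st$p[i, ]; h <- st$h[i, ]
    use <- n > 0
    if (!any(use)) stop("population ", st$pops[i], " has zero genotyped loci")
    q <- 1 - p
    pi_l <- 2 * p * q * (2 * n) / pmax(2 * n - 1, 1)
    he_l <- 2 * p * q
    data.frame(population = st$pops[i],
               n = max(st$n[i, ]),
               pi = mean(pi_l[use]),
               ho = mean(h[use]),
               fis = 1 - sum(h[use]) / sum(he_l[use]))
  })
  do.call(rbind, out)
}

#' Weir-Cockerham F_ST (global and pairwise)
#'
#' Multilocus theta is the ratio of summed among-population components to
#' summed total components (ratio of sums, the standard Weir-Cockerham
#' practice). Loci lacking data in a population drop out of that
#' population's terms; a pair's locus is skipped when either member has no
#' genotyped individual.
#'
#' @param G a [genotype_matrix()].
#' @param map a [population_map()].
#' @param pairs optional 2-column matrix/data frame of population code
#'   pairs; default all pairs.
#' @return list of class `fst_matrix`: `populations`, `theta` (symmetric
#'   pairwise matrix, diagonal 0), `global_theta`, and `per_locus`
#'   (data frame `he`, `fst` from the all-population fit).
#' @export
wc_fst <- function(G, map, pairs = NULL) {
  st <- pop_locus_stats(G, map)
  pops <- st$pops
  if (length(pops) < 2) stop("need at least two populations")
  comp <- wc_components(st$n, st$p, st$h)
  tot <- comp$a + comp$b + comp$c
  global <- sum(comp$a[comp$usable]) / sum(tot[comp$usable])
  per_locus <- data.frame(locus = colnames(G$dosage),
                          he = comp$he,
                          fst = ifelse(comp$usable & tot != 0,
                                       comp$a / tot, NA_real_))
  theta <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
  diag(theta) <- 0
  if (is.null(pairs)) {
    pairs <- t(utils::combn(pops, 2))
  } else {
    pairs <- as.matrix(pairs)
  }
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs[k, 1], pops); j <- match(pairs[k, 2], pops)
    sel <- c(i, j)
    use <- st$n[i, ] > 0 & st$n[j, ] > 0
    if (!any(use)) {
      warning("all loci skipped for pair ", pairs[k, 1], "-", pairs[k, 2])
      next
    }
    cp <- wc_components(st$n[sel, use, drop = FALSE],
                        st$p[sel, use, drop = FALSE],
                        st$h[sel, use, drop = FALSE])
    th <- sum(cp$a[cp$usable]) / sum((cp$a + cp$b + cp$c)[cp$usable])
    theta[i, j] <- theta[j, i] <- th
  }
  structure(list(populations = pops, theta = theta, global_theta = global,
                 per_locus = per_locus),
            class = "fst_matrix")
}

#' Linearize F_ST for distance-based tests
#'
#' The monotone transform `F/(1-F)`. Entries at or above 1 are clamped to
#' the largest representable value with a warning; negative estimates pass
#' through (monotonicity preserved).
#' @param f numeric vector or matrix of F_ST values.
#' @export
linearize_fst <- function(f) {
  out <- f
  hi <- !is.na(f) & f >= 1
  if (any(hi)) {
    warning(sum(hi), " F_ST value(s) >= 1 clamped")
    out[hi] <- .Machine$double.xmax
  }
  out[!hi] <- f[!hi] / (1 - f[!hi])
  out
}

#' Individual allele-sharing distance
#'
#' Mean absolute dosage difference over shared non-missing loci, scaled to
#' \[0, 1\]; input to the individual-level PCoA.
#' @param G a [genotype_matrix()].
#' @export
allele_sharing_distance <- function(G) {
  dos <- G$dosage
  n <- nrow(dos)
  D <- matrix(0, n, n, dimnames = list(G$samples, G$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
    D[i, j] <- D[j, i] <-
      if (any(ok)) mean(abs(dos[i, ok] - dos[j, ok])) / 2 else NA_real_
  }
  D
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and returns the top-k
#' coordinates scaled by the square root of their eigenvalues. Axes with
#' negative eigenvalues are reported but dropped; `k` is truncated with a
#' warning when it exceeds the number of positive eigenvalues.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of axes requested.
#' @return list `coords` (n x k'), `eigenvalues` (all), `explained`
#'   (fractions over positive eigenvalues), `n_negative`.
#' @export
pcoa <- function(D, k = 2) {
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D), tol = 1e-8), all(abs(diag(D)) < 1e-12))
  n <- nrow(D)
  fit <- cmdscale(D, k = n - 1, eig = TRUE)
  ev <- fit$eig
  npos <- sum(ev > 1e-8 * max(abs(ev), 1))
  if (k > npos) {
    warning("k truncated from ", k, " to ", npos, " positive eigenvalues")
    k <- npos
  }
  coords <- if (k > 0) fit$points[, seq_len(k), drop = FALSE]
            else matrix(0, n, 0)
  rownames(coords) <- rownames(D)
  list(coords = coords, eigenvalues = ev,
       explained = if (npos > 0) ev[seq_len(npos)] / sum(ev[ev > 0]) else numeric(0),
       n_negative = sum(ev < -1e-8 * max(abs(ev), 1)))
}
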