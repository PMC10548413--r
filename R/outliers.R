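# Simulation-null F_ST outlier detection conditioned on heterozygosity
# (FDIST-style): a Balding-Nichols island-model null calibrated to the
# observed genome-wide differentiation, equal-count He bins, upper-tail
# empirical p-values, BH q-values, and multi-method set intersection.

# Count-level simulation of one cloud of (He, theta) pairs: per locus,
# ancestral p ~ U(.01,.99); per-population Beta frequencies at
# differentiation F; genotype counts per population by exact HWE
# multinomial sampling (two nested binomials), matching Binomial(2, f)
# per individual.
#' Simulate a neutral (He, F_ST) null cloud
#'
#' Balding-Nichols island-model null at differentiation `F` with the
#' observed per-population sample sizes; per simulated locus the
#' Weir-Cockerham theta and weighted expected heterozygosity are
#' returned. Deterministic given `seed`.
#'
#' @param F island-model differentiation parameter in (0, 1).
#' @param sample_sizes per-population diploid counts.
#' @param n_loci simulated locus count.
#' @param seed integer seed.
#' @return data frame `he`, `fst` (`NA` fst for degenerate loci removed).
#' @export
simulate_null <- function(F, sample_sizes, n_loci, seed = 1L) {
  stopifnot(F > 0, F < 1, all(sample_sizes >= 1), n_loci >= 1)
  r <- length(sample_sizes)
  with_seed(seed, {
    p0 <- runif(n_loci, 0.01, 0.99)
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    f <- matrix(rbeta(r * n_loci, rep(a, each = r), rep(b, each = r)), r)
    n <- matrix(sample_sizes, r, n_loci)
    pAA <- f^2; pAa <- 2 * f * (1 - f)
    nAA <- matrix(rbinom(r * n_loci, as.vector(n), as.vector(pAA)), r)
    rest <- n - nAA
    cond <- ifelse(pAA < 1, pAa / (1 - pAA), 0)
    nAa <- matrix(rbinom(r * n_loci, as.vector(rest), as.vector(cond)), r)
    p <- (2 * nAA + nAa) / (2 * n)
    h <- nAa / n
    comp <- wc_components(n, p, h)
    tot <- comp$a + comp$b + comp$c
    ok <- comp$usable & !is.na(tot) & tot != 0
    data.frame(he = comp$he[ok], fst = (comp$a / tot)[ok])
  })
}

#' Calibrate the island-model null to observed differentiation
#'
#' Bisection on the Balding-Nichols `F` so that the trimmed mean of
#' simulated per-locus theta (matched sample sizes, `n_loci` simulated
#' loci, common random numbers across evaluations) matches the observed
#' trimmed-mean theta within `tol`. Trimming removes the stated fraction
#' of extreme loci per tail so that true outliers do not inflate the
#' neutral target.
#'
#' @param G a [genotype_matrix()].
#' @param map a [population_map()].
#' @param trim fraction trimmed per tail (default 0.05).
#' @param n_loci loci simulated per evaluation.
#' @param tol convergence tolerance on mean theta.
#' @param max_iter bisection iterations before failure.
#' @param seed seed of the common-random-numbers stream.
#' @return list `F`, `target` (observed trimmed mean), `trace`
#'   (data frame of the bisection path).
#' @export
calibrate_null <- function(G, map, trim = 0.05, n_loci = 10000,
                           tol = 0.005, max_iter = 30, seed = 1L) {
  fst <- wc_fst(G, map)
  obs <- fst$per_locus$fst
  obs <- obs[!is.na(obs)]
  target <- mean(obs, trim = trim)
  sizes <- as.integer(table(map$assignments[G$samples]))
  simmean <- function(F) {
    cl <- simulate_null(F, sizes, n_loci, seed = seed)
    mean(cl$fst, trim = trim)
  }
  lo <- 1e-4; hi <- 0.95
  trace <- data.frame(iter = integer(0), F = numeric(0), diff = numeric(0))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    dd <- simmean(mid) - target
    trace <- rbind(trace, data.frame(iter = it, F = mid, diff = dd))
    if (abs(dd) < tol)
      return(list(F = mid, target = target, trace = trace))
    if (dd > 0) hi <- mid else lo <- mid
  }
  stop("calibrate_null did not converge in ", max_iter,
       " iterations; last diff ", signif(dd, 3))
}

#' FDIST-style outlier test against a simulated null cloud
#'
#' Null loci are placed into `n_bins` equal-count expected-heterozygosity
#' bins; each observed locus gets an empirical upper-tail probability
#' `p_upper = (1 + #\{null theta in its bin >= observed theta\}) /
#' (1 + bin count)` and is flagged when `p_upper <= 1 - confidence`
#' (upper tail only: divergent selection). BH q-values are attached over
#' all observed loci. Observed He outside the simulated range falls into
#' the nearest bin with a warning.
#'
#' @param obs data frame with columns `he`, `fst` (and optionally
#'   `locus`), e.g. the `per_locus` slot of [wc_fst()].
#' @param null data frame `he`, `fst` from [simulate_null()].
#' @param confidence flagging confidence (default 0.99).
#' @param n_bins equal-count He bins (default 20).
#' @return data frame `locus, he, fst, p_upper, q, flagged`.
#' @export
fdist_outliers <- function(obs, null, confidence = 0.99, n_bins = 20) {
  stopifnot(all(c("he", "fst") %in% names(obs)),
            all(c("he", "fst") %in% names(null)))
  edges <- quantile(null$he, probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE)
  edges[1] <- -Inf; edges[n_bins + 1] <- Inf
  nbin <- findInterval(null$he, edges, rightmost.closed = TRUE)
  nbin <- pmin(pmax(nbin, 1L), n_bins)
  if (any(obs$he < min(null$he) | obs$he > max(null$he), na.rm = TRUE))
    warning("observed He outside simulated range; nearest bin used")
  obin <- pmin(pmax(findInterval(obs$he, edges, rightmost.closed = TRUE),
                    1L), n_bins)
  sorted <- lapply(seq_len(n_bins), function(b) sort(null$fst[nbin == b]))
  p_upper <- rep(NA_real_, nrow(obs))
  for (b in seq_len(n_bins)) {
    sel <- which(obin == b & !is.na(obs$fst))
    if (!length(sel)) next
    s <- sorted[[b]]
    ge <- length(s) - findInterval(obs$fst[sel] - 1e-15, s)
    p_upper[sel] <- (1 + ge) / (1 + length(s))
  }
  q <- rep(NA_real_, length(p_upper))
  ok <- !is.na(p_upper)
  q[ok] <- adjust_fdr(p_upper[ok])
  data.frame(locus = if ("locus" %in% names(obs)) obs$locus
             else seq_len(nrow(obs)),
             he = obs$he, fst = obs$fst, p_upper = p_upper, q = q,
             flagged = !is.na(p_upper) & p_upper <= 1 - confidence)
}

#' Intersect outlier sets from several methods
#'
#' @param sets named list of locus-id vectors (at least two).
#' @return list `per_set` counts, `union`, `intersection` (k-way) and
#'   `percentage` (100 * |intersection| / |union|, one decimal).
#' @export
intersect_outliers <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  un <- Reduce(union, sets)
  if (length(un) == 0) stop("empty union of outlier sets")
  inter <- Reduce(intersect, sets)
  list(per_set = vapply(sets, length, integer(1)),
       union = length(un), intersection = length(inter),
       percentage = round(100 * length(inter) / length(un), 1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement (via [stats::p.adjust()]);
#' input order preserved.
#' @param p p-values in \[0, 1\].
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}
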