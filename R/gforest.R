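# Gradient-forest turnover modelling and genomic-offset prediction.

#' Population allele frequencies from genotypes
#'
#' Alternate-allele frequency per population per locus, NA where a
#' population has no genotyped individual.
#' @param G a [genotype_matrix()].
#' @param map a [population_map()].
#' @export
population_freqs <- function(G, map) {
  st <- pop_locus_stats(G, map)
  p <- ifelse(st$n > 0, st$p, NA_real_)
  rownames(p) <- st$pops
  colnames(p) <- colnames(G$dosage)
  p
}

#' Fit a gradient-forest turnover model
#'
#' Per locus, a regression random forest (bootstrap per tree, random
#' predictor subset per split, variance-reduction splits) predicts the
#' population allele frequency from the climate variables; out-of-bag
#' R^2 measures fit quality. Every split's impurity decrease is binned
#' at its split value along the predictor's observed range, normalized
#' within locus, weighted by the locus R^2, and averaged over loci with
#' R^2 > 0. Cumulative sums of the binned importance give each
#' predictor's turnover function (non-decreasing, 0 at the range
#' minimum).
#'
#' @param freqs populations x loci allele-frequency matrix
#'   ([population_freqs()]); loci with any NA or zero variance are
#'   skipped.
#' @param climate a [climate_table()] for the same populations
#'   (current scenario).
#' @param ntree trees per locus (default 500).
#' @param n_bins importance bins per predictor (default 201).
#' @param min_node minimum samples per leaf (default 2, suited to
#'   population-level fits at small n).
#' @param mtry predictors tried per split (default `ceiling(P/3)`).
#' @param seed integer seed; fits are deterministic given it.
#' @return object of class `turnover_model`: `predictors`, `bin_edges`
#'   (per predictor), `cumimp` (per predictor cumulative importance at
#'   the edges), `importance` (per-predictor totals), `r2` (per locus),
#'   `pars`.
#' @export
fit_gradient_forest <- function(freqs, climate, ntree = 500, n_bins = 201,
                                min_node = 2, mtry = NULL, seed = 1L) {
  X <- climate$values
  stopifnot(nrow(X) >= 5, nrow(freqs) == nrow(X))
  if (!identical(rownames(freqs), rownames(X)))
    freqs <- freqs[rownames(X), , drop = FALSE]
  P <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(P / 3)
  usable <- apply(freqs, 2, function(f) !anyNA(f) && var(f) > 0)
  if (!any(usable)) stop("no usable (variable, fully observed) loci")
  if (any(!usable))
    message(sum(!usable), " constant or incomplete loci skipped")
  Y <- freqs[, usable, drop = FALSE]
  xmin <- apply(X, 2, min); xmax <- apply(X, 2, max)
  const_pred <- xmax - xmin <= 0
  xbw <- ifelse(const_pred, 1, (xmax - xmin) / n_bins)
  fit <- .gf_fit_cpp(unname(X), unname(Y), as.integer(ntree),
                     as.integer(mtry), as.integer(min_node),
                     xmin, xbw, as.integer(n_bins), as.integer(seed))
  imp <- fit$importance
  rownames(imp) <- colnames(X)
  edges <- lapply(seq_len(P), function(j) xmin[j] + xbw[j] * 0:n_bins)
  names(edges) <- colnames(X)
  cumimp <- lapply(seq_len(P), function(j) c(0, cumsum(imp[j, ])))
  names(cumimp) <- colnames(X)
  r2 <- setNames(rep(NA_real_, ncol(freqs)), colnames(freqs))
  r2[usable] <- fit$r2
  structure(list(predictors = colnames(X), bin_edges = edges,
                 cumimp = cumimp, importance = rowSums(imp),
                 r2 = r2, n_positive = fit$n_positive,
                 pars = list(ntree = ntree, n_bins = n_bins, mtry = mtry,
                             min_node = min_node, seed = seed)),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("turnover_model:", length(x$predictors), "predictors,",
      sum(!is.na(x$r2)), "loci fitted,", x$n_positive, "with R2 > 0\n")
  print(round(sort(x$importance, decreasing = TRUE), 5))
  invisible(x)
}

#' Transform climate into cumulative-importance (genomic) space
#'
#' Each predictor value is mapped through its turnover function by
#' linear interpolation within bins; values beyond the fitted range are
#' clamped to the end values (clamp events counted on the result).
#'
#' @param model a `turnover_model`.
#' @param points matrix/data frame of climate vectors covering the model
#'   predictors (extra columns ignored).
#' @return matrix of transformed vectors (attribute `n_clamped`).
#' @export
transform_climate <- function(model, points) {
  points <- as.matrix(points)
  miss <- setdiff(model$predictors, colnames(points))
  if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "))
  out <- matrix(0, nrow(points), length(model$predictors),
                dimnames = list(rownames(points), model$predictors))
  clamped <- 0L
  for (v in model$predictors) {
    e <- model$bin_edges[[v]]
    x <- points[, v]
    clamped <- clamped + sum(x < e[1] | x > e[length(e)])
    out[, v] <- approx(e, model$cumimp[[v]], xout = x, rule = 2)$y
  }
  attr(out, "n_clamped") <- clamped
  out
}

check_offset_tables <- function(current, future) {
  if (!identical(current$sites, future$sites))
    stop("site mismatch between climate tables: ",
         paste(symdiff <- union(setdiff(current$sites, future$sites),
                                setdiff(future$sites, current$sites)),
               collapse = ", "))
  if (!identical(current$variables, future$variables))
    stop("variable mismatch between climate tables")
}

#' Local genomic offset
#'
#' Per site, the Euclidean distance between the transformed current and
#' future climate: the predicted mismatch between present genomic
#' composition and what the future climate would require in place.
#'
#' @param model a `turnover_model`.
#' @param current,future [climate_table()]s with identical sites and
#'   variables.
#' @return data frame `site, local_offset` (attribute `scenario`).
#' @export
local_offset <- function(model, current, future) {
  check_offset_tables(current, future)
  tc <- transform_climate(model, current$values)
  tf <- transform_climate(model, future$values)
  out <- data.frame(site = current$sites,
                    local_offset = sqrt(rowSums((tc - tf)^2)))
  attr(out, "scenario") <- future$scenario
  out
}

#' Forward genomic offset (migration load)
#'
#' Per site, the minimum over all candidate destination sites of the
#' distance between the site's current transformed climate and the
#' destination's future transformed climate — the best achievable
#' mismatch assuming unrestricted migration (staying in place included,
#' so forward <= local everywhere).
#'
#' @inheritParams local_offset
#' @return data frame `site, forward_offset, best_site`.
#' @export
forward_offset <- function(model, current, future) {
  check_offset_tables(current, future)
  tc <- transform_climate(model, current$values)
  tf <- transform_climate(model, future$values)
  n <- nrow(tc)
  # exact pairwise distances (site counts are small; avoids the
  # cancellation noise of the crossproduct identity at zero displacement)
  d2 <- matrix(0, n, n)
  for (j in seq_len(n))
    d2[, j] <- rowSums(sweep(tc, 2, tf[j, ])^2)
  best <- apply(d2, 1, which.min)
  out <- data.frame(site = current$sites,
                    forward_offset = sqrt(d2[cbind(seq_len(n), best)]),
                    best_site = current$sites[best])
  attr(out, "scenario") <- future$scenario
  out
}

#' Offsets across scenarios, with ranking and monotonicity flags
#'
#' Computes local and forward offsets for each future scenario on the
#' same turnover model (optionally restricted to an outlier locus subset
#' via a refit), ranks sites within scenario, and flags whether each
#' site's local offset is non-decreasing across the scenario order
#' given (e.g. increasing emissions).
#'
#' @param model a `turnover_model`.
#' @param current current [climate_table()].
#' @param futures named list of future climate tables, ordered by
#'   scenario severity.
#' @return list `offsets` (long data frame `scenario, site,
#'   local_offset, forward_offset, rank_local`), `monotone` (per-site
#'   logical across the scenario order).
#' @export
offset_report <- function(model, current, futures) {
  stopifnot(length(futures) >= 1)
  rows <- lapply(names(futures), function(sc) {
    lo <- local_offset(model, current, futures[[sc]])
    fo <- forward_offset(model, current, futures[[sc]])
    data.frame(scenario = sc, site = lo$site,
               local_offset = lo$local_offset,
               forward_offset = fo$forward_offset,
               rank_local = rank(-lo$local_offset, ties.method = "min"))
  })
  offsets <- do.call(rbind, rows)
  wide <- matrix(offsets$local_offset, ncol = length(futures),
                 dimnames = list(current$sites, names(futures)))
  monotone <- apply(wide, 1, function(x) all(diff(x) >= -1e-12))
  list(offsets = offsets, monotone = monotone)
}
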