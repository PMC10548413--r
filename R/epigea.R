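# Pipeline stages wrapping the mixed model: SMV calling/filtering,
# methylation-climate EWAS, SNP-climate GEA (LMM-GEA), and gene-proximity
# annotation of hits.

#' Call single-methylation variants (SMVs)
#'
#' Cells below `min_depth` are set missing first; then sites with a
#' missing fraction above `max_missing` or an observed level range
#' (max - min) below `min_range` are dropped, in that order. The filter
#' log records counts removed per rule in application order.
#'
#' @param meth a [methylation_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_range minimum level range across samples (default 0.10).
#' @param min_depth minimum read depth for a usable cell (default 1).
#' @return list of class `smv_matrix`: `level` (samples x retained
#'   sites), `sites`, `filter_log`.
#' @export
call_smvs <- function(meth, max_missing = 0.10, min_range = 0.10,
                      min_depth = 1L) {
  stopifnot(max_missing >= 0, max_missing <= 1,
            min_range >= 0, min_range <= 1)
  lv <- meth$level
  lv[meth$depth < min_depth] <- NA_real_
  missfrac <- colMeans(is.na(lv))
  keep1 <- missfrac <= max_missing
  rng <- apply(lv, 2, function(x)
    if (all(is.na(x))) 0 else diff(range(x, na.rm = TRUE)))
  keep2 <- keep1 & rng >= min_range
  log <- c(input = ncol(lv), missing = sum(!keep1),
           range = sum(keep1) - sum(keep2), retained = sum(keep2))
  if (sum(keep2) == 0) stop("no SMVs retained after filtering")
  structure(list(level = lv[, keep2, drop = FALSE],
                 sites = meth$sites[keep2, , drop = FALSE],
                 samples = meth$samples, filter_log = log),
            class = "smv_matrix")
}

# y for one climate variable, aligned to a set of samples through their
# population assignment
climate_response <- function(climate, variable, sample_population) {
  if (!variable %in% climate$variables)
    stop("variable ", variable, " absent from climate table")
  pops <- unname(sample_population)
  miss <- setdiff(unique(pops), climate$sites)
  if (length(miss))
    stop("populations without climate rows: ", paste(miss, collapse = ", "))
  climate$values[pops, variable]
}

#' Methylation-climate EWAS
#'
#' Per climate variable, fits the kinship-corrected LMM ([fit_lmm()])
#' with the climate variable as response and each SMV's methylation
#' level as explanatory variable (kinship estimated from the methylation
#' matrix itself), and flags markers at or below that variable's
#' permutation-derived threshold. A marker may hit several variables;
#' hits are reported per (marker, variable) pair.
#'
#' @param smvs an `smv_matrix` from [call_smvs()].
#' @param climate a [climate_table()].
#' @param sample_population named vector mapping each SMV sample to a
#'   population (climate row).
#' @param variables climate variables to scan (default all).
#' @param thresholds named per-variable p-value thresholds (e.g. from
#'   [permutation_threshold()]).
#' @param K optional kinship matrix; default [kinship()] of the SMV
#'   levels.
#' @return list `hits` (significant pairs), `scans` (full per-variable
#'   scan tables), `K`.
#' @export
ewas_scan <- function(smvs, climate, sample_population,
                      variables = climate$variables, thresholds, K = NULL) {
  stopifnot(inherits(smvs, "smv_matrix"))
  if (is.null(K)) K <- kinship(smvs$level, kind = "methylation")
  scans <- list(); hits <- list()
  for (v in variables) {
    y <- climate_response(climate, v, sample_population[smvs$samples])
    fit <- fit_lmm(y, smvs$level, K)
    sc <- fit$scan
    sc$variable <- v
    thr <- thresholds[[v]]
    if (is.null(thr)) stop("no threshold supplied for ", v)
    sc$significant <- !is.na(sc$p) & sc$p <= thr
    scans[[v]] <- sc
    hits[[v]] <- sc[sc$significant, , drop = FALSE]
  }
  list(hits = do.call(rbind, hits), scans = scans, K = K)
}

#' SNP-climate association scan (LMM-GEA)
#'
#' Per climate variable, fits the kinship-corrected LMM with genotype
#' dosage as the explanatory variable (kinship from the genotypes).
#' Significance is by BH q-value (default, `q <= q_cutoff`) or by
#' per-variable permutation thresholds. Also returns the per-variable
#' hit counts and their pairwise overlaps (Venn-style table).
#'
#' @param G a [genotype_matrix()].
#' @param climate a [climate_table()].
#' @param map a [population_map()] covering the genotype samples.
#' @param variables climate variables to scan.
#' @param correction `"fdr"` or `"permutation"`.
#' @param q_cutoff BH q cutoff (default 0.05).
#' @param thresholds per-variable p thresholds when
#'   `correction = "permutation"`.
#' @param K optional precomputed kinship.
#' @return list `hits`, `scans`, `per_variable` counts, `overlap`
#'   (pairwise hit-set overlaps), `K`.
#' @export
gea_scan <- function(G, climate, map, variables = climate$variables,
                     correction = c("fdr", "permutation"),
                     q_cutoff = 0.05, thresholds = NULL, K = NULL) {
  correction <- match.arg(correction)
  if (is.null(K)) K <- kinship(G$dosage, kind = "genotype")
  samp_pop <- map$assignments[G$samples]
  scans <- list(); hit_ids <- list(); hits <- list()
  for (v in variables) {
    y <- climate_response(climate, v, samp_pop)
    fit <- fit_lmm(y, G$dosage, K)
    sc <- fit$scan
    sc$variable <- v
    if (correction == "fdr") {
      sc$q <- NA_real_
      ok <- !is.na(sc$p)
      sc$q[ok] <- adjust_fdr(sc$p[ok])
      sc$significant <- !is.na(sc$q) & sc$q <= q_cutoff
    } else {
      thr <- thresholds[[v]]
      if (is.null(thr)) stop("no permutation threshold supplied for ", v)
      sc$significant <- !is.na(sc$p) & sc$p <= thr
    }
    scans[[v]] <- sc
    hit_ids[[v]] <- sc$marker[sc$significant]
    hits[[v]] <- sc[sc$significant, , drop = FALSE]
  }
  nv <- length(variables)
  overlap <- matrix(0L, nv, nv, dimnames = list(variables, variables))
  for (i in seq_len(nv)) for (j in seq_len(nv))
    overlap[i, j] <- length(intersect(hit_ids[[i]], hit_ids[[j]]))
  list(hits = do.call(rbind, hits), scans = scans,
       per_variable = vapply(hit_ids, length, integer(1)),
       overlap = overlap, K = K)
}

#' Annotate hits with nearby genomic features
#'
#' For each hit position, lists every feature whose interval expanded by
#' `window` bp contains the position: distance 0 for overlap, else the
#' bp gap, with the boundary inclusive (a hit exactly `window` bp beyond
#' a feature end is included). Results are ordered by distance then
#' feature id. Hits on chromosomes absent from the feature table get an
#' empty list and are counted in the log.
#'
#' @param hits data frame with columns `marker`, `chrom`, `pos0`
#'   (0-based position).
#' @param features a [feature_table()].
#' @param window flank in bp (default 10000).
#' @return list `annotated` (long data frame `marker, feature, distance`),
#'   `n_unmatched_chrom`.
#' @export
annotate_proximal <- function(hits, features, window = 10000L) {
  stopifnot(all(c("marker", "chrom", "pos0") %in% names(hits)))
  out <- list(); unmatched <- 0L
  for (i in seq_len(nrow(hits))) {
    fe <- features[features$chrom == hits$chrom[i], , drop = FALSE]
    if (!nrow(fe)) {
      unmatched <- unmatched + !any(features$chrom == hits$chrom[i])
      next
    }
    p <- hits$pos0[i]
    dist <- ifelse(p < fe$start0, fe$start0 - p,
                   ifelse(p >= fe$end0, p - fe$end0 + 1L, 0L))
    sel <- which(dist <= window)
    if (!length(sel)) next
    ord <- sel[order(dist[sel], fe$id[sel])]
    out[[length(out) + 1]] <- data.frame(marker = hits$marker[i],
                                         feature = fe$id[ord],
                                         distance = dist[ord],
                                         stringsAsFactors = FALSE)
  }
  list(annotated = if (length(out)) do.call(rbind, out)
       else data.frame(marker = character(0), feature = character(0),
                       distance = integer(0)),
       n_unmatched_chrom = unmatched)
}
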