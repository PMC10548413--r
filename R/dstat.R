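# Frequency-based ABBA-BABA (Patterson's D) with delete-one block
# jackknife standard errors, plus the topology-free Dmin variant.

#' Per-population derived-allele frequencies
#'
#' With an outgroup population, the outgroup's major allele is taken as
#' ancestral; without one, the global minor allele is treated as derived
#' (policy recorded on the result).
#'
#' @param G a [genotype_matrix()].
#' @param map a [population_map()].
#' @param outgroup optional population code used to polarize alleles.
#' @return matrix populations x loci of derived-allele frequencies, with
#'   attributes `polarization` and `loci` (chrom/pos0 of the columns).
#' @export
derived_freqs <- function(G, map, outgroup = NULL) {
  st <- pop_locus_stats(G, map)
  p <- ifelse(st$n > 0, st$p, NA_real_)
  rownames(p) <- st$pops
  if (is.null(outgroup)) {
    glob <- colMeans(G$dosage, na.rm = TRUE) / 2
    flip <- glob > 0.5
    pol <- "global-minor-allele-as-derived"
  } else {
    if (!outgroup %in% st$pops) stop("outgroup ", outgroup, " not in map")
    flip <- !is.na(p[outgroup, ]) & p[outgroup, ] > 0.5
    pol <- paste0("outgroup-", outgroup, "-major-as-ancestral")
  }
  p[, flip] <- 1 - p[, flip]
  attr(p, "polarization") <- pol
  attr(p, "loci") <- G$loci
  p
}

jackknife_d <- function(abba, baba, block) {
  blocks <- unique(block)
  B <- length(blocks)
  if (B < 2) stop("need at least 2 jackknife blocks")
  sa <- sum(abba); sb <- sum(baba)
  if (sa + sb == 0) stop("D undefined: nABBA + nBABA = 0")
  d <- (sa - sb) / (sa + sb)
  d_loo <- vapply(blocks, function(b) {
    keep <- block != b
    (sum(abba[keep]) - sum(baba[keep])) / (sum(abba[keep]) + sum(baba[keep]))
  }, numeric(1))
  se <- sqrt((B - 1) / B * sum((d_loo - mean(d_loo))^2))
  list(n_abba = sa, n_baba = sb, d = d, se = se,
       z = if (se > 0) d / se else NA_real_, n_blocks = B, d_loo = d_loo)
}

#' ABBA-BABA D statistic on population allele frequencies
#'
#' Per locus with derived frequencies `p1, p2, p3` (outgroup ancestral,
#' frequency 0): `abba = (1-p1) p2 p3`, `baba = p1 (1-p2) p3`;
#' `D = (nABBA - nBABA)/(nABBA + nBABA)` over summed weights, with a
#' delete-one jackknife over contiguous locus blocks giving the standard
#' error and `Z = D/se`. An excess of ABBA (D > 0) indicates gene flow
#' between P2 and P3.
#'
#' @param freqs populations x loci derived-frequency matrix (see
#'   [derived_freqs()]); loci with missing frequency in the trio are
#'   dropped.
#' @param trio character vector `(P1, P2, P3)` of population codes.
#' @param block_size loci per jackknife block; default gives ~20 blocks.
#' @return list of class `dstat_result`: `trio`, `n_abba`, `n_baba`, `d`,
#'   `se`, `z`, `n_blocks`, `polarization`.
#' @export
abba_baba <- function(freqs, trio, block_size = NULL) {
  stopifnot(length(trio) == 3, all(trio %in% rownames(freqs)))
  p1 <- freqs[trio[1], ]; p2 <- freqs[trio[2], ]; p3 <- freqs[trio[3], ]
  keep <- !(is.na(p1) | is.na(p2) | is.na(p3))
  p1 <- p1[keep]; p2 <- p2[keep]; p3 <- p3[keep]
  L <- length(p1)
  if (is.null(block_size)) block_size <- max(1L, ceiling(L / 20))
  block <- ((seq_len(L) - 1L) %/% block_size) + 1L
  jk <- jackknife_d((1 - p1) * p2 * p3, p1 * (1 - p2) * p3, block)
  structure(c(list(trio = trio,
                   polarization = attr(freqs, "polarization")),
              jk[c("n_abba", "n_baba", "d", "se", "z", "n_blocks",
                   "d_loo")]),
            class = "dstat_result")
}

#' Minimum-|D| statistic over trio rearrangements
#'
#' Computes D for the three arrangements of the trio and returns the one
#' with minimal |D| (its se and z), a topology-agnostic measure of
#' introgression. Ties keep the earliest arrangement in canonical order
#' `(P1,P2;P3), (P1,P3;P2), (P2,P3;P1)`.
#'
#' @inheritParams abba_baba
#' @export
dmin <- function(freqs, trio, block_size = NULL) {
  arr <- list(trio,
              c(trio[1], trio[3], trio[2]),
              c(trio[2], trio[3], trio[1]))
  fits <- lapply(arr, function(a) abba_baba(freqs, a, block_size))
  absd <- vapply(fits, function(f) abs(f$d), numeric(1))
  best <- which(absd <= min(absd) + 1e-15)[1]
  out <- fits[[best]]
  out$arrangement <- best
  out$d_min <- out$d
  out
}

#' @export
print.dstat_result <- function(x, ...) {
  cat("D(", paste(x$trio, collapse = ","), ") =", round(x$d, 4),
      " se =", signif(x$se, 3), " Z =", round(x$z, 2),
      " [", x$n_blocks, "blocks;", x$polarization, "]\n")
  invisible(x)
}
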