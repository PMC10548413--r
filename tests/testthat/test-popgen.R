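test_that("diversity statistics match closed forms on tiny fixtures", {
  # one population, 2 diploids both heterozygous: p = .5, HO = 1,
  # pi = 2*.25*(4/3) = 2/3
  g <- genotype_matrix(matrix(c(1L, 1L), 2, 1), c("a", "b"), "chr1", 0L)
  sites <- data.frame(population = "P", longitude = 110, latitude = 25,
                      altitude = 0)
  map <- population_map(c(a = "P", b = "P"), sites)
  d <- diversity_stats(g, map)
  expect_equal(d$ho, 1)
  expect_equal(d$pi, 2 / 3)
  # a monomorphic locus contributes pi = 0, HO = 0
  g2 <- genotype_matrix(cbind(c(1L, 1L), c(0L, 0L)), c("a", "b"),
                        rep("chr1", 2), c(0L, 10L))
  d2 <- diversity_stats(g2, map)
  expect_equal(d2$pi, 1 / 3)
  expect_equal(d2$ho, 0.5)
})

test_that("diversity values match a per-locus spreadsheet audit on a 3-population table", {
  fx <- random_genotypes(n_pops = 3, n_per = 5, n_loci = 6, seed = 11)
  d <- diversity_stats(fx$g, fx$map)
  for (k in seq_along(levels(fx$pop))) {
    dos <- fx$g$dosage[fx$pop == levels(fx$pop)[k], , drop = FALSE]
    pis <- hos <- hes <- numeric(ncol(dos))
    for (l in seq_len(ncol(dos))) {
      gl <- dos[!is.na(dos[, l]), l]
      n <- length(gl); p <- sum(gl) / (2 * n)
      pis[l] <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
      hos[l] <- mean(gl == 1)
      hes[l] <- 2 * p * (1 - p)
    }
    expect_equal(d$pi[k], mean(pis))
    expect_equal(d$ho[k], mean(hos))
    expect_equal(d$fis[k], 1 - sum(hos) / sum(hes))
  }
})

test_that("wc_fst equals a direct transcription of the variance-component formulas", {
  for (seed in 1:20) {
    fx <- random_genotypes(n_pops = sample(2:5, 1), n_per = sample(3:8, 1),
                           n_loci = sample(3:10, 1),
                           missing = sample(c(0, .1), 1), seed = seed)
    fst <- wc_fst(fx$g, fx$map)
    expect_equal(fst$global_theta,
                 wc_oracle_theta(fx$g$dosage, fx$pop),
                 tolerance = 1e-10)
  }
})

test_that("theta is 1 for fixed alternate populations and ~0 for identical ones", {
  # two populations fixed for alternate alleles, no heterozygotes
  dos <- rbind(matrix(0L, 5, 3), matrix(2L, 5, 3))
  s <- paste0("i", 1:10)
  g <- genotype_matrix(dos, s, rep("chr1", 3), c(0L, 10L, 20L))
  sites <- data.frame(population = c("A", "B"), longitude = c(110, 112),
                      latitude = c(25, 26), altitude = 0)
  map <- population_map(setNames(rep(c("A", "B"), each = 5), s), sites)
  expect_equal(wc_fst(g, map)$global_theta, 1)
  # identical genotype tables in both populations
  half <- matrix(sample(0:2, 5 * 20, replace = TRUE), 5)
  g2 <- genotype_matrix(rbind(half, half), s, rep("chr1", 20),
                        seq_len(20) * 10L)
  th <- wc_fst(g2, map)$global_theta
  expect_lt(th, 0.02)
})

test_that("theta is invariant to allele relabeling and sample order", {
  fx <- random_genotypes(n_pops = 3, n_per = 6, n_loci = 8, seed = 3)
  base <- wc_fst(fx$g, fx$map)
  # flip reference/alternate at every locus
  gflip <- genotype_matrix(2L - fx$g$dosage, fx$g$samples,
                           fx$g$loci$chrom, fx$g$loci$pos0)
  expect_equal(wc_fst(gflip, fx$map)$global_theta, base$global_theta,
               tolerance = 1e-12)
  # permute samples
  pm <- sample(length(fx$g$samples))
  gperm <- genotype_matrix(fx$g$dosage[pm, ], fx$g$samples[pm],
                           fx$g$loci$chrom, fx$g$loci$pos0)
  expect_equal(wc_fst(gperm, fx$map)$global_theta, base$global_theta)
  expect_equal(diversity_stats(gperm, fx$map)$pi,
               diversity_stats(fx$g, fx$map)$pi)
})

test_that("pairwise theta from two populations alone matches the matrix entry", {
  fx <- random_genotypes(n_pops = 4, n_per = 5, n_loci = 10, seed = 5)
  full <- wc_fst(fx$g, fx$map)
  keep <- fx$pop %in% c("B", "D")
  gsub <- genotype_matrix(fx$g$dosage[keep, ], fx$g$samples[keep],
                          fx$g$loci$chrom, fx$g$loci$pos0)
  mapsub <- population_map(fx$map$assignments[fx$g$samples[keep]],
                           fx$map$sites[fx$map$sites$population %in%
                                          c("B", "D"), ])
  expect_equal(wc_fst(gsub, mapsub)$theta["B", "D"],
               full$theta["B", "D"], tolerance = 1e-12)
})

test_that("PCoA recovers planar configurations and matches an eigen oracle", {
  set.seed(9)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  fit <- pcoa(D, k = 2)
  expect_equal(as.matrix(dist(fit$coords)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  # all-zero distances -> all-zero coordinates
  expect_true(all(abs(suppressWarnings(
    pcoa(matrix(0, 4, 4), k = 2))$coords) < 1e-12))
  # non-Euclidean 5x5: eigenvalues match a direct double-centering oracle
  D5 <- matrix(0, 5, 5)
  D5[upper.tri(D5)] <- c(3, 5, 7, 4, 6, 8, 2, 9, 1, 5)
  D5 <- D5 + t(D5)
  fit5 <- suppressWarnings(pcoa(D5, k = 4))
  J <- diag(5) - matrix(1 / 5, 5, 5)
  B <- -0.5 * J %*% D5^2 %*% J
  ev <- sort(eigen(B, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(sort(fit5$eigenvalues, decreasing = TRUE)[1:4], ev[1:4],
               tolerance = 1e-8)
  expect_gt(fit5$n_negative, 0)
})

test_that("linearized F_ST is monotone and clamps F >= 1", {
  x <- c(-.05, 0, .1, .5, .9)
  expect_equal(linearize_fst(x), x / (1 - x))
  expect_true(all(diff(linearize_fst(x)) > 0))
  expect_warning(y <- linearize_fst(c(.2, 1)), "clamped")
  expect_equal(y[2], .Machine$double.xmax)
})
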