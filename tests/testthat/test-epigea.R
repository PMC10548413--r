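make_meth <- function(level, depth = NULL) {
  n <- nrow(level); s <- ncol(level)
  if (is.null(depth)) depth <- matrix(10L, n, s)
  methylation_table(level, depth, paste0("i", seq_len(n)),
                    data.frame(chrom = "sc1", pos0 = seq_len(s) * 100L,
                               context = "CpG"))
}

test_that("SMV filters apply depth, missingness and range rules in order", {
  # 6 engineered sites: 1 removed by missingness, 2 by range, 3 kept
  lv <- cbind(c(.1, .5, .9, NA, NA, NA, NA, NA, NA, NA),   # 70% missing
              rep(.3, 10),                                  # range 0
              seq(.30, .345, length.out = 10),              # range .045
              seq(.1, .9, length.out = 10),
              c(rep(.2, 9), .5),
              c(.05, rep(.6, 9)))
  m <- make_meth(lv)
  smv <- call_smvs(m, max_missing = .10, min_range = .10)
  expect_equal(unname(smv$filter_log),
               c(6L, 1L, 2L, 3L))
  expect_equal(ncol(smv$level), 3L)
  # identical-level site always removed by the range rule
  expect_error(call_smvs(make_meth(matrix(.3, 10, 1))), "no SMVs")
  # a site missing in 6 of 13 samples is removed
  lv2 <- cbind(c(rep(NA, 6), seq(.1, .9, length.out = 7)),
               seq(.1, .9, length.out = 13))
  m2 <- make_meth(lv2)
  expect_equal(ncol(call_smvs(m2)$level), 1L)
  # retention invariant to sample and site order
  pm <- sample(10); ps <- sample(6)
  m3 <- methylation_table(lv[pm, ps], matrix(10L, 10, 6),
                          paste0("i", seq_len(10))[pm],
                          data.frame(chrom = "sc1",
                                     pos0 = (seq_len(6) * 100L)[ps],
                                     context = "CpG"))
  expect_equal(unname(call_smvs(m3)$filter_log),
               unname(smv$filter_log))
})

test_that("min_depth masks shallow cells before the missingness rule", {
  lv <- cbind(seq(.1, .9, length.out = 10))
  dp <- matrix(10L, 10, 1); dp[1:3] <- 2L
  m <- make_meth(lv, dp)
  # with min_depth 4, 30% of cells become missing -> site dropped
  expect_error(call_smvs(m, min_depth = 4), "no SMVs")
  expect_equal(ncol(call_smvs(m, min_depth = 1)$level), 1L)
})

test_that("EWAS thresholds gate hits and planted sites are recovered", {
  spec <- landscape_spec(seed = 31)
  land <- simulate_landscape(spec)
  me <- simulate_methylation(spec, land$popmap, land$current,
                             n_sites = 300, n_assoc = 1, effect = 6,
                             noise_sd = .05, sigma_g = .1,
                             depth_mean = 300, depth_size = 100)
  smv <- call_smvs(me$methylation)
  spp <- me$truth$sample_population
  thr0 <- as.list(setNames(rep(0, 5), land$current$variables))
  ew0 <- ewas_scan(smv, land$current, spp, thresholds = thr0)
  expect_equal(nrow(ew0$hits), 0L)
  thr <- as.list(setNames(rep(1e-3, 5), land$current$variables))
  ew <- ewas_scan(smv, land$current, spp, thresholds = thr)
  hit_markers <- unique(ew$hits$marker[ew$hits$variable == spec$driver])
  expect_true(me$truth$smv_assoc_ids %in% hit_markers)
  expect_error(ewas_scan(smv, land$current, spp,
                         variables = "BIO99", thresholds = thr),
               "BIO99")
})

test_that("GEA recovers clinal loci with BH-controlled false positives", {
  spec <- landscape_spec(n_neutral = 1200, n_adaptive = 30,
                         cline_strength = 3, seed = 37)
  land <- simulate_landscape(spec)
  sim <- suppressMessages(simulate_genotypes(spec, land$popmap,
                                             land$current))
  gea <- suppressMessages(gea_scan(sim$genotypes, land$current, land$popmap,
                                   variables = spec$driver))
  hit <- gea$hits$marker
  truth <- sim$truth$adaptive_locus_ids
  expect_gte(mean(truth %in% hit), .6)
  fp <- setdiff(hit, truth)
  # BH at q <= .05: false positives a small fraction of discoveries
  expect_lte(length(fp), max(5, .25 * length(hit)))
})

test_that("null GEA p-values are uniform", {
  spec <- landscape_spec(n_pops = 13, n_per_pop = 12, n_neutral = 800,
                         n_adaptive = 0, seed = 41)
  land <- simulate_landscape(spec)
  sim <- suppressMessages(simulate_genotypes(spec, land$popmap,
                                             land$current))
  gea <- suppressMessages(gea_scan(sim$genotypes, land$current, land$popmap,
                                   variables = "BIO4"))
  p <- gea$scans$BIO4$p
  ks <- ks.test(p[!is.na(p)], "punif")
  expect_gt(ks$p.value, .01)
})

test_that("proximity annotation honours the inclusive window boundary", {
  ft <- feature_table(c("chr1", "chr1", "chr2"),
                      c(1000L, 40000L, 0L), c(2000L, 42000L, 500L),
                      c("gA", "gB", "gC"))
  hits <- data.frame(marker = c("in", "edge", "beyond", "far", "nochrom"),
                     chrom = c("chr1", "chr1", "chr1", "chr1", "chrX"),
                     pos0 = c(1500L, 2000L + 10000L - 1L, 2000L + 10000L,
                              30000L, 100L))
  ann <- annotate_proximal(hits, ft, window = 10000L)
  a <- ann$annotated
  expect_equal(a$distance[a$marker == "in"], 0L)
  # exactly window bp beyond the end (1-based gap = window) is included
  expect_true("edge" %in% a$marker)
  expect_equal(a$distance[a$marker == "edge"], 10000L)
  # window + 1 is excluded
  expect_false("beyond" %in% a$marker[a$feature == "gA"])
  expect_equal(ann$n_unmatched_chrom, 1L)
})

test_that("annotation matches a brute-force all-pairs scan", {
  set.seed(43)
  st <- sample(0:200000, 15)
  ft <- feature_table(rep(c("chr1", "chr2"), c(8, 7)),
                      st, st + sample(500:3000, 15),
                      sprintf("f%02d", 1:15))
  hits <- data.frame(marker = sprintf("h%02d", 1:20),
                     chrom = sample(c("chr1", "chr2"), 20, TRUE),
                     pos0 = sample(0:220000, 20))
  ann <- annotate_proximal(hits, ft, window = 10000L)$annotated
  # quadratic oracle
  oracle <- list()
  for (i in 1:20) for (j in 1:15) {
    if (hits$chrom[i] != ft$chrom[j]) next
    p <- hits$pos0[i]
    d <- if (p >= ft$start0[j] && p < ft$end0[j]) 0L
         else if (p < ft$start0[j]) ft$start0[j] - p
         else p - ft$end0[j] + 1L
    if (d <= 10000L)
      oracle[[length(oracle) + 1]] <- data.frame(marker = hits$marker[i],
                                                 feature = ft$id[j],
                                                 distance = d)
  }
  odf <- do.call(rbind, oracle)
  key <- function(d) sort(paste(d$marker, d$feature, d$distance))
  expect_equal(key(ann), key(odf))
})
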