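gf_fixture <- function(seed = 1, n_pops = 13, L = 40) {
  spec <- landscape_spec(n_pops = n_pops, n_per_pop = 12,
                         n_neutral = L, n_adaptive = 10,
                         cline_strength = 3, seed = seed)
  land <- simulate_landscape(spec)
  sim <- suppressMessages(simulate_genotypes(spec, land$popmap,
                                             land$current))
  fr <- population_freqs(sim$genotypes, land$popmap)
  list(spec = spec, land = land, fr = fr, truth = sim$truth)
}

test_that("gradient-forest fits are deterministic given the seed", {
  fx <- gf_fixture(seed = 3)
  m1 <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                             ntree = 50, seed = 9))
  m2 <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                             ntree = 50, seed = 9))
  expect_identical(m1$cumimp, m2$cumimp)
  expect_identical(m1$r2, m2$r2)
})

test_that("turnover functions are non-decreasing, start at zero and sum to the totals", {
  fx <- gf_fixture(seed = 5)
  m <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                            ntree = 100, seed = 1))
  for (v in m$predictors) {
    ci <- m$cumimp[[v]]
    expect_equal(ci[1], 0)
    expect_true(all(diff(ci) >= -1e-15))
    expect_equal(ci[length(ci)], unname(m$importance[v]), tolerance = 1e-9)
  }
})

test_that("climate transformation interpolates, clamps and preserves monotonicity", {
  fx <- gf_fixture(seed = 7)
  m <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                            ntree = 100, seed = 2))
  # point at every predictor's observed minimum maps to the zero vector
  pmin_ <- t(sapply(m$predictors, function(v) m$bin_edges[[v]][1]))
  colnames(pmin_) <- m$predictors
  expect_true(all(transform_climate(m, pmin_) == 0))
  # componentwise larger point transforms componentwise >=
  mid <- colMeans(fx$land$current$values)
  hi <- mid + apply(fx$land$current$values, 2, sd)
  tr <- transform_climate(m, rbind(mid, hi))
  expect_true(all(tr[2, ] - tr[1, ] >= -1e-12))
  # interpolation equals a standalone piecewise-linear oracle at midpoints
  v <- m$predictors[1]
  e <- m$bin_edges[[v]]; ci <- m$cumimp[[v]]
  mids <- (e[-1] + e[-length(e)]) / 2
  pts <- matrix(rep(colMeans(fx$land$current$values), each = length(mids)),
                nrow = length(mids),
                dimnames = list(NULL, m$predictors))
  pts[, v] <- mids
  got <- transform_climate(m, pts)[, v]
  want <- sapply(mids, function(x) {
    i <- findInterval(x, e, rightmost.closed = TRUE)
    ci[i] + (ci[i + 1] - ci[i]) * (x - e[i]) / (e[i + 1] - e[i])
  })
  expect_equal(got, want, tolerance = 1e-12)
  # beyond-range points clamp to end values
  far <- pts[1:2, , drop = FALSE]
  far[1, v] <- e[1] - 100; far[2, v] <- e[length(e)] + 100
  trf <- transform_climate(m, far)
  expect_equal(unname(trf[1, v]), ci[1])
  expect_equal(unname(trf[2, v]), ci[length(ci)])
  expect_equal(attr(trf, "n_clamped"), 2L)
})

test_that("offsets vanish when future equals current and forward <= local", {
  fx <- gf_fixture(seed = 11)
  m <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                            ntree = 100, seed = 3))
  same <- climate_table(fx$land$current$values, "same")
  lo <- local_offset(m, fx$land$current, same)
  fo <- forward_offset(m, fx$land$current, same)
  expect_true(all(lo$local_offset == 0))
  expect_true(all(fo$forward_offset == 0))
  fut <- fx$land$futures[[2]]
  lo2 <- local_offset(m, fx$land$current, fut)
  fo2 <- forward_offset(m, fx$land$current, fut)
  expect_true(all(lo2$local_offset >= 0))
  expect_true(all(fo2$forward_offset <= lo2$local_offset + 1e-12))
})

test_that("forward offset equals a brute-force all-pairs minimum on 5 sites", {
  fx <- gf_fixture(seed = 13, n_pops = 5)
  m <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                            ntree = 100, seed = 4))
  fut <- fx$land$futures[[1]]
  fo <- forward_offset(m, fx$land$current, fut)
  tc <- transform_climate(m, fx$land$current$values)
  tf <- transform_climate(m, fut$values)
  for (i in 1:5) {
    brute <- min(sapply(1:5, function(j) sqrt(sum((tc[i, ] - tf[j, ])^2))))
    expect_equal(fo$forward_offset[i], brute, tolerance = 1e-12)
  }
})

test_that("offset is invariant to duplicating every locus", {
  fx <- gf_fixture(seed = 17)
  m1 <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                             ntree = 60, seed = 5))
  m2 <- suppressMessages(fit_gradient_forest(cbind(fx$fr, fx$fr),
                                             fx$land$current,
                                             ntree = 60, seed = 5))
  fut <- fx$land$futures[[1]]
  o1 <- local_offset(m1, fx$land$current, fut)$local_offset
  o2 <- local_offset(m2, fx$land$current, fut)$local_offset
  # same loci twice: mean importance profile over loci is similar (the
  # forest stream differs, so equality is statistical, not bitwise)
  expect_equal(o1, o2, tolerance = .25)
  expect_equal(sum(m1$importance), sum(m2$importance), tolerance = .25)
})

test_that("a step-function response concentrates importance near the threshold", {
  set.seed(19)
  n <- 20
  x <- seq(0, 1, length.out = n)
  clim <- climate_table(matrix(x, n, 1,
                               dimnames = list(paste0("P", 1:n), "VAR")))
  thr <- 0.52
  y <- matrix(ifelse(x > thr, .8, .2) + rnorm(n, 0, .01), n, 1,
              dimnames = list(paste0("P", 1:n), "L1"))
  m <- fit_gradient_forest(y, clim, ntree = 300, n_bins = 100, seed = 6)
  imp <- diff(m$cumimp$VAR)
  e <- m$bin_edges$VAR
  centers <- (e[-1] + e[-length(e)]) / 2
  near <- abs(centers - thr) <= 0.05 * diff(range(x))
  expect_gte(sum(imp[near]) / sum(imp), .5)
})

test_that("nested displacement scenarios give monotone per-site offsets", {
  fx <- gf_fixture(seed = 23)
  m <- suppressMessages(fit_gradient_forest(fx$fr, fx$land$current,
                                            ntree = 100, seed = 7))
  rep_ <- offset_report(m, fx$land$current, fx$land$futures)
  expect_true(all(rep_$monotone))
  expect_equal(nrow(rep_$offsets), 3 * 13)
})

test_that("driver variable ranks first in importance for clinal loci", {
  firsts <- 0
  for (s in 1:5) {
    spec <- landscape_spec(n_pops = 13, n_neutral = 0, n_adaptive = 40,
                           cline_strength = 4, seed = 100 + s)
    land <- simulate_landscape(spec)
    sim <- suppressMessages(simulate_genotypes(spec, land$popmap,
                                               land$current))
    fr <- population_freqs(sim$genotypes, land$popmap)
    m <- suppressMessages(fit_gradient_forest(fr, land$current,
                                              ntree = 150, seed = s))
    top <- names(which.max(m$importance))
    # BIO16 drives the clines; BIO19 is spatially correlated with it
    if (top %in% c("BIO16", "BIO19")) firsts <- firsts + 1
  }
  expect_gte(firsts, 4)
})

test_that("forest skill agrees with randomForest on a strong signal", {
  skip_if_not_installed("randomForest")
  set.seed(29)
  n <- 30
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] * .2 + rnorm(n, 0, .02)
  clim <- climate_table(`rownames<-`(X, paste0("P", 1:n)))
  m <- fit_gradient_forest(matrix(plogis(y), n, 1,
                                  dimnames = list(paste0("P", 1:n), "L")),
                           clim, ntree = 300, seed = 8)
  rf <- randomForest::randomForest(X, plogis(y), ntree = 300)
  r2_rf <- 1 - min(rf$mse) / var(plogis(y)) * (n - 1) / n
  expect_gt(m$r2[1], .3)
  expect_gt(r2_rf, .3)
  expect_equal(names(which.max(m$importance)), "a")
})
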