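sites13 <- kiwifruit_sites()
map13 <- population_map(
  setNames(sites13$population, paste0(sites13$population, "_1")),
  sites13[, 1:4])

test_that("great-circle distances match a direct haversine evaluation", {
  d <- geographic_distance(map13)
  expect_true(isSymmetric(unname(d)))
  expect_true(all(diag(d) == 0))
  # WH (115°23'E, 23°52'N) to LY (119°24'E, 26°27'N)
  wh <- sites13[sites13$population == "WH", ]
  ly <- sites13[sites13$population == "LY", ]
  expect_equal(d["WH", "LY"],
               haversine_oracle(wh$longitude, wh$latitude,
                                ly$longitude, ly$latitude),
               tolerance = 0.1 / d["WH", "LY"])
  # every pair against the oracle
  for (i in 1:12) for (j in (i + 1):13)
    expect_equal(d[i, j],
                 haversine_oracle(sites13$longitude[i], sites13$latitude[i],
                                  sites13$longitude[j], sites13$latitude[j]),
                 tolerance = 1e-6)
  dl <- geographic_distance(map13, log_transform = TRUE)
  expect_equal(dl["WH", "LY"], log(d["WH", "LY"]))
  expect_true(all(diag(dl) == 0))
})

test_that("coincident sites with log transform fail with guidance", {
  s2 <- sites13[c(1, 1, 2, 3), ]
  s2$population <- c("A", "B", "C", "D")
  m <- population_map(setNames(s2$population, paste0("x", 1:4)), s2)
  expect_error(geographic_distance(m, log_transform = TRUE), "jitter")
})

test_that("greedy variable selection enforces |r| < r_max", {
  set.seed(2)
  base <- matrix(rnorm(13 * 3), 13)
  v <- cbind(A = base[, 1], B = base[, 1],
             C = base[, 2], D = base[, 3])
  rownames(v) <- paste0("P", 1:13)
  ct <- climate_table(v)
  kept <- select_uncorrelated(ct, r_max = .8)
  expect_true("A" %in% kept && !("B" %in% kept))  # earlier of a tied pair
  expect_true(all(c("C", "D") %in% kept))
  # mutually uncorrelated: all retained
  set.seed(3)
  u <- matrix(rnorm(13 * 4), 13,
              dimnames = list(paste0("P", 1:13), LETTERS[1:4]))
  expect_equal(select_uncorrelated(climate_table(u), .8), LETTERS[1:4])
  # retained set always satisfies the pairwise property (7-variable blocks)
  set.seed(4)
  w <- cbind(matrix(rnorm(20 * 2), 20) %*% matrix(rnorm(8), 2),
             matrix(rnorm(20 * 3), 20))
  colnames(w) <- paste0("V", 1:7); rownames(w) <- paste0("S", 1:20)
  kept7 <- select_uncorrelated(climate_table(w), .8)
  cm <- abs(cor(w[, kept7])); diag(cm) <- 0
  expect_true(all(cm < .8))
})

test_that("environmental distance is rotation-invariant at full rank", {
  set.seed(5)
  v <- matrix(rnorm(13 * 5), 13,
              dimnames = list(paste0("P", 1:13), paste0("BIO", 1:5)))
  ct <- climate_table(v)
  d_full <- environmental_distance(ct, n_pc = 5)
  d_std <- as.matrix(dist(scale(v)))
  expect_equal(unname(d_full), unname(d_std), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(sum(attr(d_full, "explained")[1:3]), .5)
  # identical climate rows -> zero distance
  v2 <- v; v2[2, ] <- v2[1, ]
  d2 <- environmental_distance(climate_table(v2), n_pc = 3)
  expect_equal(d2[1, 2], 0)
  # n_pc = 2 equals a direct eigen-PCA oracle
  d_2 <- environmental_distance(ct, n_pc = 2)
  z <- scale(v)
  eo <- eigen(cov(z))
  sc <- z %*% eo$vectors[, 1:2]
  expect_equal(unname(d_2), unname(as.matrix(dist(sc))), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Mantel statistic hits the exact bounds on constructed inputs", {
  set.seed(6)
  A <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_equal(mantel(A, A, n_perm = 99)$r, 1)
  B <- A; off <- row(B) != col(B)
  B[off] <- max(A) + 1 - A[off]
  expect_equal(mantel(A, B, n_perm = 99)$r, -1)
  expect_error(mantel(A, matrix(0, 6, 6)), "degenerate")
})

test_that("sampled Mantel p agrees with exhaustive enumeration on 4 sites", {
  set.seed(7)
  A <- as.matrix(dist(matrix(rnorm(8), 4)))
  B <- as.matrix(dist(matrix(rnorm(8), 4)))
  # enumerate all 4! permutations explicitly
  P <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  P <- P[apply(P, 1, function(x) length(unique(x)) == 4), ]
  va <- A[upper.tri(A)]
  r_obs <- cor(va, B[upper.tri(B)])
  r_all <- apply(P, 1, function(pm) {
    Bp <- B[pm, pm]; cor(va, Bp[upper.tri(Bp)])
  })
  p_exact <- mean(r_all >= r_obs - 1e-12)
  fit <- mantel(A, B, n_perm = 4999, seed = 11)
  # sampled p within the 99% binomial band of the enumerated p
  band <- qbinom(c(.005, .995), 4999, p_exact) / 4999
  expect_gte(fit$p, band[1] * 0.9)
  expect_lte(fit$p, band[2] * 1.1 + 1 / 5000)
})

test_that("Mantel r is invariant to monotone affine transforms", {
  set.seed(8)
  A <- as.matrix(dist(matrix(rnorm(10), 5)))
  B <- as.matrix(dist(matrix(rnorm(10), 5)))
  r1 <- mantel(A, B, n_perm = 99, seed = 1)$r
  B2 <- 3 * B + 2; diag(B2) <- 0
  expect_equal(mantel(A, B2, n_perm = 99, seed = 1)$r, r1, tolerance = 1e-12)
})

test_that("our Mantel r agrees with vegan on a fixture", {
  skip_if_not_installed("vegan")
  set.seed(9)
  A <- as.matrix(dist(matrix(rnorm(14), 7)))
  B <- as.matrix(dist(matrix(rnorm(14), 7)))
  vg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(mantel(A, B, n_perm = 99)$r, unname(vg$statistic),
               tolerance = 1e-10)
})

test_that("partial Mantel reduces and matches a residual-correlation oracle", {
  set.seed(10)
  A <- as.matrix(dist(matrix(rnorm(10), 5)))
  B <- as.matrix(dist(matrix(rnorm(10), 5)))
  Cc <- matrix(1, 5, 5); diag(Cc) <- 0
  expect_warning(fit <- partial_mantel(A, B, Cc, n_perm = 99, seed = 1),
                 "constant")
  expect_equal(fit$r, mantel(A, B, n_perm = 99, seed = 1)$r,
               tolerance = 1e-12)
  # A = B gives r = 1 whatever C
  C2 <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_equal(partial_mantel(A, A, C2, n_perm = 99)$r, 1)
  # residual-correlation oracle on a 5x5 fixture
  va <- A[upper.tri(A)]; vb <- B[upper.tri(B)]; vc <- C2[upper.tri(C2)]
  ra <- residuals(lm(va ~ vc)); rb <- residuals(lm(vb ~ vc))
  expect_equal(partial_mantel(A, B, C2, n_perm = 99)$r, cor(ra, rb),
               tolerance = 1e-10)
})

test_that("Mantel type-I error is calibrated at alpha = .05", {
  set.seed(12)
  hits <- 0; n_rep <- 500
  for (i in seq_len(n_rep)) {
    A <- as.matrix(dist(matrix(rnorm(10), 5)))
    B <- as.matrix(dist(matrix(rnorm(10), 5)))
    if (mantel(A, B, n_perm = 99, seed = i)$p <= .05) hits <- hits + 1
  }
  band <- qbinom(c(.005, .995), n_rep, .05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})
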