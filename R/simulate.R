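# Synthetic landscape, genotype and methylation generators.  These emulate
# the processed products of a RADseq + bsRADseq landscape-genomics design:
# island-model neutral structure (Balding-Nichols), climate-clinal adaptive
# loci, spatially structured methylation with planted climate associations.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sampling-site table for the kiwifruit study system
#'
#' Thirteen wild *Actinidia eriantha* sampling sites across subtropical
#' China (population code, decimal longitude/latitude, altitude, sample
#' size), used as the default site layout of the synthetic landscape.
#' @return data frame with columns `population, longitude, latitude,
#'   altitude, n`.
#' @export
kiwifruit_sites <- function() {
  dm <- function(d, m) d + m / 60
  data.frame(
    population = c("WH", "LY", "LiS", "SQ", "RY", "LS", "LC", "DK", "YP",
                   "QY", "GD", "WGS", "HA"),
    longitude = c(dm(115, 23), dm(119, 24), dm(119, 46), dm(118, 3),
                  dm(113, 3), dm(115, 58), dm(116, 50), dm(110, 40),
                  dm(108, 52), dm(112, 6), dm(107, 3), dm(114, 13),
                  dm(117, 26)),
    latitude = c(dm(23, 52), dm(26, 27), dm(28, 15), dm(28, 12), dm(24, 57),
                 dm(29, 33), dm(27, 5), dm(27, 14), dm(27, 9), dm(26, 15),
                 dm(26, 15), dm(27, 29), dm(24, 52)),
    altitude = c(686, 529, 365, 589, 820, 1080, 277, 535, 506, 146, 1113,
                 619, 861),
    n = c(12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 8, 12, 12),
    stringsAsFactors = FALSE)
}

default_climate_gradient <- function() {
  # per-variable linear spatial trend (per degree, centred) + site noise SD;
  # magnitudes typical of WorldClim values over subtropical China
  list(
    BIO2  = list(base = 8,   b_lon = -0.15, b_lat = 0.10, noise = 0.3),
    BIO4  = list(base = 750, b_lon = 5,     b_lat = 15,   noise = 20),
    BIO8  = list(base = 24,  b_lon = 0.10,  b_lat = -0.5, noise = 0.5),
    BIO16 = list(base = 650, b_lon = 25,    b_lat = -15,  noise = 30),
    BIO19 = list(base = 120, b_lon = 10,    b_lat = -8,   noise = 12))
}

default_displacement <- function() {
  # one RCP-like step; scenarios use nested multiples of it
  c(BIO2 = 0.3, BIO4 = 30, BIO8 = 1.5, BIO16 = -40, BIO19 = -10)
}

#' Specify a synthetic landscape
#'
#' Bundles every parameter of the generators. Defaults mirror the study
#' design this package emulates: 13 populations of 12 diploids on the
#' kiwifruit site layout, five bioclimatic variables, global
#' differentiation 0.193, adaptive loci clinal on BIO16.
#'
#' @param n_pops,n_per_pop populations and diploid individuals per
#'   population.
#' @param coords data frame `population, longitude, latitude, altitude`;
#'   default [kiwifruit_sites()] when `n_pops` is 13, else random sites in
#'   the same region.
#' @param climate_gradient per-variable list of `base`, `b_lon`, `b_lat`
#'   (linear trend per centred degree) and `noise` (site SD).
#' @param fst_target Balding-Nichols differentiation F of neutral loci.
#' @param n_neutral,n_adaptive locus counts.
#' @param cline_strength slope of logit population allele frequency per SD
#'   of the driver climate variable at adaptive loci.
#' @param driver name of the climate variable driving adaptive clines.
#' @param missing_rate genotype missingness injected uniformly at random.
#' @param displacement named per-variable future-climate step; scenario k
#'   of `scenarios` shifts climate by k times this vector.
#' @param scenarios labels of nested future scenarios.
#' @param admixture optional `list(donor=, recipient=, f=)` mixing fraction
#'   f of donor population frequencies into the recipient.
#' @param seed integer master seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_pops = 13, n_per_pop = 12, coords = NULL,
                           climate_gradient = default_climate_gradient(),
                           fst_target = 0.193,
                           n_neutral = 5000, n_adaptive = 50,
                           cline_strength = 2, driver = "BIO16",
                           missing_rate = 0,
                           displacement = default_displacement(),
                           scenarios = c("RCP4.5", "RCP6.0", "RCP8.5"),
                           admixture = NULL, seed = 1L) {
  stopifnot(n_pops >= 2, fst_target > 0, fst_target < 1,
            is.finite(cline_strength), n_neutral >= 0, n_adaptive >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(coords)) {
    if (n_pops == 13) coords <- kiwifruit_sites()[, 1:4]
    else coords <- with_seed(seed * 7 + 11, data.frame(
      population = sprintf("P%02d", seq_len(n_pops)),
      longitude = runif(n_pops, 107, 120),
      latitude = runif(n_pops, 23, 30),
      altitude = runif(n_pops, 100, 1200)))
  }
  stopifnot(nrow(coords) == n_pops, driver %in% names(climate_gradient))
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, coords = coords,
                 climate_gradient = climate_gradient,
                 fst_target = fst_target, n_neutral = n_neutral,
                 n_adaptive = n_adaptive, cline_strength = cline_strength,
                 driver = driver, missing_rate = missing_rate,
                 displacement = displacement, scenarios = scenarios,
                 admixture = admixture, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Simulate the landscape: populations, sites and climate tables
#'
#' Climate is a linear function of (centred) longitude and latitude plus
#' Gaussian site noise; future scenarios add nested multiples of the
#' per-variable displacement so that later scenarios displace further.
#'
#' @param spec a [landscape_spec()].
#' @return list with `popmap` ([population_map()]), `current`
#'   ([climate_table()]) and `futures` (named list of climate tables).
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  co <- spec$coords
  samples <- unlist(lapply(co$population, function(p)
    sprintf("%s_%02d", p, seq_len(spec$n_per_pop))))
  assignments <- setNames(rep(co$population, each = spec$n_per_pop), samples)
  popmap <- population_map(assignments, co)
  vars <- names(spec$climate_gradient)
  cur <- with_seed(spec$seed * 13 + 1, {
    m <- sapply(vars, function(v) {
      g <- spec$climate_gradient[[v]]
      g$base + g$b_lon * (co$longitude - mean(co$longitude)) +
        g$b_lat * (co$latitude - mean(co$latitude)) +
        rnorm(nrow(co), 0, g$noise)
    })
    rownames(m) <- co$population
    m
  })
  futures <- lapply(seq_along(spec$scenarios), function(k) {
    shift <- spec$displacement[vars] * k
    climate_table(sweep(cur, 2, shift, "+"), scenario = spec$scenarios[k])
  })
  names(futures) <- spec$scenarios
  list(popmap = popmap, current = climate_table(cur, "current"),
       futures = futures)
}

#' Simulate genotypes under island-model drift plus climate clines
#'
#' Neutral loci draw per-population allele frequencies from the
#' Balding-Nichols Beta distribution at the spec's target F; adaptive loci
#' set population frequencies by a logistic cline on the standardized
#' driver climate variable. Genotypes are binomial(2, freq) per
#' individual. An adaptive locus whose realized genotypes are monomorphic
#' is regenerated (at most 100 attempts).
#'
#' @param spec a [landscape_spec()].
#' @param popmap,climate from [simulate_landscape()] (current climate).
#' @return list with `genotypes` ([genotype_matrix()]) and `truth` (ground
#'   truth: adaptive locus ids, driver, realized population frequencies).
#' @export
simulate_genotypes <- function(spec, popmap, climate) {
  stopifnot(all(popmap$sites$population %in% rownames(climate$values)))
  pops <- popmap$sites$population
  n_pops <- length(pops)
  pop_of <- popmap$assignments
  samples <- names(pop_of)
  n_ind <- length(samples)
  L <- spec$n_neutral + spec$n_adaptive
  Fst <- spec$fst_target
  z <- as.numeric(scale(climate$values[pops, spec$driver]))
  with_seed(spec$seed * 13 + 2, {
    freq <- matrix(NA_real_, n_pops, L)
    if (spec$n_neutral > 0) {
      p0 <- runif(spec$n_neutral, 0.05, 0.95)
      a <- p0 * (1 - Fst) / Fst
      b <- (1 - p0) * (1 - Fst) / Fst
      freq[, seq_len(spec$n_neutral)] <-
        matrix(rbeta(n_pops * spec$n_neutral, rep(a, each = n_pops),
                     rep(b, each = n_pops)), n_pops)
    }
    adaptive_idx <- if (spec$n_adaptive > 0)
      spec$n_neutral + seq_len(spec$n_adaptive) else integer(0)
    # adaptive loci: island-model drift around a logistic clinal mean, so
    # cline_strength = 0 reduces exactly to the neutral Balding-Nichols law
    draw_cline <- function() {
      icpt <- qlogis(runif(1, 0.2, 0.8))
      m <- plogis(icpt + spec$cline_strength * z)
      rbeta(n_pops, m * (1 - Fst) / Fst, (1 - m) * (1 - Fst) / Fst)
    }
    for (j in adaptive_idx) freq[, j] <- draw_cline()
    if (!is.null(spec$admixture)) {
      ad <- spec$admixture
      di <- match(ad$donor, pops); ri <- match(ad$recipient, pops)
      stopifnot(!is.na(di), !is.na(ri))
      freq[ri, ] <- (1 - ad$f) * freq[ri, ] + ad$f * freq[di, ]
    }
    pop_idx <- match(pop_of[samples], pops)
    draw <- function(fcol) rbinom(n_ind, 2L, fcol[pop_idx])
    dos <- matrix(0L, n_ind, L)
    for (j in seq_len(L)) dos[, j] <- draw(freq[, j])
    # regenerate adaptive loci that came out monomorphic
    for (j in adaptive_idx) {
      att <- 0
      while (length(unique(dos[, j])) < 2) {
        att <- att + 1
        if (att > 100) stop("adaptive locus ", j,
                            " monomorphic after 100 attempts")
        freq[, j] <- draw_cline()
        dos[, j] <- draw(freq[, j])
      }
      if (att > 0) message("regenerated adaptive locus ", j,
                           " (", att, " attempts)")
    }
    if (spec$missing_rate > 0) {
      drop <- runif(length(dos)) < spec$missing_rate
      dos[drop] <- NA_integer_
    }
    chrom <- paste0("chr", ((seq_len(L) - 1L) %/% 1000L) + 1L)
    pos0 <- ((seq_len(L) - 1L) %% 1000L) * 500L
    g <- genotype_matrix(dos, samples, chrom, pos0)
    rownames(freq) <- pops
    colnames(freq) <- colnames(g$dosage)
    truth <- list(adaptive_locus_ids = colnames(g$dosage)[adaptive_idx],
                  driver = spec$driver, pop_freq = freq,
                  fst_target = Fst)
    list(genotypes = g, truth = truth)
  })
}

#' Simulate per-cytosine methylation with planted climate associations
#'
#' Background sites follow a logit-normal model: site baseline plus a
#' spatially correlated population random effect (variance `sigma_g^2` on
#' the latent scale, exponential-decay kinship over geographic distance)
#' plus residual noise. Associated sites shift the latent mean by
#' `effect` times the standardized driver variable. Observed levels are
#' binomial(depth, proportion)/depth with negative-binomial depths.
#'
#' @param spec a [landscape_spec()].
#' @param popmap,climate landscape outputs; one individual per population
#'   is simulated by default (`per_pop = 1`), matching a bsRADseq design.
#' @param n_sites,n_assoc total and climate-associated site counts.
#' @param effect latent-scale slope per SD of the driver variable.
#' @param noise_sd residual latent SD.
#' @param sigma_g SD of the population random effect on the latent scale.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param per_pop individuals per population.
#' @return list with `methylation` ([methylation_table()]) and `truth`
#'   (`smv_assoc_ids`, driver, variance components).
#' @export
simulate_methylation <- function(spec, popmap, climate, n_sites = 2000,
                                 n_assoc = 20, effect = 1, noise_sd = 0.5,
                                 sigma_g = 0.5, depth_mean = 12,
                                 depth_size = 5, per_pop = 1) {
  if (n_assoc > n_sites) stop("n_assoc exceeds n_sites")
  pops <- popmap$sites$population
  n_pops <- length(pops)
  samples <- unlist(lapply(pops, function(p)
    sprintf("%s_M%d", p, seq_len(per_pop))))
  pop_idx <- rep(seq_len(n_pops), each = per_pop)
  n_ind <- length(samples)
  z <- as.numeric(scale(climate$values[pops, spec$driver]))
  # spatial kinship of the population random effect
  d <- geographic_distance(popmap, log_transform = FALSE)
  rng <- median(d[upper.tri(d)])
  Sig <- exp(-d / max(rng, 1e-6))
  Rt <- chol(Sig + diag(1e-8, n_pops))
  with_seed(spec$seed * 13 + 3, {
    base <- rnorm(n_sites, qlogis(0.3), 1.2)
    assoc_idx <- if (n_assoc > 0) sort(sample.int(n_sites, n_assoc)) else integer(0)
    u <- crossprod(Rt, matrix(rnorm(n_pops * n_sites), n_pops)) * sigma_g
    lat <- matrix(base, n_ind, n_sites, byrow = TRUE) +
      u[pop_idx, , drop = FALSE] +
      matrix(rnorm(n_ind * n_sites, 0, noise_sd), n_ind)
    if (length(assoc_idx))
      lat[, assoc_idx] <- lat[, assoc_idx] +
        outer(z[pop_idx], rep(effect, length(assoc_idx)))
    pr <- plogis(lat)
    depth <- matrix(rnbinom(n_ind * n_sites, mu = depth_mean,
                            size = depth_size), n_ind)
    level <- matrix(NA_real_, n_ind, n_sites)
    pos <- depth > 0
    level[pos] <- rbinom(sum(pos), depth[pos], pr[pos]) / depth[pos]
    sites <- data.frame(chrom = paste0("scaf_", ((seq_len(n_sites) - 1L) %/% 500L) + 1L),
                        pos0 = ((seq_len(n_sites) - 1L) %% 500L) * 200L,
                        context = sample(c("CpG", "CHG", "CHH"), n_sites,
                                         replace = TRUE,
                                         prob = c(0.5, 0.3, 0.2)),
                        stringsAsFactors = FALSE)
    mt <- methylation_table(level, depth, samples, sites)
    truth <- list(smv_assoc_ids = colnames(mt$level)[assoc_idx],
                  driver = spec$driver,
                  sigma_g2 = sigma_g^2, sigma_e2 = noise_sd^2,
                  sample_population = setNames(pops[pop_idx], samples))
    list(methylation = mt, truth = truth)
  })
}
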