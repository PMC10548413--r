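# Independent oracle implementations and small fixture builders.  Each
# oracle is a deliberately naive, loop-based transcription of the textbook
# formula, kept separate from the package's vectorized code paths.

# --- Weir & Cockerham (1984) variance components, scalar per-locus loop ---
# geno_by_pop: list of per-population dosage vectors (0/1/2/NA), one locus.
wc_oracle_locus <- function(geno_by_pop) {
  geno_by_pop <- lapply(geno_by_pop, function(g) g[!is.na(g)])
  geno_by_pop <- geno_by_pop[vapply(geno_by_pop, length, 1L) > 0]
  r <- length(geno_by_pop)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  ni <- vapply(geno_by_pop, length, numeric(1))
  pi <- vapply(geno_by_pop, function(g) sum(g) / (2 * length(g)), numeric(1))
  hi <- vapply(geno_by_pop, function(g) mean(g == 1), numeric(1))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# multilocus theta (ratio of sums) from a dosage matrix + population factor
wc_oracle_theta <- function(dosage, pop) {
  comps <- sapply(seq_len(ncol(dosage)), function(l)
    wc_oracle_locus(split(dosage[, l], pop)))
  ok <- !is.na(comps[1, ])
  sum(comps[1, ok]) / sum(comps[, ok])
}

# --- explicit-loop D statistic with delete-one block jackknife ---
dstat_oracle <- function(p1, p2, p3, block) {
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  d_of <- function(keep)
    (sum(abba[keep]) - sum(baba[keep])) / (sum(abba[keep]) + sum(baba[keep]))
  blocks <- unique(block)
  B <- length(blocks)
  d <- d_of(rep(TRUE, length(p1)))
  loo <- numeric(B)
  for (i in seq_len(B)) loo[i] <- d_of(block != blocks[i])
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(d = d, se = se, z = d / se)
}

# --- direct haversine (km), Earth radius 6371.0088 km ---
haversine_oracle <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371.0088 * asin(sqrt(a))
}

# --- small random genotype fixture ---
random_genotypes <- function(n_pops = 3, n_per = 5, n_loci = 4,
                             missing = 0, seed = 1) {
  set.seed(seed)
  pops <- LETTERS[seq_len(n_pops)]
  samples <- paste0(rep(pops, each = n_per), "_", seq_len(n_per))
  dos <- matrix(sample(0:2, length(samples) * n_loci, replace = TRUE),
                length(samples))
  if (missing > 0) dos[runif(length(dos)) < missing] <- NA
  # guarantee every locus polymorphic and every pop partly genotyped
  dos[1, ] <- 0L; dos[2, ] <- 2L
  g <- genotype_matrix(dos, samples, rep("chr1", n_loci),
                       seq_len(n_loci) * 100L)
  sites <- data.frame(population = pops,
                      longitude = seq(110, 119, length.out = n_pops),
                      latitude = seq(24, 29, length.out = n_pops),
                      altitude = 500)
  map <- population_map(setNames(rep(pops, each = n_per), samples), sites)
  list(g = g, map = map, pop = factor(rep(pops, each = n_per)))
}

# --- toy VCF writer ---
write_toy_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
}

vcf_record <- function(chrom, pos, ref, alt, gts)
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")

default_spec <- function(...) landscape_spec(...)
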