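# Shared setup for the analysis drivers.  Every script regenerates its
# inputs deterministically from this spec (the generators are pure
# functions of the seed), so the drivers can be run independently;
# 01_simulate.R additionally writes the data products to disk for
# inspection.

library(climadapt)

MASTER_SEED <- 20260924L
RESULTS <- "results"

spec <- landscape_spec(seed = MASTER_SEED)   # 13 pops x 12, F = .193,
                                             # 5000 neutral + 50 clinal loci
land <- simulate_landscape(spec)
outdir <- function(...) {
  d <- file.path(RESULTS, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

genotypes <- function() {
  suppressMessages(simulate_genotypes(spec, land$popmap, land$current))
}

methylation <- function() {
  simulate_methylation(spec, land$popmap, land$current,
                       n_sites = 1000, n_assoc = 10, effect = 3,
                       noise_sd = .2, sigma_g = .3,
                       depth_mean = 60, depth_size = 20)
}
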