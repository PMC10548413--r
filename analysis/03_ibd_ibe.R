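#!/usr/bin/env Rscript
# Isolation by distance and by environment: climate-variable
# pre-selection at |r| < .8, environmental distance on the first three
# principal components, Mantel IBD on linearized F_ST vs log great-circle
# distance, and partial Mantel IBE controlling for geography.

source("analysis/00_common.R")
d <- outdir("landscape")

sim <- genotypes()
fst <- wc_fst(sim$genotypes, land$popmap)
gen <- linearize_fst(fst$theta)

kept <- select_uncorrelated(land$current, r_max = .8)
message("variables retained at |r| < .8: ", paste(kept, collapse = ", "))

geo <- geographic_distance(land$popmap, log_transform = TRUE)
env <- environmental_distance(land$current, n_pc = 3)
message("first 3 climate PCs explain ",
        round(100 * sum(attr(env, "explained")[1:3]), 1), "% of variance")

ibd <- mantel(gen, geo, n_perm = 9999, seed = MASTER_SEED)
ibe <- partial_mantel(gen, env, geo, n_perm = 9999, seed = MASTER_SEED)
per_var <- lapply(kept, function(v) {
  dv <- as.matrix(dist(scale(land$current$values[, v])))
  dimnames(dv) <- list(land$current$sites, land$current$sites)
  m <- mantel(gen, dv, n_perm = 9999, seed = MASTER_SEED)
  data.frame(test = paste0("IBE_", v), r = m$r, p = m$p)
})

res <- rbind(data.frame(test = "IBD", r = ibd$r, p = ibd$p),
             data.frame(test = "IBE_partial", r = ibe$r, p = ibe$p),
             do.call(rbind, per_var))
write_table(res, file.path(d, "mantel.tsv"))
message("IBD: r = ", round(ibd$r, 3), ", p = ", signif(ibd$p, 3),
        "; partial IBE: r = ", round(ibe$r, 3), ", p = ",
        signif(ibe$p, 3))
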