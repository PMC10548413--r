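#!/usr/bin/env Rscript
# Population diversity and structure: per-population pi / H_O / F_IS,
# global and pairwise Weir-Cockerham F_ST, and PCoA on linearized F_ST.

source("analysis/00_common.R")
d <- outdir("popgen")

sim <- genotypes()
G <- sim$genotypes

div <- diversity_stats(G, land$popmap)
write_table(div, file.path(d, "diversity.tsv"))

fst <- wc_fst(G, land$popmap)
pairs <- which(upper.tri(fst$theta), arr.ind = TRUE)
write_table(data.frame(pop1 = fst$populations[pairs[, 1]],
                       pop2 = fst$populations[pairs[, 2]],
                       theta = fst$theta[pairs]),
            file.path(d, "fst_pairwise.tsv"))
write_table(fst$per_locus, file.path(d, "fst_per_locus.tsv"))

pc <- pcoa(linearize_fst(fst$theta), k = 2)
write_table(data.frame(population = rownames(pc$coords),
                       axis1 = pc$coords[, 1], axis2 = pc$coords[, 2]),
            file.path(d, "pcoa.tsv"))

message("global F_ST = ", round(fst$global_theta, 4),
        " (generator target ", spec$fst_target, ")")
message("pairwise F_ST range: ",
        round(min(fst$theta[pairs]), 3), " - ",
        round(max(fst$theta[pairs]), 3))
message("PCoA axis-1 explains ",
        round(100 * pc$explained[1], 1), "% of positive inertia")
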