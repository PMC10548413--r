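#!/usr/bin/env Rscript
# Generate the synthetic study system: 13 populations x 12 diploids on
# the kiwifruit site layout, five bioclimatic variables on spatial
# gradients, 5000 neutral + 50 climate-clinal loci at global F_ST 0.193,
# and a 13-sample methylation panel with 10 planted climate-associated
# sites.  Writes the data products and the ground truth.

source("analysis/00_common.R")
d <- outdir("data")

sim <- genotypes()
G <- sim$genotypes
me <- methylation()

write_table(data.frame(sample = names(land$popmap$assignments),
                       population = unname(land$popmap$assignments)),
            file.path(d, "popmap.tsv"))
write_table(land$popmap$sites, file.path(d, "sites.tsv"))
write_table(data.frame(site = land$current$sites, land$current$values),
            file.path(d, "climate_current.tsv"))
for (sc in names(land$futures))
  write_table(data.frame(site = land$futures[[sc]]$sites,
                         land$futures[[sc]]$values),
              file.path(d, paste0("climate_", sc, ".tsv")))
write_table(data.frame(sample = G$samples, as.data.frame(G$dosage)),
            file.path(d, "genotypes.tsv"))
write_table(data.frame(locus = colnames(G$dosage),
                       adaptive = colnames(G$dosage) %in%
                         sim$truth$adaptive_locus_ids),
            file.path(d, "truth_loci.tsv"))
write_table(data.frame(site = colnames(me$methylation$level),
                       associated = colnames(me$methylation$level) %in%
                         me$truth$smv_assoc_ids),
            file.path(d, "truth_smvs.tsv"))

message("wrote synthetic data: ", length(G$samples), " samples x ",
        nrow(G$loci), " loci; ", ncol(me$methylation$level),
        " methylation sites; missing dosage fraction ",
        round(mean(is.na(G$dosage)), 4))
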