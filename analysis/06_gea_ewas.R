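#!/usr/bin/env Rscript
# Kinship-corrected association scans: LMM-GEA of genotype dosage vs each
# climate variable (BH q <= .05), and methylation EWAS with per-variable
# permutation thresholds (200 repeats), plus 10-kb proximity annotation
# of the hits against a synthetic exon model.

source("analysis/00_common.R")
d <- outdir("association")

sim <- genotypes()
G <- sim$genotypes
truth <- sim$truth$adaptive_locus_ids

gea <- suppressMessages(gea_scan(G, land$current, land$popmap))
write_table(gea$hits, file.path(d, "gea_hits.tsv"))
write_table(data.frame(variable = names(gea$per_variable),
                       n_hits = as.integer(gea$per_variable)),
            file.path(d, "gea_per_variable.tsv"))
message("GEA hits per variable: ",
        paste(names(gea$per_variable), gea$per_variable, sep = "=",
              collapse = ", "))
message("power on planted ", spec$driver, "-clinal loci: ",
        round(100 * mean(truth %in% gea$hits$marker), 1), "%")

# EWAS with permutation thresholds
me <- methylation()
smv <- call_smvs(me$methylation)
message("SMV filter log: ",
        paste(names(smv$filter_log), smv$filter_log, sep = "=",
              collapse = ", "))
K <- kinship(smv$level, "methylation")
spp <- me$truth$sample_population
thr <- sapply(land$current$variables, function(v) {
  y <- land$current$values[spp[smv$samples], v]
  permutation_threshold(y, smv$level, K, n_repeats = 200,
                        subset_size = 500, alpha = .05,
                        seed = MASTER_SEED + 4L)$threshold
})
write_table(data.frame(variable = names(thr), threshold = unname(thr)),
            file.path(d, "ewas_thresholds.tsv"))
ew <- ewas_scan(smv, land$current, spp, thresholds = as.list(thr), K = K)
write_table(ew$hits, file.path(d, "ewas_hits.tsv"))
kept <- intersect(me$truth$smv_assoc_ids, colnames(smv$level))
message(nrow(ew$hits), " EWAS hits; planted-site recovery ",
        round(100 * mean(kept %in% ew$hits$marker), 1), "%")

# proximity annotation of GEA hits against a synthetic exon model
chroms <- unique(G$loci$chrom)
feats <- do.call(rbind, lapply(chroms, function(ch) {
  starts <- seq(0L, max(G$loci$pos0[G$loci$chrom == ch]), by = 20000L)
  data.frame(chrom = ch, start0 = starts, end0 = starts + 2000L)
}))
ft <- feature_table(feats$chrom, feats$start0, feats$end0,
                    sprintf("exon_%05d", seq_len(nrow(feats))))
hit_loci <- unique(gea$hits$marker)
li <- match(hit_loci, colnames(G$dosage))
ann <- annotate_proximal(data.frame(marker = hit_loci,
                                    chrom = G$loci$chrom[li],
                                    pos0 = G$loci$pos0[li]), ft)
write_table(ann$annotated, file.path(d, "gea_annotation.tsv"))
message(length(unique(ann$annotated$feature)),
        " synthetic exons within 10 kb of a GEA hit")
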